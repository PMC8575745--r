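---
title: "Functional clustering of mortality age-at-death distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional clustering of mortality age-at-death distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The setting

A period life table summarises the mortality of a population in one year. Its
`dx` column is the *age distribution of deaths*: out of a synthetic cohort of
100,000 births (the radix), `dx` gives the number dying at each age
0, 1, ..., 110, with the open group "110+" closing the table. Viewed over age,
`dx` is a curve with up to three recognisable components: a spike at age 0
(infant mortality), a broad hump roughly between ages 20 and 65 (premature
mortality, dominated by accidents, violence, alcohol and early disease), and a
bell-shaped peak around the adult modal age at death. Over the last sixty
years the story of low-mortality countries has largely been the erosion of
the first two components and the displacement of the third: the adult mode
moves to older ages (*shifting*) while deaths concentrate around it
(*compression*).

`mortfda` treats each (country, year, sex) `dx` curve as a functional
observation and asks which curves look alike: it smooths the discrete counts
into functions, summarises them by functional principal component analysis
(FPCA), and clusters them by three methods whose agreement — or disagreement
— is itself informative. Sexes are never pooled and every year is treated as
an independent curve; trajectories through time are read off afterwards from
the country-by-year membership table.

## From counts to curves

Each observed curve $y_{ij} = x_i(t_j) + \epsilon_{ij}$ is represented by a
cubic B-spline expansion $x_i(t) = \sum_{j=1}^p \gamma_{ij}\,\psi_j(t)$, with
coefficients estimated by penalized least squares:

$$\min_\gamma \; \sum_j \left[y_{ij} - x_i(t_j)\right]^2 +
  \lambda \int_0^{110} \left[x_i''(t)\right]^2 \mathrm{d}t .$$

The solution is the closed form
$\hat\gamma = (\Psi'\Psi + \lambda R)^{-1}\Psi' y$, where $R$ is the matrix of
integrated products of second derivatives. $R$ and the basis Gram matrix $W$
(integrated products of the basis functions themselves) are computed by
per-interval Gauss–Legendre quadrature of sufficient order, so both are exact
for the piecewise-polynomial integrands, not approximations.

Two knot schemes are built in. `dense111` places one knot per age. The
default, `sparse31`, uses quarterly knots over ages 0–2 — where the infant
drop concentrates almost all the curvature — and five-yearly knots
thereafter (7, 12, ..., 107), closing with a knot at 110 so the basis domain
ends with the data. That is 31 breakpoints and $p = 33$ basis functions. The
five-yearly sequence started from age 2 does not land on 110 by itself; we
place the final knot there deliberately and accept the slightly longer last
interval (107–110). The sparse scheme is preferred both for parsimony and
because the dense one, with more coefficients than it needs, tends to chase
noise around the steep infant segment and can manufacture a second mode.

All curves share one set of knots: cluster analysis on basis coefficients is
only meaningful when every curve is expressed in the same basis. Observations
are equally weighted (death *counts* from a fixed radix carry no natural
heteroscedastic weighting of the kind rate data would). Fitted curves are
*not* renormalized back to the radix — smoothing slightly redistributes mass,
and the row sums are kept as a diagnostic (`tidy()` on the smoothed object)
rather than corrected away. Fits are unconstrained splines, so small negative
excursions at extreme ages can occur and are tolerated.

The roughness weight $\lambda$ is chosen by generalized cross-validation,
$\mathrm{GCV}(\lambda) = N\,\mathrm{SSE}/(N - \mathrm{df}(\lambda))^2$ with
df the trace of the hat matrix, minimised over a log-spaced grid
($10^{-6}$ to $10^4$, 41 points — wide enough that the ends are never
attractive for real curves). Ties break toward the larger (smoother)
$\lambda$. Both a per-curve $\lambda$ and a single common $\lambda$ (default
0.0025) are supported; on synthetic panels the downstream clusterings agree
(ARI ≥ 0.9), so the choice is not critical, and the per-curve mode is the
default.

## FPCA in coefficient space

With all curves in one basis, the sample covariance function is
$S(s,t) = \psi(s)'\,\Sigma\,\psi(t)$ with $\Sigma$ the (1/(n−1))-divisor
covariance of the coefficient vectors. Its eigenfunctions are found by the
generalized eigenproblem $\Sigma W u = \lambda u$, symmetrised through the
Cholesky factor of $W$ — the exact finite-dimensional counterpart of the
functional eigenequation, with the Gram metric rather than raw coefficients
(the alternative, treating coefficients as Euclidean data, distorts distances
whenever the basis functions overlap unevenly, as they do here with mixed
knot spacing). Scores are inner products of *mean-centered* curves with the
eigenfunctions. Centering matters: score trajectories are read against the
mean curve (a country crossing zero on a component is passing the
cross-national average), which is only true of centered scores.

Eigenfunction signs are arbitrary; we fix them deterministically so that
adding an eigenfunction to the mean *lowers* the mean age at death
($\langle t, \phi_l\rangle \le 0$). Under this convention a curve whose adult
mode sits at younger ages scores positively on the shift/compression
component, so trajectories of modernising countries drift from positive to
negative — the orientation used throughout the plots. We anchor the sign on
this integral rather than on the function's values over the younger half of
the age range because the leading components are often nearly null there,
which would make that anchor numerically unstable.

The harmonic-variation display evaluates $\bar x \pm 2\sqrt{\lambda_l}\,
\phi_l$. On synthetic panels where only the old-age peak's location and
spread vary, the first component carries ≥ 80% of the variance and its
(+)/(−) curves differ almost entirely above age 60 — the shift/compression
reading. Adding premature-mortality variation introduces a component whose
(+) and (−) curves cross near the boundary between the hump ages and the
adult ages: deaths added before the boundary are deaths removed after it,
because a death distribution conserves its mass.

One caution from the synthetic experiments: a *large* shift (say a 14-year
spread of modal ages) is visibly nonlinear in curve space, and its quadratic
part forms its own eigencomponent that correlates with no single generator
parameter. The premature-mortality component emerges as the second component
only when shift variation is moderate relative to hump variation, which is
the empirically relevant regime for the male data. The component-semantics
experiment therefore uses a 78–86 modal-age window once hump variation is
added.

## Three clustering routes

**Two-stage.** k-means on the rows of the coefficient matrix (filtering =
basis expansion, clustering = k-means), with k-means++ seeding and 50
restarts under an explicit seed. By default it runs on raw coefficients, as
in the original two-stage proposal; `use_metric = TRUE` first maps
coefficients through the Cholesky factor of $W$ so Euclidean distance equals
$L_2$ distance between curves.

**Distance-based.** The FPCA semimetric
$d_q(x_i, x_{i'}) = \left(\sum_{k\le q} (c_{ik}-c_{i'k})^2\right)^{1/2}$
— exactly the Euclidean distance between leading score vectors, and exactly
zero for curves whose difference lies beyond harmonic $q$ (hence a
*semi*metric). Agglomerative clustering cuts the tree at $K$; the default
Ward criterion on squared semimetric distances (`ward.D2`) follows standard
practice, with complete and average linkage as options. Default $q = 6$,
enough components to span all three mortality components with headroom.
Hierarchical clustering is deterministic; no seed is involved.

**Model-based (FLM).** Coefficients (in the Gram metric) follow a Gaussian
mixture whose $k$-th covariance is
$\Sigma_k = Q_k\,\mathrm{diag}(a_{k1},\dots,a_{kd_k}, b,\dots,b)\,Q_k'$:
each cluster concentrates near a $d_k$-dimensional latent subspace with
signal variances $a_{kj}$ and isotropic residual variance $b$. The common-$b$
variant is the default — one data-generating process, one noise level — with
per-cluster $b_k$ as an option. Estimation is EM: posteriors in the E-step
(log-sum-exp stabilised), weighted means, per-cluster eigendecompositions
and pooled trailing eigenvalues in the M-step. Intrinsic dimensions are
chosen by a Cattell scree test (threshold 0.2 on normalised eigenvalue drops)
on the initial k-means partition and then held fixed, which keeps the
likelihood exactly monotone — a property asserted at every iteration. EM runs
from 10 seeded k-means initializations by default, keeps the best final
likelihood, and replaces any run in which a cluster collapses (expected
size below one curve) with a fresh initialization.

Model choice uses BIC in the higher-is-better convention,
$\mathrm{BIC} = \ell - \tfrac{m}{2}\log n$, with $m$ the free-parameter
count: $(K-1)$ proportions, $Kp$ means, $\sum_k [d_k p - d_k(d_k+1)/2]$
loading parameters, $\sum_k d_k$ signal variances, and 1 (or $K$) noise
variances. `select_n_clusters()` scans a range of $K$ and flags *local
maxima* of the BIC curve rather than auto-committing to the argmax: in
practice the curve can rise again at large $K$ for spurious reasons, and the
working rule — adopt a local maximum, especially when complexity grows
steeply beyond it — is a documented, overridable policy (`policy =
"argmax"` disables it). Labels across methods or runs are aligned by exact
permutation matching on $L_2$ distances between cluster mean curves, and all
cross-run comparisons use the adjusted Rand index.

## The synthetic cohort generator

`cohort_scenario()` fixes a three-component mixture: a truncated exponential
on ages 0–2 carrying `infant_mass`, a bounded bump at (`hump_loc`,
`hump_scale`) carrying `hump_mass`, and a truncated bell at (`mode_age`,
`mode_sd`) carrying the rest. Components are discretized on bins centred at
integer ages and each is renormalized so the three masses are *exact* targets
— the kernels are chosen for interpretability and controllability, not
biological fidelity (no Gompertz tail, no parametric mortality law).
Multiplicative log-normal noise with unit mean and coefficient of variation
`noise_cv` is applied per age and the curve renormalized, so curves stay
non-negative and always sum exactly to the radix. `generate_panel()` draws
labelled panels with Gaussian jitter on scenario parameters.

The standard three-regime panel (`regime_scenarios()`) emulates the
qualitative regimes observed across developed countries: high infant
mortality with an early mode (infant 4%, mode 76); a pronounced premature
hump with a depressed mode (hump 12%, mode 74); and a late, compressed peak
(infant 0.5%, mode 87, sd 5.5). Defaults: 20 curves per regime, `noise_cv =
0.05`, jitter of 0.8 years on the mode, 0.3 on its spread and sub-percent
jitter on the masses — heterogeneity comparable to neighbouring years of one
country. On this panel all three clustering methods recover the truth with
ARI ≥ 0.95, which is the package's cross-method agreement check.

What the generator does *not* emulate: temporal autocorrelation within a
country (real adjacent years are far more similar than independent draws),
age-dependent noise (real `dx` noise scales with counts), cohort effects, and
heaping or data-quality artefacts. Passing the recovery tests therefore shows
the methods work when clusters exist and noise is benign; it does not certify
behaviour on real registration data.

## Numerical choices and problem sizes

Quadrature is exact per knot interval (Golub–Welsch Gauss–Legendre), so
penalty/Gram matrices, score integrals and the FPCA oracle comparisons are
limited only by floating point. The penalized solve uses a Cholesky
factorisation; at $\lambda = 0$ with $p > N$ the system is singular and the
error says so. GCV treats a residual below $10^{-15}$ of the signal's energy
as exactly zero, so noiseless data selects the smoothest candidate instead of
amplifying floating-point dust. Zero eigenvalues make `harmonic_variation()`
return the mean twice with a warning. EM tolerances: relative log-likelihood
change below $10^{-6}$ or 200 iterations; a likelihood decrease beyond
$10^{-6}$ relative is raised as an error rather than papered over.

The validation experiments are sized to run on a laptop in minutes: recovery
simulations use 400 observations in $p = 15$ dimensions (20 replicates),
cluster-number scans use 300 observations over $K = 2..5$, and the panel
experiments use 40–60 curves. These sizes give comfortably stable results
for the properties tested (for instance, eigenvalue estimates at $n_k = 200$
fluctuate by ~10%, which is why parameter recovery is judged on the mean
relative error across variance parameters rather than the worst single one).

## Worked example

```{r, eval = FALSE}
library(mortfda)

panel <- generate_panel(regime_scenarios(), n_per_cluster = 20,
                        jitter = regime_jitter(), seed = 1)
sm <- smooth_curves(panel$curves)            # sparse31 basis, per-curve GCV
fp <- fit_fpca(sm, q = 6)
glance(fp)                                   # variance proportions

flm <- fit_flm(sm, K = 3, seed = 1)
tidy(flm$assignment)                         # labels + posteriors
adjusted_rand_index(flm$assignment$labels, panel$labels)

autoplot(fp)                                 # harmonic-variation panels
plot_membership(flm$assignment)              # country x year cluster map
```

For file-driven work, `run_pipeline()` takes a `run_config()` (or a YAML
file), runs read/simulate → smooth → FPCA → cluster, and writes tidy CSVs
plus a manifest of seeds and file hashes; identical configuration and seed
reproduce byte-identical artifacts. Human Mortality Database period life
tables (1×1 layout) are read with `read_hmd_lifetable()`; the database
requires registration, so no data ships with the package and the synthetic
generator stands in for it everywhere in the tests.

## Known limitations

- The FLM tail model (isotropic residual variance) is deliberately simple;
  on curve panels whose within-cluster spectra decay smoothly, BIC can
  favour splitting a true cluster at small $n$. The local-maximum reading of
  the BIC curve, not its argmax, is the recommended policy.
- Intrinsic dimensions are frozen after initialization; data whose cluster
  structure only emerges late in EM could in principle deserve re-selection,
  at the cost of the monotonicity guarantee.
- Smoothing is unconstrained: no monotonicity, positivity or unimodality is
  enforced.
- The semimetric inherits FPCA's global basis: two curves differing only in
  directions beyond harmonic $q$ are indistinguishable to the
  distance-based method by construction.
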