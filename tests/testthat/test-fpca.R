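# Functional PCA: degenerate inputs, oracle equivalence with grid-weighted
# multivariate PCA, score quadrature, reconstruction identities and the
# harmonic-variation display.

# weighted multivariate PCA of smoothed curves evaluated at exact quadrature
# nodes: the independent dense-grid route to the same eigenstructure
dense_pca_oracle <- function(sm) {
  quad <- mortfda:::basis_quadrature(sm$basis)
  X <- eval_curves(sm, at = quad$nodes)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc %*% diag(sqrt(quad$weights)))
  list(values = sv$d^2 / (nrow(X) - 1),
       total = sum(quad$weights * apply(X, 2, stats::var)),
       scores = Xc %*% diag(sqrt(quad$weights)) %*% sv$v)
}

test_that("identical curves give zero eigenvalues and the common mean", {
  dx <- generate_dx(cohort_scenario(), seed = 1)
  cs <- curve_set(rbind(dx, dx, dx),
                  index = tibble::tibble(country = letters[1:3], year = 1:3,
                                         sex = "t"),
                  radix_tol = 1e-6)
  sm <- smooth_curves(cs)
  expect_warning(fp <- fit_fpca(sm, q = 2), "zero-variance")
  expect_true(all(fp$eigenvalues < 1e-6 * sum(sm$coef[1, ]^2)))
  expect_equal(fp$mean_coef, sm$coef[1, ], ignore_attr = TRUE)
})

test_that("a rank-1 family concentrates all variance on one harmonic", {
  b <- bspline_basis()
  base <- penalized_fit(generate_dx(cohort_scenario()), b, 1)$coef
  dir <- penalized_fit(generate_dx(cohort_scenario(mode_age = 90)), b,
                       1)$coef - base
  amps <- c(-2, -1, 0, 1, 2)
  coef <- t(sapply(amps, function(a) base + a * dir))
  sm <- structure(list(basis = b, coef = coef,
                       lambda = rep(1, 5), gcv = rep(NA_real_, 5),
                       df = rep(NA_real_, 5), sse = rep(NA_real_, 5),
                       fitted = coef %*% t(eval_basis(b, 0:110)),
                       fitted_mass = rep(NA_real_, 5), ages = 0:110,
                       index = tibble::tibble(country = letters[1:5],
                                              year = 1:5, sex = "t"),
                       lambda_mode = "common"),
                  class = "smoothed_curves")
  fp <- fit_fpca(sm, q = 3)
  expect_equal(fp$varprop[1], 1, tolerance = 1e-10)
  expect_lt(fp$eigenvalues[2] / fp$eigenvalues[1], 1e-12)
})

test_that("coefficient-space FPCA equals dense-grid weighted PCA", {
  fx <- regime_fixture()
  sm <- fx$smoothed
  fp <- fit_fpca(sm, q = 6)
  oracle <- dense_pca_oracle(sm)
  keep <- 1:6
  expect_lt(max(abs(fp$eigenvalues[keep] - oracle$values[keep]) /
                  oracle$values[keep]), 1e-6)
  # scores agree up to the (arbitrary) sign of each eigenvector
  for (l in keep) {
    agree <- min(max(abs(fp$scores[, l] - oracle$scores[, l])),
                 max(abs(fp$scores[, l] + oracle$scores[, l])))
    expect_lt(agree / stats::sd(fp$scores[, l]), 1e-6)
  }
  # eigenvalue sum conserves the total integrated variance
  expect_lt(abs(sum(fp$eigenvalues) - oracle$total) / oracle$total, 1e-8)
})

test_that("eigenfunctions are L2-orthonormal and scores are centered with
           variance lambda", {
  fx <- regime_fixture()
  fp <- fit_fpca(fx$smoothed, q = 5)
  G <- t(fp$harmonics) %*% fx$smoothed$basis$gram %*% fp$harmonics
  expect_lt(max(abs(G - diag(5))), 1e-8)
  expect_lt(max(abs(colMeans(fp$scores))) / sqrt(fp$eigenvalues[1]), 1e-8)
  expect_equal(apply(fp$scores, 2, stats::var), fp$eigenvalues[1:5],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(fp$varprop), 1, tolerance = 1e-12)
})

test_that("scores behave as inner products: mean scores zero, shifted mean
           recovers its amplitude", {
  fx <- regime_fixture()
  sm <- fx$smoothed
  fp <- fit_fpca(sm, q = 3)
  mk_sm <- function(coef) {
    s <- sm
    s$coef <- coef
    s$index <- sm$index[seq_len(nrow(coef)), ]
    s
  }
  # the mean curve itself scores 0 on every harmonic
  sm_mean <- mk_sm(matrix(fp$mean_coef, 1))
  for (l in 1:3) expect_lt(abs(fpca_scores(sm_mean, fp, l)),
                           1e-8 * sqrt(fp$eigenvalues[1]))
  # mean + 3 * phi_2 scores (0, 3, 0)
  sm_shift <- mk_sm(matrix(fp$mean_coef + 3 * fp$harmonics[, 2], 1))
  expect_equal(fpca_scores(sm_shift, fp, 2), 3, tolerance = 1e-8)
  expect_lt(abs(fpca_scores(sm_shift, fp, 1)), 1e-6)
  expect_lt(abs(fpca_scores(sm_shift, fp, 3)), 1e-6)
  expect_error(fpca_scores(sm_shift, fp, 9), "l must")
})

test_that("scores match trapezoid-rule integration on a 0.1-year grid", {
  fx <- regime_fixture()
  sm <- fx$smoothed
  fp <- fit_fpca(sm, q = 4)
  grid <- seq(0, 110, by = 0.1)
  w <- c(0.05, rep(0.1, length(grid) - 2), 0.05)
  B <- eval_basis(sm$basis, grid)
  Xc <- sweep(eval_curves(sm, at = grid), 2, drop(B %*% fp$mean_coef))
  scale <- max(abs(fp$scores)) # typical score magnitude
  for (l in 1:4) {
    phi <- drop(B %*% fp$harmonics[, l])
    trap <- drop(Xc %*% (w * phi))
    expect_lt(max(abs(trap - fp$scores[, l])) / scale, 1e-4)
  }
})

test_that("Karhunen-Loeve truncation error is nested and matches the
           eigenvalue tail identity", {
  fx <- regime_fixture()
  sm <- fx$smoothed
  n <- nrow(sm$coef)
  fp <- fit_fpca(sm, q = sm$basis$p)
  errs <- vapply(0:6, function(q) reconstruction_error(sm, fp, q),
                 numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  # full-rank reconstruction is exact relative to the total variance
  full <- reconstruction_error(sm, fp, sm$basis$p)
  expect_lt(full / fp$total_variance, 1e-8)
  # error at q equals (n-1)/n times the eigenvalue tail
  for (q in c(1, 3)) {
    tail_id <- sum(fp$eigenvalues[-seq_len(q)]) * (n - 1) / n
    expect_equal(errs[q + 1], tail_id, tolerance = 1e-8)
  }
})

test_that("harmonic-variation curves are symmetric about the mean and
           degenerate gracefully", {
  fx <- regime_fixture()
  fp <- fit_fpca(fx$smoothed, q = 3)
  hv <- harmonic_variation(fp, 1)
  expect_equal((hv$plus + hv$minus) / 2, hv$mean, tolerance = 1e-10)
  hv0 <- harmonic_variation(fp, 1, multiple = 0)
  expect_equal(hv0$plus, hv0$mean)
  expect_equal(hv0$minus, hv0$mean)
})

test_that("with only the old-age peak varying, the first harmonic acts
           above age 60", {
  set.seed(77)
  n <- 30
  modes <- seq(76, 90, length.out = n)
  sds <- rep(seq(5, 7.5, length.out = 6), 5)
  curves <- t(vapply(seq_len(n), function(i) {
    generate_dx(cohort_scenario(mode_age = modes[i], mode_sd = sds[i],
                                infant_mass = 0.02, noise_cv = 0.03),
                seed = 300 + i)
  }, numeric(111)))
  cs <- curve_set(curves, index = tibble::tibble(country = paste0("c", 1:n),
                                                 year = 1:n, sex = "t"),
                  radix_tol = 1e-6)
  fp <- fit_fpca(smooth_curves(cs), q = 2)
  hv <- harmonic_variation(fp, 1, at = seq(0, 110, by = 0.25))
  d2 <- (hv$plus - hv$minus)^2
  mass_above_60 <- sum(d2[hv$age > 60]) / sum(d2)
  expect_gt(mass_above_60, 0.8)
})

test_that("tidy and glance expose scores and variance proportions", {
  fx <- regime_fixture()
  fp <- fit_fpca(fx$smoothed, q = 2)
  td <- tidy(fp)
  expect_true(all(c("country", "year", "score_1", "score_2") %in% names(td)))
  expect_equal(nrow(td), n_curves(fx$panel$curves))
  gl <- glance(fp)
  expect_equal(gl$varprop_1 + gl$varprop_2,
               sum(fp$varprop[1:2]), tolerance = 1e-12)
})
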