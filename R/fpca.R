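# Functional principal component analysis of smoothed curves, carried out in
# B-spline coefficient space under the L2 metric induced by the basis Gram
# matrix W:
#   covariance  S(s,t) = psi(s)' Sigma psi(t),  Sigma = C'C / (n - 1)
#   eigenproblem  Sigma W u = lambda u  (u = basis coefficients of phi),
# symmetrized through the Cholesky factor of W. Eigenfunctions are orthonormal
# in L2; scores are L2 inner products of centered curves with eigenfunctions.

#' Fit a functional PCA to smoothed curves
#'
#' @param smoothed A [smooth_curves()] result.
#' @param q Number of harmonics (eigenfunctions) to retain, `1 <= q <= p`.
#' @param center Scores are computed on mean-centered curves (the default and
#'   the convention used throughout: score trajectories then cross zero at the
#'   mean curve).
#' @return An object of class `mortality_fpca`: `mean_coef`, `eigenvalues`
#'   (all p, descending), `harmonics` (p x q coefficient matrix of phi_l),
#'   `scores` (n x q), `varprop` (fractions of total variance, all p),
#'   `total_variance` (the integrated variance, equal to the eigenvalue sum),
#'   `basis`, `index`, `ages`.
#'
#' @details Each eigenfunction's sign is fixed deterministically: phi_l is
#'   oriented so that adding it to the mean *lowers* the mean age at death
#'   (its inner product with the identity function t is <= 0). Under this
#'   convention a curve whose adult mode sits at younger ages scores
#'   positively on the shift/compression component.
#' @export
fit_fpca <- function(smoothed, q = 6L, center = TRUE) {
  stopifnot(inherits(smoothed, "smoothed_curves"))
  n <- nrow(smoothed$coef)
  p <- smoothed$basis$p
  if (n < 2) stop("FPCA needs at least 2 curves")
  if (q < 1 || q > p) stop("q must lie in [1, p = ", p, "]")
  W <- smoothed$basis$gram
  L <- t(chol(W)) # W = L L'
  mean_coef <- colMeans(smoothed$coef)
  C <- sweep(smoothed$coef, 2, mean_coef)
  Sigma <- crossprod(C) / (n - 1)
  A <- t(L) %*% Sigma %*% L
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  # u = L^{-T} v
  U <- backsolve(t(L), e$vectors)

  total <- sum(lambda)
  if (total <= .Machine$double.eps * p) {
    warning("zero-variance input: all eigenvalues are 0")
  }

  # deterministic sign: <t, phi_l> <= 0 (adding phi lowers mean age at death)
  quad <- basis_quadrature(smoothed$basis)
  Bq <- eval_basis(smoothed$basis, quad$nodes)
  t_moment <- drop(crossprod(Bq * (quad$weights * quad$nodes),
                             rep(1, length(quad$nodes))))
  for (l in seq_len(p)) {
    s <- sum(t_moment * U[, l])
    if (abs(s) < 1e-9 * sqrt(sum(U[, l]^2))) {
      j <- which(abs(U[, l]) > 1e-12)[1]
      s <- -sign(U[j, l]) # fallback: make first nonzero coefficient positive
    }
    if (s > 0) U[, l] <- -U[, l]
  }

  centered <- if (center) C else smoothed$coef
  scores <- centered %*% W %*% U[, seq_len(q), drop = FALSE]

  structure(
    list(mean_coef = mean_coef, eigenvalues = lambda,
         harmonics = U[, seq_len(q), drop = FALSE],
         scores = scores,
         varprop = if (total > 0) lambda / total else lambda,
         total_variance = total, q = q, center = center,
         basis = smoothed$basis, index = smoothed$index,
         ages = smoothed$ages),
    class = "mortality_fpca"
  )
}

#' Principal component scores for one harmonic
#'
#' `c_il = integral (x_i(t) - xbar(t)) phi_l(t) dt`, computed in coefficient
#' space through the Gram matrix.
#'
#' @param smoothed A `smoothed_curves` object (may differ from the fitting
#'   set, e.g. new curves projected onto an existing decomposition).
#' @param result A `mortality_fpca`.
#' @param l Harmonic index (`<= q`).
#' @return Numeric vector of scores, one per curve.
#' @export
fpca_scores <- function(smoothed, result, l) {
  stopifnot(inherits(result, "mortality_fpca"))
  if (l < 1 || l > result$q) stop("l must lie in [1, q = ", result$q, "]")
  C <- sweep(smoothed$coef, 2, result$mean_coef)
  drop(C %*% result$basis$gram %*% result$harmonics[, l])
}

#' Karhunen-Loeve reconstruction from leading scores
#'
#' `xhat_i = xbar + sum_{l <= q} c_il phi_l`.
#'
#' @param result A `mortality_fpca`.
#' @param scores n x q' score matrix (q' >= `q` columns; extra ignored).
#' @param q Number of harmonics to use.
#' @return List with `coef` (n x p reconstruction coefficients) and `fitted`
#'   (curves on the age grid).
#' @export
reconstruct_curves <- function(result, scores = result$scores, q = result$q) {
  stopifnot(inherits(result, "mortality_fpca"))
  if (q > result$q) stop("q exceeds the ", result$q, " retained harmonics")
  scores <- as.matrix(scores)
  co <- matrix(result$mean_coef, nrow(scores), length(result$mean_coef),
               byrow = TRUE)
  if (q > 0) {
    co <- co + scores[, seq_len(q), drop = FALSE] %*%
      t(result$harmonics[, seq_len(q), drop = FALSE])
  }
  list(coef = co, fitted = co %*% t(eval_basis(result$basis, result$ages)))
}

#' Mean integrated squared reconstruction error at truncation q
#'
#' Mean over curves of `integral (x_i - xhat_i)^2 dt`; equals
#' `(n-1)/n * sum_{l > q} lambda_l` when evaluated on the fitting set.
#'
#' @param smoothed The curves to reconstruct.
#' @param result A `mortality_fpca` fitted on (at least) those curves.
#' @param q Truncation level (`0 <= q <=` retained harmonics).
#' @return Scalar mean integrated squared error.
#' @export
reconstruction_error <- function(smoothed, result, q) {
  stopifnot(inherits(result, "mortality_fpca"))
  if (q > result$q) stop("q exceeds the ", result$q, " retained harmonics")
  sc <- sapply(seq_len(result$q), function(l) fpca_scores(smoothed, result, l))
  sc <- matrix(sc, nrow = nrow(smoothed$coef))
  rec <- reconstruct_curves(result, sc, q = q)
  resid <- smoothed$coef - rec$coef
  W <- result$basis$gram
  mean(rowSums((resid %*% W) * resid))
}

#' Harmonic-variation curves for one component
#'
#' The mean function plus/minus `multiple * sqrt(lambda_l) * phi_l`, the
#' standard display for reading what a component does to the mean death
#' distribution (a shift/compression of the old-age peak, a premature-
#' mortality exchange, ...).
#'
#' @param result A `mortality_fpca`.
#' @param l Harmonic index.
#' @param multiple Multiple of the component's standard deviation (default 2).
#' @param at Evaluation grid (default: the age grid).
#' @return Tibble with columns `age`, `mean`, `plus`, `minus`.
#' @export
harmonic_variation <- function(result, l, multiple = 2,
                               at = result$ages) {
  stopifnot(inherits(result, "mortality_fpca"))
  if (l < 1 || l > result$q) stop("l must lie in [1, q = ", result$q, "]")
  lam <- result$eigenvalues[l]
  B <- eval_basis(result$basis, at)
  m <- drop(B %*% result$mean_coef)
  if (lam <= 0) {
    warning("eigenvalue ", l, " is zero: variation curves collapse onto ",
            "the mean")
    return(tibble::tibble(age = at, mean = m, plus = m, minus = m))
  }
  d <- multiple * sqrt(lam) * drop(B %*% result$harmonics[, l])
  tibble::tibble(age = at, mean = m, plus = m + d, minus = m - d)
}

#' @export
print.mortality_fpca <- function(x, ...) {
  q <- x$q
  cat("<mortality_fpca>", nrow(x$scores), "curves,", q,
      "retained harmonics\n")
  cat("  variance proportions:",
      paste0(sprintf("%.1f%%", 100 * x$varprop[seq_len(min(q, 4))]),
             collapse = ", "),
      if (q > 4) "..." else "", "\n")
  invisible(x)
}

#' Tidy FPCA scores
#'
#' @param x A `mortality_fpca`.
#' @param ... Unused.
#' @return Tibble with keys and one `score_l` column per retained harmonic.
#' @export
tidy.mortality_fpca <- function(x, ...) {
  sc <- tibble::as_tibble(as.data.frame(x$scores),
                          .name_repair = ~ paste0("score_", seq_along(.x)))
  dplyr::bind_cols(x$index, sc)
}

#' One-row FPCA summary
#'
#' @param x A `mortality_fpca`.
#' @param ... Unused.
#' @return Tibble with n, q, total variance and the leading variance
#'   proportions.
#' @export
glance.mortality_fpca <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores), q = x$q, total_variance = x$total_variance,
    varprop_1 = x$varprop[1],
    varprop_2 = if (length(x$varprop) > 1) x$varprop[2] else NA_real_
  )
}
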