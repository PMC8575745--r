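# Model-based functional clustering: the functional latent mixture (FLM).
#
# Basis coefficients (in the L2 metric induced by the basis Gram matrix) are
# modelled as a K-component Gaussian mixture whose k-th covariance is
#   Sigma_k = Q_k diag(a_k1, ..., a_kd_k, b, ..., b) Q_k',
# i.e. each cluster lives near a d_k-dimensional latent subspace spanned by
# the orthonormal columns of Q_k, with signal variances a_kj and isotropic
# noise b outside the subspace (common b by default, per-cluster b_k as a
# variant). Fitted by EM; intrinsic dimensions d_k are chosen by a Cattell
# scree test on the initial within-cluster eigenvalues and held fixed during
# the iterations, which keeps the likelihood exactly monotone.

# Cattell scree: keep eigen-directions up to the last "big" drop, where big
# means >= threshold * (largest drop).
cattell_dimension <- function(eigvals, threshold = 0.2, d_max = NULL) {
  p <- length(eigvals)
  if (is.null(d_max)) d_max <- p - 1L
  d_max <- min(d_max, p - 1L)
  dif <- abs(diff(eigvals[seq_len(d_max + 1L)]))
  if (max(dif) <= 0) return(1L)
  max(1L, max(which(dif >= threshold * max(dif))))
}

# log-density columns of the parameterized mixture (n x K), given parameters
# in metric space
flm_logdens <- function(H, par) {
  n <- nrow(H); p <- ncol(H); K <- length(par$pi)
  out <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    d_k <- par$d[k]
    Vk <- par$V[[k]] # p x d_k, orthonormal
    a <- par$a[[k]]
    b <- par$b[k]
    D <- sweep(H, 2, par$mu[k, ])
    proj <- D %*% Vk # n x d_k
    qf <- rowSums(sweep(proj^2, 2, a, "/")) +
      (rowSums(D^2) - rowSums(proj^2)) / b
    logdet <- sum(log(a)) + (p - d_k) * log(b)
    out[, k] <- -0.5 * (qf + logdet + p * log(2 * pi))
  }
  out
}

flm_mstep <- function(H, Tmat, d, common_b, b_floor) {
  n <- nrow(H); p <- ncol(H); K <- ncol(Tmat)
  n_k <- colSums(Tmat)
  pi_k <- n_k / n
  mu <- matrix(NA_real_, K, p)
  V <- vector("list", K); a <- vector("list", K)
  resid_tr <- numeric(K)
  eigvals <- vector("list", K)
  for (k in seq_len(K)) {
    w <- Tmat[, k]
    mu[k, ] <- colSums(H * w) / n_k[k]
    D <- sweep(H, 2, mu[k, ])
    S <- crossprod(D * sqrt(w)) / n_k[k]
    e <- eigen(S, symmetric = TRUE)
    eigvals[[k]] <- pmax(e$values, 0)
    d_k <- d[k]
    V[[k]] <- e$vectors[, seq_len(d_k), drop = FALSE]
    a[[k]] <- pmax(eigvals[[k]][seq_len(d_k)], b_floor)
    resid_tr[k] <- sum(eigvals[[k]]) - sum(eigvals[[k]][seq_len(d_k)])
  }
  if (common_b) {
    b_val <- sum(n_k * resid_tr) / sum(n_k * (p - d))
    b <- rep(max(b_val, b_floor), K)
  } else {
    b <- pmax(resid_tr / (p - d), b_floor)
  }
  list(pi = pi_k, mu = mu, V = V, a = a, b = b, d = d, eigvals = eigvals)
}

flm_em_once <- function(H, K, model, seed, max_iter, tol, threshold, d_max,
                        b_floor) {
  n <- nrow(H)
  common_b <- model == "abQkdk"
  km <- kmeans_pp(H, K, restarts = 10, seed = seed)
  Tmat <- matrix(0, n, K)
  Tmat[cbind(seq_len(n), km$cluster)] <- 1

  # choose intrinsic dimensions once, from the initial partition's scree
  par0 <- flm_mstep(H, Tmat, d = rep(1L, K), common_b = common_b,
                    b_floor = b_floor)
  d <- vapply(par0$eigvals, cattell_dimension, integer(1),
              threshold = threshold, d_max = d_max)

  par <- flm_mstep(H, Tmat, d = d, common_b = common_b, b_floor = b_floor)
  loglik_trace <- numeric(0)
  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    lognum <- sweep(flm_logdens(H, par), 2, log(par$pi), "+")
    m <- apply(lognum, 1, max)
    li <- m + log(rowSums(exp(lognum - m)))
    new_loglik <- sum(li)
    if (is.finite(loglik) &&
        new_loglik < loglik - 1e-6 * (abs(loglik) + 1)) {
      stop("EM log-likelihood decreased beyond tolerance at iteration ", it)
    }
    loglik_trace <- c(loglik_trace, new_loglik)
    Tmat <- exp(lognum - li)
    if (any(colSums(Tmat) < 1)) {
      return(list(collapsed = TRUE))
    }
    converged <- is.finite(loglik) &&
      abs(new_loglik - loglik) < tol * (abs(loglik) + 1)
    loglik <- new_loglik
    if (converged) break
    par <- flm_mstep(H, Tmat, d = d, common_b = common_b, b_floor = b_floor)
  }
  list(collapsed = FALSE, par = par, Tmat = Tmat, loglik = loglik,
       loglik_trace = loglik_trace, iterations = length(loglik_trace))
}

#' Fit the functional latent mixture (FLM) model
#'
#' EM estimation of the K-component mixture on basis coefficients in the L2
#' metric. The reduced model with a common noise variance `b` across clusters
#' (`"abQkdk"`) is the default, reflecting a single data-acquisition process;
#' `"akbkQkdk"` allows a per-cluster noise variance.
#'
#' @param smoothed A [smooth_curves()] result.
#' @param K Number of clusters.
#' @param model `"abQkdk"` (common b) or `"akbkQkdk"` (per-cluster b_k).
#' @param seed Integer seed; EM is run from `restarts` k-means
#'   initializations with seeds derived from it, keeping the best final
#'   likelihood. A restart whose clusters collapse (expected size < 1 curve)
#'   is discarded with a message.
#' @param restarts Number of seeded EM restarts (default 10).
#' @param max_iter Maximum EM iterations per restart (default 200).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param threshold Cattell scree threshold for the intrinsic dimensions d_k
#'   (default 0.2).
#' @param d_max Cap on the intrinsic dimensions (default p - 1).
#' @return List with `model` (an `flm_model`: pi, mu, Q, a, b, d, loglik,
#'   trace, complexity, bic) and `assignment` (a `cluster_assignment` with
#'   posterior membership probabilities).
#' @export
fit_flm <- function(smoothed, K, model = c("abQkdk", "akbkQkdk"),
                    seed = 1L, restarts = 10, max_iter = 200, tol = 1e-6,
                    threshold = 0.2, d_max = NULL) {
  stopifnot(inherits(smoothed, "smoothed_curves"))
  model <- match.arg(model)
  n <- nrow(smoothed$coef)
  p <- smoothed$basis$p
  if (n <= 2 * K) stop("need n > 2K curves to fit ", K, " clusters")
  U <- chol(smoothed$basis$gram)
  H <- smoothed$coef %*% t(U) # metric coordinates: <x_i, x_j> = h_i . h_j
  b_floor <- 1e-10 * mean(diag(stats::cov(H)))

  # extra seeds are held in reserve: a collapsed run is retried from a fresh
  # initialization rather than silently reducing the number of restarts
  seeds <- withr::with_seed(as.integer(seed), {
    sample.int(.Machine$integer.max - 1L, restarts * 4L)
  })
  best <- NULL
  done <- 0L
  for (r in seq_along(seeds)) {
    if (done >= restarts) break
    fit <- tryCatch(
      flm_em_once(H, K, model, seeds[r], max_iter, tol, threshold, d_max,
                  b_floor),
      error = function(e) {
        message("EM restart failed: ", conditionMessage(e))
        list(collapsed = TRUE)
      }
    )
    if (fit$collapsed) {
      message("EM restart collapsed a cluster; retrying with a new seed")
      next
    }
    done <- done + 1L
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("all EM restarts collapsed; reduce K?")

  par <- best$par
  # back-transform loadings to basis-coefficient space: Q_k = U^{-1} V_k,
  # orthonormal under the Gram metric (Q' W Q = I)
  Q <- lapply(par$V, function(V) backsolve(U, V))
  cx <- flm_complexity(K, p, par$d, common_b = model == "abQkdk")
  mu_coef <- t(backsolve(U, t(par$mu)))
  flm <- structure(
    list(K = K, model = model, pi = par$pi, mu = mu_coef, mu_metric = par$mu,
         Q = Q, a = par$a, b = if (model == "abQkdk") par$b[1] else par$b,
         d = par$d, loglik = best$loglik, loglik_trace = best$loglik_trace,
         iterations = best$iterations, complexity = cx,
         bic = best$loglik - cx / 2 * log(n), n = n, p = p,
         basis = smoothed$basis),
    class = "flm_model"
  )
  labels <- max.col(best$Tmat)
  assignment <- new_cluster_assignment(labels, smoothed$index, "flm", K,
                                       posteriors = best$Tmat)
  list(model = flm, assignment = assignment)
}

#' Simulate coefficient data from an FLM model
#'
#' Draws `n` coefficient vectors from the K-component latent mixture with
#' known parameters, returning them packaged as a `smoothed_curves` object
#' over an identity-metric basis so [fit_flm()] can be run directly on them.
#' Used for parameter-recovery and cluster-number-selection experiments.
#'
#' @param n Total number of observations.
#' @param pi Mixing proportions (length K, sums to 1).
#' @param mu K x p matrix of cluster means.
#' @param d Intrinsic dimensions (length K).
#' @param a List of length K of signal variances (a\[\[k\]\] has length d\[k\]).
#' @param b Noise variance (scalar = common, length K = per cluster).
#' @param Q Optional list of p x d\[k\] orthonormal loading matrices; random
#'   orthonormal frames are drawn when `NULL`.
#' @param seed Integer seed.
#' @return List with `smoothed` (coefficients + identity-Gram basis stub),
#'   `labels` (true components), and `params` (the generating parameters,
#'   including the drawn `Q`).
#' @export
simulate_flm <- function(n, pi, mu, d, a, b, Q = NULL, seed = 1L) {
  K <- length(pi)
  mu <- as.matrix(mu)
  p <- ncol(mu)
  stopifnot(nrow(mu) == K, length(d) == K, length(a) == K,
            abs(sum(pi) - 1) < 1e-8)
  b <- if (length(b) == 1) rep(b, K) else b
  withr::with_seed(as.integer(seed), {
    if (is.null(Q)) {
      Q <- lapply(seq_len(K), function(k) {
        qr.Q(qr(matrix(stats::rnorm(p * d[k]), p, d[k])))
      })
    }
    labels <- sample.int(K, n, replace = TRUE, prob = pi)
    H <- matrix(NA_real_, n, p)
    for (k in seq_len(K)) {
      idx <- which(labels == k)
      if (!length(idx)) next
      nk <- length(idx)
      # isotropic noise b everywhere, plus extra (a_kj - b) along the loadings
      noise <- matrix(stats::rnorm(nk * p, sd = sqrt(b[k])), nk, p)
      signal <- matrix(stats::rnorm(nk * d[k]), nk, d[k]) %*%
        diag(sqrt(pmax(a[[k]] - b[k], 0)), d[k]) %*% t(Q[[k]])
      H[idx, ] <- matrix(mu[k, ], nk, p, byrow = TRUE) + signal + noise
    }
  })
  basis <- structure(list(knots = c(0, 1), order = NA_integer_, p = p,
                          gram = diag(p), penalty = diag(p)),
                     class = "bspline_basis")
  smoothed <- structure(
    list(basis = basis, coef = H, lambda = rep(NA_real_, n),
         gcv = rep(NA_real_, n), df = rep(NA_real_, n),
         sse = rep(NA_real_, n), fitted = H, fitted_mass = rowSums(H),
         ages = seq_len(p),
         index = tibble::tibble(country = paste0("sim", seq_len(n)),
                                year = seq_len(n), sex = "sim"),
         lambda_mode = "common"),
    class = "smoothed_curves"
  )
  list(smoothed = smoothed, labels = labels,
       params = list(pi = pi, mu = mu, d = d, a = a, b = b, Q = Q))
}

#' Free-parameter count of an FLM variant
#'
#' Mixing proportions (K - 1), cluster means (K p), orthonormal loadings
#' (sum_k \[d_k p - d_k (d_k + 1) / 2\]), signal variances (sum_k d_k), and
#' the noise variance (1 if common, K otherwise).
#'
#' @param K Clusters; @param p coefficient dimension; @param d intrinsic
#'   dimensions (length K); @param common_b common noise variance?
#' @return Integer parameter count.
#' @export
flm_complexity <- function(K, p, d, common_b = TRUE) {
  stopifnot(length(d) == K)
  (K - 1) + K * p + sum(d * p - d * (d + 1) / 2) + sum(d) +
    if (common_b) 1 else K
}

#' BIC of a fitted FLM model (higher is better)
#'
#' `BIC = loglik - complexity / 2 * log(n)`: the positive-log-likelihood
#' convention under which reported values are typically negative and the best
#' model maximizes the criterion.
#'
#' @param model A fitted `flm_model`.
#' @param n Sample size (default: the fitting sample size).
#' @return Scalar BIC.
#' @export
flm_bic <- function(model, n = model$n) {
  if (!inherits(model, "flm_model")) stop("`model` must be a fitted flm_model")
  model$loglik - model$complexity / 2 * log(n)
}

#' Scan the number of clusters by BIC
#'
#' Fits the FLM for each K in `K_range` and tabulates log-likelihood,
#' complexity and BIC. Local maxima of the BIC curve are flagged. The
#' returned `chosen` K follows a documented, overridable policy: by default
#' the local maximum with the highest BIC (falling back to the global argmax
#' when the curve is monotone); the full table is returned so the analyst can
#' instead weigh complexity growth, as done when a local maximum is followed
#' by a steep complexity increase.
#'
#' @inheritParams fit_flm
#' @param K_range Integer vector of candidate K (e.g. `2:8`).
#' @param policy `"best_local_max"` (default) or `"argmax"`.
#' @return List with `table` (tibble: K, loglik, complexity, bic,
#'   local_max), `chosen`, and `fits` (named list of [fit_flm()] results).
#' @export
select_n_clusters <- function(smoothed, K_range = 2:8,
                              model = c("abQkdk", "akbkQkdk"), seed = 1L,
                              restarts = 10, max_iter = 200, tol = 1e-6,
                              threshold = 0.2,
                              policy = c("best_local_max", "argmax")) {
  model <- match.arg(model)
  policy <- match.arg(policy)
  K_range <- sort(unique(as.integer(K_range)))
  fits <- list()
  rows <- list()
  for (K in K_range) {
    f <- tryCatch(
      fit_flm(smoothed, K, model = model, seed = seed,
              restarts = restarts, max_iter = max_iter, tol = tol,
              threshold = threshold),
      error = function(e) {
        message("K = ", K, " not fittable (", conditionMessage(e),
                "); recorded as NA")
        NULL
      }
    )
    fits[[as.character(K)]] <- f
    rows[[as.character(K)]] <- tibble::tibble(
      K = K,
      loglik = if (is.null(f)) NA_real_ else f$model$loglik,
      complexity = if (is.null(f)) NA_real_ else f$model$complexity,
      bic = if (is.null(f)) NA_real_ else f$model$bic
    )
  }
  tab <- dplyr::bind_rows(rows)
  b <- ifelse(is.na(tab$bic), -Inf, tab$bic)
  nK <- length(b)
  local_max <- vapply(seq_len(nK), function(i) {
    left_ok <- i == 1 || b[i] > b[i - 1]
    right_ok <- i == nK || b[i] > b[i + 1]
    # interior points only: endpoints are not evidence of a turning point
    i > 1 && i < nK && left_ok && right_ok
  }, logical(1))
  tab$local_max <- local_max
  chosen <- if (policy == "argmax" || !any(local_max)) {
    tab$K[which.max(b)]
  } else {
    cand <- which(local_max)
    tab$K[cand[which.max(b[cand])]]
  }
  list(table = tab, chosen = chosen, fits = fits)
}

#' @export
print.flm_model <- function(x, ...) {
  cat("<flm_model> FLM[", if (identical(x$model, "abQkdk")) "a_kj b Q_k d_k"
      else "a_kj b_k Q_k d_k", "] with K =", x$K, "\n")
  cat("  loglik:", format(x$loglik), " complexity:", x$complexity,
      " BIC:", format(x$bic), "\n")
  cat("  intrinsic dimensions d_k:", paste(x$d, collapse = ", "),
      " noise b:", paste(signif(x$b, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy per-cluster FLM parameters
#' @param x A fitted `flm_model`.
#' @param ... Unused.
#' @return Tibble with one row per cluster: mixing proportion, intrinsic
#'   dimension, leading signal variance and noise variance.
#' @export
tidy.flm_model <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$K), pi = x$pi, d = x$d,
    a_1 = vapply(x$a, `[`, numeric(1), 1),
    b = if (length(x$b) == 1) rep(x$b, x$K) else x$b
  )
}

#' One-row FLM fit summary
#' @param x A fitted `flm_model`.
#' @param ... Unused.
#' @return Tibble with K, loglik, complexity, BIC, iterations.
#' @export
glance.flm_model <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik, complexity = x$complexity,
                 bic = x$bic, iterations = x$iterations)
}
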