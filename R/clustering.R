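# Functional clustering of smoothed curves: two-stage k-means on basis
# coefficients, hierarchical clustering on the FPCA-score semimetric, and
# label bookkeeping shared by all methods. The model-based (FLM) method lives
# in flm.R.

new_cluster_assignment <- function(labels, index, method, K,
                                   posteriors = NULL) {
  labels <- as.integer(labels)
  stopifnot(all(labels >= 1L), all(labels <= K))
  if (!is.null(posteriors)) {
    stopifnot(nrow(posteriors) == length(labels), ncol(posteriors) == K)
  }
  structure(list(labels = labels, index = tibble::as_tibble(index),
                 method = method, K = as.integer(K), posteriors = posteriors),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment>", x$method, "with K =", x$K, ":",
      paste(tabulate(x$labels, x$K), collapse = "/"), "curves per cluster\n")
  invisible(x)
}

#' Tidy a cluster assignment
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return Tibble with keys, `cluster`, and (for model-based fits) posterior
#'   membership probabilities `p_1..p_K`.
#' @export
tidy.cluster_assignment <- function(x, ...) {
  out <- dplyr::bind_cols(x$index, tibble::tibble(cluster = x$labels))
  if (!is.null(x$posteriors)) {
    po <- tibble::as_tibble(as.data.frame(x$posteriors),
                            .name_repair = ~ paste0("p_", seq_along(.x)))
    out <- dplyr::bind_cols(out, po)
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-invariant agreement between two labelings (1 = identical
#' partitions, ~0 = chance). Thin wrapper over [mclust::adjustedRandIndex()].
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

# k-means++ seeding: spread initial centers proportionally to squared
# distance from the nearest chosen center.
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
  for (k in seq_len(K)[-1]) {
    prob <- d2 / sum(d2)
    if (any(!is.finite(prob)) || sum(d2) == 0) {
      centers[k] <- sample.int(n, 1)
    } else {
      centers[k] <- sample.int(n, 1, prob = prob)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[k], ])^2))
  }
  X[centers, , drop = FALSE]
}

# k-means with k-means++ restarts, deterministic under seed.
kmeans_pp <- function(X, K, restarts = 50, seed = 1L, iter_max = 100) {
  withr::with_seed(as.integer(seed), {
    best <- NULL
    for (r in seq_len(restarts)) {
      cen <- kmeanspp_centers(X, K)
      # jitter exact duplicates so stats::kmeans accepts the centers
      if (anyDuplicated(cen)) {
        cen <- cen + stats::rnorm(length(cen), 0, 1e-8 * (1 + sd(X)))
      }
      km <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = cen,
                                       iter.max = iter_max)),
        error = function(e) NULL
      )
      if (is.null(km)) next
      if (length(unique(km$cluster)) < K) next # empty cluster: retry
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("k-means failed to produce ", K,
                            " non-empty clusters")
    best
  })
}

#' Two-stage functional clustering: k-means on B-spline coefficients
#'
#' The filtering step is the basis expansion itself; the clustering step is
#' k-means (k-means++ initialization, multiple restarts) on the coefficient
#' rows, optionally in the L2 (Gram) metric.
#'
#' @param smoothed A [smooth_curves()] result.
#' @param K Number of clusters (>= 2, < n).
#' @param seed Integer seed (restarts are deterministic given the seed).
#' @param restarts Number of k-means++ restarts (default 50).
#' @param use_metric If `TRUE`, cluster in the Gram metric (Euclidean
#'   distance on coefficients then equals L2 distance between curves);
#'   default `FALSE` clusters the raw coefficients.
#' @return A `cluster_assignment`.
#' @export
cluster_two_stage <- function(smoothed, K, seed = 1L, restarts = 50,
                              use_metric = FALSE) {
  stopifnot(inherits(smoothed, "smoothed_curves"))
  n <- nrow(smoothed$coef)
  if (K < 1 || K > n) stop("K must lie in [1, n]")
  X <- smoothed$coef
  if (use_metric) X <- X %*% t(chol(smoothed$basis$gram))
  if (K == n) {
    return(new_cluster_assignment(seq_len(n), smoothed$index,
                                  "two_stage", K))
  }
  km <- kmeans_pp(X, K, restarts = restarts, seed = seed)
  new_cluster_assignment(km$cluster, smoothed$index, "two_stage", K)
}

#' FPCA-score semimetric between curves
#'
#' `d_q(x_i, x_j) = sqrt(sum_{k <= q} (c_ik - c_jk)^2)`: the Euclidean
#' distance between the first `q` principal component scores. It is a
#' semimetric — two different curves whose difference lies entirely beyond
#' harmonic `q` are at distance zero.
#'
#' @param scores_i,scores_j Score vectors (length >= q) of the two curves,
#'   from a common FPCA.
#' @param q Number of leading components to compare.
#' @return Non-negative scalar distance.
#' @export
semimetric_fpca <- function(scores_i, scores_j, q = length(scores_i)) {
  if (q > length(scores_i) || q > length(scores_j)) {
    stop("q exceeds the number of available scores")
  }
  sqrt(sum((scores_i[seq_len(q)] - scores_j[seq_len(q)])^2))
}

#' Pairwise semimetric distance matrix from an FPCA
#'
#' @param result A [fit_fpca()] result with at least `q` harmonics.
#' @param q Number of components (default 6).
#' @return A `dist` object over curves.
#' @export
semimetric_dist <- function(result, q = 6L) {
  stopifnot(inherits(result, "mortality_fpca"))
  if (q > result$q) stop("q exceeds the ", result$q, " retained harmonics")
  stats::dist(result$scores[, seq_len(q), drop = FALSE])
}

#' Distance-based functional clustering via the FPCA semimetric
#'
#' Agglomerative clustering on the pairwise `d_q` semimetric, tree cut at
#' `K`. The default Ward criterion operates on squared semimetric distances
#' (`stats::hclust` method `"ward.D2"`); hierarchical clustering is
#' deterministic, no seed involved.
#'
#' @param smoothed A [smooth_curves()] result.
#' @param q Number of leading FPCA components in the semimetric (default 6).
#' @param K Number of clusters.
#' @param linkage `"ward"`, `"complete"` or `"average"`.
#' @param fpca Optionally a pre-computed [fit_fpca()] on the same curves.
#' @return A `cluster_assignment`.
#' @export
cluster_distance_based <- function(smoothed, q = 6L, K = 5L,
                                   linkage = c("ward", "complete", "average"),
                                   fpca = NULL) {
  stopifnot(inherits(smoothed, "smoothed_curves"))
  linkage <- match.arg(linkage)
  if (is.null(fpca)) fpca <- fit_fpca(smoothed, q = q)
  d <- semimetric_dist(fpca, q = q)
  if (any(!is.finite(d))) stop("semimetric distance matrix contains ",
                               "non-finite values")
  method <- c(ward = "ward.D2", complete = "complete",
              average = "average")[[linkage]]
  labels <- if (K == 1) rep(1L, nrow(smoothed$coef)) else {
    stats::cutree(stats::hclust(d, method = method), k = K)
  }
  new_cluster_assignment(labels, smoothed$index, "distance_based", K)
}

#' Country-by-year cluster membership table
#'
#' Rearranges an assignment into the wide matrix used to follow each
#' country's trajectory through the clusters over time (one row per country,
#' one column per year). Cells missing from the assignment are left `NA`.
#'
#' @param assignment A `cluster_assignment` (or a tidy data frame with
#'   columns `country`, `year`, `cluster`).
#' @param sex Optional filter when the assignment mixes sexes.
#' @return List with `wide` (tibble, countries x years) and `tidy` (long
#'   tibble `country, year, cluster`).
#' @export
membership_matrix <- function(assignment, sex = NULL) {
  df <- if (inherits(assignment, "cluster_assignment")) {
    tidy.cluster_assignment(assignment)
  } else tibble::as_tibble(assignment)
  stopifnot(all(c("country", "year", "cluster") %in% names(df)))
  if (!is.null(sex) && "sex" %in% names(df)) {
    df <- dplyr::filter(df, .data$sex == !!sex)
  }
  long <- dplyr::arrange(df[, c("country", "year", "cluster")],
                         .data$country, .data$year)
  full <- tidyr::expand_grid(country = unique(long$country),
                             year = sort(unique(long$year)))
  long_f <- dplyr::left_join(full, long, by = c("country", "year"))
  n_missing <- sum(is.na(long_f$cluster))
  if (n_missing > 0) {
    message(n_missing, " (country, year) cell(s) missing; left empty")
  }
  wide <- tidyr::pivot_wider(long_f, names_from = "year",
                             values_from = "cluster")
  list(wide = wide, tidy = long_f)
}

#' Harmonize cluster labels across assignments by matching cluster means
#'
#' Cluster labels are arbitrary; to compare runs or methods, labels of
#' `target` are permuted so its cluster mean curves align with those of
#' `reference` (exact assignment search over permutations on the L2 distance
#' between mean curves; K <= 10).
#'
#' @param reference,target `cluster_assignment`s over the same curves.
#' @param smoothed The common `smoothed_curves`.
#' @return `target` with relabeled clusters.
#' @export
harmonize_labels <- function(reference, target, smoothed) {
  K <- reference$K
  if (target$K != K) stop("assignments must share K")
  if (K > 10) stop("exact permutation matching supports K <= 10")
  W <- smoothed$basis$gram
  mean_of <- function(lab) {
    t(sapply(seq_len(K), function(k) {
      colMeans(smoothed$coef[lab == k, , drop = FALSE])
    }))
  }
  mr <- mean_of(reference$labels)
  mt <- mean_of(target$labels)
  cost <- matrix(0, K, K) # cost[i, j]: target cluster i relabeled as j
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      d <- mt[i, ] - mr[j, ]
      cost[i, j] <- drop(crossprod(d, W %*% d))
    }
  }
  perms <- permutations_of(K)
  total <- apply(perms, 1, function(pm) sum(cost[cbind(seq_len(K), pm)]))
  best <- perms[which.min(total), ]
  relab <- best[target$labels]
  post <- target$posteriors
  if (!is.null(post)) post <- post[, order(best), drop = FALSE]
  new_cluster_assignment(relab, target$index, target$method, K,
                         posteriors = post)
}

# all permutations of 1..K as a matrix (K! rows)
permutations_of <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1L)
  out <- matrix(0L, 0, K)
  for (pos in seq_len(K)) {
    left <- sub[, seq_len(pos - 1), drop = FALSE]
    right <- if (pos <= K - 1) sub[, pos:(K - 1), drop = FALSE]
             else sub[, 0, drop = FALSE]
    out <- rbind(out, cbind(left, K, right))
  }
  colnames(out) <- NULL
  out
}
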