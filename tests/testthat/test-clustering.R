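# Two-stage and distance-based clustering, the FPCA semimetric, label
# harmonization and the membership table.

test_that("two-stage k-means recovers two well-separated regimes exactly", {
  scens <- list(a = cohort_scenario(mode_age = 75, noise_cv = 0),
                b = cohort_scenario(mode_age = 90, noise_cv = 0))
  panel <- generate_panel(scens, n_per_cluster = 10, seed = 3)
  sm <- smooth_curves(panel$curves)
  a <- cluster_two_stage(sm, 2, seed = 5)
  expect_equal(adjusted_rand_index(a$labels, panel$labels), 1)
  # the Gram-metric variant agrees on separated data
  am <- cluster_two_stage(sm, 2, seed = 5, use_metric = TRUE)
  expect_equal(adjusted_rand_index(am$labels, panel$labels), 1)
})

test_that("K = n yields singleton clusters; duplication preserves the
           partition", {
  fx <- regime_fixture()
  sm <- fx$smoothed
  n <- nrow(sm$coef)
  a <- cluster_two_stage(sm, n, seed = 1)
  expect_equal(sort(a$labels), 1:n)

  # duplicated dataset: each curve twice -> same partition structure
  sm2 <- sm
  sm2$coef <- rbind(sm$coef, sm$coef)
  sm2$index <- dplyr::bind_rows(
    sm$index, dplyr::mutate(sm$index, year = .data$year + 1000)
  )
  sm2$lambda <- c(sm$lambda, sm$lambda)
  a1 <- cluster_two_stage(sm, 3, seed = 9)
  a2 <- cluster_two_stage(sm2, 3, seed = 9)
  expect_equal(adjusted_rand_index(a2$labels[1:n], a2$labels[n + 1:n]), 1)
  expect_equal(adjusted_rand_index(a1$labels, a2$labels[1:n]), 1)
})

test_that("the FPCA semimetric is the Euclidean distance on score vectors
           and matches its direct double-sum form", {
  fx <- regime_fixture()
  sm <- fx$smoothed
  fp <- fit_fpca(sm, q = 6)
  s <- fp$scores
  # exact identity with the Euclidean norm of score differences
  D <- as.matrix(semimetric_dist(fp, q = 6))
  for (pair in list(c(1, 2), c(5, 40), c(13, 27))) {
    i <- pair[1]; j <- pair[2]
    expect_identical(semimetric_fpca(s[i, ], s[j, ], q = 6),
                     sqrt(sum((s[i, 1:6] - s[j, 1:6])^2)))
    expect_equal(D[i, j], semimetric_fpca(s[i, ], s[j, ], q = 6),
                 tolerance = 1e-12)
  }
  # direct evaluation: scores as weighted sums over discretized curves
  quad <- mortfda:::basis_quadrature(sm$basis)
  B <- eval_basis(sm$basis, quad$nodes)
  X <- eval_curves(sm, at = quad$nodes)
  phi <- B %*% fp$harmonics # eigenfunctions on the grid
  for (pair in list(c(1, 40), c(2, 33))) {
    i <- pair[1]; j <- pair[2]
    diff_ij <- X[i, ] - X[j, ]
    direct <- sqrt(sum(vapply(1:6, function(k) {
      sum(diff_ij * quad$weights * phi[, k])^2
    }, numeric(1))))
    expect_lt(abs(direct - D[i, j]) / D[i, j], 1e-6)
  }
  # autosimilarity and the semimetric (non-identity) property
  expect_identical(semimetric_fpca(s[1, ], s[1, ], q = 6), 0)
  beyond <- s[1, ]
  beyond_other <- beyond
  # curves differing only in harmonic q+1 are indistinguishable at level q
  expect_equal(semimetric_fpca(c(beyond, 5), c(beyond_other, -5), q = 6), 0)
  expect_error(semimetric_fpca(s[1, ], s[2, ], q = 20), "exceeds")
})

test_that("distance-based clustering recovers three separated regimes and
           is invariant to curve order", {
  scens <- regime_scenarios(noise_cv = 0)
  panel <- generate_panel(scens, n_per_cluster = 8, seed = 21)
  sm <- smooth_curves(panel$curves)
  a <- cluster_distance_based(sm, q = 6, K = 3)
  expect_equal(adjusted_rand_index(a$labels, panel$labels), 1)

  a1 <- cluster_distance_based(sm, q = 6, K = 1)
  expect_true(all(a1$labels == 1))

  perm <- sample(seq_len(nrow(sm$coef)))
  smp <- sm
  smp$coef <- sm$coef[perm, ]
  smp$index <- sm$index[perm, ]
  ap <- cluster_distance_based(smp, q = 6, K = 3)
  expect_equal(adjusted_rand_index(ap$labels, a$labels[perm]), 1)

  # alternative linkages are accepted
  ac <- cluster_distance_based(sm, q = 6, K = 3, linkage = "complete")
  expect_equal(adjusted_rand_index(ac$labels, panel$labels), 1)
})

test_that("membership matrix lays out countries by years and shows a
           scripted cluster switch", {
  years <- 1:50
  df <- tidyr::expand_grid(country = c("Alpha", "Beta"), year = years)
  df$cluster <- ifelse(df$country == "Alpha" & df$year >= 30, 2L, 1L)
  df$sex <- "t"
  mm <- membership_matrix(df)
  expect_equal(nrow(mm$wide), 2)
  expect_equal(ncol(mm$wide), 1 + 50)
  alpha <- unlist(mm$wide[mm$wide$country == "Alpha", -1])
  expect_equal(unname(alpha[29:31]), c(1L, 2L, 2L)) # switch lands at year 30
  # missing cells stay empty
  expect_message(mm2 <- membership_matrix(df[-3, ]), "missing")
  expect_true(any(is.na(mm2$wide)))
})

test_that("harmonizing relabeled identical partitions recovers identical
           tables", {
  fx <- regime_fixture()
  sm <- fx$smoothed
  a <- cluster_two_stage(sm, 3, seed = 2)
  relab <- a
  map <- c(3L, 1L, 2L)
  relab$labels <- map[a$labels]
  h <- harmonize_labels(a, relab, sm)
  expect_identical(h$labels, a$labels)
  expect_identical(membership_matrix(h)$wide, membership_matrix(a)$wide)
})

test_that("assignment tidier carries posteriors when present", {
  fx <- regime_fixture()
  f <- suppressMessages(fit_flm(fx$smoothed, 3, seed = 4, restarts = 3))
  td <- tidy(f$assignment)
  expect_true(all(c("cluster", "p_1", "p_2", "p_3") %in% names(td)))
  expect_equal(rowSums(as.matrix(td[, c("p_1", "p_2", "p_3")])),
               rep(1, nrow(td)), tolerance = 1e-10)
  expect_equal(td$cluster, max.col(f$assignment$posteriors))
})
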