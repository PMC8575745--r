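# Penalized B-spline smoothing: knot schemes, closed-form fit vs a generic
# numerical minimizer, GCV, and monotonicity in lambda.

test_that("knot schemes have the documented length, range and spacing", {
  k31 <- build_knots("sparse31")
  expect_length(k31, 31)
  expect_equal(range(k31), c(0, 110))
  expect_equal(k31[1:9], seq(0, 2, by = 0.25)) # quarterly on the infant ages
  expect_true(all(diff(k31) > 0))

  k111 <- build_knots("dense111")
  expect_length(k111, 111)
  expect_equal(unique(diff(k111)), 1)
  expect_error(build_knots("bogus"))
})

test_that("basis dimensions and penalty structure are as constructed", {
  b <- bspline_basis(build_knots("sparse31"))
  expect_equal(b$p, 29 + 4) # interior knots + order
  expect_true(isSymmetric(b$gram))
  expect_true(isSymmetric(b$penalty))
  ev <- eigen(b$penalty, symmetric = TRUE, only.values = TRUE)$values
  # nullspace of the curvature penalty is exactly the linear functions
  expect_equal(sum(ev < 1e-10 * max(ev)), 2)
  expect_true(all(eigen(b$gram, only.values = TRUE)$values > 0))
})

test_that("integrated squared curvature from the penalty matrix matches
           independent quadrature", {
  b <- bspline_basis()
  set.seed(11)
  for (i in 1:5) {
    g <- rnorm(b$p, sd = 100)
    exact <- drop(t(g) %*% b$penalty %*% g)
    # composite Simpson on a fine grid, independent of the Gauss rule
    h <- 0.025
    grid <- seq(0, 110, by = h)
    d2 <- drop(eval_basis(b, grid, deriv = 2) %*% g)^2
    n <- length(grid)
    simpson <- h / 3 * sum(d2 * c(1, rep(c(4, 2), (n - 3) / 2), 4, 1))
    expect_equal(simpson, exact, tolerance = 1e-8)
  }
})

test_that("a linear signal is reproduced exactly for any lambda", {
  b <- bspline_basis()
  y <- 2 + 3 * (0:110)
  for (lam in c(0.01, 1, 1e6)) {
    fit <- penalized_fit(y, b, lam)
    expect_equal(fit$fitted, y, tolerance = 1e-8)
  }
})

test_that("very large lambda shrinks the fit to the least-squares line", {
  b <- bspline_basis()
  set.seed(2)
  y <- generate_dx(cohort_scenario(noise_cv = 0.1), seed = 2)
  fit <- penalized_fit(y, b, 1e12)
  line <- stats::lm(y ~ x, data = data.frame(y = y, x = 0:110))
  expect_equal(fit$fitted, unname(fitted(line)), tolerance = 1e-3)
})

test_that("closed-form coefficients match a brute-force minimizer of the
           penalized objective", {
  knots <- seq(0, 19, length.out = 7) # p = 9 on a 20-point grid
  b <- bspline_basis(knots)
  ages <- 0:19
  Psi <- eval_basis(b, ages)
  # independent penalty quadrature: composite Simpson on the curvature
  h <- 0.005
  grid <- seq(0, 19, by = h)
  B2 <- eval_basis(b, grid, deriv = 2)
  n <- length(grid)
  sw <- h / 3 * c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
  R_num <- t(B2 * sw) %*% B2
  set.seed(31)
  for (i in 1:20) {
    y <- rnorm(20, sd = 10)
    lam <- 10^runif(1, -2, 2)
    fit <- penalized_fit(y, b, lam, ages = ages)
    obj <- function(g) sum((y - Psi %*% g)^2) + lam * drop(t(g) %*% R_num %*% g)
    grd <- function(g) drop(-2 * t(Psi) %*% (y - Psi %*% g) +
                              2 * lam * R_num %*% g)
    opt <- optim(rep(0, b$p), obj, grd, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    expect_lt(max(abs(fit$coef - opt$par)) / max(abs(fit$coef)), 1e-6)
  }
})

test_that("GCV equals the formula computed from an explicitly formed hat
           matrix", {
  b <- bspline_basis()
  y <- generate_dx(cohort_scenario(noise_cv = 0.1), seed = 4)
  lam <- 0.5
  Psi <- eval_basis(b, 0:110)
  H <- Psi %*% solve(crossprod(Psi) + lam * b$penalty, t(Psi))
  sse <- sum((y - H %*% y)^2)
  N <- 111
  expect_equal(gcv_score(y, b, lam), N * sse / (N - sum(diag(H)))^2,
               tolerance = 1e-10)
})

test_that("effective df decreases and SSE increases with lambda", {
  b <- bspline_basis()
  y <- generate_dx(cohort_scenario(noise_cv = 0.2), seed = 6)
  lams <- 10^seq(-4, 6, by = 1)
  fits <- lapply(lams, function(l) penalized_fit(y, b, l))
  dfs <- vapply(fits, `[[`, numeric(1), "df")
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  expect_true(all(diff(dfs) < 1e-8))
  expect_true(all(diff(sses) > -1e-8))
})

test_that("GCV-selected lambda beats the grid extremes on noisy data", {
  b <- bspline_basis()
  truth <- generate_dx(cohort_scenario(infant_mass = 0, hump_mass = 0.08,
                                       mode_age = 80, mode_sd = 9))
  rmse <- function(lam, y) {
    sqrt(mean((penalized_fit(y, b, lam)$fitted - truth)^2))
  }
  grid <- default_lambda_grid()
  wins <- 0
  set.seed(100)
  for (s in 1:5) {
    y <- truth + rnorm(111, sd = 400) # smooth curve + iid noise
    lam_gcv <- select_lambda(y, b, grid)$lambda
    if (rmse(lam_gcv, y) < rmse(min(grid), y) &&
        rmse(lam_gcv, y) < rmse(max(grid), y)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 4) # recovery can tie on an occasional draw
})

test_that("noiseless near-linear data pushes GCV to the smoothest lambda", {
  b <- bspline_basis()
  y <- 5 + 0.2 * (0:110)
  sel <- select_lambda(y, b, 10^seq(-3, 3, by = 1))
  expect_equal(sel$lambda, 1e3) # argmin at the grid max, ties to smoother
})

test_that("smooth_curves handles identical rows and both lambda modes", {
  dx <- generate_dx(cohort_scenario(noise_cv = 0), seed = 1)
  curves <- curve_set(rbind(dx, dx, dx),
                      index = tibble::tibble(country = c("A", "B", "C"),
                                             year = 1:3, sex = "t"),
                      radix_tol = 1e-6)
  sm <- smooth_curves(curves)
  expect_equal(sm$coef[1, ], sm$coef[2, ])
  expect_equal(sm$coef[1, ], sm$coef[3, ])

  sm_c <- smooth_curves(curves, lambda_mode = "common", lambda0 = 0.0025)
  expect_true(all(sm_c$lambda == 0.0025))
})

test_that("common and per-curve lambda give the same downstream clusters", {
  fx <- regime_fixture()
  sm_c <- smooth_curves(fx$panel$curves, lambda_mode = "common",
                        lambda0 = 0.0025)
  a_per <- cluster_two_stage(fx$smoothed, 3, seed = 1)
  a_com <- cluster_two_stage(sm_c, 3, seed = 1)
  expect_gte(adjusted_rand_index(a_per$labels, a_com$labels), 0.9)
})

test_that("sparse-knot smoothing of a sharp-infant-drop curve keeps one
           adult mode", {
  # a 1960s Eastern-European-like profile: huge infant spike, early mode
  y <- generate_dx(cohort_scenario(infant_mass = 0.06, hump_mass = 0.08,
                                   hump_loc = 45, hump_scale = 15,
                                   mode_age = 72, mode_sd = 11,
                                   noise_cv = 0.08), seed = 60)
  b <- bspline_basis(build_knots("sparse31"))
  fit <- penalized_fit(y, b, select_lambda(y, b)$lambda)
  grid <- seq(5, 110, by = 0.5) # adult ages, past the infant drop
  vals <- drop(eval_basis(b, grid) %*% fit$coef)
  peaks <- which(diff(sign(diff(vals))) == -2) + 1
  substantive <- sum(vals[peaks] > 0.1 * max(vals))
  expect_equal(substantive, 1) # unique substantive adult mode
})

test_that("smoothed coefficients survive a CSV+sidecar round-trip", {
  fx <- regime_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_smoothed_csv(fx$smoothed, path)
  back <- read_smoothed_csv(path)
  expect_equal(back$coef, fx$smoothed$coef, tolerance = 1e-12)
  expect_equal(back$basis$knots, fx$smoothed$basis$knots)
  expect_equal(back$lambda, fx$smoothed$lambda)
})
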