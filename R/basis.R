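# B-spline basis systems on the age domain, with exactly integrated Gram and
# roughness-penalty matrices.

#' Build a knot sequence for the age domain 0 to 110
#'
#' Two fixed schemes are provided. `"dense111"` places one knot at every
#' integer age (0, 1, ..., 110). `"sparse31"` is the parsimonious scheme used
#' throughout the package: quarterly knots over the infant ages \[0, 2\]
#' (0, 0.25, ..., 2), then one knot every five years (7, 12, ..., 107), with a
#' final knot at 110 so the basis domain closes at the oldest age. The sparse
#' scheme concentrates resolution where death distributions have the steepest
#' curvature (the infant drop) while keeping the coefficient vector short.
#'
#' @param scheme One of `"dense111"` or `"sparse31"`.
#' @return A strictly increasing numeric vector of breakpoints spanning
#'   \[0, 110\].
#' @examples
#' length(build_knots("sparse31")) # 31
#' @export
build_knots <- function(scheme = c("sparse31", "dense111")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    dense111 = as.numeric(0:110),
    sparse31 = c(seq(0, 2, by = 0.25), seq(7, 107, by = 5), 110)
  )
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch (symmetric
# tridiagonal Jacobi matrix); exact for polynomials of degree <= 2n - 1.
gauss_legendre <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 2))
  j <- seq_len(n - 1)
  beta <- j / sqrt(4 * j^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(j, j + 1)] <- beta
  J[cbind(j + 1, j)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

#' Construct a cubic B-spline basis with penalty and Gram matrices
#'
#' Builds the basis system used for all smoothing, FPCA and clustering steps:
#' `p = #interior knots + order` B-spline functions on the given breakpoints,
#' together with the second-derivative roughness penalty matrix
#' `R[j, k] = integral of psi_j''(t) psi_k''(t) dt` and the Gram matrix
#' `W[j, k] = integral of psi_j(t) psi_k(t) dt`. Both integrals are computed by
#' per-interval Gauss-Legendre quadrature of sufficient degree to be exact for
#' the piecewise-polynomial integrands.
#'
#' @param knots Strictly increasing breakpoints (see [build_knots()]).
#' @param order Polynomial order of the spline (4 = cubic, the default).
#' @return An object of class `bspline_basis` with elements `knots`, `order`,
#'   `p` (number of basis functions), `penalty` (p x p), and `gram` (p x p).
#' @export
bspline_basis <- function(knots = build_knots("sparse31"), order = 4L) {
  knots <- as.numeric(knots)
  if (length(knots) < 2 || any(diff(knots) <= 0)) {
    stop("`knots` must be strictly increasing with at least two values")
  }
  order <- as.integer(order)
  aug <- c(rep(knots[1], order), knots[-c(1, length(knots))],
           rep(knots[length(knots)], order))
  p <- length(aug) - order
  basis <- structure(
    list(knots = knots, order = order, p = p, aug_knots = aug),
    class = "bspline_basis"
  )
  # psi''psi'' is piecewise degree 2(order-3) + ... : for cubic, degree 4;
  # psi psi is degree 2(order-1) = 6. A rule exact to degree 2*order is ample.
  gl <- gauss_legendre(order + 1L)
  W <- matrix(0, p, p)
  R <- matrix(0, p, p)
  for (i in seq_len(length(knots) - 1)) {
    a <- knots[i]; b <- knots[i + 1]
    x <- (b - a) / 2 * gl$nodes + (a + b) / 2
    w <- (b - a) / 2 * gl$weights
    B0 <- eval_basis(basis, x, deriv = 0L)
    B2 <- eval_basis(basis, x, deriv = 2L)
    W <- W + crossprod(B0 * sqrt(w))
    R <- R + crossprod(B2 * sqrt(w))
  }
  basis$gram <- (W + t(W)) / 2
  basis$penalty <- (R + t(R)) / 2
  basis
}

#' Evaluate a B-spline basis (or a derivative) at points
#'
#' @param basis A `bspline_basis`.
#' @param x Evaluation points inside the basis domain.
#' @param deriv Derivative order (0 = function values).
#' @return A `length(x)` x `p` design matrix.
#' @export
eval_basis <- function(basis, x, deriv = 0L) {
  stopifnot(inherits(basis, "bspline_basis"))
  rng <- range(basis$knots)
  if (any(x < rng[1] - 1e-9 | x > rng[2] + 1e-9)) {
    stop("evaluation points outside the basis domain [",
         rng[1], ", ", rng[2], "]")
  }
  x <- pmin(pmax(x, rng[1]), rng[2])
  splines::splineDesign(basis$aug_knots, x, ord = basis$order,
                        derivs = rep(as.integer(deriv), length(x)),
                        outer.ok = FALSE)
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat("<bspline_basis> order", x$order, "with", length(x$knots),
      "breakpoints on [", x$knots[1], ",", x$knots[length(x$knots)],
      "] (p =", x$p, "basis functions)\n")
  invisible(x)
}

# Quadrature nodes/weights spanning the whole basis domain, exact per interval.
# Used wherever an L2 integral of (products of) spline functions is needed.
basis_quadrature <- function(basis, degree_exact = 2L * basis$order) {
  npt <- ceiling((degree_exact + 1) / 2)
  gl <- gauss_legendre(npt)
  knots <- basis$knots
  nodes <- c(); weights <- c()
  for (i in seq_len(length(knots) - 1)) {
    a <- knots[i]; b <- knots[i + 1]
    nodes <- c(nodes, (b - a) / 2 * gl$nodes + (a + b) / 2)
    weights <- c(weights, (b - a) / 2 * gl$weights)
  }
  list(nodes = nodes, weights = weights)
}
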