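# Container for discretized age-at-death distributions: one d_x curve per
# (country, year, sex) unit on a common integer age grid.

#' Assemble a mortality curve set
#'
#' A `curve_set` holds the raw discretized death distributions analysed by the
#' smoothing, FPCA and clustering stages: an age grid (0..110, with the open
#' "110+" group collapsed to age 110), a curve matrix with one row per
#' population unit, and an index of `(country, year, sex)` keys. Every row is
#' expected to sum to the life-table radix of 100,000 deaths.
#'
#' @param curves Numeric matrix, one row per unit, one column per age.
#' @param ages Strictly increasing integer age grid (default `0:110`).
#' @param index Data frame with columns `country`, `year`, `sex`, one row per
#'   curve, no duplicate keys.
#' @param radix Expected row sum (default 100000).
#' @param radix_tol Allowed absolute deviation of row sums from `radix`
#'   (default 1; raw life-table rows sum exactly after 110+ aggregation, small
#'   rounding slack is tolerated). Use `Inf` to skip the check.
#' @return An object of class `curve_set`.
#' @export
curve_set <- function(curves, ages = 0:110, index = NULL,
                      radix = 100000, radix_tol = 1) {
  curves <- as.matrix(curves)
  ages <- as.numeric(ages)
  if (ncol(curves) != length(ages)) {
    stop("`curves` must have one column per age (", length(ages), ")")
  }
  if (any(diff(ages) <= 0)) stop("`ages` must be strictly increasing")
  if (any(curves < 0)) stop("curve values must be non-negative")
  if (is.null(index)) {
    index <- tibble::tibble(country = "SYN", year = seq_len(nrow(curves)),
                            sex = "total")
  }
  index <- tibble::as_tibble(index)
  stopifnot(all(c("country", "year", "sex") %in% names(index)),
            nrow(index) == nrow(curves))
  key <- paste(index$country, index$year, index$sex)
  if (anyDuplicated(key)) stop("duplicate (country, year, sex) keys in index")
  if (is.finite(radix_tol)) {
    rs <- rowSums(curves)
    bad <- which(abs(rs - radix) > radix_tol)
    if (length(bad)) {
      stop("curve row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           " do not sum to the radix ", radix, " within +/-", radix_tol)
    }
  }
  dimnames(curves) <- list(key, NULL)
  structure(list(ages = ages, curves = curves, index = index, radix = radix),
            class = "curve_set")
}

#' Build a curve set from a long (tidy) data frame
#'
#' The tidy dialect has one row per (country, year, sex, age) with a `dx`
#' column; this is the CSV layout written by [write_curves_csv()].
#'
#' @param data Data frame with columns `country`, `year`, `sex`, `age`, `dx`.
#' @param ... Passed to [curve_set()] (e.g. `radix_tol`).
#' @return A `curve_set`.
#' @export
as_curve_set <- function(data, ...) {
  stopifnot(all(c("country", "year", "sex", "age", "dx") %in% names(data)))
  wide <- tidyr::pivot_wider(
    dplyr::arrange(tibble::as_tibble(data), .data$country, .data$year,
                   .data$sex, .data$age),
    id_cols = c("country", "year", "sex"),
    names_from = "age", values_from = "dx"
  )
  ages <- as.numeric(setdiff(names(wide), c("country", "year", "sex")))
  curve_set(as.matrix(wide[, as.character(ages)]), ages = ages,
            index = wide[, c("country", "year", "sex")], ...)
}

#' @export
as_tibble.curve_set <- function(x, ...) {
  idx <- x$index[rep(seq_len(nrow(x$index)), each = length(x$ages)), ]
  tibble::tibble(
    country = idx$country, year = idx$year, sex = idx$sex,
    age = rep(x$ages, nrow(x$curves)),
    dx = as.vector(t(x$curves))
  )
}

#' @export
print.curve_set <- function(x, ...) {
  cat("<curve_set>", nrow(x$curves), "curves on ages",
      x$ages[1], "-", x$ages[length(x$ages)],
      "(", length(unique(x$index$country)), "countries,",
      length(unique(x$index$year)), "years )\n")
  invisible(x)
}

#' Number of curves in a curve set
#' @param x A `curve_set`.
#' @export
n_curves <- function(x) nrow(x$curves)
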