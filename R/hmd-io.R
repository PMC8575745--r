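# Readers and writers for Human Mortality Database style period life tables
# and the package's tidy CSV dialect.

#' Read d_x curves from an HMD-style period life table
#'
#' Parses the whitespace-delimited 1x1 period life-table layout (header naming
#' columns `Year Age mx qx ax lx dx Lx Tx ex`, 111 age rows 0..110+ per year
#' block, radix 100,000) and extracts the age distribution of deaths `dx` for
#' each year in range. The open age group "110+" is collapsed onto age 110 so
#' that every curve lives on the closed grid 0..110.
#'
#' @param path Path to the life-table text file.
#' @param sex Sex label to attach to the curves (HMD ships one file per sex).
#' @param year_range Closed integer interval `c(from, to)`; years present in
#'   the file but outside the range are dropped, years in the range but absent
#'   from the file are skipped with a warning.
#' @param country Country code to attach (default: file name without
#'   extension).
#' @param radix_tol Row-sum tolerance passed to [curve_set()].
#' @return A [curve_set()] with one curve per available year.
#' @export
read_hmd_lifetable <- function(path, sex = c("male", "female", "total"),
                               year_range = c(1960L, 2018L),
                               country = NULL, radix_tol = 1) {
  sex <- match.arg(sex)
  if (is.null(country)) {
    country <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  # locate the header: the line naming the columns
  hdr_i <- which(grepl("\\bYear\\b", lines) & grepl("\\bAge\\b", lines))[1]
  if (is.na(hdr_i)) stop("malformed header: no line naming columns Year, Age")
  hdr <- strsplit(trimws(lines[hdr_i]), "\\s+")[[1]]
  for (col in c("Year", "Age", "dx")) {
    if (!col %in% hdr) stop("malformed header: missing column '", col, "'")
  }
  body <- lines[-seq_len(hdr_i)]
  fields <- strsplit(trimws(body), "\\s+")
  keep <- vapply(fields, length, 1L) == length(hdr)
  fields <- fields[keep]
  if (!length(fields)) stop("no data rows found in ", path)
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- hdr
  year <- as.integer(tab$Year)
  age <- suppressWarnings(as.integer(sub("\\+$", "", tab$Age)))
  dx <- suppressWarnings(as.numeric(gsub(",", "", tab$dx)))
  if (anyNA(year) || anyNA(age) || anyNA(dx)) {
    stop("unparseable Year/Age/dx values in ", path)
  }

  wanted <- seq.int(year_range[1], year_range[2])
  have <- intersect(wanted, unique(year))
  missing_years <- setdiff(wanted, have)
  if (length(missing_years)) {
    warning("skipping ", length(missing_years), " year(s) absent from ",
            basename(path), ": ",
            paste(utils::head(missing_years, 10), collapse = ", "),
            if (length(missing_years) > 10) ", ..." else "")
  }
  if (!length(have)) stop("no years of ", basename(path), " fall in [",
                          year_range[1], ", ", year_range[2], "]")

  curves <- matrix(NA_real_, length(have), 111)
  for (k in seq_along(have)) {
    sel <- year == have[k]
    if (sum(sel) != 111) {
      stop("year block ", have[k], " has ", sum(sel),
           " age rows (expected 111: ages 0-110+)")
    }
    a <- age[sel]
    if (!identical(sort(a), 0:110)) {
      stop("year block ", have[k], " does not cover ages 0-110+")
    }
    # 110+ already carries the open-group total; collapsing is a relabel
    curves[k, ] <- dx[sel][order(a)]
  }
  curve_set(curves, ages = 0:110,
            index = tibble::tibble(country = country, year = have, sex = sex),
            radix_tol = radix_tol)
}

#' Apply the study's country-selection rules
#'
#' Removes countries whose series are too short or whose populations are too
#' small, and optionally replaces unified Germany with its East/West split so
#' the series reach back to 1960.
#'
#' @param available Character vector of available country codes.
#' @param exclusions_short Codes excluded for short time series.
#' @param exclusions_small Codes excluded for small population size.
#' @param split_germany If `TRUE` and `"Germany"` (or `"DEUTNP"`) is present,
#'   replace it in place by East and West Germany.
#' @return Character vector of retained codes, input order preserved.
#' @examples
#' apply_country_selection(c("Sweden", "Chile", "Germany"),
#'                         exclusions_short = "Chile", split_germany = TRUE)
#' @export
apply_country_selection <- function(available,
                                    exclusions_short = character(),
                                    exclusions_small = character(),
                                    split_germany = FALSE) {
  excl <- c(exclusions_short, exclusions_small)
  unknown <- setdiff(excl, available)
  if (length(unknown)) {
    stop("exclusion code(s) not in `available`: ",
         paste(unknown, collapse = ", "))
  }
  out <- as.list(setdiff(available, excl))
  if (split_germany) {
    for (g in c("Germany", "DEUTNP")) {
      i <- match(g, out)
      if (!is.na(i)) {
        out[[i]] <- if (g == "DEUTNP") c("DEUTE", "DEUTW")
                    else c("East Germany", "West Germany")
      }
    }
  }
  unlist(out)
}

#' The 40 populations of the Human Mortality Database (circa 2020)
#'
#' Country list as available at download time, used with
#' [apply_country_selection()] to reproduce the 32-population analysis set.
#' @return Character vector of 40 country names.
#' @export
hmd_country_codes <- function() {
  c("Australia", "Austria", "Belarus", "Belgium", "Bulgaria", "Canada",
    "Chile", "Croatia", "Czechia", "Denmark", "Estonia", "Finland", "France",
    "Germany", "Greece", "Hungary", "Iceland", "Ireland", "Israel", "Italy",
    "Japan", "Korea", "Latvia", "Lithuania", "Luxembourg", "Netherlands",
    "New Zealand", "Norway", "Poland", "Portugal", "Russia", "Slovakia",
    "Slovenia", "Spain", "Sweden", "Switzerland", "Taiwan", "Ukraine",
    "United Kingdom", "United States")
}

#' Default exclusion lists for the 32-country analysis set
#' @return Named list with elements `short` (series too short) and `small`
#'   (population too small).
#' @export
hmd_default_exclusions <- function() {
  list(short = c("Chile", "Croatia", "Greece", "Israel", "Slovenia",
                 "Korea", "Taiwan"),
       small = c("Luxembourg", "Iceland"))
}

#' Write / read a curve set as tidy CSV
#'
#' The tidy dialect has columns `country, year, sex, age, dx`; writing then
#' re-reading reproduces the curve matrix bit-exactly (values are printed with
#' full precision).
#'
#' @param x A `curve_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(x, path) {
  stopifnot(inherits(x, "curve_set"))
  df <- as_tibble.curve_set(x)
  df$dx <- sprintf("%.17g", df$dx) # 17 significant digits: exact round trip
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_curves_csv
#' @param radix_tol Row-sum tolerance passed to [curve_set()].
#' @export
read_curves_csv <- function(path, radix_tol = 1) {
  # base parser: correctly rounded doubles, so 17-digit writes reload exactly
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  as_curve_set(df, radix_tol = radix_tol)
}
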