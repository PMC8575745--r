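# Programmatic fixtures: small HMD-style life-table files and reusable panels.

# Write an HMD-style 1x1 period life table. `dx_by_year` is a named list:
# year -> numeric vector of 111 dx values (ages 0..110+).
write_hmd_fixture <- function(path, dx_by_year, country = "Testland") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0(country, ", Life tables (period 1x1), Total",
           "\tLast modified: 01 Jan 2020"),
    "",
    paste(" Year", "Age", "mx", "qx", "ax", "lx", "dx", "Lx", "Tx", "ex",
          sep = "\t")
  ), con)
  for (yr in names(dx_by_year)) {
    dx <- dx_by_year[[yr]]
    stopifnot(length(dx) == 111)
    age_lab <- c(as.character(0:109), "110+")
    for (j in seq_len(111)) {
      writeLines(paste(yr, age_lab[j], "0.001", "0.001", "0.5", "100000",
                       format(dx[j], scientific = FALSE), "0", "0", "70.0",
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

# A dx vector from the generator, rounded to keep the fixture readable while
# summing to the radix within +/-1.
fixture_dx <- function(seed = 1, ...) {
  sc <- cohort_scenario(...)
  round(generate_dx(sc, seed = seed), 1)
}

# Shared small regime panel + smooth fit (computed once per test run)
regime_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- generate_panel(regime_scenarios(), n_per_cluster = 15,
                              jitter = regime_jitter(), seed = 42)
      sm <- smooth_curves(panel$curves)
      cache <<- list(panel = panel, smoothed = sm)
    }
    cache
  }
})
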