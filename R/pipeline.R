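# End-to-end orchestration: (read | simulate) -> smooth -> FPCA -> cluster ->
# tidy CSV artifacts + manifest. Reports are data-first; figures are derived
# separately by the plot_* functions so nothing downstream depends on
# rendering.

#' Build a pipeline run configuration
#'
#' @param input Either `list(mode = "synthetic", scenarios = <named list of
#'   cohort_scenario>, n_per_cluster =, jitter =)` or `list(mode = "hmd_dir",
#'   dir =, countries =, sex =, year_range =)`. A YAML file path with the
#'   same structure is also accepted by [run_pipeline()].
#' @param knot_scheme `"sparse31"` or `"dense111"`.
#' @param lambda_mode `"per_curve"` or `"common"`.
#' @param lambda0 Common smoothing parameter when `lambda_mode = "common"`.
#' @param methods Clustering methods to run: subset of `c("two_stage",
#'   "distance_based", "flm")`.
#' @param K Number of clusters, or `NULL` to scan `K_range` by BIC (FLM).
#' @param K_range Candidate K scanned when `K` is `NULL`.
#' @param q Number of FPCA components for the semimetric (default 6).
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(input, knot_scheme = "sparse31",
                       lambda_mode = "per_curve", lambda0 = 0.0025,
                       methods = c("two_stage", "distance_based", "flm"),
                       K = 5L, K_range = 2:8, q = 6L, seed = 1L,
                       out_dir = tempfile("mortfda_run_")) {
  methods <- match.arg(methods, c("two_stage", "distance_based", "flm"),
                       several.ok = TRUE)
  structure(list(input = input, knot_scheme = knot_scheme,
                 lambda_mode = lambda_mode, lambda0 = lambda0,
                 methods = methods, K = K, K_range = K_range, q = q,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

load_run_input <- function(input, seed) {
  if (identical(input$mode, "synthetic")) {
    scenarios <- input$scenarios
    if (is.null(scenarios)) scenarios <- regime_scenarios()
    jitter <- if (is.null(input$jitter)) regime_jitter() else input$jitter
    npc <- if (is.null(input$n_per_cluster)) 20L else input$n_per_cluster
    panel <- generate_panel(scenarios, n_per_cluster = npc, jitter = jitter,
                            seed = seed)
    list(curves = panel$curves, labels = panel$labels)
  } else if (identical(input$mode, "hmd_dir")) {
    if (!dir.exists(input$dir)) stop("input directory not found: ",
                                     input$dir)
    sets <- lapply(input$countries, function(cc) {
      read_hmd_lifetable(file.path(input$dir, paste0(cc, ".txt")),
                         sex = input$sex, year_range = input$year_range,
                         country = cc)
    })
    ages <- sets[[1]]$ages
    curves <- do.call(rbind, lapply(sets, function(s) s$curves))
    index <- dplyr::bind_rows(lapply(sets, function(s) s$index))
    list(curves = curve_set(curves, ages = ages, index = index),
         labels = NULL)
  } else {
    stop("unknown input mode: ", input$mode)
  }
}

#' Run the full mortality-curve analysis pipeline
#'
#' Executes read/simulate, penalized smoothing, FPCA, the requested
#' clustering methods, and writes tidy CSV artifacts plus a JSON manifest
#' (seeds, stage parameters, file hashes). Identical configuration and seed
#' give byte-identical outputs.
#'
#' @param config A [run_config()], or the path of a YAML file with the same
#'   fields.
#' @return The manifest (invisibly a list), with `$files` naming every
#'   artifact and its MD5 hash.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    if (!is.null(raw$methods)) raw$methods <- unlist(raw$methods)
    if (!is.null(raw$K_range)) raw$K_range <- unlist(raw$K_range)
    if (!is.null(raw$input$year_range)) {
      raw$input$year_range <- unlist(raw$input$year_range)
    }
    if (!is.null(raw$input$scenarios)) {
      raw$input$scenarios <- lapply(raw$input$scenarios, function(s) {
        do.call(cohort_scenario, s)
      })
    }
    config <- do.call(run_config, raw)
  }
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- "input"
  manifest <- list(seed = config$seed, knot_scheme = config$knot_scheme,
                   lambda_mode = config$lambda_mode,
                   methods = config$methods, q = config$q,
                   package_version = as.character(
                     utils::packageVersion("mortfda")))
  result <- tryCatch({
    dat <- load_run_input(config$input, seed = config$seed)
    write_curves_csv(dat$curves, out("curves.csv"))

    stage <- "smoothing"
    basis <- bspline_basis(build_knots(config$knot_scheme))
    sm <- smooth_curves(dat$curves, basis, lambda_mode = config$lambda_mode,
                        lambda0 = config$lambda0)
    write_smoothed_csv(sm, out("smoothed_coefficients.csv"))
    readr::write_csv(tidy.smoothed_curves(sm), out("smoothing_summary.csv"))

    stage <- "fpca"
    q <- min(config$q, basis$p)
    fp <- fit_fpca(sm, q = q)
    readr::write_csv(tidy.mortality_fpca(fp), out("fpca_scores.csv"))
    readr::write_csv(
      tibble::tibble(component = seq_along(fp$eigenvalues),
                     eigenvalue = fp$eigenvalues, varprop = fp$varprop),
      out("fpca_varprop.csv")
    )
    harm <- dplyr::bind_rows(lapply(seq_len(q), function(l) {
      dplyr::mutate(harmonic_variation(fp, l), component = l,
                    .before = 1)
    }))
    readr::write_csv(harm, out("harmonic_variation.csv"))

    stage <- "clustering"
    assignments <- list()
    if (is.null(config$K) && "flm" %in% config$methods) {
      scan <- select_n_clusters(sm, K_range = config$K_range,
                                seed = config$seed)
      readr::write_csv(scan$table, out("bic_table.csv"))
      K <- scan$chosen
      assignments$flm <- scan$fits[[as.character(K)]]$assignment
    } else {
      K <- config$K
      if ("flm" %in% config$methods) {
        f <- fit_flm(sm, K, seed = config$seed)
        assignments$flm <- f$assignment
        readr::write_csv(glance.flm_model(f$model), out("bic_table.csv"))
      }
    }
    if ("two_stage" %in% config$methods) {
      assignments$two_stage <- cluster_two_stage(sm, K, seed = config$seed)
    }
    if ("distance_based" %in% config$methods) {
      assignments$distance_based <- cluster_distance_based(sm, q = q, K = K,
                                                           fpca = fp)
    }
    # harmonize labels to the first method's and export
    ref <- assignments[[1]]
    for (m in names(assignments)) {
      a <- if (m == names(assignments)[1]) assignments[[m]] else {
        harmonize_labels(ref, assignments[[m]], sm)
      }
      assignments[[m]] <- a
      readr::write_csv(tidy.cluster_assignment(a),
                       out(paste0("assignment_", m, ".csv")))
      mm <- membership_matrix(a)
      readr::write_csv(mm$wide, out(paste0("membership_", m, ".csv")))
    }

    stage <- "report"
    means <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
      sel <- ref$labels == k
      co <- colMeans(sm$coef[sel, , drop = FALSE])
      tibble::tibble(cluster = k, age = sm$ages,
                     dx = drop(eval_basis(basis, sm$ages) %*% co))
    }))
    readr::write_csv(means, out("cluster_means.csv"))
    if (!is.null(dat$labels)) {
      readr::write_csv(tibble::tibble(truth = dat$labels),
                       out("true_labels.csv"))
    }
    assignments
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  files <- list.files(config$out_dir, pattern = "\\.(csv|yml)$")
  manifest$files <- as.list(tools::md5sum(file.path(config$out_dir, files)))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(manifest, list(assignments = result, out_dir = config$out_dir)))
}
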