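#' Run the end-to-end report pipeline
#'
#' Executes the enabled analysis stages for each model in a run
#' configuration and writes a machine-readable bundle: `report.json` (the
#' configuration echoed verbatim, plus every stage's results), CSV side
#' tables of top features, and a plain-text log recording resolved
#' defaults and seeds. Every number in the report is reproducible from the
#' configuration and seed alone.
#'
#' A configuration is a named list (or path to a JSON file) with:
#' \describe{
#'   \item{seed}{Mandatory integer; master seed for all stochastic
#'     stages.}
#'   \item{stages}{Named flags: `discrimination`, `domains`, `penetrance`,
#'     `gait` (all default `TRUE` except `domains`).}
#'   \item{resample}{Optional overrides for [resample_config()].}
#'   \item{models}{A named list; each model either gives file inputs
#'     (`feature_table`, `gait_table` CSV paths) or simulation parameters
#'     (`cohort` = arguments to [cohort_spec()], `gait` = arguments to
#'     [generate_gait_table()]).}
#' }
#'
#' @param config A named list or a path to a JSON config file.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out_dir` or a temporary directory.
#' @return An object of class `report_bundle`: list with `report` (the
#'   full results list), `paths` of written files, and `errors` (named
#'   list of stage failures, empty on full success).
#' @export
run_report <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  if (is.null(config$seed)) abort("config must provide a seed")
  seed <- as.integer(config$seed)
  out_dir <- out_dir %||% config$out_dir %||% tempfile("phenodisc_report_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stages <- utils::modifyList(
    list(discrimination = TRUE, domains = FALSE, penetrance = TRUE,
         gait = TRUE),
    as.list(config$stages %||% list())
  )
  rs_args <- as.list(config$resample %||% list())
  rs_args$seed <- seed
  cfg <- do.call(resample_config, rs_args)

  log_path <- file.path(out_dir, "run.log")
  log_lines <- c(
    sprintf("phenodisc run: seed=%d", seed),
    sprintf("resample: n_repetitions=%d subsample_fraction=%g n_overlap_samples=%d",
            cfg$n_repetitions, cfg$subsample_fraction,
            cfg$n_overlap_samples),
    sprintf("stages: %s",
            paste(names(stages)[unlist(stages)], collapse = ", "))
  )
  errors <- list()
  paths <- c(report = file.path(out_dir, "report.json"), log = log_path)

  models <- config$models %||% list()
  if (!length(models)) abort("config must list at least one model")
  model_reports <- list()

  for (mi in seq_along(models)) {
    mname <- names(models)[mi] %||% paste0("model", mi)
    if (is.null(mname) || !nzchar(mname)) mname <- paste0("model", mi)
    mcfg <- models[[mi]]
    mrep <- list()
    log_lines <- c(log_lines, sprintf("model %s:", mname))

    run_stage <- function(stage, fun) {
      tryCatch(fun(), error = function(e) {
        errors[[paste(mname, stage, sep = "/")]] <<- conditionMessage(e)
        log_lines <<- c(log_lines, sprintf("  %s FAILED: %s", stage,
                                           conditionMessage(e)))
        NULL
      })
    }

    # --- inputs -----------------------------------------------------------
    ft <- run_stage("input", function() {
      if (!is.null(mcfg$feature_table)) {
        read_feature_table(mcfg$feature_table)
      } else if (!is.null(mcfg$cohort)) {
        ca <- mcfg$cohort
        ca$seed <- ca$seed %||% (seed + 13L * mi)
        if (!is.null(ca$effect_features) && length(ca$effect_features) == 2L &&
            !is.null(names(ca$effect_features))) {
          ca$effect_features <- seq(ca$effect_features[["from"]],
                                    ca$effect_features[["to"]])
        }
        domains <- ca$feature_domains
        ca$feature_domains <- NULL
        spec <- do.call(cohort_spec, ca)
        tab <- generate_feature_table(spec, feature_domains = domains)
        write_cohort_spec(spec, file.path(out_dir,
                                          paste0(mname, "_cohort_spec.json")))
        write_feature_table(tab, file.path(out_dir,
                                           paste0(mname, "_features.csv")))
        tab
      } else {
        NULL
      }
    })
    gt <- run_stage("gait_input", function() {
      if (!is.null(mcfg$gait_table)) {
        read_gait_table(mcfg$gait_table)
      } else if (!is.null(mcfg$gait)) {
        ga <- mcfg$gait
        ga$seed <- ga$seed %||% (seed + 17L * mi)
        tab <- do.call(generate_gait_table, ga)
        write_gait_table(tab, file.path(out_dir,
                                        paste0(mname, "_gait.csv")))
        tab
      } else {
        NULL
      }
    })

    # --- stages -----------------------------------------------------------
    if (isTRUE(stages$discrimination) && !is.null(ft)) {
      res <- run_stage("discrimination", function() discriminate(ft, cfg))
      if (!is.null(res)) {
        mrep$discrimination <- serialize_discrimination(res)
        tf_path <- file.path(out_dir, paste0(mname, "_top_features.csv"))
        readr::write_csv(res$top_features, tf_path)
        paths[paste0(mname, "_top_features")] <- tf_path
        log_lines <- c(log_lines,
                       sprintf("  discrimination: index=%.2f%% p=%.4g",
                               res$index, res$p_value))
      }
    }
    if (isTRUE(stages$domains) && !is.null(ft) &&
        !is.null(attr(ft, "domains"))) {
      res <- run_stage("domains", function() {
        domain_discrimination(ft, cfg = cfg)
      })
      if (!is.null(res)) {
        mrep$domains <- res |>
          dplyr::select(!"result") |>
          as.list()
        log_lines <- c(log_lines,
                       sprintf("  domains: %d analyzed", nrow(res)))
      }
    }
    if (isTRUE(stages$penetrance) && !is.null(ft)) {
      res <- run_stage("penetrance", function() {
        penetrance_analysis(ft, seed = seed)
      })
      if (!is.null(res)) {
        mrep$penetrance <- serialize_penetrance(res)
        log_lines <- c(log_lines,
                       sprintf("  penetrance: z_WT=%.3f z_MT=%.3f", res$z_WT,
                               res$z_MT))
      }
    }
    if (isTRUE(stages$gait) && !is.null(gt)) {
      res <- run_stage("gait", function() serialize_gait(gt))
      if (!is.null(res)) {
        mrep$gait <- res
        log_lines <- c(log_lines, "  gait: stride~speed and paw~weight fits")
      }
    }
    model_reports[[mname]] <- mrep
  }

  report <- list(
    config = config,
    resolved = list(seed = seed, stages = stages,
                    resample = unclass(cfg)),
    models = model_reports,
    errors = errors
  )
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  log_lines <- c(log_lines, sprintf("finished at %s",
                                    format(Sys.time(), usetz = TRUE)))
  writeLines(log_lines, log_path)

  structure(list(report = report, paths = paths, errors = errors,
                 out_dir = out_dir),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", length(x$report$models), " model(s) -> ",
      x$out_dir, "\n", sep = "")
  if (length(x$errors)) {
    cat("  stage failures:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

serialize_discrimination <- function(res) {
  list(
    index_percent = res$index,
    overlap = res$overlap,
    p_value = res$p_value,
    correct_distribution = res$correct_distribution$index,
    null_distribution = res$null_distribution$index,
    top_features = res$top_features,
    projection = list(
      coords = res$projection$coords,
      ellipses = res$projection$ellipses
    ),
    clouds = lapply(res$clouds, function(cl) {
      list(mean = cl$mean, covariance = cl$covariance, n = cl$n)
    })
  )
}

serialize_penetrance <- function(res) {
  list(
    scores = res$scores,
    z_WT = res$z_WT, z_MT = res$z_MT,
    sigma_WT = res$sigma_WT, sigma_MT = res$sigma_MT,
    mean_test = res$mean_test,
    variability_test = res$variability_test
  )
}

serialize_gait <- function(gt) {
  by_group <- split(gt, gt$group)
  stride_fits <- lapply(by_group, function(d) {
    f <- power_fit(d, x = speed, y = stride_duration)
    list(a = f$a, b = f$b, sigma = f$sigma, r.squared = f$r.squared,
         n = f$n)
  })
  paw_fits <- lapply(by_group, function(d) {
    f <- linear_fit(d, x = body_weight, y = paw_area)
    list(intercept = f$intercept, slope = f$slope, sigma = f$sigma,
         r.squared = f$r.squared, n = f$n)
  })
  stride_cmp <- compare_regressions(gt, x = speed, y = stride_duration,
                                    transform = "loglog")
  paw_cmp <- compare_regressions(gt, x = body_weight, y = paw_area,
                                 transform = "identity")
  list(
    stride_vs_speed = list(fits = stride_fits,
                           comparison = serialize_comparison(stride_cmp)),
    paw_vs_weight = list(fits = paw_fits,
                         comparison = serialize_comparison(paw_cmp))
  )
}

serialize_comparison <- function(cmp) {
  list(
    transform = cmp$transform,
    slope_difference = cmp$slope_difference, slope_p = cmp$slope_p,
    intercept_difference = cmp$intercept_difference,
    intercept_p = cmp$intercept_p,
    f_statistic = cmp$f_statistic, f_p = cmp$f_p,
    loo_slope_range = cmp$loo_slope_range
  )
}
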