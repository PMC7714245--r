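#' Pipeline configuration
#'
#' Builds (or reads from YAML) the configuration consumed by the pipeline
#' commands [cmd_simulate()], [cmd_metrics()], [cmd_predict()] and
#' [cmd_report()]. Defaults reproduce the standard analysis settings:
#' densities 0.10-0.15, 10000 permutation iterations, alpha 0.05, retention
#' of positive-r permutation-significant models.
#'
#' @param path Optional YAML file; keys override the defaults.
#' @param ... Named overrides applied after the file (CLI flags use this).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    input_dir = ".", output_dir = "stopnet-output",
    seed = 1L,
    densities = default_densities(),
    rank_rule = "ceiling", omission_policy = "exclude",
    n_perm = 10000L, alpha = 0.05,
    bf_sided = "two", power_ncp = "n",
    retain_sign = "positive",
    cohort = list(), sst = list(),
    simulate_sessions = FALSE, overwrite = FALSE
  )
  if (!is.null(path)) {
    stopifnot_param(file.exists(path), sprintf("config file not found: %s", path))
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, logical(1))]
  cfg <- modifyList(cfg, dots)
  stopifnot_param(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
  stopifnot_param(all(cfg$densities > 0 & cfg$densities <= 1),
                  "densities must lie in (0, 1]")
  stopifnot_param(cfg$n_perm >= 1, "n_perm must be positive")
  structure(cfg, class = "pipeline_config")
}

# Hash of the analysis-relevant configuration; file-system locations are
# excluded so runs in different directories compare equal.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$input_dir <- NULL
  cfg$output_dir <- NULL
  rlang::hash(cfg)
}

pipeline_log <- function(level, fmt, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

out_path <- function(config, ...) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(config$output_dir, ...)
  if (file.exists(p) && !isTRUE(config$overwrite)) {
    abort(sprintf("output exists and overwrite is FALSE: %s", p),
          class = "stopnet_io_error")
  }
  p
}

write_manifest <- function(config, stage, files) {
  manifest <- list(stage = stage, config_hash = config_hash(config),
                   seed = config$seed, files = sort(basename(files)))
  path <- file.path(config$output_dir, paste0("manifest-", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Pipeline stage commands
#'
#' Thin command wrappers over the package functions, each reading and
#' writing the documented CSV/JSON formats under `config$output_dir` and
#' recording a manifest (config hash + seed) so a rerun with the same config
#' is byte-reproducible. `cmd_simulate()` writes a synthetic cohort (one
#' connectivity matrix per subject, a parcellation table, a behavior table
#' and optional trial logs); `cmd_metrics()` reads matrices and parcellation
#' and writes the long-format nodal metric table; `cmd_predict()` reads
#' metrics and behavior and writes the per-network results CSV plus a
#' per-model JSON detail file; `cmd_report()` renders a plain-text summary
#' of the results.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the paths written.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmd_simulate <- function(config = pipeline_config()) {
  pipeline_log("INFO", "simulate: generating cohort (seed %d)", config$seed)
  params <- do.call(cohort_params, config$cohort)
  cohort <- generate_cohort(params, seed = config$seed,
                            densities = config$densities,
                            keep_connectomes = TRUE,
                            simulate_sessions = isTRUE(config$simulate_sessions))
  files <- character()
  files[1] <- write_parcellation(cohort$parcellation,
                                 out_path(config, "parcellation.csv"))
  files[2] <- write_behavior(cohort$behavior, out_path(config, "behavior.csv"))
  for (s in names(cohort$connectomes)) {
    files <- c(files, write_connectivity_matrix(
      cohort$connectomes[[s]],
      out_path(config, sprintf("connectivity_%s.csv", s))))
  }
  if (!is.null(cohort$sessions)) {
    for (s in names(cohort$sessions)) {
      files <- c(files, write_trial_log(
        cohort$sessions[[s]],
        out_path(config, sprintf("trials_%s.csv", s)), subject = s))
    }
  }
  files <- c(files, write_manifest(config, "simulate", files))
  pipeline_log("INFO", "simulate: wrote %d files", length(files))
  invisible(files)
}

#' @rdname pipeline-commands
#' @export
cmd_metrics <- function(config = pipeline_config()) {
  parc <- read_parcellation(file.path(config$input_dir, "parcellation.csv"))
  mats <- list.files(config$input_dir, pattern = "^connectivity_.*\\.csv$",
                     full.names = TRUE)
  stopifnot_param(length(mats) >= 1, "no connectivity_*.csv inputs found")
  pipeline_log("INFO", "metrics: %d subjects, %d densities",
               length(mats), length(config$densities))
  rows <- purrr::map(mats, function(f) {
    subject <- sub("^connectivity_(.*)\\.csv$", "\\1", basename(f))
    C <- read_connectivity_matrix(f)
    if (nrow(C) != nrow(parc)) {
      abort(sprintf("subject %s: matrix is %dx%d but parcellation has %d nodes",
                    subject, nrow(C), ncol(C), nrow(parc)),
            class = "stopnet_input_error")
    }
    m <- nodal_metrics(C, parc, densities = config$densities)
    m$subject <- subject
    dplyr::relocate(m, "subject")
  })
  metrics <- bind_rows(rows)
  f <- write_metrics(metrics, out_path(config, "metrics.csv"))
  write_manifest(config, "metrics", f)
  invisible(f)
}

#' @rdname pipeline-commands
#' @export
cmd_predict <- function(config = pipeline_config()) {
  metrics <- read_metrics(file.path(config$input_dir, "metrics.csv"))
  behavior <- read_behavior(file.path(config$input_dir, "behavior.csv"))
  missing <- setdiff(behavior$subject, metrics$subject)
  if (length(missing)) {
    abort(paste0("subjects missing from metrics: ",
                 paste(missing, collapse = ", ")),
          class = "stopnet_input_error")
  }
  cohort <- as_cohort(metrics, behavior)
  pipeline_log("INFO", "predict: %d subjects, %d networks, %d permutations",
               nrow(behavior), dplyr::n_distinct(cohort$parcellation$network),
               config$n_perm)
  results <- run_network_models(cohort, n_perm = config$n_perm,
                                alpha = config$alpha, seed = config$seed,
                                bf_sided = config$bf_sided,
                                power_ncp = config$power_ncp)
  f1 <- write_results(results, out_path(config, "results.csv"))
  details <- attr(results, "details")
  detail_json <- list(
    config_hash = config_hash(config), seed = config$seed,
    settings = attr(results, "settings"),
    models = purrr::map(details, function(d) {
      list(coefficients = as.list(d$coefficients),
           predictions = as.numeric(d$predictions),
           null_summary = as.list(setNames(as.numeric(d$null_summary),
                                           names(d$null_summary))))
    })
  )
  f2 <- out_path(config, "model_details.json")
  jsonlite::write_json(detail_json, f2, auto_unbox = TRUE, digits = NA)
  write_manifest(config, "predict", c(f1, f2))
  invisible(c(f1, f2))
}

#' @rdname pipeline-commands
#' @export
cmd_report <- function(config = pipeline_config()) {
  rf <- file.path(config$input_dir, "results.csv")
  stopifnot_param(file.exists(rf), sprintf("results file not found: %s", rf))
  results <- read_results(rf)
  lines <- c("stopnet prediction report",
             sprintf("config %s seed %d", config_hash(config), config$seed),
             "")
  if (nrow(results) == 0) {
    lines <- c(lines, "no models")
  } else {
    bar_unit <- 40
    for (i in seq_len(nrow(results))) {
      r <- results[i, ]
      bar <- strrep("#", round(abs(r$r_value %||% 0) * bar_unit))
      lines <- c(lines, sprintf(
        "%-4s %-12s r=%+ .3f p=%.4f power=%.2f %s %s",
        toupper(r$property), r$network, r$r_value, r$permutation_p,
        r$observed_power, ifelse(isTRUE(r$retained), "*", " "), bar))
    }
    lines <- c(lines, "", sprintf("%d/%d models retained (p < alpha, r > 0)",
                                  sum(results$retained, na.rm = TRUE),
                                  nrow(results)))
  }
  f <- out_path(config, "report.txt")
  writeLines(lines, f)
  write_manifest(config, "report", f)
  invisible(f)
}
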