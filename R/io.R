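#' Read and write stop-signal trial logs
#'
#' One row per trial with columns
#' `subject,block,trial,type,ssd_ms,rt_ms,response,correct`; `ssd_ms` is
#' empty on go trials and `rt_ms` empty when no response was emitted.
#'
#' @param session An `"sst_session"` tibble (or a bound set of them with a
#'   `subject` column already present).
#' @param path File path.
#' @param subject Subject id written into the log (ignored when the session
#'   already has a `subject` column).
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   returns a tibble with the columns above plus `staircase` if present.
#' @export
write_trial_log <- function(session, path, subject = "sub001") {
  d <- as_tibble(session)
  if (!"subject" %in% names(d)) d$subject <- subject
  d <- d[, intersect(c("subject", "block", "trial", "type", "ssd_ms",
                       "rt_ms", "response", "correct", "staircase"),
                     names(d))]
  readr::write_csv(d, path, na = "")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject = readr::col_character(),
                    block = readr::col_integer(),
                    trial = readr::col_integer(),
                    type = readr::col_character(),
                    ssd_ms = readr::col_double(),
                    rt_ms = readr::col_double(),
                    response = readr::col_logical(),
                    correct = readr::col_logical(),
                    .default = readr::col_guess()))
}

#' Read and write connectivity matrices
#'
#' Square CSV with a header row of node ids; values are the pairwise
#' correlations.
#'
#' @param C Square numeric matrix.
#' @param path File path.
#' @return `read_connectivity_matrix()` returns a numeric matrix with
#'   dimnames taken from the header.
#' @export
write_connectivity_matrix <- function(C, path) {
  C <- as.matrix(C)
  ids <- colnames(C) %||% as.character(seq_len(ncol(C)))
  d <- as_tibble(as.data.frame(C), .name_repair = ~ids)
  readr::write_csv(d, path)
  invisible(path)
}

#' @rdname write_connectivity_matrix
#' @export
read_connectivity_matrix <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  M <- as.matrix(d)
  stopifnot_param(nrow(M) == ncol(M), "connectivity matrix must be square")
  dimnames(M) <- list(colnames(d), colnames(d))
  M
}

#' Read and write parcellation tables
#'
#' CSV with columns `node_id,node_name,network_label` (the on-disk name of
#' the in-memory `network` column).
#'
#' @param parcellation Tibble with `node_id`, `node_name`, `network`.
#' @param path File path.
#' @return `read_parcellation()` returns a tibble with `node_id`,
#'   `node_name`, `network`.
#' @export
write_parcellation <- function(parcellation, path) {
  d <- tibble(node_id = parcellation$node_id,
              node_name = parcellation$node_name %||%
                as.character(parcellation$node_id),
              network_label = parcellation$network)
  readr::write_csv(d, path)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot_param(all(c("node_id", "network_label") %in% names(d)),
                  "parcellation CSV needs node_id and network_label columns")
  tibble(node_id = as.integer(d$node_id),
         node_name = if ("node_name" %in% names(d)) d$node_name
                     else as.character(d$node_id),
         network = d$network_label)
}

#' Read and write nodal metric tables
#'
#' Long-format CSV `subject,node_id,network,metric,value` with `metric` in
#' `{"pc", "wmd"}`.
#'
#' @param metrics Wide metric tibble (`subject`, `node_id`, `network`, `pc`,
#'   `wmd`).
#' @param path File path.
#' @return `read_metrics()` returns the wide tibble form.
#' @export
write_metrics <- function(metrics, path) {
  long <- tidyr::pivot_longer(metrics, dplyr::all_of(c("pc", "wmd")),
                              names_to = "metric", values_to = "value")
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  tidyr::pivot_wider(long, names_from = "metric", values_from = "value")
}

#' Read and write per-subject behavior tables
#'
#' CSV with columns `subject,ssrt_ms,motion`.
#'
#' @param behavior Tibble with those columns.
#' @param path File path.
#' @return `read_behavior()` returns the tibble.
#' @export
write_behavior <- function(behavior, path) {
  readr::write_csv(behavior[, c("subject", "ssrt_ms", "motion")], path)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write the per-network results table
#'
#' CSV with columns
#' `property,network,r_value,permutation_p,observed_power,bf10,retained`.
#'
#' @param results A `"network_models"` tibble.
#' @param path File path.
#' @return `read_results()` returns the tibble.
#' @export
write_results <- function(results, path) {
  d <- if (inherits(results, "network_models")) tidy(results) else
    as_tibble(results)
  d <- d[, c("property", "network", "r_value", "permutation_p",
                         "observed_power", "bf10", "retained")]
  readr::write_csv(d, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
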