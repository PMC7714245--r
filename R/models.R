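#' Assemble a cohort from metric and behavior tables
#'
#' Builds the cohort container consumed by [build_feature_block()] and
#' [run_network_models()]: a long per-node metric table plus a per-subject
#' behavior table (observed SSRT and a head-motion scalar), aligned on
#' subject id.
#'
#' @param metrics Tibble with columns `subject`, `node_id`, `network`, `pc`,
#'   `wmd` (one row per subject x node).
#' @param behavior Tibble with columns `subject`, `ssrt_ms`, `motion`.
#' @param parcellation Optional parcellation tibble (`node_id`, `network`);
#'   reconstructed from `metrics` if omitted.
#' @return An object of class `"sst_cohort"`.
#' @export
as_cohort <- function(metrics, behavior, parcellation = NULL) {
  stopifnot_param(all(c("subject", "node_id", "network", "pc", "wmd")
                      %in% names(metrics)),
                  "metrics needs subject/node_id/network/pc/wmd columns")
  stopifnot_param(all(c("subject", "ssrt_ms", "motion") %in% names(behavior)),
                  "behavior needs subject/ssrt_ms/motion columns")
  stopifnot_param(!anyNA(behavior$ssrt_ms) && !anyNA(behavior$motion),
                  "behavior must have no missing SSRT or motion")
  stopifnot_param(setequal(unique(metrics$subject), behavior$subject),
                  "metrics and behavior cover different subjects")
  if (is.null(parcellation)) {
    parcellation <- dplyr::distinct(metrics[metrics$subject ==
                                              metrics$subject[1],
                                            c("node_id", "network")])
    parcellation <- dplyr::arrange(parcellation, .data$node_id)
  }
  structure(list(metrics = tibble::as_tibble(metrics),
                 behavior = tibble::as_tibble(behavior),
                 parcellation = tibble::as_tibble(parcellation)),
            class = "sst_cohort")
}

#' @export
print.sst_cohort <- function(x, ...) {
  cat(sprintf("<sst_cohort> %d subjects, %d nodes, %d networks\n",
              nrow(x$behavior), nrow(x$parcellation),
              dplyr::n_distinct(x$parcellation$network)))
  invisible(x)
}

fit_r_squared <- function(X, y) {
  qrd <- design_qr(X)
  res <- qr.resid(qrd, y)
  1 - sum(res^2) / sum((y - mean(y))^2)
}

# Drop exactly aliased predictor columns (QR pivoting, as lm() does for
# aliased terms). Within-module degree z-scores sum to zero across a
# network's nodes by construction, so every WMD block carries one exactly
# redundant column; removing it spans the same column space and leaves the
# fitted values, leverages and LOOCV predictions unchanged.
drop_aliased_columns <- function(X) {
  D <- cbind(1, X)
  qrd <- qr(D)
  if (qrd$rank == ncol(D)) {
    return(list(X = X, aliased = character()))
  }
  keep <- sort(qrd$pivot[seq_len(qrd$rank)])
  if (!1 %in% keep) {
    abort("intercept aliased: predictors contain a constant column",
          class = "stopnet_rank_error")
  }
  keep_x <- keep[keep > 1] - 1
  aliased <- setdiff(seq_len(ncol(X)), keep_x)
  list(X = X[, keep_x, drop = FALSE],
       aliased = colnames(X)[aliased] %||% as.character(aliased))
}

#' Fit all per-network prediction models
#'
#' For every network x property (participation coefficient, within-module
#' degree) combination, fits the multiple regression
#' `SSRT ~ b0 + b1 node_1 + ... + bk node_k` over the network's nodes,
#' obtains leave-one-out cross-validated predictions, correlates them with
#' the observed SSRT partialling out head motion, and attaches a permutation
#' p-value, a Jeffreys correlation Bayes factor and the observed power of the
#' full fit. A model is `retained` when its permutation p-value is below
#' `alpha` and its partial correlation is positive. With a 17-network
#' parcellation this yields 34 models.
#'
#' @param cohort An `"sst_cohort"`.
#' @param n_perm Permutation iterations per model (default 10000).
#' @param alpha Significance level for retention (default 0.05).
#' @param seed Integer seed driving all permutations.
#' @param properties Properties to model (default both `"pc"` and `"wmd"`).
#' @param bf_sided Bayes factor sidedness, see [bf10_correlation()].
#' @param power_ncp Power noncentrality convention, see [posthoc_power()].
#' @param fdr If `TRUE`, append a Benjamini-Hochberg adjusted p column
#'   (`p_fdr`); off by default (uncorrected inference).
#' @param drop_aliased If `TRUE` (default), exactly redundant predictor
#'   columns are removed by QR pivoting before fitting (see Details); with
#'   `FALSE` a rank-deficient block is recorded as a failed model instead.
#'
#' @details Within-module degree z-scores sum to zero across the nodes of a
#'   network, so a network's full WMD block is always rank-deficient by one
#'   column. Dropping an exactly aliased column is a reparametrization that
#'   spans the same column space, leaving fitted values and leave-one-out
#'   predictions unchanged; the dropped node ids are recorded per model in
#'   the `"details"` attribute. Nothing is ever numerically regularized.
#' @return A tibble of class `"network_models"`, one row per model, sorted by
#'   property then network: `property`, `network`, `n_nodes`, `r_value`,
#'   `permutation_p`, `bf10`, `observed_power`, `r_squared`, `retained`,
#'   `error` (NA unless the model failed). Full-fit coefficients and LOOCV
#'   predictions are attached as the `"details"` attribute (a named list).
#' @examples
#' cohort <- generate_cohort(cohort_params(n_subjects = 20, n_nodes = 24,
#'                                         n_networks = 3), seed = 1,
#'                           densities = c(0.30, 0.35))
#' run_network_models(cohort, n_perm = 200, seed = 1)
#' @export
run_network_models <- function(cohort, n_perm = 10000, alpha = 0.05,
                               seed = NULL, properties = c("pc", "wmd"),
                               bf_sided = "two", power_ncp = "n",
                               fdr = FALSE, drop_aliased = TRUE) {
  stopifnot_param(inherits(cohort, "sst_cohort"), "cohort must be an sst_cohort")
  networks <- sort(unique(cohort$parcellation$network))
  stopifnot_param(length(networks) >= 2, "need at least 2 networks")
  y <- cohort$behavior$ssrt_ms
  motion <- cohort$behavior$motion
  n <- length(y)

  grid <- tidyr::expand_grid(property = properties, network = networks)
  details <- list()
  rows <- purrr::pmap(grid, function(property, network) {
    X <- build_feature_block(cohort, network, property)
    k <- ncol(X)
    model_seed <- if (is.null(seed)) NULL else
      (as.integer(seed) + 7L * match(network, networks) +
         131L * match(property, properties)) %% .Machine$integer.max
    res <- tryCatch({
      aliased <- character()
      if (drop_aliased) {
        dropped <- drop_aliased_columns(X)
        X <- dropped$X
        aliased <- dropped$aliased
      }
      k_fit <- ncol(X)
      pred <- loocv_predict(X, y)
      r <- partial_pearson(pred, y, motion)
      perm <- permutation_pvalue(X, y, motion, n_iter = n_perm,
                                 seed = model_seed)
      r2 <- fit_r_squared(X, y)
      coefs <- qr.coef(design_qr(X), y)
      details[[paste(property, network, sep = ".")]] <<- list(
        coefficients = coefs, predictions = pred, aliased = aliased,
        null_summary = summary(perm$null))
      tibble(property = property, network = network, n_nodes = k,
             r_value = r, permutation_p = perm$p_value,
             bf10 = bf10_correlation(r, n, sided = bf_sided),
             observed_power = posthoc_power(r2, n, k_fit, alpha = alpha,
                                            ncp = power_ncp),
             r_squared = r2,
             retained = perm$p_value < alpha && r > 0,
             error = NA_character_)
    }, error = function(e) {
      tibble(property = property, network = network, n_nodes = k,
             r_value = NA_real_, permutation_p = NA_real_, bf10 = NA_real_,
             observed_power = NA_real_, r_squared = NA_real_,
             retained = NA, error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::arrange(bind_rows(rows), .data$property, .data$network)
  if (fdr) out$p_fdr <- stats::p.adjust(out$permutation_p, method = "BH")
  attr(out, "details") <- details
  attr(out, "settings") <- list(n_perm = n_perm, alpha = alpha, seed = seed,
                                bf_sided = bf_sided, power_ncp = power_ncp,
                                n_subjects = n)
  class(out) <- c("network_models", class(out))
  out
}

#' @rdname run_network_models
#' @param x,... A `"network_models"` table; further arguments are ignored.
#' @method tidy network_models
#' @export
tidy.network_models <- function(x, ...) {
  out <- x
  attr(out, "details") <- NULL
  attr(out, "settings") <- NULL
  class(out) <- setdiff(class(out), "network_models")
  out
}

#' @rdname run_network_models
#' @method glance network_models
#' @export
glance.network_models <- function(x, ...) {
  s <- attr(x, "settings")
  tibble(n_models = nrow(x), n_retained = sum(x$retained, na.rm = TRUE),
         n_failed = sum(!is.na(x$error)),
         n_subjects = s$n_subjects, n_perm = s$n_perm, alpha = s$alpha)
}

#' Bar chart of per-network prediction accuracy
#'
#' Partial correlation between predicted and observed SSRT for each network,
#' faceted by property, with retained (permutation-significant, positive-r)
#' models starred.
#'
#' @param object A `"network_models"` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot network_models
#' @export
autoplot.network_models <- function(object, ...) {
  d <- tidy(object)
  d$star <- ifelse(!is.na(d$retained) & d$retained, "*", "")
  ggplot2::ggplot(d, ggplot2::aes(.data$network, .data$r_value,
                                  fill = .data$property)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$star), vjust = 0, size = 6) +
    ggplot2::facet_wrap(~property, ncol = 1,
                        labeller = ggplot2::as_labeller(toupper)) +
    ggplot2::labs(x = NULL, y = "partial r (predicted vs observed SSRT)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
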