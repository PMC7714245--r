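#' Generate a node-to-network parcellation
#'
#' Partitions `n_nodes` nodes into `n_networks` labelled networks with sizes
#' as equal as possible (or exactly `sizes` if given). Labels are `"N01"`,
#' `"N02"`, ... and nodes are assigned in contiguous runs, so the same
#' arguments always produce the same table.
#'
#' @param n_nodes Number of nodes (default 400).
#' @param n_networks Number of networks (default 17).
#' @param sizes Optional integer vector of per-network sizes summing to
#'   `n_nodes`.
#' @param seed Unused for the contiguous layout; accepted for interface
#'   symmetry with the other generators.
#' @return A tibble with columns `node_id`, `node_name`, `network`.
#' @export
generate_parcellation <- function(n_nodes = 400, n_networks = 17,
                                  sizes = NULL, seed = NULL) {
  stopifnot_param(n_networks >= 2 && n_networks <= n_nodes,
                  "need 2 <= n_networks <= n_nodes")
  if (is.null(sizes)) {
    base <- n_nodes %/% n_networks
    sizes <- rep(base, n_networks)
    extra <- n_nodes - base * n_networks
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  }
  stopifnot_param(length(sizes) == n_networks && all(sizes >= 1) &&
                    sum(sizes) == n_nodes,
                  "sizes must be positive and sum to n_nodes")
  network <- rep(sprintf("N%02d", seq_len(n_networks)), times = sizes)
  tibble(node_id = seq_len(n_nodes),
         node_name = sprintf("%s_node%03d", network, seq_len(n_nodes)),
         network = network)
}

#' Synthetic cohort parameters
#'
#' Parameters of the synthetic-cohort generator: a weighted stochastic-block
#' connectome per subject (strong within-network weights, weak between-
#' network weights) in which one designated network's between-network weights
#' are shifted linearly by a latent per-subject signal, so that the subject's
#' mean participation coefficient of that network rises with the signal; the
#' observed SSRT is a linear function of the signal plus a head-motion
#' nuisance and Gaussian noise.
#'
#' The desk-scale defaults (60 nodes, 6 networks, 40 subjects) keep the full
#' pipeline fast while preserving the modular structure; `n_nodes = 400`,
#' `n_networks = 17` reproduces the full-scale shape.
#'
#' @param n_subjects Number of subjects (>= 10).
#' @param n_nodes,n_networks Parcellation shape.
#' @param within_mean,within_sd Weight distribution of within-network pairs.
#' @param between_mean,between_sd Weight distribution of between-network
#'   pairs.
#' @param signal_network Label of the network carrying the behavioral signal.
#' @param signal_scale Shift (correlation units) of the signal network's
#'   between-network weights per SD of the latent subject signal.
#' @param beta_ms Effect on SSRT, ms per SD of the latent signal.
#' @param noise_sd_ms Residual SSRT noise sd, ms.
#' @param intercept_ms Baseline SSRT, ms.
#' @param motion_coef_ms SSRT shift per mm of mean frame-to-frame motion.
#' @param motion_meanlog,motion_sdlog Log-normal parameters of the motion
#'   scalar (mm).
#' @return A list of class `"cohort_params"`.
#' @export
cohort_params <- function(n_subjects = 40, n_nodes = 60, n_networks = 6,
                          within_mean = 0.5, within_sd = 0.12,
                          between_mean = 0.15, between_sd = 0.12,
                          signal_network = "N01", signal_scale = 0.05,
                          beta_ms = 40, noise_sd_ms = 70,
                          intercept_ms = 220, motion_coef_ms = 150,
                          motion_meanlog = log(0.1), motion_sdlog = 0.4) {
  p <- list(n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
            n_networks = as.integer(n_networks),
            within_mean = within_mean, within_sd = within_sd,
            between_mean = between_mean, between_sd = between_sd,
            signal_network = signal_network, signal_scale = signal_scale,
            beta_ms = beta_ms, noise_sd_ms = noise_sd_ms,
            intercept_ms = intercept_ms, motion_coef_ms = motion_coef_ms,
            motion_meanlog = motion_meanlog, motion_sdlog = motion_sdlog)
  stopifnot_param(p$n_subjects >= 10, "need n_subjects >= 10")
  stopifnot_param(p$within_sd >= 0 && p$between_sd >= 0 && p$noise_sd_ms >= 0,
                  "sds must be >= 0")
  parc <- generate_parcellation(p$n_nodes, p$n_networks)
  stopifnot_param(p$signal_network %in% parc$network,
                  sprintf("signal network '%s' not in parcellation",
                          p$signal_network))
  structure(p, class = "cohort_params")
}

#' Generate one subject's weighted connectome
#'
#' Weighted stochastic-block correlation matrix: within-network pair weights
#' are drawn around `within_mean`, between-network pairs around
#' `between_mean`, and every between-network pair touching the signal
#' network is shifted by `signal_scale * subject_signal`. Weights are
#' truncated to \[-1, 1\].
#'
#' @param params A [cohort_params()] object.
#' @param subject_signal Latent signal of the subject, in SD units.
#' @param seed Integer seed.
#' @param parcellation Optional precomputed parcellation (saves rebuilding).
#' @return Symmetric `n_nodes` x `n_nodes` matrix with unit diagonal.
#' @export
generate_connectome <- function(params, subject_signal = 0, seed = NULL,
                                parcellation = NULL) {
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  if (abs(params$within_mean) > 1 || abs(params$between_mean) > 1) {
    warn("block mean weights outside [-1, 1] will be truncated")
  }
  parc <- parcellation %||%
    generate_parcellation(params$n_nodes, params$n_networks)
  lab <- parc$network
  n <- params$n_nodes
  with_seed(seed, {
    same <- outer(lab, lab, `==`)
    sig_touch <- outer(lab == params$signal_network,
                       lab == params$signal_network, `|`)
    mu <- ifelse(same, params$within_mean,
                 params$between_mean +
                   ifelse(sig_touch, params$signal_scale * subject_signal, 0))
    sdm <- ifelse(same, params$within_sd, params$between_sd)
    W <- matrix(rnorm(n * n), n, n)
    W <- mu + sdm * W
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    W <- pmin(pmax(W, -1), 1)
    diag(W) <- 1
    dimnames(W) <- list(parc$node_id, parc$node_id)
    W
  })
}

#' Generate a synthetic cohort
#'
#' Draws a latent standard-normal signal per subject, builds the subject's
#' connectome with [generate_connectome()], computes threshold-averaged nodal
#' metrics with [nodal_metrics()], draws a log-normal head-motion scalar, and
#' assigns `SSRT = intercept + beta * signal + motion_coef * motion + noise`.
#' Optionally also simulates a full stop-signal session per subject whose
#' race-model true SSRT equals the assigned value.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed; every subject's randomness derives from it.
#' @param densities Density grid for [nodal_metrics()].
#' @param keep_connectomes If `TRUE`, attach the raw matrices.
#' @param simulate_sessions If `TRUE`, simulate an SST session per subject
#'   (slower); sessions are attached as `sessions`.
#' @return An `"sst_cohort"` with an extra `truth` tibble (`subject`,
#'   `signal`, plus the generating parameters as attribute `"params"`).
#' @export
generate_cohort <- function(params = cohort_params(), seed = NULL,
                            densities = default_densities(),
                            keep_connectomes = FALSE,
                            simulate_sessions = FALSE) {
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  parc <- generate_parcellation(params$n_nodes, params$n_networks)
  with_seed(seed, {
    subjects <- sprintf("sub%03d", seq_len(params$n_subjects))
    signal <- rnorm(params$n_subjects)
    motion <- stats::rlnorm(params$n_subjects, params$motion_meanlog,
                            params$motion_sdlog)
    noise <- rnorm(params$n_subjects, 0, params$noise_sd_ms)
    ssrt <- params$intercept_ms + params$beta_ms * signal +
      params$motion_coef_ms * motion + noise
    ssrt <- pmax(ssrt, 50)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, params$n_subjects)

    conns <- vector("list", params$n_subjects)
    metrics <- vector("list", params$n_subjects)
    sessions <- if (simulate_sessions) vector("list", params$n_subjects)
    for (i in seq_len(params$n_subjects)) {
      W <- generate_connectome(params, signal[i], seed = sub_seeds[i],
                               parcellation = parc)
      m <- nodal_metrics(W, parc, densities = densities)
      m$subject <- subjects[i]
      metrics[[i]] <- m
      if (keep_connectomes) conns[[i]] <- W
      if (simulate_sessions) {
        sessions[[i]] <- simulate_sst(sst_params(ssrt_true = ssrt[i]),
                                      seed = sub_seeds[i])
      }
    }
    cohort <- as_cohort(
      metrics = dplyr::relocate(bind_rows(metrics), "subject"),
      behavior = tibble(subject = subjects, ssrt_ms = ssrt, motion = motion),
      parcellation = parc
    )
    cohort$truth <- tibble(subject = subjects, signal = signal)
    attr(cohort, "params") <- params
    if (keep_connectomes) cohort$connectomes <- setNames(conns, subjects)
    if (simulate_sessions) cohort$sessions <- setNames(sessions, subjects)
    cohort
  })
}
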