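#' Pearson correlation matrix between ROI time series
#'
#' @param timeseries T x N numeric matrix (time points by nodes), T >= 3.
#'   Column names, if present, are kept as node ids.
#' @return N x N symmetric correlation matrix.
#' @export
roi_correlation_matrix <- function(timeseries) {
  timeseries <- as.matrix(timeseries)
  stopifnot_param(nrow(timeseries) >= 3, "need at least 3 time points")
  sds <- apply(timeseries, 2, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- colnames(timeseries)[bad] %||% as.character(bad)
    abort(paste0("constant time series for node(s): ",
                 paste(nm, collapse = ", ")),
          class = "stopnet_input_error")
  }
  cor(timeseries)
}

#' Binarize a connectivity matrix at a proportional density threshold
#'
#' Keeps the strongest positive off-diagonal correlations so that the number
#' of retained undirected edges equals `round(density * N * (N - 1) / 2)`,
#' then sets them to 1. Negative correlations are never retained. Ties at the
#' cutoff are broken deterministically by (weight descending, then smaller
#' node-index pair).
#'
#' @param C Symmetric N x N connectivity matrix; the diagonal is ignored.
#' @param density Proportion of possible edges to keep, in (0, 1].
#' @return N x N adjacency matrix in `{0, 1}` with zero diagonal and
#'   attributes `density` (requested) and `n_edges` (retained).
#' @export
threshold_by_density <- function(C, density) {
  C <- as.matrix(C)
  n <- nrow(C)
  stopifnot_param(n == ncol(C), "C must be square")
  stopifnot_param(is.numeric(density) && length(density) == 1 &&
                    density > 0 && density <= 1,
                  "density must lie in (0, 1]")
  idx <- which(upper.tri(C), arr.ind = TRUE)
  w <- C[idx]
  target <- round(density * n * (n - 1) / 2)
  pos <- which(w > 0)
  if (length(pos) < target) {
    warn(sprintf("only %d positive edges available for target %d; keeping all",
                 length(pos), target))
    keep <- pos
  } else {
    # stable tie-break: weight desc, then row, then col
    ord <- order(-w[pos], idx[pos, 1], idx[pos, 2])
    keep <- pos[ord[seq_len(target)]]
  }
  A <- matrix(0, n, n, dimnames = dimnames(C))
  A[idx[keep, , drop = FALSE]] <- 1
  A <- A + t(A)
  attr(A, "density") <- density
  attr(A, "n_edges") <- length(keep)
  A
}

labels_for_graph <- function(A, parcellation) {
  if (is.data.frame(parcellation)) {
    stopifnot_param(all(c("node_id", "network") %in% names(parcellation)),
                    "parcellation needs node_id and network columns")
    lab <- parcellation$network[order(parcellation$node_id)]
  } else {
    lab <- as.character(parcellation)
  }
  stopifnot_param(length(lab) == nrow(A),
                  "parcellation does not match graph size")
  lab
}

#' Participation coefficient of each node
#'
#' `PC_i = 1 - sum_s (K_is / K_i)^2`, where `K_i` is the degree of node `i`
#' and `K_is` its number of edges into network `s`. A node whose edges all
#' stay inside one network has PC 0; spreading edges evenly over the `N_M`
#' networks approaches the upper bound `1 - 1/N_M`. Isolated nodes
#' (`K_i = 0`) are assigned PC 0.
#'
#' @param A Binary symmetric adjacency matrix (e.g. from
#'   [threshold_by_density()]).
#' @param parcellation Parcellation tibble (`node_id`, `network`) or a
#'   character vector of per-node network labels.
#' @return Numeric vector of PC values, one per node.
#' @export
participation_coefficient <- function(A, parcellation) {
  A <- as.matrix(A)
  lab <- labels_for_graph(A, parcellation)
  M <- stats::model.matrix(~ 0 + factor(lab))   # N x n_networks indicator
  Kis <- A %*% M
  Ki <- rowSums(A)
  pc <- 1 - rowSums((Kis / ifelse(Ki > 0, Ki, 1))^2)
  pc[Ki == 0] <- 0
  as.numeric(pc)
}

#' Within-module degree z-score of each node
#'
#' For node `i` in network `s` with within-network degree `k_i`,
#' `WMD_i = (k_i - mean(k in s)) / sd(k in s)`. The sd is the population sd
#' over the network's nodes by default. Networks whose within-degree sd is
#' zero get WMD 0 for all their nodes.
#'
#' @inheritParams participation_coefficient
#' @param sd_type `"population"` (divide by module size, default) or
#'   `"sample"`.
#' @return Numeric vector of WMD values, one per node.
#' @export
within_module_degree <- function(A, parcellation,
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  A <- as.matrix(A)
  lab <- labels_for_graph(A, parcellation)
  sizes <- table(lab)
  if (any(sizes < 2)) {
    abort(paste0("singleton network(s): ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")),
          class = "stopnet_input_error")
  }
  wmd <- numeric(nrow(A))
  for (s in unique(lab)) {
    members <- which(lab == s)
    k <- rowSums(A[members, members, drop = FALSE])
    mu <- mean(k)
    sdev <- if (sd_type == "population") {
      sqrt(mean((k - mu)^2))
    } else {
      sd(k)
    }
    wmd[members] <- if (sdev > 0) (k - mu) / sdev else 0
  }
  wmd
}

#' Nodal metrics averaged over a density grid
#'
#' Binarizes a weighted connectivity matrix at each density, computes the
#' participation coefficient and within-module degree z-score per node, and
#' averages both metrics elementwise across densities. The default grid is
#' 0.10 to 0.15 in steps of 0.01.
#'
#' @param C Weighted symmetric connectivity matrix.
#' @param parcellation Parcellation tibble (`node_id`, `network`) or label
#'   vector.
#' @param densities Numeric vector of densities in (0, 1].
#' @param sd_type Passed to [within_module_degree()].
#' @param weighted_pc If `TRUE`, compute the participation coefficient from
#'   the positive connection weights themselves (strengths) rather than from
#'   the binarized graphs; the WMD is still computed on the binarized graphs.
#'   Default `FALSE`: both metrics use the same binarized graphs.
#' @return A tibble with one row per node: `node_id`, `network`, `pc`, `wmd`;
#'   the density grid is attached as attribute `"densities"`.
#' @examples
#' parc <- generate_parcellation(n_nodes = 30, n_networks = 3, seed = 1)
#' C <- generate_connectome(cohort_params(n_nodes = 30, n_networks = 3),
#'                          subject_signal = 0, seed = 1)
#' nodal_metrics(C, parc)
#' @export
nodal_metrics <- function(C, parcellation,
                          densities = default_densities(),
                          sd_type = "population", weighted_pc = FALSE) {
  stopifnot_param(length(densities) >= 1 && all(densities > 0 & densities <= 1),
                  "densities must be non-empty, each in (0, 1]")
  C <- as.matrix(C)
  lab <- labels_for_graph(C, parcellation)
  if (weighted_pc) {
    W <- pmax(C, 0)
    diag(W) <- 0
    pc_w <- participation_coefficient(W, lab)
  }
  pc_acc <- wmd_acc <- 0
  for (d in densities) {
    A <- threshold_by_density(C, d)
    pc_acc <- pc_acc + participation_coefficient(A, lab)
    wmd_acc <- wmd_acc + within_module_degree(A, lab, sd_type = sd_type)
  }
  out <- tibble(node_id = seq_along(lab), network = lab,
                pc = if (weighted_pc) pc_w else pc_acc / length(densities),
                wmd = wmd_acc / length(densities))
  attr(out, "densities") <- densities
  out
}

#' Default density grid for threshold averaging
#'
#' @return `seq(0.10, 0.15, by = 0.01)`.
#' @export
default_densities <- function() seq(0.10, 0.15, by = 0.01)
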