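# Hand-buildable fixtures used across test files.

# A minimal session data frame with full control over every trial.
make_session <- function(block, type, rt_ms, response, ssd_ms,
                         correct = NULL) {
  if (is.null(correct)) {
    correct <- ifelse(type == "go", response, !response)
  }
  tibble::tibble(block = block, trial = seq_along(block), type = type,
                 stimulus = "left", response = response, correct = correct,
                 rt_ms = rt_ms, ssd_ms = ssd_ms,
                 staircase = ifelse(type == "stop", 1L, NA_integer_))
}

# Symmetric binary adjacency from an edge list on n nodes.
adj_from_edges <- function(n, edges) {
  A <- matrix(0, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  A
}

# Random symmetric weight matrix with unit diagonal.
random_weight_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    C <- matrix(runif(n * n, -1, 1), n, n)
    C[lower.tri(C)] <- t(C)[lower.tri(C)]
    diag(C) <- 1
    C
  })
}

# Brute-force participation coefficient by explicit per-node edge tally.
pc_brute <- function(A, lab) {
  sapply(seq_len(nrow(A)), function(i) {
    Ki <- sum(A[i, ])
    if (Ki == 0) return(0)
    1 - sum(sapply(unique(lab), function(s) (sum(A[i, lab == s]) / Ki)^2))
  })
}
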