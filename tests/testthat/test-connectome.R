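test_that("ROI correlation matrix matches the definitional computation", {
  ts <- withr::with_seed(10, matrix(rnorm(300), 50, 6))
  C <- roi_correlation_matrix(ts)
  manual <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    xi <- ts[, i] - mean(ts[, i]); xj <- ts[, j] - mean(ts[, j])
    manual[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(unname(C), manual)
  expect_equal(C, t(C))

  # identical columns correlate at 1; orthogonal sinusoids at ~0
  ts2 <- cbind(a = ts[, 1], b = ts[, 1])
  expect_equal(roi_correlation_matrix(ts2)["a", "b"], 1)
  t_grid <- seq(0, 4 * pi, length.out = 101)[-101]
  C3 <- roi_correlation_matrix(cbind(sin(t_grid), cos(t_grid)))
  expect_lt(abs(C3[1, 2]), 1e-10)

  expect_error(roi_correlation_matrix(cbind(ts, k = rep(1, 50))), "k",
               class = "stopnet_input_error")
})

test_that("density thresholding keeps exactly the strongest positive edges", {
  C <- random_weight_matrix(10, seed = 1)
  C[] <- abs(C); diag(C) <- 1  # all-positive distinct weights
  A <- threshold_by_density(C, 0.2)
  expect_equal(sum(A) / 2, round(0.2 * 45)) # 9 edges
  # they are the 9 largest off-diagonal weights
  w <- C[upper.tri(C)]
  cutoff <- sort(w, decreasing = TRUE)[9]
  expect_true(all(C[A == 1] >= cutoff))
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
  # density 1 on an all-positive matrix gives the complete graph
  A1 <- threshold_by_density(C, 1)
  expect_equal(sum(A1) / 2, 45)
})

test_that("negative correlations are never retained and shortfalls warn", {
  C <- matrix(-0.5, 6, 6); diag(C) <- 1
  C[1, 2] <- C[2, 1] <- 0.9
  C[3, 4] <- C[4, 3] <- 0.8
  expect_warning(A <- threshold_by_density(C, 0.5), "positive")
  expect_equal(sum(A) / 2, 2)
  expect_equal(A[1, 2], 1)
  expect_equal(A[5, 6], 0)
  expect_error(threshold_by_density(C, 0), class = "stopnet_param_error")
  expect_error(threshold_by_density(C, 1.2), class = "stopnet_param_error")
})

test_that("participation coefficient boundary cases", {
  # node 1 keeps every edge inside its own 4-node module
  lab <- rep(c("m1", "m2", "m3"), each = 4)
  A <- adj_from_edges(12, list(c(1, 2), c(1, 3), c(1, 4), c(2, 5), c(5, 6),
                               c(9, 10), c(6, 9)))
  pc <- participation_coefficient(A, lab)
  expect_identical(pc[1], 0)
  # a node with one edge into each of 17 networks: PC = 1 - 17 (1/17)^2
  lab17 <- c("h", paste0("n", 1:17))
  A17 <- adj_from_edges(18, lapply(2:18, function(j) c(1, j)))
  expect_equal(participation_coefficient(A17, lab17)[1], 16 / 17)
  # isolated node gets PC 0 by convention
  expect_identical(pc[12], 0)
})

test_that("PC and WMD match brute-force oracles on random graphs", {
  for (seed in c(3, 4)) {
    A <- withr::with_seed(seed, {
      A <- matrix(rbinom(900, 1, 0.3), 30, 30)
      A[lower.tri(A)] <- t(A)[lower.tri(A)]; diag(A) <- 0; A
    })
    lab <- withr::with_seed(seed, sample(rep(c("a", "b", "c", "d"), length.out = 30)))
    expect_equal(participation_coefficient(A, lab), pc_brute(A, lab))
    wmd <- within_module_degree(A, lab)
    for (s in unique(lab)) {
      m <- which(lab == s)
      k <- rowSums(A[m, m, drop = FALSE])
      z <- if (sd(k) > 0) (k - mean(k)) / sqrt(mean((k - mean(k))^2)) else 0 * k
      expect_equal(wmd[m], z)
      expect_lt(abs(mean(wmd[m])), 1e-12) # zero mean within module
    }
  }
})

test_that("WMD hand example and degenerate modules", {
  # 3-node module with edges a-b, a-c: within-degrees 2,1,1 (population sd)
  lab <- c("x", "x", "x", "y", "y")
  A <- adj_from_edges(5, list(c(1, 2), c(1, 3), c(4, 5)))
  wmd <- within_module_degree(A, lab)
  expect_equal(wmd[1], sqrt(2), tolerance = 1e-12)
  expect_equal(wmd[2], -1 / sqrt(2), tolerance = 1e-12)
  # equal within-degrees give 0 for the whole module
  expect_equal(wmd[4:5], c(0, 0))
  # sample-sd option rescales by sqrt((m-1)/m)
  wmd_s <- within_module_degree(A, lab, sd_type = "sample")
  expect_equal(wmd_s[1], wmd[1] * sqrt(2 / 3), tolerance = 1e-12)
  expect_error(within_module_degree(A, c("x", "x", "x", "y", "z")), "z",
               class = "stopnet_input_error")
})

test_that("metrics are equivariant under node relabelling", {
  C <- random_weight_matrix(24, seed = 6)
  lab <- rep(c("a", "b", "c"), each = 8)
  perm <- withr::with_seed(9, sample(24))
  A <- threshold_by_density(C, 0.3)
  Ap <- threshold_by_density(C[perm, perm], 0.3)
  expect_equal(participation_coefficient(A, lab)[perm],
               participation_coefficient(Ap, lab[perm]))
  expect_equal(within_module_degree(A, lab)[perm],
               within_module_degree(Ap, lab[perm]))
  # and identical on the transposed adjacency
  expect_equal(participation_coefficient(t(A), lab),
               participation_coefficient(A, lab))
})

test_that("PC stays within [0, 1 - 1/N_M] whenever degrees are positive", {
  for (seed in 1:5) {
    n_mod <- withr::with_seed(seed, sample(2:6, 1))
    C <- random_weight_matrix(30, seed = seed + 50)
    lab <- rep(paste0("m", seq_len(n_mod)), length.out = 30)
    A <- threshold_by_density(C, 0.25)
    pc <- participation_coefficient(A, lab)
    expect_true(all(pc >= 0))
    expect_true(all(pc <= 1 - 1 / n_mod + 1e-12))
  }
})

test_that("threshold averaging equals the mean of single-density tables", {
  C <- random_weight_matrix(50, seed = 12)
  parc <- generate_parcellation(n_nodes = 50, n_networks = 5)
  single <- nodal_metrics(C, parc, densities = 0.12)
  direct_A <- threshold_by_density(C, 0.12)
  expect_equal(single$pc, participation_coefficient(direct_A, parc))
  expect_equal(single$wmd, within_module_degree(direct_A, parc))

  two <- nodal_metrics(C, parc, densities = c(0.10, 0.15))
  a <- nodal_metrics(C, parc, densities = 0.10)
  b <- nodal_metrics(C, parc, densities = 0.15)
  expect_equal(two$pc, (a$pc + b$pc) / 2)
  expect_equal(two$wmd, (a$wmd + b$wmd) / 2)

  # default grid matches an explicit loop-and-average oracle
  full <- nodal_metrics(C, parc)
  acc_pc <- acc_wmd <- 0
  for (d in seq(0.10, 0.15, by = 0.01)) {
    A <- threshold_by_density(C, d)
    acc_pc <- acc_pc + participation_coefficient(A, parc)
    acc_wmd <- acc_wmd + within_module_degree(A, parc)
  }
  expect_equal(full$pc, acc_pc / 6)
  expect_equal(full$wmd, acc_wmd / 6)
})

test_that("connectivity matrices and parcellations round-trip through CSV", {
  C <- random_weight_matrix(8, seed = 3)
  dimnames(C) <- list(1:8, 1:8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_connectivity_matrix(C, f)
  expect_equal(unname(read_connectivity_matrix(f)), unname(C))

  parc <- generate_parcellation(n_nodes = 20, n_networks = 4)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_parcellation(parc, f2)
  expect_equal(read_parcellation(f2), parc)
})
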