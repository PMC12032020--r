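## Dense oracle for the diffusion map: eigendecompose the nonsymmetric
## Markov operator directly (an independent numerical route from the
## symmetric-conjugate solver used by the implementation).
diffusion_oracle <- function(W, n_components = 10, alpha = 0.5) {
  d <- rowSums(W)
  W1 <- W / outer(d^alpha, d^alpha)
  M <- W1 / rowSums(W1)
  e <- eigen(M)
  ord <- order(Re(e$values), decreasing = TRUE)
  lam <- Re(e$values[ord])
  vec <- Re(e$vectors[, ord])
  idx <- 1 + seq_len(n_components)
  vec[, idx, drop = FALSE] *
    matrix(lam[idx] / (1 - lam[idx]), nrow(W), n_components, byrow = TRUE)
}

test_that("diffusion_map matches the dense nonsymmetric eigensolver oracle", {
  A <- random_affinity(100, seed = 21)
  got <- diffusion_map(A, n_components = 10, alpha = 0.5)
  want <- diffusion_oracle(A, 10, 0.5)
  expect_equal(diff(got$eigenvalues) <= 1e-12, rep(TRUE, 9))
  for (j in 1:10) {
    expect_gt(abs(cor(got$components[, j], want[, j])), 0.999)
  }
})

test_that("the first gradient separates a two-block affinity by sign", {
  n <- 40
  A <- matrix(0.01, n, n)
  A[1:20, 1:20] <- 1
  A[21:40, 21:40] <- 1
  g <- diffusion_map(A, n_components = 2)
  s <- sign(g$components[, 1])
  expect_true(all(s[1:20] == s[1]) && all(s[21:40] == -s[1]))
})

test_that("diffusion_map validates inputs and rejects disconnected graphs", {
  A <- diag(2) %x% matrix(1, 5, 5)  # two disconnected blocks
  expect_error(diffusion_map(A, n_components = 2), "component sizes: 5, 5")
  expect_error(diffusion_map(-random_affinity(10, 1), n_components = 2),
               "nonnegative")
  ## defaults mirror the standard gradient settings
  expect_equal(formals(diffusion_map)$n_components, 10)
  expect_equal(formals(diffusion_map)$alpha, 0.5)
})

test_that("embedding is deterministic including component signs", {
  A <- random_affinity(80, seed = 3)
  g1 <- diffusion_map(A, 5)
  g2 <- diffusion_map(A, 5)
  expect_identical(g1$components, g2$components)
  for (j in 1:5) {
    cmp <- g1$components[, j]
    expect_gt(cmp[which.max(abs(cmp))], 0)
  }
})

test_that("procrustes alignment recovers planted rotations and never hurts", {
  A <- random_affinity(60, seed = 8)
  ref <- diffusion_map(A, 5)
  ## identity case
  self <- procrustes_align(ref, ref)
  expect_lt(max(abs(self$components - ref$components)), 1e-9)
  ## planted random orthogonal rotation
  Q <- qr.Q(qr(with_seed(4, matrix(rnorm(25), 5, 5))))
  rot <- ref
  rot$components <- ref$components %*% Q
  back <- procrustes_align(rot, ref)
  expect_lt(sqrt(sum((back$components - ref$components)^2)), 1e-9)
  ## optimality: alignment never increases Frobenius distance (20 pairs)
  for (s in 1:20) {
    src <- ref
    src$components <- ref$components +
      with_seed(100 + s, matrix(rnorm(60 * 5, sd = 0.3), 60, 5))
    aligned <- procrustes_align(src, ref)
    expect_lte(sum((aligned$components - ref$components)^2),
               sum((src$components - ref$components)^2) + 1e-12)
  }
  bad <- diffusion_map(random_affinity(30, 9), 5)
  expect_error(procrustes_align(bad, ref), "shape mismatch")
})

test_that("normalize_and_stack scales columns to max |value| 1 in modality order", {
  mk <- function(mod, seed) {
    g <- diffusion_map(random_affinity(30, seed), 6)
    g$modality <- mod
    g
  }
  gs <- list(mk("MPC", 1), mk("SC", 2), mk("FC", 3))
  mg <- normalize_and_stack(gs, 5)
  expect_equal(ncol(mg$values), 15)
  expect_equal(unname(apply(abs(mg$values), 2, max)), rep(1, 15),
               tolerance = 1e-9)
  expect_equal(colnames(mg$values)[c(1, 6, 11)],
               c("MPC_G1", "SC_G1", "FC_G1"))
  ## forced example: a column (-2, 1) maps to (-1, 0.5)
  g2 <- gs[[1]]
  g2$components <- cbind(c(-2, 1, 0), c(1, 0, -1), c(0, 1, 0))
  mg2 <- normalize_and_stack(list(g2, g2, g2), 3)
  expect_equal(unname(mg2$values[, 1]), c(-1, 0.5, 0))
  expect_error(normalize_and_stack(gs, 8), "3..7")
  expect_error(normalize_and_stack(gs, 2), "3..7")
})

test_that("group templates reduce to the subject embedding for trivial groups", {
  W <- with_seed(13, { M <- matrix(runif(50 * 50, 0.05, 1), 50, 50)
                       (M + t(M)) / 2 })
  diag(W) <- 0
  cn <- connectome(W, "FC")
  single <- group_template(list(cn), keep_fraction = 0.2, n_components = 5)
  own <- diffusion_map(normalized_angle_affinity(sparsify_rows(cn, 0.2)), 5)
  expect_equal(single$components, own$components, tolerance = 1e-12)
  trip <- group_template(list(cn, cn, cn), keep_fraction = 0.2,
                         n_components = 5)
  expect_equal(trip$components, own$components, tolerance = 1e-12)
})

test_that("averaging two noisy subjects does not hurt planted-axis recovery", {
  ds <- dataset_small()
  mk_subject <- function(seed) {
    spec <- planted_gradient_spec(snr = 2, seed = seed)
    make_multimodal_dataset(mesh_L2(), spec, n_areas = 12, n_timepoints = 60)
  }
  ## two datasets sharing the planted axis is emulated by two noisy FC scans
  ## of one dataset (same latent axis, independent noise)
  d1 <- mk_subject(5)
  rec <- function(cn) {
    g <- diffusion_map(normalized_angle_affinity(sparsify_rows(cn, 0.1)), 5)
    abs(cor(g$components[, 1], d1$planted[, 1], method = "spearman"))
  }
  fc1 <- build_fc(d1$timeseries$task1)
  fc2 <- build_fc(d1$timeseries$task3)
  tmpl <- group_template(list(fc1, fc2), keep_fraction = 0.1,
                         n_components = 5)
  r_t <- abs(cor(tmpl$components[, 1], d1$planted[, 1], method = "spearman"))
  expect_gte(r_t, max(rec(fc1), rec(fc2)) - 0.02)
})
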