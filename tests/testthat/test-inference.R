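spin_fixture <- function() memo("spin_fixture", function() {
  mesh <- mesh_L2()
  atlas <- make_parcellation(mesh, 10, softness = 0, seed = 2)
  lab <- assign_area_labels(atlas)
  idx <- spin_rotation_indices(mesh, 200, seed = 5)
  list(mesh = mesh, lab = lab, idx = idx)
})

test_that("identity rotation reproduces the observed area map exactly", {
  fx <- spin_fixture()
  map <- with_seed(1, rnorm(10))
  names(map) <- fx$lab$area_ids
  nulls <- spin_nulls(map, fx$lab, fx$mesh, n_perm = 3, seed = 9,
                      include_identity = TRUE)
  expect_equal(unname(nulls$null_values[1, ]), unname(map))
})

test_that("rotation resampling only permutes existing vertex values", {
  fx <- spin_fixture()
  map <- with_seed(2, rnorm(10)); names(map) <- fx$lab$area_ids
  vvals <- map[fx$lab$label]
  for (p in c(1, 50, 200)) {
    resampled <- vvals[fx$idx[p, ]]
    expect_true(all(resampled[!is.na(resampled)] %in% map))
  }
})

test_that("null means of a smooth map sit near the observed spatial mean", {
  fx <- spin_fixture()
  f <- make_smooth_field(fx$mesh, 30, seed = 7)
  map <- area_means_of(f, fx$lab)
  nulls <- spin_nulls(map, fx$lab, fx$mesh, indices = fx$idx)
  ## expectation of a rotated value is the spatial mean of the projected map
  vvals <- map[fx$lab$label]
  spatial_mean <- mean(vvals, na.rm = TRUE)
  nm <- colMeans(nulls$null_values, na.rm = TRUE)
  se <- apply(nulls$null_values, 2, sd, na.rm = TRUE) /
    sqrt(colSums(!is.na(nulls$null_values)))
  expect_true(all(abs(nm - spatial_mean) <= 3 * se))
})

test_that("spin nulls are reproducible from the seed", {
  fx <- spin_fixture()
  map <- with_seed(3, rnorm(10)); names(map) <- fx$lab$area_ids
  n1 <- spin_nulls(map, fx$lab, fx$mesh, n_perm = 50, seed = 42)
  n2 <- spin_nulls(map, fx$lab, fx$mesh, n_perm = 50, seed = 42)
  expect_identical(n1$null_values, n2$null_values)
})

test_that("extreme_area_test produces the forced permutation p-values and BH counts", {
  ## area 1 above all 1000 nulls -> p = 2/1001; area 2 at the null median
  nv <- matrix(with_seed(4, rnorm(1000 * 2)), 1000, 2)
  nv[, 2] <- sort(nv[, 2])
  store <- structure(list(null_values = `colnames<-`(nv, c("A1", "A2")),
                          n_perm = 1000, seed = 1, area_ids = c("A1", "A2")),
                     class = "spin_null_store")
  obs <- c(A1 = max(nv[, 1]) + 1, A2 = stats::median(nv[, 2]))
  res <- extreme_area_test(obs, store, q = 0.05)
  expect_equal(res$p_two_sided[1], 2 / 1001, tolerance = 1e-12)
  expect_gt(res$p_two_sided[2], 0.95)
  expect_true(res$flag_high[1])
  expect_false(res$flag_high[2] || res$flag_low[2])
  ## BH step-up arithmetic: (0.001, 0.02, 0.8) at q = 0.05 -> 2 rejections
  expect_equal(sum(p.adjust(c(0.001, 0.02, 0.8), "BH") <= 0.05), 2)
})

test_that("spin_spearman has exact endpoints and the residualization identity", {
  fx <- spin_fixture()
  f <- make_smooth_field(fx$mesh, 30, seed = 11)
  x <- area_means_of(f, fx$lab)
  nulls <- spin_nulls(x, fx$lab, fx$mesh, indices = fx$idx)
  same <- spin_spearman(x, x, nulls)
  expect_equal(same$rho, 1)
  expect_lt(same$p_spin, 0.05)
  ## covariate = x: partial rho collapses to ~0
  y <- with_seed(12, rnorm(length(x)))
  part <- spin_spearman(x, y, nulls, covariate = x)
  expect_lt(abs(part$rho), 1e-8)
  expect_error(spin_spearman(rep(1, 10), y, nulls), "constant")
})

test_that("hierarchy contrasts give hand-computed t, d and CI values", {
  vals <- c(1, 2, 3, 2, 3, 4)
  labs <- factor(rep(c("a", "b"), each = 3))
  out <- hierarchy_ttests(vals, labs)
  expect_equal(out$mean_diff, -1)
  expect_equal(out$t, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(out$cohens_d, -1)
  expect_equal(out$ci_low, -1 - qt(0.975, 4) * sqrt(2 / 3), tolerance = 1e-12)
  ## identical groups: t = 0, d = 0, CI spans 0
  out0 <- hierarchy_ttests(c(1, 2, 3, 1, 2, 3), labs)
  expect_equal(out0$t, 0)
  expect_equal(out0$cohens_d, 0)
  expect_true(out0$ci_low < 0 && out0$ci_high > 0)
  ## zero pooled variance flags the contrast with signed infinite d
  outz <- hierarchy_ttests(c(1, 1, 1, 2, 2, 2), labs)
  expect_true(outz$zero_variance)
  expect_equal(outz$cohens_d, -Inf)
})

test_that("a planted monotone hierarchy recovers every pairwise sign", {
  ds <- dataset_small()
  lab <- assign_area_labels(ds$atlas)
  area_axis <- area_means_of(ds$planted[, 1], lab)
  out <- hierarchy_ttests(area_axis, ds$hierarchy[names(area_axis)])
  lv <- c(idiotypic = 1, unimodal = 2, heteromodal = 3, paralimbic = 4)
  want <- apply(utils::combn(levels(droplevels(ds$hierarchy)), 2), 2,
                function(p) sign(lv[p[1]] - lv[p[2]]))
  expect_equal(sign(out$t), unname(want))
})

test_that("participation coefficient matches closed forms and a node loop", {
  ## all strength in one community -> 0; equal split over 4 -> 0.75
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 3
  comm <- factor(c(1, 1, 2, 3, 4))
  expect_equal(participation_coefficient(W, comm)[1], 0)
  W2 <- matrix(0, 5, 5)
  W2[1, 2:5] <- W2[2:5, 1] <- 1
  comm2 <- factor(c(1, 1, 2, 3, 4))
  expect_equal(participation_coefficient(W2, comm2)[1], 0.75)
  ## zero-strength node -> 0
  expect_equal(participation_coefficient(W, comm)[5], 0)
  ## 20-node random weighted graph vs naive per-node loop
  W3 <- random_fc(20, 40)
  cm <- factor(with_seed(41, sample(1:4, 20, replace = TRUE)))
  got <- participation_coefficient(W3, cm)
  for (i in 1:20) {
    wpos <- pmax(W3[i, ], 0)
    k <- sum(wpos)
    want <- if (k == 0) 0 else 1 - sum(tapply(wpos, cm, sum)^2 / k^2)
    expect_equal(got[i], unname(want), tolerance = 1e-12)
  }
})

test_that("global strength is the off-diagonal row mean", {
  W <- matrix(0.7, 6, 6); diag(W) <- 0
  expect_equal(global_strength(W), rep(0.7, 6))
  expect_equal(global_strength(matrix(0, 4, 4)), rep(0, 4))
  W3 <- random_fc(15, 50)
  got <- global_strength(W3)
  for (i in 1:15) expect_equal(got[i], mean(W3[i, -i]), tolerance = 1e-12)
})
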