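test_that("icosphere meshes have the closed-manifold counts and exact radii", {
  for (L in 0:2) {
    m <- make_sphere_mesh(L, radius = 100, hemispheres = 1)
    V <- nrow(m$coords); E <- nrow(mesh_edges(m)); F <- nrow(m$triangles)
    expect_equal(V, 10 * 4^L + 2)
    expect_equal(V - E + F, 2)                       # Euler characteristic
    expect_true(all(m$triangles >= 1 & m$triangles <= V))
  }
  m3 <- make_sphere_mesh(3, radius = 100, hemispheres = 1)
  expect_lt(max(abs(sqrt(rowSums(m3$coords^2)) - 100)), 1e-9)
  ## level 1, one hemisphere: V = 42, F = 80, E = 120
  m1 <- make_sphere_mesh(1, hemispheres = 1)
  expect_equal(c(nrow(m1$coords), nrow(m1$triangles), nrow(mesh_edges(m1))),
               c(42, 80, 120))
})

test_that("two-hemisphere meshes keep hemispheres disjoint and mark a polar cap", {
  m <- mesh_L2_bi()
  g <- igraph::components(mesh_graph(m))
  expect_equal(g$no, 2)
  expect_equal(as.numeric(table(m$hemisphere)), c(162, 162))
  ## midwall = ceil(2%) per hemisphere at the +z pole
  expect_equal(sum(m$midwall), 2 * ceiling(0.02 * 162))
  expect_true(all(m$coords[m$midwall, 3] > 0))
})

test_that("hard parcellation is a one-hot cover with connected areas", {
  mesh <- mesh_L2()
  atlas1 <- make_parcellation(mesh, 1, softness = 0, seed = 1)
  cs <- colSums(atlas1$prob)
  expect_true(all(cs[!mesh$midwall] == 1))
  expect_true(all(cs[mesh$midwall] == 0))

  atlas <- make_parcellation(mesh, 20, softness = 0, seed = 2)
  expect_true(all(colSums(atlas$prob) <= 1 + 1e-9))
  lab <- assign_area_labels(atlas)
  ## every argmax label set is geodesically connected (BFS oracle over the
  ## induced subgraph)
  g <- mesh_graph(mesh)
  for (a in seq_along(atlas$area_ids)) {
    vs <- which(!is.na(lab$label) & lab$label == a)
    expect_gt(length(vs), 0)
    sub <- igraph::induced_subgraph(g, vs)
    expect_equal(igraph::components(sub)$no, 1)
  }
})

test_that("parcellation softness spreads probability and seeds reproduce", {
  mesh <- mesh_L2()
  soft <- make_parcellation(mesh, 8, softness = 20, seed = 4)
  cs <- colSums(soft$prob)
  expect_lt(max(abs(cs[!mesh$midwall] - 1)), 1e-9)
  expect_true(all(soft$prob >= 0 & soft$prob <= 1))
  ## soft assignment is genuinely soft somewhere
  expect_true(any(soft$prob > 0 & soft$prob < 0.99))
  expect_identical(make_parcellation(mesh, 8, softness = 20, seed = 4)$prob,
                   soft$prob)
  expect_error(make_parcellation(mesh, 10000, seed = 1), "exceeds")
})

test_that("smooth fields are standardized and their smoothness tracks the length scale", {
  mesh <- mesh_L2()
  e <- mesh_edges(mesh)
  f <- make_smooth_field(mesh, 30, seed = 1)
  ctx <- !mesh$midwall
  expect_lt(abs(mean(f[ctx])), 1e-9)
  expect_lt(abs(sd(f[ctx]) - 1), 1e-9)
  ## correlation_length 0: white noise, neighbor-pair correlation ~ 0
  rs <- vapply(1:50, function(s) {
    x <- make_smooth_field(mesh, 0, seed = s)
    cor(x[e[, 1]], x[e[, 2]])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
  ## half the mesh diameter: neighbors nearly identical
  big <- make_smooth_field(mesh, pi * 100 / 2, seed = 2)
  expect_gt(cor(big[e[, 1]], big[e[, 2]]), 0.9)
})

test_that("the multimodal generator is seed-deterministic and internally consistent", {
  ds <- dataset_small()
  ds2 <- make_multimodal_dataset(mesh_L2(), planted_gradient_spec(seed = 5),
                                 n_areas = 12, n_timepoints = 60)
  expect_identical(ds[setdiff(names(ds), "mesh")],
                   ds2[setdiff(names(ds2), "mesh")])
  nv <- nrow(ds$mesh$coords)
  expect_equal(dim(ds$sc), c(nv, nv))
  expect_symmetric(ds$sc)
  expect_true(all(diag(ds$sc) == 0) && all(ds$sc >= 0))
  expect_equal(nrow(ds$profiles), 12)
  expect_equal(unname(vapply(ds$timeseries, ncol, integer(1))),
               rep(nv, 4))
  expect_equal(nrow(ds$planted), nv)
  expect_setequal(levels(ds$hierarchy),
                  c("idiotypic", "unimodal", "heteromodal", "paralimbic"))
  expect_error(make_multimodal_dataset(mesh_L2(),
                                       planted_gradient_spec(seed = 1),
                                       n_depths = 2),
               "n_depths")
})

test_that("zero flexibility gives exactly identical task scans", {
  ds <- make_multimodal_dataset(mesh_L2(), planted_gradient_spec(seed = 9),
                                n_areas = 10, n_timepoints = 40,
                                flex_amplitude = 0)
  expect_identical(ds$timeseries$task1, ds$timeseries$task2)
  expect_identical(ds$timeseries$task1, ds$timeseries$task3)
})

test_that("a single noise-free planted axis is recovered by the embedding stage", {
  ## oracle = running the embedding stage itself on noise-free data
  mesh <- mesh_L3()
  ds <- make_multimodal_dataset(mesh,
                                planted_gradient_spec(n_axes = 1, snr = Inf,
                                                      seed = 11))
  rec <- function(cn) {
    g <- diffusion_map(normalized_angle_affinity(sparsify_rows(cn, 0.1)), 5)
    abs(cor(g$components[, 1], ds$planted[, 1], method = "spearman"))
  }
  ## the local (floored) MPC kernel caps noise-free recovery near 0.99
  expect_gt(rec(build_mpc(ds$profiles)), 0.95)
  expect_gt(rec(build_fc(ds$timeseries$rest)), 0.99)
})

test_that("hierarchy labels follow the planted-axis quartiles", {
  ds <- dataset_small()
  lab <- assign_area_labels(ds$atlas)
  area_axis <- area_means_of(ds$planted[, 1], lab)
  ord <- c(idiotypic = 1, unimodal = 2, heteromodal = 3, paralimbic = 4)
  expect_gt(cor(area_axis, ord[as.character(ds$hierarchy)],
                method = "spearman"), 0.9)
})
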