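## Shared fixtures, memoized so repeated tests do not rebuild meshes.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

mesh_L2 <- function() memo("mesh_L2", function() {
  make_sphere_mesh(2, radius = 100, hemispheres = 1)
})

mesh_L2_bi <- function() memo("mesh_L2_bi", function() {
  make_sphere_mesh(2, radius = 100, hemispheres = 2)
})

mesh_L3 <- function() memo("mesh_L3", function() {
  make_sphere_mesh(3, radius = 100, hemispheres = 1)
})

## Small high-SNR dataset on the one-hemisphere level-2 mesh.
dataset_small <- function() memo("dataset_small", function() {
  make_multimodal_dataset(mesh_L2(), planted_gradient_spec(seed = 5),
                          n_areas = 12, n_timepoints = 60)
})

## A hard Voronoi labeling over n areas on the level-2 mesh.
labeling_small <- function() memo("labeling_small", function() {
  assign_area_labels(make_parcellation(mesh_L2(), 12, softness = 0, seed = 3))
})

## Random symmetric affinity with positive entries (connected by construction).
random_affinity <- function(n, seed) {
  with_seed(seed, {
    M <- matrix(runif(n * n, 0.01, 1), n, n)
    A <- (M + t(M)) / 2
    diag(A) <- 1
    A
  })
}

expect_symmetric <- function(m, tol = 1e-10) {
  expect_lt(max(abs(m - t(m))), tol)
}

## nv vertices split round-robin over n_areas hard areas.
small_labeling <- function(nv, n_areas = 3) {
  prob <- matrix(0, n_areas, nv)
  grp <- rep(seq_len(n_areas), length.out = nv)
  prob[cbind(grp, seq_len(nv))] <- 1
  assign_area_labels(structure(list(prob = prob,
                                    area_ids = paste0("A", seq_len(n_areas))),
                               class = "prob_atlas"))
}

## Random symmetric zero-diagonal matrix (FC-like fixture).
random_fc <- function(nv, seed) {
  with_seed(seed, {
    M <- matrix(rnorm(nv * nv), nv, nv)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    M
  })
}
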