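#' Synthetic probabilistic parcellation of a spherical mesh
#'
#' Emulates a probabilistic cytoarchitectonic atlas: area seeds are placed by
#' farthest-point sampling on geodesic distances (graph shortest paths over
#' mesh edges), vertices are soft-assigned to areas by a softmax over
#' negative geodesic distance with temperature `softness`. `softness = 0`
#' degenerates to a hard geodesic-Voronoi one-hot atlas. Mid-wall vertices
#' receive all-zero probability columns. When the mesh has two hemispheres
#' the requested areas are split across them (left gets the extra area when
#' `n_areas` is odd) because geodesics do not cross hemispheres.
#'
#' @param mesh a `cortex_mesh`.
#' @param n_areas number of areas (>= 1, at most the non-mid-wall vertex
#'   count).
#' @param softness soft-assignment temperature in mesh distance units;
#'   0 gives a hard parcellation.
#' @param seed integer seed for the farthest-point start vertex.
#' @return an object of class `prob_atlas`: list with `prob` (area x vertex
#'   matrix, per-vertex column sums 1 for cortical vertices, 0 for mid-wall)
#'   and `area_ids`.
#' @export
make_parcellation <- function(mesh, n_areas, softness = 0, seed = 1) {
  stopifnot(inherits(mesh, "cortex_mesh"), n_areas >= 1, softness >= 0)
  nv <- nrow(mesh$coords)
  cortical <- which(!mesh$midwall)
  if (n_areas > length(cortical)) {
    stop_fmt("n_areas (%d) exceeds the %d available non-mid-wall vertices",
             n_areas, length(cortical))
  }
  hemis <- levels(droplevels(mesh$hemisphere))
  ## split areas across hemispheres proportional to cortical vertex counts
  if (length(hemis) == 2L) {
    n_left <- ceiling(n_areas / 2)
    alloc <- c(left = n_left, right = n_areas - n_left)
    alloc <- alloc[alloc > 0]
  } else {
    alloc <- stats::setNames(n_areas, hemis)
  }
  g <- mesh_graph(mesh)
  prob <- matrix(0, n_areas, nv)
  area0 <- 0L
  for (h in names(alloc)) {
    hv <- which(mesh$hemisphere == h & !mesh$midwall)
    n_h <- alloc[[h]]
    seeds <- farthest_point_sample(g, hv, n_h,
                                   child_seed(seed, paste0("fps_", h)))
    D <- igraph::distances(g, v = seeds, to = hv)   # n_h x |hv|
    if (softness == 0) {
      nearest <- apply(D, 2, which.min)             # ties -> lowest area index
      for (a in seq_len(n_h)) {
        prob[area0 + a, hv[nearest == a]] <- 1
      }
    } else {
      E <- exp(-sweep(D, 2, apply(D, 2, min)) / softness)
      P <- sweep(E, 2, colSums(E), "/")
      prob[area0 + seq_len(n_h), hv] <- P
    }
    area0 <- area0 + n_h
  }
  structure(list(prob = prob, area_ids = paste0("A", seq_len(n_areas))),
            class = "prob_atlas")
}

## Farthest-point sampling restricted to `candidates`; seeded random start,
## then iteratively the candidate farthest from the chosen set (ties by
## vertex index).
farthest_point_sample <- function(graph, candidates, n, seed) {
  stopifnot(n <= length(candidates))
  start <- with_seed(seed, candidates[sample.int(length(candidates), 1L)])
  chosen <- start
  if (n > 1L) {
    dmin <- igraph::distances(graph, v = start, to = candidates)[1L, ]
    for (k in 2:n) {
      nxt <- candidates[which.max(dmin)]
      chosen <- c(chosen, nxt)
      dmin <- pmin(dmin, igraph::distances(graph, v = nxt, to = candidates)[1L, ])
    }
  }
  chosen
}

#' @export
print.prob_atlas <- function(x, ...) {
  cat(sprintf("prob_atlas: %d areas over %d vertices (%d unassigned)\n",
              nrow(x$prob), ncol(x$prob), sum(colSums(x$prob) == 0)))
  invisible(x)
}

#' Spatially autocorrelated random field on a mesh
#'
#' White Gaussian noise on the vertices is diffused by iterated
#' neighbourhood averaging `x <- (x + mean of neighbours)/2` until the
#' requested correlation length is reached (the iteration count scales as
#' `(correlation_length / mean edge length)^2`, the random-walk scaling of
#' diffusion), then standardized to mean 0 and SD 1 over non-mid-wall
#' vertices. `correlation_length = 0` returns standardized white noise.
#'
#' @param mesh a `cortex_mesh`.
#' @param correlation_length smoothness scale in mesh units (>= 0).
#' @param seed integer seed.
#' @return numeric vector, one value per vertex (mid-wall vertices included,
#'   standardized with the cortical statistics).
#' @export
make_smooth_field <- function(mesh, correlation_length, seed = 1) {
  stopifnot(inherits(mesh, "cortex_mesh"), correlation_length >= 0)
  nv <- nrow(mesh$coords)
  x <- with_seed(seed, rnorm(nv))
  if (correlation_length > 0) {
    A <- mesh_adjacency(mesh)
    deg <- Matrix::rowSums(A)
    h <- mean_edge_length(mesh)
    n_iter <- min(ceiling((correlation_length / h)^2), 5000L)
    for (i in seq_len(n_iter)) {
      x <- 0.5 * (x + as.numeric(A %*% x) / deg)
    }
  }
  ctx <- !mesh$midwall
  (x - mean(x[ctx])) / sd(x[ctx])
}
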