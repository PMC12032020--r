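#' Spherical cortical surface meshes
#'
#' `make_sphere_mesh()` builds an icosphere per hemisphere by repeated
#' triangle subdivision of an icosahedron, giving `10 * 4^L + 2` vertices per
#' hemisphere at subdivision level `L`. It is the geometric substrate for the
#' synthetic cortex: parcellation, smoothing and spin rotations all operate
#' on it. A small polar cap around the +z pole is flagged as the mid-wall
#' analogue (the medial-wall vertices excluded from cortical analysis).
#'
#' Both hemispheres are concentric spheres sharing vertex coordinates;
#' hemisphere membership is carried per vertex and edges never cross
#' hemispheres. Vertex ordering is fully deterministic.
#'
#' @param subdivision_level integer >= 0; level 0 is the icosahedron.
#' @param radius sphere radius in mm-like units.
#' @param hemispheres 1 or 2.
#' @param midwall_fraction fraction of vertices per hemisphere assigned to
#'   the polar mid-wall cap (default 0.02).
#' @return an object of class `cortex_mesh`: list with `coords` (V x 3),
#'   `triangles` (F x 3, 1-based), `hemisphere` (factor per vertex),
#'   `midwall` (logical per vertex) and `radius`.
#' @examples
#' m <- make_sphere_mesh(1, radius = 100, hemispheres = 1)
#' nrow(m$coords)  # 42
#' @export
make_sphere_mesh <- function(subdivision_level, radius = 100, hemispheres = 2,
                             midwall_fraction = 0.02) {
  stopifnot(subdivision_level >= 0, radius > 0, hemispheres %in% c(1L, 2L),
            midwall_fraction >= 0, midwall_fraction < 1)
  base <- icosphere(subdivision_level)
  v <- base$vertices * radius
  f <- base$faces
  nv <- nrow(v)

  ## mid-wall: the ceil(frac * V) vertices closest to the +z pole, fixed pole
  ## for determinism; ties broken by vertex index
  n_cap <- ceiling(midwall_fraction * nv)
  cap <- rep(FALSE, nv)
  if (n_cap > 0) cap[order(-v[, 3], seq_len(nv))[seq_len(n_cap)]] <- TRUE

  if (hemispheres == 1L) {
    coords <- v
    tri <- f
    hemi <- factor(rep("left", nv), levels = c("left", "right"))
    midwall <- cap
  } else {
    coords <- rbind(v, v)
    tri <- rbind(f, f + nv)
    hemi <- factor(rep(c("left", "right"), each = nv),
                   levels = c("left", "right"))
    midwall <- c(cap, cap)
  }
  structure(
    list(coords = coords, triangles = tri, hemisphere = hemi,
         midwall = midwall, radius = radius,
         subdivision_level = as.integer(subdivision_level)),
    class = "cortex_mesh")
}

## Unit icosphere: deterministic midpoint-cache subdivision of the canonical
## icosahedron.
icosphere <- function(level) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  f <- rbind(
    c(1, 12,  6), c(1,  6,  2), c(1,  2,  8), c(1,  8, 11), c(1, 11, 12),
    c(2,  6, 10), c(6, 12,  5), c(12, 11, 3), c(11, 8,  7), c(8,  2,  9),
    c(4, 10,  5), c(4,  5,  3), c(4,  3,  7), c(4,  7,  9), c(4,  9, 10),
    c(5, 10,  6), c(3,  5, 12), c(7,  3, 11), c(9,  7,  8), c(10, 9,  2))
  v <- v / sqrt(rowSums(v^2))
  for (l in seq_len(level)) {
    cache <- new.env(hash = TRUE, parent = emptyenv())
    vlist <- asplit(v, 1)
    mid_idx <- function(i, j) {
      key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
      idx <- cache[[key]]
      if (is.null(idx)) {
        p <- vlist[[i]] + vlist[[j]]
        vlist[[length(vlist) + 1L]] <<- p / sqrt(sum(p^2))
        idx <- length(vlist)
        cache[[key]] <- idx
      }
      idx
    }
    newfaces <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- mid_idx(a, b); bc <- mid_idx(b, c_); ca <- mid_idx(c_, a)
      newfaces[(k - 1L) * 4L + 1L, ] <- c(a, ab, ca)
      newfaces[(k - 1L) * 4L + 2L, ] <- c(b, bc, ab)
      newfaces[(k - 1L) * 4L + 3L, ] <- c(c_, ca, bc)
      newfaces[(k - 1L) * 4L + 4L, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- newfaces
  }
  list(vertices = v, faces = f)
}

#' Convenience mesh presets
#'
#' `"test"` (level 3, 642 vertices/hemisphere) is sized for simulation
#' studies and the test suite; `"default"` (level 4, 2562/hemisphere) for
#' routine analyses; `"paper_scale"` (level 5, 10242/hemisphere) is the
#' closest icosphere level above the 4432 vertices/hemisphere of the fsLR-5k
#' convention, which icosahedral subdivision cannot hit exactly.
#'
#' @param preset one of `"test"`, `"default"`, `"paper_scale"`.
#' @param ... passed to [make_sphere_mesh()].
#' @return a `cortex_mesh`.
#' @export
mesh_preset <- function(preset = c("test", "default", "paper_scale"), ...) {
  level <- switch(match.arg(preset), test = 3L, default = 4L,
                  paper_scale = 5L)
  make_sphere_mesh(level, ...)
}

#' Undirected unique edge list of a mesh
#' @param mesh a `cortex_mesh`.
#' @return two-column integer matrix of vertex index pairs (i < j).
#' @export
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Sparse vertex adjacency matrix
#' @param mesh a `cortex_mesh`.
#' @return symmetric sparse 0/1 Matrix (V x V).
#' @export
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  nv <- nrow(mesh$coords)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(nv, nv))
}

## igraph over mesh edges, weighted by Euclidean edge length; geodesic
## distances are approximated by shortest paths on this graph.
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$coords[e[, 1], , drop = FALSE] -
                     mesh$coords[e[, 2], , drop = FALSE])^2))
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  mean(sqrt(rowSums((mesh$coords[e[, 1], , drop = FALSE] -
                     mesh$coords[e[, 2], , drop = FALSE])^2)))
}

#' @export
print.cortex_mesh <- function(x, ...) {
  cat(sprintf(
    "cortex_mesh: %d vertices (%d hemisphere(s)), %d triangles, radius %g\n",
    nrow(x$coords), nlevels(droplevels(x$hemisphere)), nrow(x$triangles),
    x$radius))
  cat(sprintf("  mid-wall vertices: %d\n", sum(x$midwall)))
  invisible(x)
}
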