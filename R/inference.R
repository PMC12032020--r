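#' Precompute spin-rotation resampling indices for a spherical mesh
#'
#' Each permutation draws a uniform random 3D rotation (QR orthonormalization
#' of a Gaussian matrix, determinant forced to +1). The rotation is applied
#' to the right-hemisphere vertex sphere and its x-mirrored counterpart to
#' the left hemisphere, preserving left/right correspondence. Every vertex
#' is then re-assigned the index of its nearest rotated vertex within the
#' same hemisphere (maximum dot product on the sphere). The indices depend
#' only on the mesh and seed, never on the map being tested, so one store
#' can back the nulls of many maps.
#'
#' @param mesh a spherical `cortex_mesh`.
#' @param n_perm number of rotations.
#' @param seed integer seed.
#' @param include_identity if `TRUE`, permutation 1 is the identity rotation
#'   (so its null realization equals the observed map).
#' @return object of class `spin_indices`: integer matrix (n_perm x V),
#'   row p giving for each vertex the source vertex whose value it receives.
#' @export
spin_rotation_indices <- function(mesh, n_perm, seed = 1,
                                  include_identity = FALSE) {
  stopifnot(inherits(mesh, "cortex_mesh"), n_perm >= 1)
  r <- sqrt(rowSums(mesh$coords^2))
  if (max(abs(r - mesh$radius)) > 1e-6 * mesh$radius) {
    stop_fmt("mesh is not spherical; spin rotation requires a sphere")
  }
  nv <- nrow(mesh$coords)
  hemis <- levels(droplevels(mesh$hemisphere))
  hv <- lapply(hemis, function(h) which(mesh$hemisphere == h))
  names(hv) <- hemis
  P <- mesh$coords / mesh$radius
  mirror <- diag(c(-1, 1, 1))

  idx <- matrix(0L, n_perm, nv)
  rots <- with_seed(seed, lapply(seq_len(n_perm), function(p) {
    random_rotation()
  }))
  for (p in seq_len(n_perm)) {
    R <- rots[[p]]
    if (include_identity && p == 1L) R <- diag(3)
    for (h in hemis) {
      Rh <- if (h == "left") mirror %*% R %*% mirror else R
      v <- hv[[h]]
      rot <- P[v, , drop = FALSE] %*% t(Rh)     # rotated positions
      ## nearest rotated vertex to each original position
      idx[p, v] <- v[max.col(P[v, , drop = FALSE] %*% t(rot),
                             ties.method = "first")]
    }
  }
  structure(idx, class = "spin_indices", seed = seed,
            include_identity = include_identity)
}

## Uniform random rotation: QR of a Gaussian 3x3, signs fixed by the R
## diagonal, determinant forced to +1.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin-permutation null realizations of an area-level map
#'
#' Projects the per-area map to vertices through the fixed labeling, applies
#' each precomputed spin rotation by nearest-vertex resampling, and
#' re-aggregates to areas under the same fixed labeling (mean over assigned
#' vertices, unassigned/mid-wall vertices excluded). An area whose vertices
#' all receive unassigned values in a permutation gets `NA` for that
#' permutation.
#'
#' @param map named per-area numeric vector (names = area ids).
#' @param labeling an `area_labeling`.
#' @param mesh the spherical `cortex_mesh` the labeling lives on.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed (ignored when `indices` is supplied).
#' @param indices optional precomputed [spin_rotation_indices()].
#' @param include_identity passed through when indices are computed here.
#' @return object of class `spin_null_store`: `null_values` (n_perm x
#'   n_areas), `n_perm`, `seed`, `area_ids`.
#' @export
spin_nulls <- function(map, labeling, mesh, n_perm = 1000, seed = 1,
                       indices = NULL, include_identity = FALSE) {
  stopifnot(inherits(labeling, "area_labeling"))
  if (is.null(indices)) {
    indices <- spin_rotation_indices(mesh, n_perm, seed,
                                     include_identity = include_identity)
  }
  n_perm <- nrow(indices)
  nv <- length(labeling$label)
  stopifnot(ncol(indices) == nv)
  if (is.null(names(map))) names(map) <- labeling$area_ids[seq_along(map)]
  pos <- match(names(map), labeling$area_ids)
  if (anyNA(pos)) stop_fmt("map names do not match the labeling's area ids")

  vvals <- rep(NA_real_, nv)
  assigned <- !is.na(labeling$label)
  vvals[assigned] <- map[match(labeling$area_ids[labeling$label[assigned]],
                               names(map))]

  present <- sort(unique(labeling$label[assigned]))
  null_values <- matrix(NA_real_, n_perm, length(map),
                        dimnames = list(NULL, names(map)))
  lbl <- labeling$label
  for (p in seq_len(n_perm)) {
    vp <- vvals[indices[p, ]]
    okv <- assigned & !is.na(vp)
    if (!any(okv)) next
    sums <- rowsum(vp[okv], lbl[okv])
    cnts <- as.numeric(table(lbl[okv]))
    ids <- labeling$area_ids[sort(unique(lbl[okv]))]
    null_values[p, match(ids, names(map))] <- sums[, 1] / cnts
  }
  structure(list(null_values = null_values, n_perm = n_perm,
                 seed = attr(indices, "seed"), area_ids = names(map)),
            class = "spin_null_store")
}

#' @export
print.spin_null_store <- function(x, ...) {
  cat(sprintf("spin_null_store: %d permutations x %d areas (seed %s)\n",
              x$n_perm, ncol(x$null_values), format(x$seed)))
  invisible(x)
}

#' Detect areas with extreme values against spin nulls
#'
#' Per area, one-sided permutation p-values with the (count + 1)/(n + 1)
#' estimator, combined two-sided as `2 * min(p_high, p_low)` capped at 1,
#' then Benjamini-Hochberg correction across areas at level `q`. An area is
#' flagged high (low) when its high (low) side wins and the corrected
#' two-sided p-value survives FDR.
#'
#' @param observed named per-area numeric vector.
#' @param nulls a `spin_null_store` covering the observed areas.
#' @param q FDR level (default 0.05).
#' @return data.frame with area, observed, p_high, p_low, p_two_sided,
#'   p_fdr, flag_high, flag_low.
#' @export
extreme_area_test <- function(observed, nulls, q = 0.05) {
  stopifnot(inherits(nulls, "spin_null_store"))
  N <- nulls$null_values[, names(observed), drop = FALSE]
  n_eff <- colSums(!is.na(N))
  p_high <- (1 + colSums(sweep(N, 2, observed, ">="), na.rm = TRUE)) /
    (n_eff + 1)
  p_low <- (1 + colSums(sweep(N, 2, observed, "<="), na.rm = TRUE)) /
    (n_eff + 1)
  p2 <- pmin(1, 2 * pmin(p_high, p_low))
  p_fdr <- p.adjust(p2, method = "BH")
  data.frame(area = names(observed), observed = as.numeric(observed),
             p_high = as.numeric(p_high), p_low = as.numeric(p_low),
             p_two_sided = as.numeric(p2), p_fdr = as.numeric(p_fdr),
             flag_high = as.logical(p_high < p_low & p_fdr <= q),
             flag_low = as.logical(p_low < p_high & p_fdr <= q),
             row.names = NULL)
}

#' Spin-corrected (partial) Spearman correlation
#'
#' Spearman correlation of two per-area maps with a spatial permutation
#' p-value: the correlation is recomputed between each null realization of
#' `x` and the fixed `y`, and
#' `p_spin = (1 + #\{|rho_perm| >= |rho_obs|\}) / (n_perm + 1)`. With a
#' covariate, a partial Spearman is used (correlation of the residuals of
#' the ranked maps after linear fits on the ranked covariate), identically
#' for observed and null correlations.
#'
#' @param x,y named per-area numeric vectors (>= 5 areas).
#' @param nulls_of_x a `spin_null_store` of `x` realizations.
#' @param covariate optional per-area covariate map.
#' @return list with `rho`, `p_spin`, `n_perm_used`.
#' @export
spin_spearman <- function(x, y, nulls_of_x, covariate = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 5,
            inherits(nulls_of_x, "spin_null_store"))
  if (sd(x) == 0 || sd(y) == 0) stop_fmt("constant input map")
  rho_obs <- spearman_stat(x, y, covariate)
  N <- nulls_of_x$null_values
  if (!is.null(names(x))) N <- N[, names(x), drop = FALSE]
  rho_perm <- apply(N, 1, function(xp) {
    ok <- !is.na(xp)
    if (sum(ok) < 5 || sd(xp[ok]) == 0) return(NA_real_)
    spearman_stat(xp[ok], y[ok],
                  if (is.null(covariate)) NULL else covariate[ok])
  })
  used <- sum(!is.na(rho_perm))
  p <- (1 + sum(abs(rho_perm) >= abs(rho_obs), na.rm = TRUE)) / (used + 1)
  list(rho = rho_obs, p_spin = p, n_perm_used = used)
}

spearman_stat <- function(x, y, covariate = NULL) {
  rx <- rank(x); ry <- rank(y)
  if (is.null(covariate)) return(cor(rx, ry))
  rc <- rank(covariate)
  ex <- residuals(lm(rx ~ rc))
  ey <- residuals(lm(ry ~ rc))
  ## a map collinear with the covariate carries no partial information
  if (sd(ex) < 1e-9 || sd(ey) < 1e-9) return(0)
  cor(ex, ey)
}

#' Pairwise hierarchy-level contrasts with spin-permutation p-values
#'
#' For each pair of hierarchy levels: a two-sided pooled-variance Student
#' t-test, Cohen's d (pooled SD), the 95% t-based confidence interval of the
#' mean difference, a spin p-value (proportion of null realizations whose
#' |t| reaches the observed |t|, with the +1 correction), and
#' Benjamini-Hochberg FDR across the contrasts.
#'
#' @param values per-unit (area or vertex) numeric vector.
#' @param labels factor of hierarchy levels per unit (e.g. idiotypic,
#'   unimodal, heteromodal, paralimbic), each level with >= 2 units.
#' @param nulls a `spin_null_store` of `values` realizations over the same
#'   units (optional: `NULL` skips spin p-values).
#' @return data.frame with one row per level pair: group sizes, mean
#'   difference, t, Cohen's d, CI bounds, p_spin, p_fdr, and a
#'   `zero_variance` flag (d reported as signed `Inf` there).
#' @export
hierarchy_ttests <- function(values, labels, nulls = NULL) {
  labels <- droplevels(as.factor(labels))
  stopifnot(length(values) == length(labels))
  if (any(table(labels) < 2)) stop_fmt("every hierarchy level needs >= 2 units")
  prs <- utils::combn(levels(labels), 2)
  N <- if (!is.null(nulls)) nulls$null_values else NULL

  one <- function(a, b, vals) {
    x <- vals[labels == a]; y <- vals[labels == b]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    nx <- length(x); ny <- length(y)
    if (nx < 2 || ny < 2) return(c(NA, NA, NA, NA))
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
      (nx + ny - 2)
    md <- mean(x) - mean(y)
    if (sp2 == 0) return(c(md, Inf * sign(md), Inf * sign(md), 0))
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    c(md, md / se, md / sqrt(sp2), se)
  }

  rows <- lapply(seq_len(ncol(prs)), function(j) {
    a <- prs[1, j]; b <- prs[2, j]
    nx <- sum(labels == a); ny <- sum(labels == b)
    st <- one(a, b, values)
    md <- st[1]; tval <- st[2]; d <- st[3]; se <- st[4]
    df <- nx + ny - 2
    zero_var <- is.infinite(tval)
    if (zero_var) {
      ci <- c(md, md)
      p_spin <- NA_real_
    } else {
      ci <- md + c(-1, 1) * qt(0.975, df) * se
      p_spin <- NA_real_
      if (!is.null(N)) {
        tp <- apply(N, 1, function(vp) one(a, b, vp)[2])
        used <- sum(is.finite(tp))
        p_spin <- (1 + sum(abs(tp) >= abs(tval), na.rm = TRUE)) / (used + 1)
      }
    }
    data.frame(contrast = paste(a, "vs", b), n1 = nx, n2 = ny,
               mean_diff = md, t = tval, cohens_d = d,
               ci_low = ci[1], ci_high = ci[2], p_spin = p_spin,
               zero_variance = zero_var)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p_spin, method = "BH")
  out
}

#' Participation coefficient of a weighted graph
#'
#' `PC_i = 1 - sum_s (k_is / k_i)^2` over communities s, using positive
#' weights only; nodes with zero positive strength get `PC = 0`.
#'
#' @param fc a `connectome` (or square weight matrix).
#' @param communities factor of community memberships per node.
#' @return per-node numeric vector.
#' @export
participation_coefficient <- function(fc, communities) {
  W <- if (inherits(fc, "connectome")) fc$weights else fc
  communities <- as.factor(communities)
  stopifnot(nrow(W) == ncol(W), length(communities) == nrow(W))
  W <- pmax(W, 0)
  k <- rowSums(W)
  ind <- stats::model.matrix(~ communities - 1)
  ks <- W %*% ind
  pc <- 1 - rowSums((ks / ifelse(k == 0, 1, k))^2)
  pc[k == 0] <- 0
  as.numeric(pc)
}

#' Global connectivity strength
#'
#' Row mean of a square connectivity matrix excluding the diagonal.
#'
#' @param fc a `connectome` (or square matrix).
#' @return per-node numeric vector.
#' @export
global_strength <- function(fc) {
  W <- if (inherits(fc, "connectome")) fc$weights else fc
  stopifnot(nrow(W) == ncol(W))
  (rowSums(W) - diag(W)) / (nrow(W) - 1)
}
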