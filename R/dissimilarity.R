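#' Cosine distance between two vectors
#'
#' `1 - (a . b) / (||a|| ||b||)`, in \[0, 2\]. Zero vectors are an error;
#' callers are expected to exclude or flag such vertices.
#'
#' @param a,b numeric vectors of equal length, both nonzero.
#' @return the cosine distance.
#' @examples
#' cosine_distance(c(1, 1), c(1, 0))  # 1 - 1/sqrt(2)
#' @export
cosine_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_fmt("cosine distance undefined for zero vector")
  1 - clip(sum(a * b) / (na * nb), -1, 1)
}

## Row-normalize a profile matrix, erroring on zero rows with the area name.
row_unit <- function(P, what = "area") {
  rn <- sqrt(rowSums(P^2))
  zero <- which(rn == 0)
  if (length(zero)) {
    nm <- rownames(P)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop_fmt("zero-vector profile for %s %s", what,
             paste(head(nm, 5), collapse = ", "))
  }
  P / rn
}

#' Inter-areal dissimilarity of gradient profiles
#'
#' Full pairwise cosine-distance matrix between area gradient profiles; the
#' inter-areal dissimilarity of an area is the mean of its row over the
#' other n - 1 areas.
#'
#' @param profiles a `gradient_profile_matrix` (or plain area-by-p matrix
#'   with >= 2 rows).
#' @return object of class `dissimilarity_result`: `matrix` (area x area,
#'   symmetric, zero diagonal, entries in \[0, 2\]), `per_area` (named row
#'   means excluding the diagonal), `kind = "inter"`.
#' @export
inter_areal_dissimilarity <- function(profiles) {
  P <- if (inherits(profiles, "gradient_profile_matrix")) {
    profiles$profiles
  } else {
    profiles
  }
  stopifnot(is.matrix(P), nrow(P) >= 2)
  N <- row_unit(P)
  D <- clip(1 - tcrossprod(N), 0, 2)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  per_area <- rowSums(D) / (nrow(D) - 1)
  names(per_area) <- rownames(P)
  structure(list(matrix = D, per_area = per_area, kind = "inter"),
            class = "dissimilarity_result")
}

#' Similarity affinity between area gradient profiles
#'
#' Entrywise `1 - cosine distance` (i.e. the cosine similarity), diagonal 1;
#' the input to the hierarchical clustering of areas.
#'
#' @inheritParams inter_areal_dissimilarity
#' @return symmetric area-by-area similarity matrix in \[-1, 1\].
#' @export
similarity_affinity <- function(profiles) {
  P <- if (inherits(profiles, "gradient_profile_matrix")) {
    profiles$profiles
  } else {
    profiles
  }
  stopifnot(is.matrix(P), nrow(P) >= 2)
  N <- row_unit(P)
  S <- clip(tcrossprod(N), -1, 1)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' Intra-areal dissimilarity of vertex gradients
#'
#' For each assigned vertex, the cosine distance between its multimodal
#' gradient vector and the mean gradient profile of its own area. Area
#' summaries are reported both raw (`per_area_mean`) and adjusted for area
#' size (`per_area_size_adjusted`: residuals of a Spearman-style linear fit
#' of the ranked per-area means on the ranked vertex counts, since area size
#' correlates positively with within-area spread).
#'
#' @param gradients a `multimodal_gradients` (or vertex-by-p matrix).
#' @param labeling an `area_labeling` sharing the vertex ordering.
#' @return object of class `intra_areal_result`: `per_vertex` (NA for
#'   unassigned or zero-profile vertices), `per_area_mean`,
#'   `per_area_size_adjusted`, `singleton_areas`, `excluded_vertices`.
#' @export
intra_areal_dissimilarity <- function(gradients, labeling) {
  G <- if (inherits(gradients, "multimodal_gradients")) {
    gradients$values
  } else {
    gradients
  }
  stopifnot(inherits(labeling, "area_labeling"),
            nrow(G) == length(labeling$label))
  nv <- nrow(G)
  lbl <- labeling$label
  per_vertex <- rep(NA_real_, nv)
  rn <- sqrt(rowSums(G^2))
  excluded <- which(!is.na(lbl) & rn == 0)
  usable <- which(!is.na(lbl) & rn > 0)

  lab_u <- lbl[usable]
  means <- rowsum(G[usable, , drop = FALSE], lab_u) /
    as.numeric(table(lab_u))
  present <- sort(unique(lab_u))
  mean_of <- means[match(lbl[usable], present), , drop = FALSE]
  num <- rowSums(G[usable, , drop = FALSE] * mean_of)
  den <- rn[usable] * sqrt(rowSums(mean_of^2))
  per_vertex[usable] <- ifelse(den == 0, NA_real_,
                               clip(1 - num / den, 0, 2))

  counts <- as.numeric(table(lab_u))
  singles <- present[counts == 1]
  per_vertex[usable][lab_u %in% singles] <- 0  # vertex equals its own mean
  if (length(singles)) {
    warn_fmt("%d singleton area(s): intra-areal dissimilarity fixed at 0 (%s)",
             length(singles),
             paste(labeling$area_ids[singles], collapse = ", "))
  }

  pam <- rowsum(per_vertex[usable], lab_u)[, 1] / counts
  names(pam) <- labeling$area_ids[present]
  adj <- rank_residuals(pam, counts)
  structure(list(per_vertex = per_vertex, per_area_mean = pam,
                 per_area_size_adjusted = adj,
                 singleton_areas = labeling$area_ids[singles],
                 excluded_vertices = excluded),
            class = "intra_areal_result")
}

## Residuals of rank(y) regressed linearly on rank(x) (Spearman-style
## adjustment; scale is in rank units).
rank_residuals <- function(y, x) {
  r <- residuals(lm(rank(y) ~ rank(x)))
  stats::setNames(as.numeric(r), names(y))
}

#' Hierarchical clustering of areas by gradient-profile similarity
#'
#' Agglomerative clustering with average linkage on distance
#' `1 - similarity`; the number of clusters is chosen by the maximum mean
#' silhouette width over `k_min..k_max`, ties resolved toward the smaller k.
#'
#' @param similarity symmetric area-by-area similarity matrix (e.g. from
#'   [similarity_affinity()]).
#' @param k_min,k_max cluster-count range, `2 <= k_min <= k_max < n`.
#' @return list with `labels` (integer per area), `chosen_k`, `criterion`
#'   (named mean silhouette per k) and the `hclust` tree.
#' @export
cluster_areas <- function(similarity, k_min = 2, k_max = 8) {
  stopifnot(is.matrix(similarity), nrow(similarity) == ncol(similarity))
  n <- nrow(similarity)
  stopifnot(2 <= k_min, k_min <= k_max, k_max < n)
  if (sd(similarity) == 0) {
    stop_fmt("degenerate similarity matrix (all entries identical)")
  }
  D <- 1 - similarity
  diag(D) <- 0
  dd <- as.dist((D + t(D)) / 2)
  hc <- hclust(dd, method = "average")
  ks <- k_min:k_max
  crit <- vapply(ks, function(k) {
    ct <- cutree(hc, k = k)
    sw <- cluster::silhouette(ct, dd)[, "sil_width"]
    mean(sw)
  }, numeric(1))
  names(crit) <- ks
  chosen <- ks[which.max(crit)]  # first maximum -> smallest k on ties
  labels <- cutree(hc, k = chosen)
  names(labels) <- rownames(similarity)
  list(labels = labels, chosen_k = chosen, criterion = crit, tree = hc)
}
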