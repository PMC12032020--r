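#' Hard area labels from a probabilistic atlas
#'
#' Assigns each vertex the area with the highest probability; vertices with
#' all-zero probability (mid-wall or uncovered cortex) are left unassigned
#' (`NA`). Ties are broken in favour of the lowest area index.
#'
#' @param atlas a `prob_atlas`.
#' @return object of class `area_labeling`: `label` (integer area index per
#'   vertex, `NA` = unassigned), `area_ids`, `area_sizes` (named vertex
#'   counts, zero-size areas included).
#' @export
assign_area_labels <- function(atlas) {
  stopifnot(inherits(atlas, "prob_atlas"))
  pm <- t(atlas$prob)                       # vertex x area
  lbl <- max.col(pm, ties.method = "first") # ties -> lowest area index
  lbl[rowSums(pm) == 0] <- NA_integer_
  sizes <- tabulate(lbl, nbins = nrow(atlas$prob))
  names(sizes) <- atlas$area_ids
  structure(list(label = lbl, area_ids = atlas$area_ids, area_sizes = sizes),
            class = "area_labeling")
}

#' @export
print.area_labeling <- function(x, ...) {
  cat(sprintf("area_labeling: %d vertices, %d areas (%d unassigned vertices)\n",
              length(x$label), length(x$area_ids), sum(is.na(x$label))))
  invisible(x)
}

#' Area-wise gradient profiles
#'
#' Averages the vertex-wise multimodal gradients within each labeled area.
#' Unassigned vertices are excluded; areas ending up with zero vertices are
#' dropped with a warning.
#'
#' @param gradients a `multimodal_gradients` object (or plain vertex-by-p
#'   matrix).
#' @param labeling an `area_labeling` sharing the vertex ordering.
#' @return object of class `gradient_profile_matrix`: `profiles` (area x p,
#'   rownames = area ids), `area_ids` (retained areas), `k_per_modality`.
#' @export
compute_area_profiles <- function(gradients, labeling) {
  G <- if (inherits(gradients, "multimodal_gradients")) {
    gradients$values
  } else {
    gradients
  }
  stopifnot(inherits(labeling, "area_labeling"),
            nrow(G) == length(labeling$label))
  keep <- !is.na(labeling$label)
  lbl <- labeling$label[keep]
  sums <- rowsum(G[keep, , drop = FALSE], lbl)
  counts <- as.numeric(table(lbl))
  profiles <- sums / counts
  present <- sort(unique(lbl))
  rownames(profiles) <- labeling$area_ids[present]
  dropped <- setdiff(seq_along(labeling$area_ids), present)
  if (length(dropped)) {
    warn_fmt("dropping %d area(s) with no assigned vertices: %s",
             length(dropped),
             paste(labeling$area_ids[dropped], collapse = ", "))
  }
  k <- if (inherits(gradients, "multimodal_gradients")) {
    gradients$k_per_modality
  } else {
    NA_integer_
  }
  structure(list(profiles = profiles,
                 area_ids = labeling$area_ids[present],
                 k_per_modality = k),
            class = "gradient_profile_matrix")
}

#' @export
print.gradient_profile_matrix <- function(x, ...) {
  cat(sprintf("gradient_profile_matrix: %d areas x %d gradient columns\n",
              nrow(x$profiles), ncol(x$profiles)))
  invisible(x)
}

#' Order areas along the principal component of their gradient profiles
#'
#' Column-centered PCA of the area-by-gradient profile matrix; areas are
#' sorted by their PC1 score (ascending). The PC1 sign is fixed so that the
#' score with the largest absolute value is positive.
#'
#' @param profiles a `gradient_profile_matrix` (or plain matrix, >= 2 rows).
#' @return list with `ordering` (area permutation, ascending PC1),
#'   `pc1_scores` (named per area) and `variance_explained` (fractions over
#'   all components, summing to 1).
#' @export
pca_reorder <- function(profiles) {
  P <- if (inherits(profiles, "gradient_profile_matrix")) {
    profiles$profiles
  } else {
    profiles
  }
  stopifnot(is.matrix(P), nrow(P) >= 2)
  if (all(apply(P, 2, sd) == 0)) {
    stop_fmt("profile matrix has rank 0 (all rows identical); PCA undefined")
  }
  pc <- prcomp(P, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  s1 <- pc$x[, 1]
  if (s1[which.max(abs(s1))] < 0) s1 <- -s1
  names(s1) <- rownames(P)
  list(ordering = order(s1), pc1_scores = s1, variance_explained = ve)
}
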