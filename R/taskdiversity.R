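#' Cross-task functional diversity maps
#'
#' For each vertex, the T x T matrix of cosine distances between the
#' vertex's whole-brain FC rows across tasks is computed (the vertex's own
#' diagonal FC entry is 0 in every task and therefore inert in the cosine).
#' The per-task diversity of a vertex is the mean distance between that task
#' and the other T - 1 tasks; the overall diversity is the mean over tasks;
#' the area map averages overall diversity over the assigned vertices.
#'
#' @param stack a `task_fc_stack` (>= 2 tasks, shared shape).
#' @param labeling an `area_labeling` sharing the vertex ordering.
#' @return object of class `diversity_maps`: `per_vertex_overall`,
#'   `per_vertex_per_task` (vertex x task matrix), `per_area` (named),
#'   `excluded_vertices` (vertices with a zero FC row in some task,
#'   excluded from area means).
#' @export
cross_task_diversity <- function(stack, labeling) {
  stopifnot(inherits(stack, "task_fc_stack"),
            inherits(labeling, "area_labeling"))
  fc <- stack$fc
  nt <- length(fc)
  nv <- nrow(fc[[1]])
  stopifnot(nv == length(labeling$label))

  norms <- vapply(fc, function(m) sqrt(rowSums(m^2)), numeric(nv))
  bad <- which(rowSums(norms == 0) > 0)

  ## mean pairwise distance accumulators: per task = mean over partners
  per_task <- matrix(0, nv, nt, dimnames = list(NULL, stack$task_names))
  for (s in seq_len(nt - 1)) {
    for (t in (s + 1):nt) {
      cs <- clip(rowSums(fc[[s]] * fc[[t]]) / (norms[, s] * norms[, t]), -1, 1)
      d <- 1 - cs
      ## identical fingerprints have exactly zero distance; guard the
      ## sqrt(x)*sqrt(x) != x rounding of the normalization
      d[rowSums(abs(fc[[s]] - fc[[t]])) == 0] <- 0
      per_task[, s] <- per_task[, s] + d
      per_task[, t] <- per_task[, t] + d
    }
  }
  per_task <- per_task / (nt - 1)
  overall <- rowMeans(per_task)
  if (length(bad)) {
    per_task[bad, ] <- NA_real_
    overall[bad] <- NA_real_
  }

  keep <- !is.na(labeling$label) & !is.na(overall)
  lbl <- labeling$label[keep]
  per_area <- rowsum(overall[keep], lbl)[, 1] / as.numeric(table(lbl))
  names(per_area) <- labeling$area_ids[sort(unique(lbl))]

  structure(list(per_vertex_overall = overall,
                 per_vertex_per_task = per_task,
                 per_area = per_area,
                 excluded_vertices = bad),
            class = "diversity_maps")
}

#' @export
print.diversity_maps <- function(x, ...) {
  cat(sprintf(
    "diversity_maps: %d vertices x %d tasks, %d areas (%d excluded vertices)\n",
    nrow(x$per_vertex_per_task), ncol(x$per_vertex_per_task),
    length(x$per_area), length(x$excluded_vertices)))
  invisible(x)
}

#' Intra-areal cross-task variability
#'
#' For each vertex v of an area a and each task t, the mean FC strength
#' from v to the other vertices of a is computed; the per-vertex sample SD
#' (denominator n - 1) across tasks is then averaged over the area's
#' vertices (the sum of vertex SDs divided by the vertex count, controlling
#' for parcel size). Singleton areas are excluded with a warning.
#'
#' @inheritParams cross_task_diversity
#' @return named per-area numeric vector (`NA` for excluded singletons).
#' @export
intra_areal_task_sd <- function(stack, labeling) {
  stopifnot(inherits(stack, "task_fc_stack"),
            inherits(labeling, "area_labeling"))
  fc <- stack$fc
  nt <- length(fc)
  lbl <- labeling$label
  present <- sort(unique(lbl[!is.na(lbl)]))
  out <- stats::setNames(rep(NA_real_, length(present)),
                         labeling$area_ids[present])
  skipped <- character(0)
  for (j in seq_along(present)) {
    a <- present[j]
    vs <- which(!is.na(lbl) & lbl == a)
    if (length(vs) < 2) {
      skipped <- c(skipped, labeling$area_ids[a])
      next
    }
    ## |a| x T matrix of within-area mean FC (own zero diagonal excluded)
    wm <- vapply(fc, function(m) {
      rowSums(m[vs, vs, drop = FALSE]) / (length(vs) - 1)
    }, numeric(length(vs)))
    sds <- apply(wm, 1, sd)
    out[j] <- sum(sds) / length(vs)
  }
  if (length(skipped)) {
    warn_fmt("excluding %d singleton area(s) from cross-task SD: %s",
             length(skipped), paste(skipped, collapse = ", "))
  }
  out
}
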