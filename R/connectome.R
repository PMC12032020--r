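#' Construct a connectome object
#'
#' A tagged square vertex-by-vertex matrix. Unsparsified connectomes must be
#' symmetric within 1e-8 and have a zero diagonal; row-sparsified matrices
#' (see [sparsify_rows()]) are allowed to be asymmetric.
#'
#' @param weights square numeric matrix, finite entries.
#' @param modality one of `"MPC"`, `"SC"`, `"FC"`.
#' @param task_tag optional task label (FC only).
#' @param exclusions integer vector of vertices whose rows/columns were
#'   zeroed (e.g. constant inputs).
#' @param sparsified logical; skip the symmetry requirement.
#' @return object of class `connectome`.
#' @export
connectome <- function(weights, modality, task_tag = NULL,
                       exclusions = integer(0), sparsified = FALSE) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  modality <- match.arg(modality, c("MPC", "SC", "FC"))
  if (any(!is.finite(weights))) stop_fmt("non-finite connectome entries")
  if (!sparsified && max(abs(weights - t(weights))) > 1e-8) {
    stop_fmt("connectome matrix is not symmetric within 1e-8")
  }
  if (any(diag(weights) != 0)) stop_fmt("connectome diagonal must be zero")
  structure(list(weights = weights, modality = modality, task_tag = task_tag,
                 exclusions = exclusions, sparsified = sparsified),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome [%s%s]: %d x %d%s%s\n", x$modality,
              if (is.null(x$task_tag)) "" else paste0("/", x$task_tag),
              nrow(x$weights), ncol(x$weights),
              if (x$sparsified) ", row-sparsified" else "",
              if (length(x$exclusions)) sprintf(", %d excluded vertices",
                                                length(x$exclusions)) else ""))
  invisible(x)
}

#' @export
as.matrix.connectome <- function(x, ...) x$weights

#' Microstructural profile covariance from depth profiles
#'
#' Cross-correlates per-vertex intensity profiles with partial correlations
#' controlling for the average cortex-wide intensity profile, then applies a
#' Fisher r-to-z transform (the log-transform of the MPC convention) with
#' non-positive values floored at 0. For vertices i, j and mean profile m:
#' `r_ij|m = (r_ij - r_im r_jm) / sqrt((1 - r_im^2)(1 - r_jm^2))`.
#' Correlations are clipped to +/-(1 - 1e-6) before the transform.
#'
#' @param profiles depth-by-vertex numeric matrix (>= 3 depths, >= 3
#'   vertices).
#' @return a `connectome` of modality `"MPC"`; degenerate vertices
#'   (constant profiles, or profiles collinear with the mean profile, whose
#'   partial correlation is undefined) are zeroed and listed in
#'   `$exclusions`.
#' @export
build_mpc <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 3, ncol(profiles) >= 3)
  nv <- ncol(profiles)
  sds <- apply(profiles, 2, sd)
  excl <- which(sds == 0)
  ok <- setdiff(seq_len(nv), excl)
  m <- rowMeans(profiles)
  if (length(ok) >= 2 && sd(m) > 0) {
    rim_all <- as.numeric(cor(profiles[, ok, drop = FALSE], m))
    degen <- ok[abs(rim_all) >= COR_CLIP]
    excl <- sort(c(excl, degen))
    ok <- setdiff(ok, degen)
  }
  Z <- matrix(0, nv, nv)
  if (length(ok) >= 2) {
    P <- profiles[, ok, drop = FALSE]
    R <- cor(P)
    rim <- if (sd(m) > 0) as.numeric(cor(P, m)) else rep(0, length(ok))
    pr <- (R - outer(rim, rim)) / sqrt(outer(1 - rim^2, 1 - rim^2))
    z <- fisher_z(pr)
    z[z < 0] <- 0
    diag(z) <- 0
    Z[ok, ok] <- z
  }
  connectome(Z, "MPC", exclusions = excl)
}

#' Functional connectivity from vertex timeseries
#'
#' Pearson correlation of all vertex pairs followed by a Fisher r-to-z
#' transform (correlations clipped to +/-(1 - 1e-6)); zero diagonal.
#'
#' @param timeseries timepoint-by-vertex numeric matrix (>= 3 timepoints).
#' @param task_tag optional task label.
#' @return a `connectome` of modality `"FC"`; constant columns are zeroed
#'   and listed in `$exclusions`.
#' @export
build_fc <- function(timeseries, task_tag = NULL) {
  stopifnot(is.matrix(timeseries), nrow(timeseries) >= 3)
  nv <- ncol(timeseries)
  sds <- apply(timeseries, 2, sd)
  excl <- which(sds == 0)
  ok <- setdiff(seq_len(nv), excl)
  Z <- matrix(0, nv, nv)
  if (length(ok) >= 2) {
    z <- fisher_z(cor(timeseries[, ok, drop = FALSE]))
    diag(z) <- 0
    Z[ok, ok] <- z
  }
  connectome(Z, "FC", task_tag = task_tag, exclusions = excl)
}

#' Row-wise sparsification of a connectome
#'
#' Per row, retains the `ceiling(keep_fraction * (n - 1))` largest
#' off-diagonal entries and zeroes the rest; ties at the cutoff are broken
#' in favour of the lower column index. The default pipeline keeps the top
#' 10% of weights. The result is generally asymmetric.
#'
#' @param conn a `connectome`.
#' @param keep_fraction fraction in (0, 1] of off-diagonal entries to keep
#'   per row.
#' @return a row-sparsified `connectome`.
#' @export
sparsify_rows <- function(conn, keep_fraction = 0.10) {
  stopifnot(inherits(conn, "connectome"),
            keep_fraction > 0, keep_fraction <= 1)
  W <- conn$weights
  n <- nrow(W)
  m <- ceiling(keep_fraction * (n - 1))
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cols <- setdiff(seq_len(n), i)
    vals <- W[i, cols]
    keep <- cols[order(-vals, cols)[seq_len(m)]]
    out[i, keep] <- W[i, keep]
  }
  connectome(out, conn$modality, task_tag = conn$task_tag,
             exclusions = conn$exclusions, sparsified = TRUE)
}

#' Normalized-angle affinity of a connectome
#'
#' Cosine similarity `c_ij` between the (typically row-sparsified)
#' connectivity rows, mapped into \[0, 1\] by
#' `A_ij = 1 - acos(clip(c_ij, -1, 1)) / pi`, diagonal forced to 1 and
#' symmetrized as `(A + t(A)) / 2`.
#'
#' @param conn a `connectome`.
#' @return object of class `affinity_matrix` with fields `values` and
#'   `source_modality`.
#' @export
normalized_angle_affinity <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  W <- conn$weights
  rn <- sqrt(rowSums(W^2))
  zero <- which(rn == 0)
  if (length(zero)) {
    stop_fmt("all-zero connectivity row(s) at vertex %s; cannot form affinity",
             paste(head(zero, 5), collapse = ", "))
  }
  C <- tcrossprod(W / rn)
  A <- 1 - acos(clip(C, -1, 1)) / pi
  A <- (A + t(A)) / 2
  diag(A) <- 1
  structure(list(values = A, source_modality = conn$modality),
            class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("affinity_matrix [%s]: %d x %d, range [%.3f, %.3f]\n",
              x$source_modality, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}
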