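#' Diffusion-map embedding of an affinity matrix
#'
#' Spectral embedding with anisotropic normalization: with `D` the diagonal
#' of row sums of the affinity `W`, form `W' = D^-alpha W D^-alpha`, row
#' normalize to the Markov operator `M`, and eigendecompose (via the
#' symmetric conjugate of `M`, which shares its spectrum). The trivial
#' constant eigenvector is dropped and component i is the i-th nontrivial
#' eigenvector scaled by `lambda_i / (1 - lambda_i)` (diffusion time 0
#' convention). Each component's sign is fixed so that its maximum-|value|
#' entry is positive, making downstream alignment deterministic.
#'
#' @param affinity an `affinity_matrix` (or symmetric nonnegative matrix).
#' @param n_components number of nontrivial components to keep (default 10).
#' @param alpha anisotropic normalization exponent (default 0.5).
#' @return object of class `gradient_set`: `components` (vertex x k),
#'   `eigenvalues` (k, nonincreasing), `eigenvalues_full` (all nontrivial
#'   eigenvalues, for variance accounting), `modality`, `alpha`.
#' @export
diffusion_map <- function(affinity, n_components = 10, alpha = 0.5) {
  W <- if (inherits(affinity, "affinity_matrix")) affinity$values else affinity
  modality <- if (inherits(affinity, "affinity_matrix")) {
    affinity$source_modality
  } else {
    "custom"
  }
  n <- nrow(W)
  stopifnot(is.matrix(W), n == ncol(W), n_components >= 1, n_components < n)
  if (any(W < 0)) stop_fmt("affinity entries must be nonnegative")
  if (max(abs(W - t(W))) > 1e-8) stop_fmt("affinity matrix must be symmetric")

  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected"))
  if (comp$no > 1) {
    stop_fmt("affinity graph is disconnected (component sizes: %s)",
             paste(comp$csize, collapse = ", "))
  }

  d <- rowSums(W)
  W1 <- W / outer(d^alpha, d^alpha)
  d1 <- rowSums(W1)
  S <- W1 / outer(sqrt(d1), sqrt(d1))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values                     # nonincreasing; lam[1] = 1 (trivial)
  psi <- e$vectors / sqrt(d1)         # eigenvectors of M
  idx <- 1 + seq_len(n_components)
  lam_k <- lam[idx]
  scale_k <- lam_k / (1 - lam_k)
  comps <- psi[, idx, drop = FALSE] *
    matrix(scale_k, n, n_components, byrow = TRUE)
  for (j in seq_len(n_components)) {
    if (comps[which.max(abs(comps[, j])), j] < 0) comps[, j] <- -comps[, j]
  }
  colnames(comps) <- paste0("G", seq_len(n_components))
  structure(list(components = comps, eigenvalues = lam_k,
                 eigenvalues_full = lam[-1], modality = modality,
                 alpha = alpha, n_components = as.integer(n_components)),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("gradient_set [%s]: %d vertices x %d components (alpha = %g)\n",
              x$modality, nrow(x$components), ncol(x$components), x$alpha))
  invisible(x)
}

#' Orthogonal Procrustes alignment of gradient sets
#'
#' Finds the single orthogonal transform (after column centering; no
#' scaling) minimizing the Frobenius distance from the source components to
#' the reference, and applies it to the source. Used to align subject-level
#' gradients to a template and the right hemisphere to the left.
#'
#' @param source,reference `gradient_set` objects with matching component
#'   shapes.
#' @return the aligned `gradient_set` (source eigenvalues retained), with
#'   the rotation stored in `$rotation`.
#' @export
procrustes_align <- function(source, reference) {
  stopifnot(inherits(source, "gradient_set"),
            inherits(reference, "gradient_set"))
  X <- source$components
  Y <- reference$components
  if (!all(dim(X) == dim(Y))) {
    stop_fmt("shape mismatch: source %dx%d vs reference %dx%d",
             nrow(X), ncol(X), nrow(Y), ncol(Y))
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sv <- svd(crossprod(Xc, Yc))
  R <- sv$u %*% t(sv$v)
  aligned <- Xc %*% R +
    matrix(colMeans(Y), nrow(Y), ncol(Y), byrow = TRUE)
  colnames(aligned) <- colnames(Y)
  out <- source
  out$components <- aligned
  out$rotation <- R
  out
}

#' Normalize gradients per modality and stack into the multimodal array
#'
#' Takes the first `k` components of each modality, divides each column by
#' the maximum absolute value of that column (so every gradient spans
#' \[-1, 1\]), and concatenates in order MPC, SC, FC.
#'
#' @param gradsets list of three `gradient_set`s in order MPC, SC, FC.
#' @param k_per_modality gradients per modality, in the supported range
#'   3..7 (default 5).
#' @return object of class `multimodal_gradients`: `values` (vertex x 3k,
#'   columns `MPC_G1..FC_Gk`), `k_per_modality`, `modalities`.
#' @export
normalize_and_stack <- function(gradsets, k_per_modality = 5) {
  stopifnot(is.list(gradsets), length(gradsets) == 3)
  k <- as.integer(k_per_modality)
  if (k < 3 || k > 7) stop_fmt("k_per_modality must be in 3..7, got %d", k)
  mods <- vapply(gradsets, function(g) g$modality, character(1))
  blocks <- lapply(gradsets, function(g) {
    if (ncol(g$components) < k) {
      stop_fmt("%s gradient set has %d < %d components", g$modality,
               ncol(g$components), k)
    }
    B <- g$components[, seq_len(k), drop = FALSE]
    sweep(B, 2, apply(abs(B), 2, max), "/")
  })
  values <- do.call(cbind, blocks)
  colnames(values) <- unlist(lapply(mods, function(m) paste0(m, "_G", 1:k)))
  structure(list(values = values, k_per_modality = k, modalities = mods),
            class = "multimodal_gradients")
}

#' @export
print.multimodal_gradients <- function(x, ...) {
  cat(sprintf("multimodal_gradients: %d vertices x %d columns (%s; k = %d)\n",
              nrow(x$values), ncol(x$values),
              paste(x$modalities, collapse = ", "), x$k_per_modality))
  invisible(x)
}

#' Group-level gradient template from subject connectomes
#'
#' Averages subject connectome matrices entrywise, then sparsifies, forms
#' the normalized-angle affinity and embeds it; the result serves as the
#' Procrustes reference for subject-level gradients.
#'
#' @param connectomes list of `connectome`s sharing modality and shape.
#' @param keep_fraction row sparsity passed to [sparsify_rows()].
#' @param n_components,alpha passed to [diffusion_map()].
#' @return a `gradient_set`.
#' @export
group_template <- function(connectomes, keep_fraction = 0.10,
                           n_components = 10, alpha = 0.5) {
  stopifnot(is.list(connectomes), length(connectomes) >= 1)
  dims <- vapply(connectomes, function(x) dim(x$weights), integer(2))
  if (any(dims != dims[, 1])) stop_fmt("subject connectomes differ in shape")
  W <- Reduce(`+`, lapply(connectomes, function(x) x$weights)) /
    length(connectomes)
  avg <- connectome(W, connectomes[[1]]$modality)
  diffusion_map(normalized_angle_affinity(sparsify_rows(avg, keep_fraction)),
                n_components = n_components, alpha = alpha)
}
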