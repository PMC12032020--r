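#' Specification of planted gradients for the synthetic cortex
#'
#' Bundles the latent-axis settings used by [make_multimodal_dataset()]:
#' how many smooth latent axes to plant, their spatial correlation length,
#' the per-modality signal-to-noise ratios, and the master seed from which
#' all generation is derived.
#'
#' @param n_axes number of planted axes (>= 1); axis 1 plays the role of the
#'   sensory-fugal axis every modality encodes.
#' @param correlation_length smoothness scale of the planted fields (mesh
#'   units); recycled across axes.
#' @param snr named or unnamed numeric of per-modality signal-to-noise
#'   ratios for `mpc`, `sc`, `fc`; `Inf` means noise-free.
#' @param seed integer master seed.
#' @return object of class `planted_gradient_spec`.
#' @export
planted_gradient_spec <- function(n_axes = 2, correlation_length = 25,
                                  snr = c(mpc = 4, sc = 4, fc = 4),
                                  seed = 1) {
  stopifnot(n_axes >= 1, all(correlation_length > 0))
  if (is.null(names(snr))) {
    snr <- rep_len(snr, 3L)
    names(snr) <- c("mpc", "sc", "fc")
  }
  stopifnot(all(c("mpc", "sc", "fc") %in% names(snr)), all(snr > 0))
  structure(list(n_axes = as.integer(n_axes),
                 correlation_length = rep_len(correlation_length, n_axes),
                 snr = snr[c("mpc", "sc", "fc")],
                 seed = as.integer(seed)),
            class = "planted_gradient_spec")
}

#' Generate a synthetic multimodal cortical dataset
#'
#' Produces the full set of inputs the gradient pipeline consumes, with the
#' statistical structure the analysis assumes and a retained ground truth:
#'
#' * depth-by-vertex intensity profiles whose shape rotates along planted
#'   axis 1 (the MPC source);
#' * per-scan vertex timeseries (one rest scan plus `n_tasks` task scans)
#'   whose pairwise correlation falls off with latent-axis distance, task
#'   scans perturbed through a smooth "flexibility" field (the FC source);
#' * a distance-decaying structural connectivity matrix modulated by
#'   latent-axis similarity;
#' * a probabilistic Voronoi parcellation, per-area hierarchy levels
#'   (quartiles of planted axis 1, ordered idiotypic, unimodal, heteromodal,
#'   paralimbic), a noisy per-area histological-gradient analogue, and a
#'   per-area tSNR covariate map.
#'
#' The latent axis enters every modality through the monotone angle
#' `theta = (pi/2) * rank(axis1) / V`, so rank correlations against
#' `planted[, 1]` measure recovery directly. Timeseries noise is drawn once
#' and shared across scans; task scans differ only through the flexibility
#' perturbation, so `flex_amplitude = 0` yields exactly identical task FC
#' (an exact negative control). All randomness derives from `spec$seed`.
#'
#' @param mesh a `cortex_mesh`.
#' @param spec a [planted_gradient_spec()].
#' @param n_depths number of intracortical sampling depths (>= 3; study
#'   analogue: 14 equivolumetric surfaces with the two boundary surfaces
#'   removed, 12 usable depths).
#' @param n_timepoints timepoints per scan (>= 20).
#' @param n_tasks number of task scans (>= 2).
#' @param n_areas parcellation size.
#' @param softness parcellation temperature (see [make_parcellation()]).
#' @param flex_amplitude amplitude (radians) of the per-task latent-angle
#'   perturbation; 0 disables task differences.
#' @return object of class `synthetic_cortex_dataset`; see fields in the
#'   package vignette. `planted` (vertex x n_axes) is the ground truth.
#' @export
make_multimodal_dataset <- function(mesh, spec, n_depths = 12,
                                    n_timepoints = 150, n_tasks = 3,
                                    n_areas = 48, softness = 0,
                                    flex_amplitude = 0.4) {
  stopifnot(inherits(mesh, "cortex_mesh"),
            inherits(spec, "planted_gradient_spec"),
            n_depths >= 3, n_timepoints >= 20, n_tasks >= 2)
  nv <- nrow(mesh$coords)
  seed <- spec$seed

  atlas <- make_parcellation(mesh, n_areas, softness,
                             seed = child_seed(seed, "atlas"))
  labeling <- assign_area_labels(atlas)

  planted <- vapply(seq_len(spec$n_axes), function(j) {
    make_smooth_field(mesh, spec$correlation_length[j],
                      seed = child_seed(seed, paste0("axis", j)))
  }, numeric(nv))
  colnames(planted) <- paste0("axis", seq_len(spec$n_axes))

  ## Each planted axis j is encoded through a monotone angle in [0, pi/2]
  ## with geometrically decaying per-modality amplitudes, so gradient 1 is
  ## dominated by axis 1 while higher gradients carry stable secondary
  ## structure (as multi-gradient cortical data does). Secondary amplitude
  ## is weakest for MPC, whose floored partial-correlation kernel is
  ## spatially local and most sensitive to axis mixing. The number of
  ## encoded axes is capped by the depth-basis capacity.
  n_enc <- min(spec$n_axes, max(1L, (n_depths - 2L) %/% 2L))
  thetas <- vapply(seq_len(n_enc), function(j) {
    (pi / 2) * (rank(planted[, j], ties.method = "first") - 1) / (nv - 1)
  }, numeric(nv))
  amp_mpc <- 0.2^(seq_len(n_enc) - 1)
  amp_fc <- 0.3^(seq_len(n_enc) - 1)
  amp_sc <- 0.4^(seq_len(n_enc) - 1)
  theta <- thetas[, 1]

  ## --- depth profiles (MPC source) ---------------------------------------
  ## Orthogonal depth basis pairs mixed with the planted angles: the
  ## partial correlation between two vertices' profiles (controlling the
  ## mean profile) falls with their latent-angle distances.
  xd <- seq_len(n_depths) / (n_depths + 1)
  base <- 1.5 - xd
  profiles <- outer(base, rep(1, nv))
  for (j in seq_len(n_enc)) {
    b1 <- sqrt(2) * cos((2 * j - 1) * pi * xd)
    b2 <- sqrt(2) * cos(2 * j * pi * xd)
    profiles <- profiles +
      amp_mpc[j] * (b1 %o% cos(thetas[, j]) + b2 %o% sin(thetas[, j]))
  }
  if (is.finite(spec$snr[["mpc"]])) {
    profiles <- profiles +
      with_seed(child_seed(seed, "profiles"),
                matrix(rnorm(n_depths * nv), n_depths, nv)) / spec$snr[["mpc"]]
  }

  ## --- timeseries (FC source) --------------------------------------------
  ## Shared latent source pairs mixed by the (possibly task-shifted)
  ## angles; the noise realization is shared across scans so task effects
  ## are pure.
  src <- with_seed(child_seed(seed, "sources"),
                   matrix(rnorm(n_timepoints * 2 * n_enc), n_timepoints,
                          2 * n_enc))
  eps <- if (is.finite(spec$snr[["fc"]])) {
    with_seed(child_seed(seed, "ts_noise"),
              matrix(rnorm(n_timepoints * nv), n_timepoints, nv)) /
      spec$snr[["fc"]]
  } else {
    matrix(0, n_timepoints, nv)
  }
  flex <- pnorm(make_smooth_field(mesh, spec$correlation_length[1],
                                  seed = child_seed(seed, "flex")))
  shifts <- c(rest = 0,
              stats::setNames(flex_amplitude * seq(-1, 1, length.out = n_tasks),
                              paste0("task", seq_len(n_tasks))))
  timeseries <- lapply(shifts, function(s) {
    y <- eps
    for (j in seq_len(n_enc)) {
      th <- thetas[, j] + if (j == 1) flex * s else 0
      y <- y + amp_fc[j] * (src[, 2 * j - 1] %o% cos(th) +
                              src[, 2 * j] %o% sin(th))
    }
    y
  })

  ## --- structural connectivity -------------------------------------------
  ## Exponential decay in Euclidean (chord) distance, a fixed 2*radius
  ## inter-hemispheric penalty (the hemispheres are concentric spheres),
  ## modulated by latent-axis similarity; multiplicative log-normal noise.
  dmat <- as.matrix(stats::dist(mesh$coords))
  hh <- as.integer(mesh$hemisphere)
  cross <- outer(hh, hh, "!=")
  dmat[cross] <- dmat[cross] + 2 * mesh$radius
  sc <- exp(-dmat / (mesh$radius / 2))
  for (j in seq_len(n_enc)) {
    sc <- sc * exp(-amp_sc[j] * abs(outer(thetas[, j], thetas[, j], "-")))
  }
  if (is.finite(spec$snr[["sc"]])) {
    E <- with_seed(child_seed(seed, "sc_noise"),
                   matrix(rnorm(nv * nv), nv, nv))
    sc <- sc * exp((E + t(E)) / (2 * spec$snr[["sc"]]))
  }
  diag(sc) <- 0

  ## --- area-level annotations --------------------------------------------
  area_axis <- area_means_of(planted[, 1], labeling)
  hierarchy <- hierarchy_from_axis(area_axis)
  histo <- area_axis +
    with_seed(child_seed(seed, "histo"), rnorm(length(area_axis))) * 0.1
  tsnr_field <- make_smooth_field(mesh, spec$correlation_length[1],
                                  seed = child_seed(seed, "tsnr"))
  tsnr <- 50 + 10 * area_means_of(tsnr_field, labeling)

  structure(
    list(mesh = mesh, atlas = atlas, profiles = profiles,
         timeseries = timeseries, sc = sc, planted = planted,
         hierarchy = hierarchy, histological_gradient = histo,
         covariates = list(tsnr = tsnr), spec = spec,
         params = list(n_depths = n_depths, n_timepoints = n_timepoints,
                       n_tasks = n_tasks, n_areas = n_areas,
                       softness = softness, flex_amplitude = flex_amplitude)),
    class = "synthetic_cortex_dataset")
}

area_means_of <- function(values, labeling) {
  keep <- !is.na(labeling$label)
  m <- rowsum(values[keep], labeling$label[keep]) /
    as.numeric(table(labeling$label[keep]))
  stats::setNames(as.numeric(m), labeling$area_ids[sort(unique(labeling$label[keep]))])
}

## Mesulam-style four-zone labels from quartiles of the latent axis: the
## sensory end (lowest quartile) is idiotypic, the apex paralimbic.
hierarchy_from_axis <- function(area_axis) {
  qs <- quantile(area_axis, c(0, 0.25, 0.5, 0.75, 1))
  lv <- c("idiotypic", "unimodal", "heteromodal", "paralimbic")
  cut(area_axis, breaks = qs, labels = lv, include.lowest = TRUE) |>
    stats::setNames(names(area_axis))
}

#' @export
print.synthetic_cortex_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_cortex_dataset: %d vertices, %d areas, %d depths, %d scans\n",
    nrow(x$mesh$coords), length(x$atlas$area_ids), nrow(x$profiles),
    length(x$timeseries)))
  invisible(x)
}

#' Build a task FC stack with an exactly linear task perturbation
#'
#' A controlled generator for the cross-task statistics: each task matrix is
#' `base + amplitude * d_t * (flex %o% flex)` with task loadings `d_t`
#' equally spaced in \[-1, 1\]. Every within-area FC mean is then exactly
#' linear in `amplitude`, so the cross-task SD scales exactly linearly too.
#'
#' @param base_fc symmetric vertex-by-vertex base FC matrix (zero diagonal).
#' @param flexibility per-vertex nonnegative flexibility values.
#' @param amplitude perturbation amplitude (0 yields identical tasks).
#' @param n_tasks number of tasks (>= 2).
#' @return a `task_fc_stack`.
#' @export
make_task_fc_stack <- function(base_fc, flexibility, amplitude = 0.1,
                               n_tasks = 4) {
  stopifnot(nrow(base_fc) == ncol(base_fc),
            length(flexibility) == nrow(base_fc), n_tasks >= 2)
  d <- seq(-1, 1, length.out = n_tasks)
  pert <- flexibility %o% flexibility
  fc <- lapply(d, function(dt) {
    m <- base_fc + amplitude * dt * pert
    diag(m) <- 0
    m
  })
  task_fc_stack(stats::setNames(fc, paste0("task", seq_len(n_tasks))))
}

#' Construct a task-tagged FC stack
#' @param fc named list of vertex-by-vertex FC matrices (or `connectome`
#'   objects) sharing shape and vertex ordering; at least 2 tasks.
#' @return object of class `task_fc_stack` with fields `fc` (list of
#'   matrices) and `task_names`.
#' @export
task_fc_stack <- function(fc) {
  stopifnot(is.list(fc), length(fc) >= 2)
  fc <- lapply(fc, function(m) if (inherits(m, "connectome")) m$weights else m)
  dims <- vapply(fc, dim, integer(2))
  if (any(dims != dims[, 1])) stop_fmt("task FC matrices differ in shape")
  if (is.null(names(fc))) names(fc) <- paste0("task", seq_along(fc))
  structure(list(fc = fc, task_names = names(fc)), class = "task_fc_stack")
}
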