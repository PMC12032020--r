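#' Pipeline configuration
#'
#' Validated bundle of all analysis settings. Defaults follow the study
#' convention: 10% row sparsity, 10 diffusion components at alpha 0.5, the
#' first 5 gradients per modality, 1000 spin permutations, FDR level 0.05.
#'
#' @param simulate named list of generator settings (see
#'   [make_multimodal_dataset()]): `subdivision_level`, `hemispheres`,
#'   `n_areas`, `n_axes`, `correlation_length`, `snr`, `n_depths`,
#'   `n_timepoints`, `n_tasks`, `softness`, `flex_amplitude`. Ignored when
#'   `input_dir` points at a written dataset.
#' @param input_dir optional directory of matrices written with
#'   [write_outputs()]-compatible writers (alternative to simulation).
#' @param keep_fraction row sparsity in (0, 1], scalar or named per modality
#'   (`mpc`, `sc`, `fc`).
#' @param n_components diffusion components (default 10).
#' @param alpha diffusion anisotropy exponent (default 0.5).
#' @param k_per_modality gradients kept per modality, range 3..7 (default 5).
#' @param n_perm spin permutations (default 1000).
#' @param fdr_q FDR level (default 0.05).
#' @param seed global seed; every stage derives its own child seed from it.
#' @param out_dir optional output directory for [run_pipeline()].
#' @return object of class `gm_config`.
#' @export
gm_config <- function(simulate = list(), input_dir = NULL,
                      keep_fraction = 0.10, n_components = 10, alpha = 0.5,
                      k_per_modality = 5, n_perm = 1000, fdr_q = 0.05,
                      seed = 1, out_dir = NULL) {
  kf <- keep_fraction
  if (is.null(names(kf))) {
    kf <- stats::setNames(rep_len(kf, 3), c("mpc", "sc", "fc"))
  }
  if (any(kf <= 0) || any(kf > 1)) {
    stop_fmt("keep_fraction must lie in (0, 1], got %s",
             paste(format(kf), collapse = ", "))
  }
  if (k_per_modality < 3 || k_per_modality > 7) {
    stop_fmt("k_per_modality must be in 3..7, got %s", format(k_per_modality))
  }
  if (n_components <= k_per_modality) {
    stop_fmt("n_components (%d) must exceed k_per_modality (%d)",
             n_components, k_per_modality)
  }
  stopifnot(alpha >= 0, n_perm >= 1, fdr_q > 0, fdr_q < 1)
  sim_defaults <- list(subdivision_level = 3, hemispheres = 2, n_areas = 48,
                       n_axes = 2, correlation_length = 25,
                       snr = c(mpc = 4, sc = 4, fc = 4), n_depths = 12,
                       n_timepoints = 150, n_tasks = 3, softness = 0,
                       flex_amplitude = 0.4)
  sim <- utils::modifyList(sim_defaults, simulate)
  structure(list(simulate = sim, input_dir = input_dir,
                 keep_fraction = kf, n_components = as.integer(n_components),
                 alpha = alpha, k_per_modality = as.integer(k_per_modality),
                 n_perm = as.integer(n_perm), fdr_q = fdr_q,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "gm_config")
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror the [gm_config()] arguments.
#' @return a `gm_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate$snr)) y$simulate$snr <- unlist(y$simulate$snr)
  if (!is.null(y$keep_fraction)) y$keep_fraction <- unlist(y$keep_fraction)
  do.call(gm_config, y)
}

#' Run the full multimodal gradient analysis
#'
#' Sequences the pipeline: synthetic data generation (or loading) ->
#' connectome construction (MPC from depth profiles, FC from the rest scan,
#' SC consumed as a matrix) -> row sparsification -> normalized-angle
#' affinity -> diffusion-map gradients -> per-modality normalization and
#' stacking -> area profiles and PCA reordering -> inter-/intra-areal
#' dissimilarity, similarity clustering -> cross-task diversity -> spin
#' permutation inference (extreme areas, hierarchy contrasts, Spearman
#' associations, participation coefficient, global FC strength).
#'
#' All randomness derives from `config$seed` through stage-named child
#' seeds, so reruns with one seed are identical.
#'
#' @param config a `gm_config`.
#' @return object of class `gm_report`; see the vignette for the fields.
#'   When `config$out_dir` is set the report and tables are also written
#'   there (see [write_outputs()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "gm_config"))
  sim <- config$simulate
  dataset <- local({
    mesh <- make_sphere_mesh(sim$subdivision_level,
                             hemispheres = sim$hemispheres)
    spec <- planted_gradient_spec(n_axes = sim$n_axes,
                                  correlation_length = sim$correlation_length,
                                  snr = sim$snr,
                                  seed = child_seed(config$seed, "simulate"))
    make_multimodal_dataset(mesh, spec, n_depths = sim$n_depths,
                            n_timepoints = sim$n_timepoints,
                            n_tasks = sim$n_tasks, n_areas = sim$n_areas,
                            softness = sim$softness,
                            flex_amplitude = sim$flex_amplitude)
  })
  labeling <- assign_area_labels(dataset$atlas)

  conns <- list(
    MPC = build_mpc(dataset$profiles),
    SC = connectome(dataset$sc, "SC"),
    FC = build_fc(dataset$timeseries$rest))
  kf <- config$keep_fraction[c("mpc", "sc", "fc")]
  gradsets <- Map(function(cn, f) {
    diffusion_map(normalized_angle_affinity(sparsify_rows(cn, f)),
                  n_components = config$n_components, alpha = config$alpha)
  }, conns, kf)
  gradients <- normalize_and_stack(gradsets, config$k_per_modality)

  profiles <- compute_area_profiles(gradients, labeling)
  pca <- pca_reorder(profiles)
  inter <- inter_areal_dissimilarity(profiles)
  intra <- intra_areal_dissimilarity(gradients, labeling)
  sim_aff <- similarity_affinity(profiles)
  clust <- cluster_areas(sim_aff, k_min = 2,
                         k_max = min(8, nrow(sim_aff) - 1))

  task_names <- setdiff(names(dataset$timeseries), "rest")
  stack <- task_fc_stack(lapply(dataset$timeseries[task_names], build_fc))
  diversity <- cross_task_diversity(stack, labeling)
  task_sd <- intra_areal_task_sd(stack, labeling)

  ## --- inference ----------------------------------------------------------
  idx <- spin_rotation_indices(dataset$mesh, config$n_perm,
                               seed = child_seed(config$seed, "spin"))
  aset <- names(inter$per_area)
  nulls_inter <- spin_nulls(inter$per_area, labeling, dataset$mesh,
                            indices = idx)
  extreme <- extreme_area_test(inter$per_area, nulls_inter, q = config$fdr_q)
  hier <- dataset$hierarchy[aset]
  contrasts <- hierarchy_ttests(inter$per_area, hier, nulls_inter)
  histo <- dataset$histological_gradient[aset]
  cor_histo <- spin_spearman(inter$per_area, histo, nulls_inter)
  cor_div <- spin_spearman(inter$per_area, diversity$per_area[aset],
                           nulls_inter)
  cor_div_tsnr <- spin_spearman(inter$per_area, diversity$per_area[aset],
                                nulls_inter,
                                covariate = dataset$covariates$tsnr[aset])
  cor_size <- spin_spearman(intra$per_area_mean[aset],
                            as.numeric(labeling$area_sizes[aset]),
                            spin_nulls(intra$per_area_mean[aset], labeling,
                                       dataset$mesh, indices = idx))
  fc_area <- area_block_means(conns$FC$weights, labeling, aset)
  pc <- participation_coefficient(fc_area, hier)
  gstr <- global_strength(fc_area)

  area_table <- data.frame(
    area = aset,
    inter_dissimilarity = as.numeric(inter$per_area),
    intra_dissimilarity = as.numeric(intra$per_area_mean[aset]),
    intra_size_adjusted = as.numeric(intra$per_area_size_adjusted[aset]),
    cross_task_diversity = as.numeric(diversity$per_area[aset]),
    intra_task_sd = as.numeric(task_sd[aset]),
    hierarchy = as.character(hier),
    cluster = as.integer(clust$labels[aset]),
    pc1_score = as.numeric(pca$pc1_scores[aset]),
    participation = as.numeric(pc),
    global_fc_strength = as.numeric(gstr),
    flag_high_inter = extreme$flag_high[match(aset, extreme$area)],
    flag_low_inter = extreme$flag_low[match(aset, extreme$area)])

  cfg_public <- config[c("simulate", "keep_fraction", "n_components",
                         "alpha", "k_per_modality", "n_perm", "fdr_q",
                         "seed")]
  report <- structure(list(
    area_table = area_table,
    contrasts = contrasts,
    correlations = list(
      inter_vs_histological = cor_histo,
      inter_vs_cross_task_diversity = cor_div,
      inter_vs_diversity_partial_tsnr = cor_div_tsnr,
      intra_vs_area_size = cor_size),
    pca = list(variance_explained = pca$variance_explained,
               ordering = pca$ordering),
    clustering = list(chosen_k = clust$chosen_k, criterion = clust$criterion),
    summary = list(
      mean_inter = mean(inter$per_area),
      mean_intra = mean(intra$per_vertex, na.rm = TRUE),
      pc1_variance_pct = 100 * pca$variance_explained[1]),
    provenance = list(config = cfg_public, config_hash = config_hash(cfg_public),
                      seed = config$seed,
                      package_version = as.character(utils::packageVersion("gradmosaic"))),
    gradients = gradients, profiles = profiles, labeling = labeling,
    dataset = dataset, gradient_sets = gradsets),
    class = "gm_report")
  if (!is.null(config$out_dir)) write_outputs(report, config$out_dir)
  report
}

## Aggregate a vertex-level symmetric matrix to area-by-area block means
## (off-diagonal blocks: mean over vertex pairs; diagonal zeroed).
area_block_means <- function(W, labeling, area_ids) {
  keep <- !is.na(labeling$label)
  lbl <- labeling$label[keep]
  ind <- stats::model.matrix(~ factor(lbl) - 1)
  cnt <- colSums(ind)
  B <- t(ind) %*% W[keep, keep] %*% ind / outer(cnt, cnt)
  B <- as.matrix(B)
  present <- labeling$area_ids[sort(unique(lbl))]
  dimnames(B) <- list(present, present)
  B <- B[area_ids, area_ids]
  diag(B) <- 0
  B
}

#' @export
print.gm_report <- function(x, ...) {
  cat(sprintf("gm_report: %d areas | mean inter %.4f | mean intra %.4f | PC1 %.1f%% | k = %d\n",
              nrow(x$area_table), x$summary$mean_inter, x$summary$mean_intra,
              x$summary$pc1_variance_pct, x$clustering$chosen_k))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the per-area table, the contrast table, the inter-areal distance
#' matrix and a machine-readable `report.json` (correlations, PCA variance
#' fractions, clustering criterion, provenance). Rewriting with the same
#' config and seed reproduces identical bytes.
#'
#' @param report a `gm_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_area_table(report$area_table, file.path(dir, "area_table.tsv"))
  write_area_table(report$contrasts, file.path(dir, "contrasts.tsv"))
  json <- list(
    correlations = lapply(report$correlations, function(z) {
      z[c("rho", "p_spin", "n_perm_used")]
    }),
    pca_variance_explained = report$pca$variance_explained,
    clustering = report$clustering,
    summary = report$summary,
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Robustness sweep over sparsity and gradient count
#'
#' Recomputes the embedding and dissimilarity stage for every combination of
#' `keep_fractions` and `k_values` on one generated dataset, and reports the
#' pairwise Pearson correlations of the resulting per-area inter- and
#' intra-areal dissimilarity maps across settings.
#'
#' @param config a `gm_config` (its dataset settings and seed are reused).
#' @param keep_fractions numeric vector of row sparsities in (0, 1].
#' @param k_values integer vector of per-modality gradient counts in 3..7.
#' @return list with `settings` (data.frame), `inter_correlation` and
#'   `intra_correlation` (setting-by-setting Pearson matrices).
#' @export
robustness_sweep <- function(config, keep_fractions = c(0.1),
                             k_values = c(5)) {
  stopifnot(length(keep_fractions) >= 1, length(k_values) >= 1,
            all(keep_fractions > 0), all(keep_fractions <= 1),
            all(k_values >= 3), all(k_values <= 7))
  sim <- config$simulate
  mesh <- make_sphere_mesh(sim$subdivision_level, hemispheres = sim$hemispheres)
  spec <- planted_gradient_spec(n_axes = sim$n_axes,
                                correlation_length = sim$correlation_length,
                                snr = sim$snr,
                                seed = child_seed(config$seed, "simulate"))
  dataset <- make_multimodal_dataset(mesh, spec, n_depths = sim$n_depths,
                                     n_timepoints = sim$n_timepoints,
                                     n_tasks = sim$n_tasks,
                                     n_areas = sim$n_areas,
                                     softness = sim$softness,
                                     flex_amplitude = sim$flex_amplitude)
  labeling <- assign_area_labels(dataset$atlas)
  conns <- list(MPC = build_mpc(dataset$profiles),
                SC = connectome(dataset$sc, "SC"),
                FC = build_fc(dataset$timeseries$rest))

  settings <- expand.grid(keep_fraction = keep_fractions, k = k_values,
                          KEEP.OUT.ATTRS = FALSE)
  inter_maps <- list(); intra_maps <- list()
  for (i in seq_len(nrow(settings))) {
    f <- settings$keep_fraction[i]; k <- settings$k[i]
    gradsets <- lapply(conns, function(cn) {
      diffusion_map(normalized_angle_affinity(sparsify_rows(cn, f)),
                    n_components = config$n_components, alpha = config$alpha)
    })
    gr <- normalize_and_stack(gradsets, k)
    pr <- compute_area_profiles(gr, labeling)
    inter_maps[[i]] <- inter_areal_dissimilarity(pr)$per_area
    intra_maps[[i]] <- intra_areal_dissimilarity(gr, labeling)$per_area_mean
  }
  nm <- sprintf("kf%.2f_k%d", settings$keep_fraction, settings$k)
  inter_cor <- cor(do.call(cbind, inter_maps))
  intra_cor <- cor(do.call(cbind, intra_maps))
  dimnames(inter_cor) <- dimnames(intra_cor) <- list(nm, nm)
  list(settings = settings, inter_correlation = inter_cor,
       intra_correlation = intra_cor)
}
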