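# End-to-end orchestration on synthetic data: cohorts -> ALFF -> group test
# -> association per dataset -> partition -> enrichment suite ->
# cross-disorder overlap.

alff_for_cohort <- function(cohort, cfg) {
  acfg <- alff_config(tr = cfg$tr, band_low = cfg$band_low,
                      band_high = cfg$band_high,
                      drop_initial_volumes = cfg$drop_initial_volumes)
  lapply(cohort$subjects, function(s) {
    r <- regress_nuisance(s)
    compute_alff(r, acfg)
  })
}

dataset_tmap <- function(cohort, cfg, seed) {
  maps <- alff_for_cohort(cohort, cfg)
  permutation_group_test(maps, cohort$covariates$group,
                         cohort$covariates[, c("age", "sex", "mean_fd")],
                         B = cfg$B_group, seed = seed, alpha = cfg$alpha)
}

#' Run the full synthetic-data pipeline
#'
#' Generates planted truth and all inputs, then executes the stages in
#' order: two BOLD cohorts (dataset 1 with the full planted effect,
#' dataset 2 with a weaker one, mirroring a clinically heterogeneous
#' replication sample) -> per-subject ALFF -> voxel-wise Freedman-Lane
#' permutation group test per dataset -> threshold overlap and surrogate
#' spatial correlation of the two t-maps -> expression preprocessing ->
#' sphere sampling and gene-map association per dataset -> the
#' sensitive/insensitive partition -> DEG / category-score / temporal /
#' cell-type enrichment -> optional third (cross-disorder) association and
#' overlap proportions. Per-stage artifacts are written as TSV/GMT/JSON when
#' `cfg$output_dir` is set; a machine-readable summary is always returned.
#'
#' @param cfg a [run_config()] (or path to a JSON config).
#' @return list of class `pipeline_run`: `summary` plus stage objects.
#' @export
run_pipeline <- function(cfg = demo_run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  seed <- cfg$seed
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))

  truth <- make_default_truth(
    n_genes = cfg$n_genes, grid_shape = cfg$grid_shape,
    voxel_size = cfg$voxel_size, smoothness = cfg$smoothness,
    n_signal = cfg$n_signal, signal_rho = cfg$signal_rho,
    n_stages = cfg$n_stages, seed = derive_seed(seed, 1))
  spec <- cohort_spec(cfg$n_per_group, cfg$n_volumes, cfg$tr,
                      cfg$grid_shape, cfg$voxel_size)

  message("stage: cohorts + ALFF + group tests")
  cohort1 <- gen_cohort(spec, truth$effect_map, cfg$effect_scale_1,
                        seed = derive_seed(seed, 2))
  cohort2 <- gen_cohort(spec, truth$effect_map, cfg$effect_scale_2,
                        seed = derive_seed(seed, 3))
  tmap1 <- dataset_tmap(cohort1, cfg, derive_seed(seed, 4))
  tmap2 <- dataset_tmap(cohort2, cfg, derive_seed(seed, 5))
  overlap <- threshold_overlap(tmap1, tmap2)
  spatial <- map_spatial_correlation(
    tmap1, tmap2, n_surrogates = max(20L, cfg$B_assoc %/% 10L),
    seed = derive_seed(seed, 6), subsample_cap = 2000)

  message("stage: expression")
  region_coords <- gen_sample_coords(cfg$n_regions, cfg$grid_shape,
                                     cfg$voxel_size,
                                     seed = derive_seed(seed, 7))
  rownames(region_coords) <- sprintf("R%02d", seq_len(cfg$n_regions))
  # samples jittered around region centroids (within the 2 mm assignment
  # radius), plus 5% stragglers that the assignment step must drop
  sample_coords <- withr::with_seed(derive_seed(seed, 8), {
    ctr <- region_coords[sample.int(cfg$n_regions, cfg$n_samples,
                                    replace = TRUE), , drop = FALSE]
    jit <- matrix(runif(cfg$n_samples * 3, -1, 1), ncol = 3)
    jit <- jit / pmax(1, sqrt(rowSums(jit^2))) * runif(cfg$n_samples, 0, 1.9)
    far <- sample.int(cfg$n_samples, max(1L, cfg$n_samples %/% 20L))
    jit[far, 1] <- jit[far, 1] + 8
    xy <- ctr + jit
    lim <- (cfg$grid_shape - 1) * cfg$voxel_size
    for (k in 1:3) xy[, k] <- pmin(pmax(xy[, k], 0), lim[k])
    xy
  })
  raw_expr <- gen_expression(cfg$n_genes, sample_coords, cfg$n_donors, truth,
                             seed = derive_seed(seed, 9))
  expr <- process_expression(raw_expr, region_coords)

  message("stage: association + partition")
  idx <- match(expr$samples$sample_id, raw_expr$samples$sample_id)
  coords_kept <- as.matrix(raw_expr$samples[idx, c("x", "y", "z")])
  pheno1 <- sample_phenotype(tmap1, coords_kept, radius = cfg$radius)
  pheno2 <- sample_phenotype(tmap2, coords_kept, radius = cfg$radius)
  assoc1 <- gene_map_association(expr, pheno1, B = cfg$B_assoc,
                                 seed = derive_seed(seed, 10),
                                 ds_quantile = cfg$ds_quantile,
                                 alpha = cfg$alpha, return_ensemble = TRUE)
  assoc2 <- gene_map_association(expr, pheno2, B = cfg$B_assoc,
                                 seed = derive_seed(seed, 11),
                                 ds_quantile = cfg$ds_quantile,
                                 alpha = cfg$alpha)
  partition <- partition_genes(assoc1, assoc2)

  message("stage: enrichment suite")
  ann <- gen_annotations(cfg$n_categories, cfg$category_size_range,
                         cfg$n_stages, truth, genes,
                         seed = derive_seed(seed, 12))
  sens <- partition$sensitive
  insens <- partition$insensitive
  deg_enrich <- list()
  for (cl in c("sensitive", "insensitive")) for (dl in c("up", "down")) {
    deg_enrich[[paste(cl, dl, sep = "_")]] <-
      fisher_enrichment(partition[[cl]], ann$deg[[dl]], genes,
                        family_size = 4)
  }
  cat_scores <- category_score_test(
    ann$categories, setNames(assoc1$r, assoc1$gene),
    attr(assoc1, "ensemble_absr"))
  n_psi_null <- max(200L, cfg$E_ensemble)
  psi <- compute_psi(ann$stage_matrix, n_null = n_psi_null,
                     seed = derive_seed(seed, 13))
  stage_sens <- if (length(sens))
    stage_enrichment(sens, psi, n_gene_sets = 2) else NULL
  stage_insens <- if (length(insens))
    stage_enrichment(insens, psi, n_gene_sets = 2) else NULL
  ct_sens <- if (length(sens))
    celltype_enrichment(sens, ann$markers, genes, n_gene_sets = 2) else NULL
  ct_insens <- if (length(insens))
    celltype_enrichment(insens, ann$markers, genes, n_gene_sets = 2) else NULL

  cross <- NULL
  if (isTRUE(cfg$with_cross_disorder)) {
    message("stage: cross-disorder")
    cohort3 <- gen_cohort(spec, truth$effect_map, cfg$effect_scale_2,
                          seed = derive_seed(seed, 14))
    tmap3 <- dataset_tmap(cohort3, cfg, derive_seed(seed, 15))
    pheno3 <- sample_phenotype(tmap3, coords_kept, radius = cfg$radius)
    assoc3 <- gene_map_association(expr, pheno3, B = cfg$B_assoc,
                                   seed = derive_seed(seed, 16),
                                   ds_quantile = cfg$ds_quantile,
                                   alpha = cfg$alpha)
    cross <- cross_disorder_overlap(partition, assoc3)
  }

  summary <- list(
    seed = seed,
    n_mask_voxels = sum(tmap1$mask),
    n_fwe_voxels = c(dataset1 = sum(tmap1$p_fwe[tmap1$mask] < 0.05),
                     dataset2 = sum(tmap2$p_fwe[tmap2$mask] < 0.05)),
    overlap = overlap,
    spatial_r = spatial$r, spatial_p = spatial$p_perm,
    n_genes_analyzed = nrow(assoc1),
    n_significant = c(dataset1 = sum(assoc1$significant),
                      dataset2 = sum(assoc2$significant)),
    n_sensitive = length(sens), n_insensitive = length(insens),
    signal_recovered = length(intersect(truth$signal_genes,
                                        assoc1$gene[assoc1$significant])),
    n_signal_planted = length(truth$signal_genes),
    top_category = cat_scores$category[which.min(cat_scores$p_perm)],
    cross_disorder = cross
  )

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- cfg$output_dir
    write.table(cohort1$covariates, file.path(od, "covariates_dataset1.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(assoc1, file.path(od, "gene_assoc_dataset1.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(assoc2, file.path(od, "gene_assoc_dataset2.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(list(sensitive = sens, insensitive = insens),
              file.path(od, "partition.gmt"))
    write.table(cat_scores, file.path(od, "category_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sm <- summary
    sm$overlap <- NULL; sm$cross_disorder <- NULL
    jsonlite::write_json(sm, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write.table(overlap, file.path(od, "threshold_overlap.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  structure(list(summary = summary, truth = truth, tmap1 = tmap1,
                 tmap2 = tmap2, expr = expr, assoc1 = assoc1,
                 assoc2 = assoc2, partition = partition,
                 deg_enrichment = deg_enrich, category_scores = cat_scores,
                 psi = psi, stage_enrichment = list(sensitive = stage_sens,
                                                    insensitive = stage_insens),
                 celltype_enrichment = list(sensitive = ct_sens,
                                            insensitive = ct_insens),
                 cross_disorder = cross, config = cfg),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_run>\n")
  cat(sprintf("  mask voxels: %d; FWE voxels: %d / %d (dataset 1 / 2)\n",
              s$n_mask_voxels, s$n_fwe_voxels[1], s$n_fwe_voxels[2]))
  cat(sprintf("  t-map spatial r = %.3f (p = %.4f)\n", s$spatial_r,
              s$spatial_p))
  cat(sprintf("  genes: %d analyzed, %d / %d significant, %d sensitive, %d insensitive\n",
              s$n_genes_analyzed, s$n_significant[1], s$n_significant[2],
              s$n_sensitive, s$n_insensitive))
  cat(sprintf("  planted signal recovered: %d / %d; top category: %s\n",
              s$signal_recovered, s$n_signal_planted, s$top_category))
  invisible(x)
}
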