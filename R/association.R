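# Transcriptome-neuroimaging association: sphere-sampled t-values, gene-wise
# spatial correlation with a max-|r| surrogate-permutation FWE null, DS
# filtering, and the cross-dataset sensitive/insensitive partition.

#' Sample a t-map at expression sample locations
#'
#' For each sample coordinate, averages the t values of in-mask voxels whose
#' centers lie within `radius` mm (inclusive) of the coordinate. Samples
#' with no contributing voxel are dropped with a warning.
#'
#' @param tmap a [tstat_map()].
#' @param sample_coords numeric matrix n x 3 of mm coordinates.
#' @param radius sphere radius in mm (> 0); default 6.
#' @return data frame of class `sampled_phenotype`: `sample` (row index
#'   into `sample_coords`), `t` (mean in-sphere t), `n_voxels`; the
#'   coordinates of retained samples are kept in attribute `coords`.
#' @export
sample_phenotype <- function(tmap, sample_coords, radius = 6) {
  stopifnot(inherits(tmap, "tstat_map"))
  check_scalar(radius, "radius", lower = 1e-12)
  sample_coords <- as.matrix(sample_coords)
  m <- as.vector(tmap$mask)
  vox <- voxel_coords(dim(tmap$mask), tmap$voxel_size)[m, , drop = FALSE]
  tv <- tmap$t[tmap$mask]
  n <- nrow(sample_coords)
  tout <- numeric(n); nv <- integer(n)
  r2 <- radius^2
  for (i in seq_len(n)) {
    d2 <- (vox[, 1] - sample_coords[i, 1])^2 +
      (vox[, 2] - sample_coords[i, 2])^2 +
      (vox[, 3] - sample_coords[i, 3])^2
    sel <- d2 <= r2 + 1e-9
    nv[i] <- sum(sel)
    tout[i] <- if (nv[i]) mean(tv[sel]) else NA_real_
  }
  keep <- nv >= 1L
  if (!all(keep))
    warnf("dropping %d sample(s) with no in-mask voxel within %g mm",
          sum(!keep), radius)
  out <- data.frame(sample = which(keep), t = tout[keep],
                    n_voxels = nv[keep])
  attr(out, "coords") <- sample_coords[keep, , drop = FALSE]
  attr(out, "radius") <- radius
  class(out) <- c("sampled_phenotype", "data.frame")
  out
}

#' Gene-wise spatial association with max-|r| FWE permutation
#'
#' Observed statistic: Pearson correlation of each gene's expression with
#' the sphere-sampled t-vector across samples. Null: `B` variogram-matched
#' surrogate t-vectors are generated on the sample coordinates; for each,
#' all gene correlations are recomputed and the maximum |r*| over genes is
#' recorded. `p_fwe = (1 + #{max|r*| >= |r|}) / (B + 1)`. A gene is
#' significant iff `p_fwe < alpha` and its DS score is in the top
#' `ds_quantile` fraction of the analyzed gene universe (threshold =
#' empirical `1 - ds_quantile` quantile; the DS filter is
#' phenotype-independent so it is applied to observed results only).
#' Zero-variance genes get r = 0, p = 1 and are flagged.
#'
#' @param expr an [expression_dataset()] (DS required unless
#'   `ds_quantile = 0`... use 0 to disable the filter).
#' @param pheno a [sample_phenotype()] result aligned with `expr` samples
#'   (the phenotype's retained samples index the expression columns).
#' @param B number of surrogate permutations.
#' @param seed integer RNG seed.
#' @param ds_quantile fraction of top-DS genes eligible (default 0.5, the
#'   top half); 0 disables the DS filter.
#' @param alpha FWE significance level.
#' @param bonferroni additionally Bonferroni-correct the permutation FWE
#'   p-values by the number of analyzed genes before thresholding (off by
#'   default: the max-statistic construction is already family-wise, and
#'   stacking both corrections double-counts).
#' @param return_ensemble keep the genes x B matrix of |r*| as attribute
#'   `ensemble_absr` (used by ensemble-null category scoring).
#' @param ... passed to [make_surrogates()].
#' @return data frame of class `gene_assoc`: gene, r, p_fwe, sign, ds,
#'   significant; attributes `n_perm`, `ds_threshold`, optionally
#'   `ensemble_absr`.
#' @export
gene_map_association <- function(expr, pheno, B = 1000, seed = 1,
                                 ds_quantile = 0.5, alpha = 0.05,
                                 bonferroni = FALSE, return_ensemble = FALSE,
                                 ...) {
  stopifnot(inherits(expr, "expression_dataset"))
  E <- expr$expr[, pheno$sample, drop = FALSE]
  tvec <- pheno$t
  if (length(tvec) < 10) stopf("need at least 10 samples")
  if (var(tvec) == 0) stopf("zero-variance phenotype")
  gene_sd <- apply(E, 1, sd)
  valid <- gene_sd > 0
  if (any(!valid)) warnf("%d zero-variance gene(s): r = 0, p = 1", sum(!valid))
  r <- rep(0, nrow(E))
  r[valid] <- drop(cor(t(E[valid, , drop = FALSE]), tvec))
  coords <- attr(pheno, "coords")
  sur <- make_surrogates(tvec, coords, B, seed = seed, ...)
  Rstar <- abs(cor(t(E[valid, , drop = FALSE]), sur$values))  # genes x B
  max_star <- apply(Rstar, 2, max)
  absr <- abs(r)
  p_fwe <- (1 + vapply(absr, function(a) sum(max_star >= a), numeric(1))) /
    (B + 1)
  p_fwe[!valid] <- 1
  ds <- expr$ds
  if (ds_quantile > 0) {
    if (is.null(ds)) stopf("DS scores required (or set ds_quantile = 0)")
    ds <- ds[rownames(E)]
    ds_thr <- quantile(ds, 1 - ds_quantile, names = FALSE)
    ds_pass <- ds >= ds_thr
  } else {
    if (is.null(ds)) ds <- rep(NA_real_, nrow(E))
    ds_thr <- -Inf
    ds_pass <- TRUE
  }
  p_thresh <- if (bonferroni) pmin(1, p_fwe * nrow(E)) else p_fwe
  out <- data.frame(gene = rownames(E), r = r, p_fwe = p_fwe,
                    sign = ifelse(r >= 0, "+", "-"), ds = unname(ds),
                    significant = p_thresh < alpha & ds_pass,
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- B
  attr(out, "ds_threshold") <- ds_thr
  attr(out, "alpha") <- alpha
  if (return_ensemble) {
    ens <- matrix(0, nrow(E), B, dimnames = list(rownames(E), NULL))
    ens[valid, ] <- Rstar
    attr(out, "ensemble_absr") <- ens
  }
  class(out) <- c("gene_assoc", "data.frame")
  out
}

#' Partition genes into clinically sensitive / insensitive sets
#'
#' Insensitive: significant in both association tables with the same effect
#' sign (replicating). Sensitive: significant in table 1 but not in the
#' insensitive set — including genes significant in both with opposite
#' signs, which do not replicate directionally.
#'
#' @param assoc1,assoc2 `gene_assoc` tables over the same gene universe.
#' @return list of class `gene_partition`: `sensitive`, `insensitive`.
#' @export
partition_genes <- function(assoc1, assoc2) {
  common <- intersect(assoc1$gene, assoc2$gene)
  if (!length(common)) stopf("association tables share no genes")
  a1 <- assoc1[match(common, assoc1$gene), ]
  a2 <- assoc2[match(common, assoc2$gene), ]
  both <- a1$significant & a2$significant & a1$sign == a2$sign
  insensitive <- common[both]
  sensitive <- setdiff(common[a1$significant], insensitive)
  structure(list(sensitive = sensitive, insensitive = insensitive),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("<gene_partition> %d sensitive, %d insensitive genes\n",
              length(x$sensitive), length(x$insensitive)))
  invisible(x)
}

#' Overlap of partition classes with another disorder's associations
#'
#' For each class, the fraction of its genes that are significant in the
#' other disorder's association table (with counts). Empty classes report
#' `NA`.
#'
#' @param partition a [partition_genes()] result.
#' @param other a `gene_assoc` table on a shared gene universe.
#' @return data frame: class, n_class, n_overlap, proportion.
#' @export
cross_disorder_overlap <- function(partition, other) {
  stopifnot(inherits(partition, "gene_partition"))
  sig <- other$gene[other$significant]
  if (!length(intersect(unlist(partition), other$gene)) &&
      length(unlist(partition)))
    stopf("partition and association table share no genes")
  rows <- lapply(c("sensitive", "insensitive"), function(cl) {
    g <- partition[[cl]]
    n <- length(g)
    ov <- length(intersect(g, sig))
    data.frame(class = cl, n_class = n, n_overlap = ov,
               proportion = if (n) ov / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
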