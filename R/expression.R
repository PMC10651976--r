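# Donor-level microarray expression preprocessing: intensity filter, RNA-seq
# guided probe selection, sample-to-region assignment, scaled robust sigmoid
# normalization, differential stability.

#' Intensity-based probe filtering
#'
#' A probe is retained iff it is called above background in at least
#' `min_fraction` of samples (>= convention at the boundary).
#'
#' @param pacall logical matrix probes x samples of above-background calls.
#' @param min_fraction minimum fraction of above-background samples.
#' @return character vector of retained probe ids.
#' @export
intensity_filter <- function(pacall, min_fraction = 0.5) {
  if (is.null(rownames(pacall))) stopf("`pacall` needs probe rownames")
  check_scalar(min_fraction, "min_fraction", lower = 0, upper = 1)
  frac <- rowMeans(pacall)
  keep <- rownames(pacall)[frac >= min_fraction]
  if (!length(keep)) warnf("intensity filter retained no probes")
  keep
}

#' RNA-seq-guided probe selection
#'
#' Per gene, each candidate probe's expression profile is correlated with
#' the gene's RNA-seq profile over the shared samples; probes with
#' correlation <= `r_thresh` are dropped (strictly greater survives), and
#' among survivors the probe with the highest correlation represents the
#' gene. Genes with no surviving probe, or absent from the RNA-seq
#' reference, are dropped (the latter with a warning).
#'
#' @param probes numeric matrix probes x samples (probe rownames).
#' @param probe_info data frame with columns `probe_id`, `gene`.
#' @param rnaseq numeric matrix genes x samples (sample names shared with
#'   `probes`).
#' @param r_thresh correlation threshold (probes must exceed it strictly).
#' @param method correlation flavor, `"pearson"` (default) or `"spearman"`.
#' @return genes x samples matrix (all `probes` columns), with attribute
#'   `selected_probe` (gene -> probe id).
#' @export
select_probes <- function(probes, probe_info, rnaseq, r_thresh = 0.2,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(colnames(probes), colnames(rnaseq))
  if (length(shared) < 3) stopf("need >= 3 shared samples with the RNA-seq reference")
  genes <- unique(probe_info$gene)
  missing <- setdiff(genes, rownames(rnaseq))
  if (length(missing)) {
    warnf("%d gene(s) absent from the RNA-seq reference; dropped",
          length(missing))
    genes <- setdiff(genes, missing)
  }
  sel <- character(0)
  keep_genes <- character(0)
  for (g in genes) {
    pids <- probe_info$probe_id[probe_info$gene == g]
    pids <- intersect(pids, rownames(probes))
    if (!length(pids)) next
    rr <- vapply(pids, function(p)
      suppressWarnings(cor(probes[p, shared], rnaseq[g, shared],
                           method = method)), numeric(1))
    rr[is.na(rr)] <- -Inf
    ok <- rr > r_thresh
    if (!any(ok)) next
    sel <- c(sel, pids[ok][which.max(rr[ok])])
    keep_genes <- c(keep_genes, g)
  }
  out <- probes[sel, , drop = FALSE]
  rownames(out) <- keep_genes
  attr(out, "selected_probe") <- setNames(sel, keep_genes)
  out
}

#' Assign samples to region centroids within a distance threshold
#'
#' Each sample is assigned to its nearest region centroid iff the Euclidean
#' distance is at most `max_dist` mm; samples beyond the threshold are left
#' unassigned (`NA`).
#'
#' @param sample_coords numeric matrix n x 3 (mm).
#' @param region_coords numeric matrix r x 3 with region rownames.
#' @param max_dist assignment radius in mm.
#' @return character vector of region labels (NA for unassigned), one per
#'   sample.
#' @export
assign_samples <- function(sample_coords, region_coords, max_dist = 2) {
  sample_coords <- as.matrix(sample_coords)
  region_coords <- as.matrix(region_coords)
  if (is.null(rownames(region_coords)))
    stopf("`region_coords` needs region rownames")
  check_scalar(max_dist, "max_dist", lower = 0)
  out <- rep(NA_character_, nrow(sample_coords))
  for (i in seq_len(nrow(sample_coords))) {
    d2 <- colSums((t(region_coords) - sample_coords[i, ])^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) <= max_dist) out[i] <- rownames(region_coords)[j]
  }
  out
}

srs_vector <- function(x) {
  med <- median(x)
  iqr <- IQR(x)
  if (iqr == 0) {
    warnf("IQR = 0; falling back to rank-based sigmoid")
    x <- rank(x)
    med <- median(x)
    iqr <- IQR(x)
    if (iqr == 0) return(rep(0.5, length(x)))  # all tied
  }
  s <- 1 / (1 + exp(-(x - med) / (iqr / 1.35)))
  rng <- range(s)
  if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1]) else rep(0.5, length(s))
}

#' Scaled robust sigmoid normalization
#'
#' Per gene within each donor: `s = 1 / (1 + exp(-(x - median) /
#' (IQR / 1.35)))` followed by min-max rescaling to [0, 1]. The IQR / 1.35
#' scaling makes the denominator a robust SD estimate; the sigmoid bounds
#' outlier influence; donor-wise application removes between-donor offset
#' and scale differences before profiles are concatenated across donors.
#'
#' @param mat numeric matrix genes x samples.
#' @param donor character/factor of donor labels, one per column; `NULL`
#'   treats all samples as one donor.
#' @return normalized matrix in [0, 1], same dimnames.
#' @export
srs_normalize <- function(mat, donor = NULL) {
  if (is.null(donor)) donor <- rep("d1", ncol(mat))
  if (length(donor) != ncol(mat)) stopf("one donor label per column required")
  out <- mat
  for (d in unique(donor)) {
    sel <- donor == d
    if (sum(sel) < 3) stopf("donor '%s' has fewer than 3 samples", d)
    out[, sel] <- t(apply(mat[, sel, drop = FALSE], 1, srs_vector))
  }
  out
}

#' Differential stability across donors
#'
#' For each gene, DS is the mean over donor pairs of the Spearman
#' correlation between the gene's regional expression profiles in the two
#' donors, computed over regions present (non-NA) in both.
#'
#' @param donor_region_mats named list of genes x regions matrices, one per
#'   donor (same gene rownames; region columns may differ / contain NA).
#' @param min_common_regions minimum shared regions for a pair to count.
#' @return named numeric vector of DS scores in [-1, 1].
#' @export
differential_stability <- function(donor_region_mats,
                                   min_common_regions = 3) {
  if (length(donor_region_mats) < 2) stopf("need at least 2 donors")
  genes <- rownames(donor_region_mats[[1]])
  for (m in donor_region_mats)
    if (!identical(rownames(m), genes)) stopf("gene rownames must agree")
  nd <- length(donor_region_mats)
  acc <- matrix(0, length(genes), 0)
  for (a in seq_len(nd - 1)) for (b in seq.int(a + 1, nd)) {
    ma <- donor_region_mats[[a]]; mb <- donor_region_mats[[b]]
    common <- intersect(colnames(ma), colnames(mb))
    ok <- common[colSums(is.na(ma[, common, drop = FALSE])) == 0 &
                   colSums(is.na(mb[, common, drop = FALSE])) == 0]
    if (length(ok) < min_common_regions)
      stopf("donor pair %d/%d shares fewer than %d regions", a, b,
            min_common_regions)
    ra <- t(apply(ma[, ok, drop = FALSE], 1, rank))
    rb <- t(apply(mb[, ok, drop = FALSE], 1, rank))
    rho <- vapply(seq_along(genes), function(i) {
      if (sd(ra[i, ]) == 0 || sd(rb[i, ]) == 0) return(0)
      cor(ra[i, ], rb[i, ])
    }, numeric(1))
    acc <- cbind(acc, rho)
  }
  setNames(rowMeans(acc), genes)
}

#' Run the full expression preprocessing chain
#'
#' Intensity filter -> probe selection -> sample/region assignment ->
#' scaled robust sigmoid normalization (per donor) -> differential
#' stability on region-averaged donor profiles. Mirrors the standard
#' donor-atlas processing order.
#'
#' @param raw output of [gen_expression()] (or equivalently structured
#'   list).
#' @param region_coords region centroid matrix for [assign_samples()];
#'   `NULL` skips assignment (all samples kept, regions from metadata).
#' @param max_dist assignment radius, mm.
#' @param min_fraction intensity-filter threshold.
#' @param r_thresh probe-selection threshold.
#' @return an [expression_dataset()] restricted to assigned samples, with DS
#'   scores.
#' @export
process_expression <- function(raw, region_coords = NULL, max_dist = 2,
                               min_fraction = 0.5, r_thresh = 0.2) {
  keep <- intensity_filter(raw$pacall, min_fraction)
  probes <- raw$probes[keep, , drop = FALSE]
  pinfo <- raw$probe_info[raw$probe_info$probe_id %in% keep, , drop = FALSE]
  expr <- select_probes(probes, pinfo, raw$rnaseq, r_thresh)
  selected <- attr(expr, "selected_probe")
  samples <- raw$samples
  if (!is.null(region_coords)) {
    samples$region <- assign_samples(samples[, c("x", "y", "z")],
                                     region_coords, max_dist)
    sel <- !is.na(samples$region)
    if (!all(sel))
      message(sprintf("dropping %d/%d samples beyond %g mm of any region",
                      sum(!sel), length(sel), max_dist))
    samples <- samples[sel, , drop = FALSE]
    expr <- expr[, samples$sample_id, drop = FALSE]
  }
  norm <- srs_normalize(expr, samples$donor)
  attr(norm, "selected_probe") <- selected
  donors <- unique(samples$donor)
  ds <- NULL
  if (length(donors) >= 2 && !all(is.na(samples$region))) {
    mats <- lapply(donors, function(d) {
      sel <- samples$donor == d
      sub <- norm[, sel, drop = FALSE]
      regs <- samples$region[sel]
      m <- vapply(unique(regs), function(r)
        rowMeans(sub[, regs == r, drop = FALSE]), numeric(nrow(sub)))
      matrix(m, nrow = nrow(sub),
             dimnames = list(rownames(sub), unique(regs)))
    })
    names(mats) <- donors
    ds <- differential_stability(mats)
  }
  expression_dataset(norm, samples, ds)
}
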