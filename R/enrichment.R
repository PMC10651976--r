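# Gene-set annotation statistics: Fisher/hypergeometric over-representation,
# ensemble-null category scores, specificity-index (pSI) temporal
# enrichment, cell-type enrichment.

#' Fisher over-representation test
#'
#' One-sided hypergeometric upper tail on the 2 x 2 query x target table
#' over a background universe. The reported odds ratio is the sample OR
#' `ad / bc` (0 when the overlap is empty; `Inf` when `bc = 0` with a
#' positive overlap), matching the convention of reporting OR = 0 for zero
#' overlap. Bonferroni correction by `family_size`.
#'
#' @param query,target,background character vectors; `query` and `target`
#'   must be subsets of `background`.
#' @param family_size number of tests in the correction family.
#' @return list of class `enrichment_result`: n_query, n_target, overlap,
#'   n_background, odds_ratio, p, p_corrected, family_size.
#' @export
fisher_enrichment <- function(query, target, background, family_size = 1) {
  query <- unique(query); target <- unique(target)
  background <- unique(background)
  if (!all(query %in% background)) stopf("query must be a subset of background")
  if (!all(target %in% background)) stopf("target must be a subset of background")
  check_scalar(family_size, "family_size", lower = 1, integerish = TRUE)
  n <- length(background)
  a <- length(intersect(query, target))
  b <- length(query) - a
  cc <- length(target) - a
  d <- n - a - b - cc
  p <- phyper(a - 1, length(target), n - length(target), length(query),
              lower.tail = FALSE)
  or <- if (a == 0) 0 else if (b == 0 || cc == 0) Inf else a * d / (b * cc)
  structure(list(n_query = length(query), n_target = length(target),
                 overlap = a, n_background = n, odds_ratio = or, p = p,
                 p_corrected = min(1, p * family_size),
                 family_size = family_size),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment> %d/%d of query in target (target %d, background %d), OR = %.3g, p = %.3g (corrected %.3g)\n",
    x$overlap, x$n_query, x$n_target, x$n_background, x$odds_ratio, x$p,
    x$p_corrected))
  invisible(x)
}

#' Category scores against an ensemble null
#'
#' A category's score is the mean of |r| over its measured member genes,
#' where r comes from the gene-map association. The null distribution is
#' built by the same scoring applied to each column of an ensemble |r|
#' matrix computed from randomized (autocorrelation-preserving) phenotypes:
#' `p_perm = (1 + #{null >= score}) / (E + 1)`, Bonferroni over the number
#' of scored categories. This guards against the false positives that
#' within-category co-expression plus spatial autocorrelation produce under
#' gene-sampling nulls.
#'
#' @param categories named list: category id -> gene ids.
#' @param r_obs named numeric vector of observed correlations (signed or
#'   absolute; absolute values are taken).
#' @param ensemble_absr genes x E matrix of |r| under randomized phenotypes
#'   (same gene universe as `r_obs`), e.g. the `ensemble_absr` attribute of
#'   [gene_map_association()].
#' @return data frame: category, n_genes, score, p_perm, p_corrected.
#' @export
category_score_test <- function(categories, r_obs, ensemble_absr) {
  E <- ncol(ensemble_absr)
  if (E < 20) stopf("need an ensemble of at least 20 randomized phenotypes")
  absr <- abs(r_obs)
  rows <- list()
  for (id in names(categories)) {
    mem <- intersect(categories[[id]], names(absr))
    mem <- intersect(mem, rownames(ensemble_absr))
    if (!length(mem)) {
      warnf("category '%s' has no measured genes; skipped", id)
      next
    }
    score <- mean(absr[mem])
    null_scores <- colMeans(ensemble_absr[mem, , drop = FALSE])
    p <- (1 + sum(null_scores >= score)) / (E + 1)
    rows[[id]] <- data.frame(category = id, n_genes = length(mem),
                             score = score, p_perm = p,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_corrected <- pmin(1, out$p_perm * nrow(out))
  out
}

#' Specificity index p-values (pSI) per gene and stage
#'
#' For gene g and stage s, the specificity index SI is the mean, over the
#' other stages j, of g's rank (1 = largest) of fold-change FC_g(s vs j)
#' among all genes. The null permutes gene identities within each
#' comparison `n_null` times; `pSI = (1 + #{SI_null <= SI}) / (n_null + 1)`,
#' so small pSI marks genes specifically elevated in that stage.
#' Non-positive expression is shifted by `min + 1e-6 * max` before the
#' ratio fold-change, with a message.
#'
#' @param stage_mat numeric matrix genes x stages (>= 20 genes, >= 2
#'   stages).
#' @param n_null permutation count.
#' @param seed integer RNG seed.
#' @param threshold specificity threshold stored for downstream use.
#' @return genes x stages matrix of pSI values, class `psi_table`, with
#'   attribute `threshold`.
#' @export
compute_psi <- function(stage_mat, n_null = 1000, seed = 1,
                        threshold = 0.01) {
  if (ncol(stage_mat) < 2) stopf("need at least 2 stages")
  if (nrow(stage_mat) < 20) stopf("need at least 20 genes")
  if (any(stage_mat <= 0)) {
    message("non-positive expression values; applying shift before fold-change")
    stage_mat <- stage_mat - min(stage_mat) + 1e-6 * max(abs(stage_mat))
  }
  G <- nrow(stage_mat); S <- ncol(stage_mat)
  psi <- matrix(NA_real_, G, S, dimnames = dimnames(stage_mat))
  withr::with_seed(seed, {
    for (s in seq_len(S)) {
      others <- setdiff(seq_len(S), s)
      ranks <- vapply(others, function(j) {
        fc <- stage_mat[, s] / stage_mat[, j]
        rank(-fc, ties.method = "average")
      }, numeric(G))                        # G x (S-1)
      si <- rowMeans(ranks)
      cnt <- numeric(G)
      for (e in seq_len(n_null)) {
        null_si <- rowMeans(vapply(seq_len(S - 1), function(j)
          ranks[sample.int(G), j], numeric(G)))
        cnt <- cnt + (null_si <= si)
      }
      psi[, s] <- (1 + cnt) / (n_null + 1)
    }
  })
  structure(psi, class = c("psi_table", "matrix"), threshold = threshold)
}

#' Temporal (stage) enrichment of a gene set
#'
#' Per stage, the target set is the genes with pSI below `threshold`;
#' over-representation of the query is tested with [fisher_enrichment()]
#' over the pSI gene universe, Bonferroni-corrected for
#' `n_gene_sets * n_stages` tests.
#'
#' @param genes character query set (subset of the pSI universe).
#' @param psi a [compute_psi()] result.
#' @param threshold pSI cutoff (default the table's stored threshold).
#' @param n_gene_sets number of query gene sets in the correction family.
#' @return data frame: stage, n_specific, overlap, odds_ratio, p,
#'   p_corrected.
#' @export
stage_enrichment <- function(genes, psi, threshold = NULL, n_gene_sets = 1) {
  stopifnot(inherits(psi, "psi_table"))
  threshold <- threshold %||% attr(psi, "threshold")
  universe <- rownames(psi)
  if (!all(genes %in% universe)) stopf("gene set must lie in the pSI universe")
  fam <- n_gene_sets * ncol(psi)
  rows <- lapply(colnames(psi), function(s) {
    target <- universe[psi[, s] < threshold]
    fr <- fisher_enrichment(genes, target, universe, family_size = fam)
    data.frame(stage = s, n_specific = length(target), overlap = fr$overlap,
               odds_ratio = fr$odds_ratio, p = fr$p,
               p_corrected = fr$p_corrected, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cell-type enrichment of a gene set
#'
#' Fisher over-representation against each cell type's marker list,
#' Bonferroni-corrected for `n_gene_sets * n_celltypes` tests.
#'
#' @param genes character query set.
#' @param markers named list: cell type -> marker gene ids (labels must be
#'   drawn from `valid_types`).
#' @param background character gene universe.
#' @param n_gene_sets number of query gene sets in the correction family.
#' @param valid_types allowed cell-type labels.
#' @return data frame: cell_type, n_markers, overlap, odds_ratio, p,
#'   p_corrected.
#' @export
celltype_enrichment <- function(genes, markers, background, n_gene_sets = 1,
                                valid_types = c("neurons", "astrocytes",
                                                "oligodendrocytes",
                                                "microglia", "macrophage")) {
  bad <- setdiff(names(markers), valid_types)
  if (length(bad)) stopf("unknown cell-type label(s): %s",
                         paste(bad, collapse = ", "))
  fam <- n_gene_sets * length(markers)
  rows <- lapply(names(markers), function(ct) {
    fr <- fisher_enrichment(genes, intersect(markers[[ct]], background),
                            background, family_size = fam)
    data.frame(cell_type = ct, n_markers = fr$n_target, overlap = fr$overlap,
               odds_ratio = fr$odds_ratio, p = fr$p,
               p_corrected = fr$p_corrected, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
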