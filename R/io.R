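# Plain-text I/O: GMT gene sets, TSV matrices/tables, JSON configs.

#' Read / write GMT gene-set files
#'
#' One set per line: `name <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a numeric matrix as TSV (rownames in first column)
#' @param mat numeric matrix with dimnames.
#' @param path file path.
#' @param id_col name for the rowname column.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Pipeline run configuration
#'
#' Validated key-value configuration for [run_pipeline()]. Defaults follow
#' the reference analysis: 5000 group-test permutations, 1000 association
#' surrogates, 1000 ensemble phenotypes, alpha 0.05, 6 mm sphere, top-50%
#' DS filter. `demo_run_config()` scales the permutation counts down for a
#' minutes-scale desk run; everything else is unchanged.
#'
#' @param ... overrides of the default fields.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    n_per_group = 20L, n_volumes = 180L, tr = 2, grid_shape = c(16L, 16L, 12L),
    voxel_size = 3, smoothness = 9,
    effect_scale_1 = 1.5, effect_scale_2 = 0.75,
    n_genes = 500L, n_signal = 25L, signal_rho = 0.8, n_samples = 300L,
    n_donors = 6L, n_regions = 34L, n_stages = 10L,
    band_low = 0.01, band_high = 0.08, drop_initial_volumes = 10L,
    radius = 6, B_group = 5000L, B_assoc = 1000L, E_ensemble = 1000L,
    n_categories = 20L, category_size_range = c(5L, 40L),
    alpha = 0.05, ds_quantile = 0.5, seed = 1L,
    with_cross_disorder = TRUE, output_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  for (f in c("B_group", "B_assoc", "E_ensemble", "n_per_group", "n_genes",
              "n_samples"))
    check_scalar(cfg[[f]], f, lower = 1, integerish = TRUE)
  check_scalar(cfg$alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar(cfg$ds_quantile, "ds_quantile", lower = 0, upper = 1)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
demo_run_config <- function(...) {
  run_config(B_group = 200L, B_assoc = 200L, E_ensemble = 200L,
             n_per_group = 8L, n_genes = 200L, n_samples = 150L,
             n_volumes = 80L, grid_shape = c(10L, 10L, 8L),
             n_regions = 12L, ...)
}

#' Save / load a run configuration as JSON
#' @param cfg a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(run_config, raw)
}
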