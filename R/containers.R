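# Lightweight S3 containers for the imaging side of the pipeline.
# Images live in memory as plain R arrays with an isotropic-voxel affine
# (see voxel_coords); serialization is plain text (TSV/JSON).

#' 4D BOLD time-series image
#'
#' The per-subject input to ALFF computation: a 4D array (x, y, z, time) with
#' repetition time, voxel size and an analysis mask.
#'
#' @param data 4D numeric array, dimensions x, y, z, time.
#' @param tr repetition time in seconds.
#' @param voxel_size isotropic voxel edge in mm.
#' @param mask logical 3D array matching the spatial dimensions; default all
#'   `TRUE`.
#' @return an object of class `ts_image`.
#' @export
ts_image <- function(data, tr, voxel_size = 3, mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stopf("`data` must be a 4D array (x, y, z, time)")
  check_scalar(tr, "tr", lower = 1e-9)
  check_scalar(voxel_size, "voxel_size", lower = 1e-9)
  sp <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, sp)
  if (!identical(dim(mask), as.integer(sp)))
    stopf("mask dimensions must match the spatial dimensions of `data`")
  structure(
    list(data = data, tr = tr, voxel_size = voxel_size,
         mask = array(as.logical(mask), sp)),
    class = "ts_image"
  )
}

#' @export
print.ts_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ts_image> %d x %d x %d voxels, %d volumes, TR = %gs, %g mm\n",
              d[1], d[2], d[3], d[4], x$tr, x$voxel_size))
  invisible(x)
}

#' ALFF configuration
#'
#' @param band_low,band_high low-frequency band edges in Hz (inclusive on the
#'   DFT frequency grid). Defaults 0.01 and 0.08 Hz, the standard
#'   low-frequency fluctuation band.
#' @param tr repetition time in seconds.
#' @param drop_initial_volumes number of initial volumes discarded before the
#'   spectrum is computed (signal-equilibration convention; default 10).
#' @return an object of class `alff_config`.
#' @export
alff_config <- function(tr, band_low = 0.01, band_high = 0.08,
                        drop_initial_volumes = 10) {
  check_scalar(tr, "tr", lower = 1e-9)
  check_scalar(band_low, "band_low", lower = 0)
  check_scalar(band_high, "band_high", lower = 0)
  check_scalar(drop_initial_volumes, "drop_initial_volumes", lower = 0,
               integerish = TRUE)
  nyquist <- 1 / (2 * tr)
  if (!(band_low < band_high))
    stopf("band_low must be < band_high")
  if (band_high > nyquist + 1e-12)
    stopf("band_high (%g Hz) exceeds the Nyquist frequency (%g Hz)",
          band_high, nyquist)
  structure(
    list(band_low = band_low, band_high = band_high, tr = tr,
         drop_initial_volumes = as.integer(drop_initial_volumes)),
    class = "alff_config"
  )
}

#' Construct a t-statistic map object
#'
#' Container for the voxel-wise group-difference test: the observed t map,
#' degrees of freedom, uncorrected and FWE-corrected permutation p maps, and
#' the analysis mask. Positive t means patients > controls.
#'
#' @param t,p_uncorrected,p_fwe 3D numeric arrays.
#' @param df residual degrees of freedom.
#' @param n_permutations number of permutations used.
#' @param mask logical 3D array.
#' @param voxel_size voxel edge in mm.
#' @return an object of class `tstat_map`.
#' @export
tstat_map <- function(t, df, p_uncorrected, p_fwe, n_permutations, mask,
                      voxel_size = 3) {
  stopifnot(identical(dim(t), dim(mask)),
            identical(dim(p_uncorrected), dim(mask)),
            identical(dim(p_fwe), dim(mask)))
  structure(
    list(t = t, df = df, p_uncorrected = p_uncorrected, p_fwe = p_fwe,
         n_permutations = n_permutations, mask = array(as.logical(mask), dim(mask)),
         voxel_size = voxel_size),
    class = "tstat_map"
  )
}

#' @export
print.tstat_map <- function(x, ...) {
  nm <- sum(x$mask)
  cat(sprintf(
    "<tstat_map> %s voxels in mask, df = %d, B = %d, %d voxels FWE p < 0.05\n",
    nm, x$df, x$n_permutations, sum(x$p_fwe[x$mask] < 0.05)))
  invisible(x)
}

#' Expression dataset container
#'
#' Genes x samples normalized expression with per-sample metadata and
#' per-gene differential stability (DS).
#'
#' @param expr numeric matrix, genes x samples, rownames = gene ids.
#' @param samples data frame with one row per sample: `sample_id`, `donor`,
#'   `region`, `x`, `y`, `z` (MNI-style mm coordinates).
#' @param ds named numeric vector of DS scores, one per gene (may be `NULL`
#'   before [differential_stability()] is run).
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(expr, samples, ds = NULL) {
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stopf("`expr` must be a matrix with gene rownames")
  if (nrow(samples) != ncol(expr))
    stopf("`samples` must have one row per expression column")
  need <- c("sample_id", "donor", "x", "y", "z")
  if (!all(need %in% names(samples)))
    stopf("`samples` must contain columns: %s", paste(need, collapse = ", "))
  if (!all(is.finite(as.matrix(samples[, c("x", "y", "z")]))))
    stopf("sample coordinates must be finite")
  if (!is.null(ds)) {
    ds <- ds[rownames(expr)]
    if (anyNA(ds)) stopf("`ds` must cover every gene in `expr`")
  }
  structure(list(expr = expr, samples = samples, ds = ds),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples, %d donors%s\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$samples$donor)),
              if (is.null(x$ds)) "" else ", DS available"))
  invisible(x)
}
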