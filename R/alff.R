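# ALFF: nuisance regression, framewise displacement, amplitude spectrum.

#' Mean framewise displacement
#'
#' Framewise displacement at volume t is the sum of absolute volume-to-volume
#' changes of the six rigid-body parameters, with rotations (radians)
#' converted to arc length on a 50 mm sphere (Power convention):
#' `FD_t = sum |d translations| + sum |50 * d rotations|`.
#'
#' @param motion_params numeric matrix, volumes x 6: three translations (mm)
#'   then three rotations (radians).
#' @return mean FD in mm over volumes 2..T.
#' @export
mean_fd <- function(motion_params) {
  motion_params <- as.matrix(motion_params)
  if (ncol(motion_params) != 6L)
    stopf("`motion_params` must have 6 columns (3 translations, 3 rotations)")
  if (nrow(motion_params) < 2L)
    stopf("need at least 2 volumes to compute framewise displacement")
  d <- abs(diff(motion_params))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + rowSums(50 * d[, 4:6, drop = FALSE])
  mean(fd)
}

#' Regress nuisance signals out of a time series image
#'
#' Per voxel, returns residuals of the least-squares projection of the series
#' onto an intercept, a linear trend, and the supplied confound columns.
#' Collinear design columns are dropped with a warning.
#'
#' @param series a [ts_image()].
#' @param confounds optional numeric matrix, volumes x q (e.g. tissue signals
#'   and motion expansions). `NULL` means detrend/demean only.
#' @return a [ts_image()] of residuals (same dimensions, mask, TR).
#' @export
regress_nuisance <- function(series, confounds = NULL) {
  stopifnot(inherits(series, "ts_image"))
  d <- dim(series$data)
  nt <- d[4]
  X <- cbind(intercept = 1, trend = seq_len(nt) - (nt + 1) / 2)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nt)
      stopf("confound rows (%d) must match volume count (%d)",
            nrow(confounds), nt)
    X <- cbind(X, confounds)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warnf("design is rank-deficient; dropping %d collinear column(s)",
          ncol(X) - qx$rank)
    qx <- qr(X[, keep, drop = FALSE])
  }
  Y <- matrix(series$data, nrow = prod(d[1:3]), ncol = nt)
  res <- t(qr.resid(qx, t(Y)))
  out <- series
  out$data <- array(res, d)
  out
}

#' Amplitude of low-frequency fluctuations
#'
#' Per voxel the series (after dropping initial volumes) is Fourier
#' transformed; the one-sided amplitude spectrum is `sqrt(2) / N * |DFT_k|`
#' at frequencies `f_k = k / (N * TR)`, k = 1, ..., excluding DC and Nyquist
#' (i.e. `sqrt(|DFT|^2 * 2 / N^2)`). Raw ALFF is the mean amplitude over the
#' in-band frequency bins (band edges inclusive); the standardized map is the
#' raw map divided by its mean over the mask, so the standardized map
#' averages exactly 1 in-mask. Any fixed spectral convention cancels in the
#' standardized map, which is what downstream group analysis consumes.
#'
#' @param series a [ts_image()].
#' @param cfg an [alff_config()]; its `tr` must match the series.
#' @param mask optional logical 3D array overriding `series$mask`.
#' @return list of class `alff_map` with `raw`, `standardized` (3D arrays)
#'   and `mask`.
#' @export
compute_alff <- function(series, cfg, mask = NULL) {
  stopifnot(inherits(series, "ts_image"), inherits(cfg, "alff_config"))
  if (abs(cfg$tr - series$tr) > 1e-9)
    stopf("cfg$tr (%g) does not match series TR (%g)", cfg$tr, series$tr)
  d <- dim(series$data)
  mask <- mask %||% series$mask
  if (!identical(dim(mask), d[1:3])) stopf("mask dimensions mismatch")
  if (!any(mask)) stopf("empty mask")
  drop <- cfg$drop_initial_volumes
  if (d[4] - drop < 32L)
    stopf("need at least 32 volumes after dropping %d, have %d",
          drop, d[4] - drop)
  keep_t <- seq.int(drop + 1L, d[4])
  n <- length(keep_t)
  Y <- matrix(series$data[, , , keep_t, drop = FALSE],
              nrow = prod(d[1:3]), ncol = n)
  # one-sided bins excluding DC; exclude Nyquist when n is even
  kmax <- if (n %% 2L == 0L) n %/% 2L - 1L else (n - 1L) %/% 2L
  freqs <- seq_len(kmax) / (n * cfg$tr)
  in_band <- freqs >= cfg$band_low - 1e-12 & freqs <= cfg$band_high + 1e-12
  if (!any(in_band))
    stopf("no DFT frequencies fall inside [%g, %g] Hz",
          cfg$band_low, cfg$band_high)
  sp <- stats::mvfft(t(Y))                      # n x V complex
  amp <- sqrt(2) / n * Mod(sp[1L + which(in_band), , drop = FALSE])
  raw <- colMeans(amp)
  raw_arr <- array(raw, d[1:3])
  gm <- mean(raw_arr[mask])
  std_arr <- if (gm > 0) raw_arr / gm else raw_arr
  raw_arr[!mask] <- NA_real_
  std_arr[!mask] <- NA_real_
  structure(list(raw = raw_arr, standardized = std_arr, mask = mask,
                 config = cfg, voxel_size = series$voxel_size),
            class = "alff_map")
}
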