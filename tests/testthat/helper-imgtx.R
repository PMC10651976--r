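# Shared fixtures and independent oracles. Oracles are deliberately written
# as direct/brute-force computations, independent of the package internals
# they check.

# direct DFT-summation amplitude oracle: one-sided amplitude sqrt(2)/N |X_k|
# at f_k = k/(N*tr), k = 1..(excl. DC/Nyquist), averaged over [lo, hi]
oracle_alff <- function(x, tr, lo, hi) {
  n <- length(x)
  kmax <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  tt <- seq_len(n) - 1
  amps <- vapply(seq_len(kmax), function(k) {
    re <- sum(x * cos(2 * pi * k * tt / n))
    im <- -sum(x * sin(2 * pi * k * tt / n))
    sqrt(2) / n * sqrt(re^2 + im^2)
  }, numeric(1))
  f <- seq_len(kmax) / (n * tr)
  mean(amps[f >= lo - 1e-12 & f <= hi + 1e-12])
}

# upper-tail hypergeometric by explicit point-mass summation (log space)
oracle_hyper_upper <- function(a, K, N, n) {
  hi <- min(K, n)
  if (a > hi) return(0)
  vals <- vapply(a:hi, function(k)
    exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)), numeric(1))
  sum(vals)
}

# tiny 4D series with a single deterministic per-voxel series
const_series <- function(value, dims = c(2, 2, 1), nt = 48, tr = 2) {
  ts_image(array(value, c(dims, nt)), tr = tr)
}

# synthetic expression dataset built through the full preprocessing chain
# (jittered region sampling, probes, filters, SRS, DS), mirroring realistic
# input structure; returns the dataset plus retained sample coordinates
make_synthetic_dataset <- function(n_genes = 500, n_samples = 300,
                                   n_signal = 25, signal_rho = 0.8,
                                   grid_shape = c(16, 16, 12),
                                   seed = 1) {
  truth <- make_default_truth(n_genes = n_genes, grid_shape = grid_shape,
                              n_signal = n_signal, signal_rho = signal_rho,
                              seed = seed)
  region_coords <- gen_sample_coords(12, grid_shape, 3,
                                     seed = seed + 1)
  rownames(region_coords) <- sprintf("R%02d", 1:12)
  coords <- withr::with_seed(seed + 2, {
    ctr <- region_coords[sample.int(12, n_samples, replace = TRUE), ,
                         drop = FALSE]
    jit <- matrix(runif(n_samples * 3, -1, 1), ncol = 3)
    jit <- jit / pmax(1, sqrt(rowSums(jit^2))) * runif(n_samples, 0, 1.9)
    xy <- ctr + jit
    lim <- (grid_shape - 1) * 3
    for (k in 1:3) xy[, k] <- pmin(pmax(xy[, k], 0), lim[k])
    xy
  })
  raw <- suppressWarnings(gen_expression(n_genes, coords, 6, truth,
                                         seed = seed + 3))
  expr <- suppressMessages(process_expression(raw, region_coords))
  idx <- match(expr$samples$sample_id, raw$samples$sample_id)
  list(truth = truth, expr = expr,
       coords = as.matrix(raw$samples[idx, c("x", "y", "z")]),
       raw = raw)
}

# a tstat_map wrapping an arbitrary 3D array (for sampling / correlation
# tests that only need the t field)
wrap_tmap <- function(arr, voxel_size = 3, mask = NULL) {
  mask <- mask %||% array(TRUE, dim(arr))
  ones <- array(1, dim(arr))
  tstat_map(arr, df = 10, p_uncorrected = ones, p_fwe = ones,
            n_permutations = 0, mask = mask, voxel_size = voxel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
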