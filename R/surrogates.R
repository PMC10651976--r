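# Variogram-matched surrogate maps on arbitrary point sets.
#
# The engine behind spatial-autocorrelation-preserving nulls: permute the
# map, re-impose autocorrelation by kernel smoothing over k nearest
# neighbours, fit (alpha, beta) so the candidate's variogram matches the
# empirical one, pick the best k, then (optionally) rank-map the original
# values back onto the candidate so each surrogate has exactly the original
# value multiset.

# Gaussian smoothing matrix across variogram bins (rows normalized)
bin_smoother <- function(centers, bandwidth) {
  W <- outer(centers, centers, function(a, b) exp(-((a - b) / bandwidth)^2 / 2))
  W / rowSums(W)
}

# pair structure reused for many variograms on the same point set
pair_structure <- function(coords, n_bins, max_dist_fraction, bandwidth = NULL) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  dmax <- max(D)
  if (dmax <= 0) stopf("all points are coincident")
  h_max <- max_dist_fraction * dmax
  ut <- which(upper.tri(D), arr.ind = TRUE)
  keep <- D[ut] <= h_max & D[ut] > 0
  pi_ <- ut[keep, 1]; pj <- ut[keep, 2]
  d <- D[ut][keep]
  edges <- seq(0, h_max, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(d, edges, rightmost.closed = TRUE), 1L), n_bins)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- tabulate(bin, n_bins)
  bw <- bandwidth %||% (2 * diff(centers[1:2]))
  list(i = pi_, j = pj, bin = bin, counts = counts, centers = centers,
       smoother = bin_smoother(centers, bw), D = D, n = n, bandwidth = bw)
}

# smoothed variogram(s); X is an n x B matrix of maps -> n_bins x B
variogram_of <- function(X, ps) {
  X <- as.matrix(X)
  sq <- (X[ps$i, , drop = FALSE] - X[ps$j, , drop = FALSE])^2
  g <- rowsum(sq, ps$bin, reorder = TRUE)
  present <- sort(unique(ps$bin))
  full <- matrix(NA_real_, length(ps$counts), ncol(X))
  full[present, ] <- g / ps$counts[present] / 2
  # empty bins: carry nearest non-empty value before smoothing
  if (anyNA(full[, 1])) {
    ok <- which(!is.na(full[, 1]))
    for (b in which(is.na(full[, 1]))) {
      nb <- ok[which.min(abs(ok - b))]
      full[b, ] <- full[nb, ]
    }
  }
  ps$smoother %*% full
}

#' Empirical (binned, smoothed) variogram
#'
#' Semivariance `gamma(h) = 0.5 * mean (x_i - x_j)^2` over point pairs whose
#' distance falls in bin h, for bins spanning `[0, max_dist_fraction * max
#' pairwise distance]`, then Gaussian-kernel smoothed across bins (default
#' bandwidth: two bin widths). Distances beyond the fraction cutoff are
#' ignored: the near half of the distance range is where the variogram is
#' informative about autocorrelation.
#'
#' @param values numeric vector, one value per point.
#' @param coords numeric matrix n x d of point coordinates (mm).
#' @param n_bins number of distance bins.
#' @param max_dist_fraction fraction of the maximum pairwise distance to bin.
#' @param bandwidth Gaussian smoothing bandwidth across bins (mm).
#' @return object of class `imgtx_variogram`: `bin_centers`, `gamma`,
#'   `n_pairs`.
#' @export
empirical_variogram <- function(values, coords, n_bins = 25,
                                max_dist_fraction = 0.5, bandwidth = NULL) {
  coords <- as.matrix(coords)
  if (length(values) != nrow(coords)) stopf("values/coords length mismatch")
  if (length(values) < 10) stopf("need at least 10 points")
  ps <- pair_structure(coords, n_bins, max_dist_fraction, bandwidth)
  g <- drop(variogram_of(matrix(values, ncol = 1), ps))
  structure(list(bin_centers = ps$centers, gamma = g, n_pairs = ps$counts,
                 bandwidth = ps$bandwidth),
            class = "imgtx_variogram")
}

# least-squares fit gamma_emp ~ alpha + beta * gamma_cand, coefficients
# clamped non-negative; vectorized over columns of G (n_bins x B)
fit_alpha_beta <- function(gamma_emp, G) {
  nb <- length(gamma_emp)
  xm <- colMeans(G)
  ym <- mean(gamma_emp)
  sxx <- colSums(G^2) - nb * xm^2
  sxy <- colSums(G * gamma_emp) - nb * xm * ym
  beta <- ifelse(sxx > 1e-12, sxy / sxx, 0)
  beta <- pmax(beta, 0)
  alpha <- pmax(ym - beta * xm, 0)
  pred <- sweep(sweep(G, 2, beta, `*`), 2, alpha, `+`)
  sse <- colSums((pred - gamma_emp)^2)
  list(alpha = alpha, beta = beta, sse = sse)
}

#' Variogram-matched surrogate maps
#'
#' For each surrogate: (1) randomly permute the map values; (2) for each
#' candidate neighbourhood size k, smooth the permuted map with an
#' exponentially decaying kernel `exp(-d_ij / d_k(i))` over each point's k
#' nearest neighbours (d_k(i) = distance to the k-th neighbour); (3) fit
#' non-negative scalars (alpha, beta) by least squares so the variogram of
#' `sqrt(beta) * smoothed + sqrt(alpha) * white noise` matches the empirical
#' variogram (white noise adds a constant alpha to the semivariance at every
#' lag); (4) keep the k with minimal residual SSE; (5) if `resample`, replace
#' the surrogate's values by the original values via rank mapping, so the
#' value multiset is preserved exactly.
#'
#' @param values numeric vector, the map.
#' @param coords numeric matrix n x d (mm).
#' @param n_surrogates number of surrogates (>= 1).
#' @param seed integer RNG seed.
#' @param kernel_grid fractions of n defining the candidate k grid.
#' @param resample rank-map original values onto each surrogate (default
#'   TRUE).
#' @param n_bins,max_dist_fraction,bandwidth variogram settings, see
#'   [empirical_variogram()].
#' @return object of class `imgtx_surrogates`: `values` (n x n_surrogates
#'   matrix), `k_chosen`, `resampled`.
#' @export
make_surrogates <- function(values, coords, n_surrogates, seed = 1,
                            kernel_grid = c(0.1, 0.2, 0.3, 0.4),
                            resample = TRUE, n_bins = 25,
                            max_dist_fraction = 0.5, bandwidth = NULL) {
  coords <- as.matrix(coords)
  n <- length(values)
  if (n != nrow(coords)) stopf("values/coords length mismatch")
  check_scalar(n_surrogates, "n_surrogates", lower = 1, integerish = TRUE)
  if (!length(kernel_grid)) stopf("kernel_grid must be non-empty")
  if (var(values) == 0) {
    return(structure(list(values = matrix(values, n, n_surrogates),
                          k_chosen = rep(NA_integer_, n_surrogates),
                          resampled = resample),
                     class = "imgtx_surrogates"))
  }
  ks <- unique(pmax(1L, pmin(n - 1L, as.integer(round(kernel_grid * n)))))
  if (any(round(kernel_grid * n) >= n))
    warnf("kernel k >= n_points; clamped to n - 1")
  ps <- pair_structure(coords, n_bins, max_dist_fraction, bandwidth)
  gamma_emp <- drop(variogram_of(matrix(values, ncol = 1), ps))
  # neighbour structure: ordered distances per point
  ord <- apply(ps$D, 1, order)          # n x n (column i = neighbours of i)
  withr::with_seed(seed, {
    B <- n_surrogates
    P <- vapply(seq_len(B), function(b) values[sample.int(n)], numeric(n))
    best_sse <- rep(Inf, B)
    best <- list(sm = NULL, alpha = NULL, beta = NULL, k = NULL)
    cand_sm <- matrix(0, n, B)
    chosen_k <- integer(B)
    chosen_alpha <- numeric(B)
    chosen_beta <- numeric(B)
    for (k in ks) {
      # kernel weights: k nearest neighbours (excluding self), scale d_k
      W <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- ord[2:(k + 1L), i]
        dk <- ps$D[i, nb[k]]
        w <- exp(-ps$D[i, nb] / dk)
        W[i, nb] <- w / sum(w)
      }
      Sm <- W %*% P
      G <- variogram_of(Sm, ps)
      ft <- fit_alpha_beta(gamma_emp, G)
      upd <- ft$sse < best_sse
      if (any(upd)) {
        cand_sm[, upd] <- Sm[, upd]
        chosen_k[upd] <- k
        chosen_alpha[upd] <- ft$alpha[upd]
        chosen_beta[upd] <- ft$beta[upd]
        best_sse[upd] <- ft$sse[upd]
      }
    }
    Z <- matrix(rnorm(n * B), n, B)
    out <- sweep(cand_sm, 2, sqrt(chosen_beta), `*`) +
      sweep(Z, 2, sqrt(chosen_alpha), `*`)
    if (resample) {
      sv <- sort(values)
      out <- apply(out, 2, function(col) sv[rank(col, ties.method = "first")])
    }
    structure(list(values = out, k_chosen = chosen_k, resampled = resample,
                   sse = best_sse),
              class = "imgtx_surrogates")
  })
}

#' @export
print.imgtx_surrogates <- function(x, ...) {
  cat(sprintf("<imgtx_surrogates> %d points x %d surrogates%s\n",
              nrow(x$values), ncol(x$values),
              if (isTRUE(x$resampled)) ", resampled" else ""))
  invisible(x)
}
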