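# Voxel-wise covariate-adjusted permutation inference and demographics tests.

# t statistics for one design column, vectorized over columns of Y
# X: n x p full-rank design, Y: n x V, col: index of the tested coefficient
vox_tstats <- function(X, Y, col, xtxinv = NULL) {
  p <- ncol(X)
  n <- nrow(X)
  xtxinv <- xtxinv %||% chol2inv(chol(crossprod(X)))
  A <- xtxinv %*% t(X)
  coef <- A %*% Y
  res <- Y - X %*% coef
  sigma2 <- colSums(res^2) / (n - p)
  tt <- coef[col, ] / sqrt(xtxinv[col, col] * sigma2)
  tt[!is.finite(tt)] <- 0
  tt
}

#' Voxel-wise group permutation test with FWE correction
#'
#' The observed statistic is the group-coefficient t from voxel-wise least
#' squares on `[intercept, group, covariates]` (t > 0 means patients >
#' controls). The null is built by Freedman-Lane residual permutation: fit
#' the covariates-only (reduced) model, permute its residuals, add back the
#' reduced fit, and recompute the full-model t, B times. Per voxel,
#' `p_uncorrected = (1 + #{|t*| >= |t|}) / (B + 1)`; the FWE-corrected p
#' compares each observed |t| to the permutation distribution of the maximum
#' |t*| across the mask (max-statistic correction). Voxels constant across
#' subjects get t = 0, p = 1.
#'
#' @param alff_maps list of `alff_map` objects (standardized maps are used),
#'   or a subjects x voxels matrix of in-mask values (then `mask` required).
#' @param group factor/character with two levels; the second level
#'   (patients) is the positive direction. A character vector is coerced
#'   with `control < patient` ordering if those labels are present,
#'   otherwise alphabetically.
#' @param covariates data frame or matrix of per-subject covariates (e.g.
#'   age, sex, mean FD); may be `NULL`.
#' @param mask logical 3D array (required when `alff_maps` is a matrix).
#' @param B number of permutations.
#' @param seed integer RNG seed.
#' @param alpha significance level recorded in the result.
#' @return a [tstat_map()].
#' @export
permutation_group_test <- function(alff_maps, group, covariates = NULL,
                                   mask = NULL, B = 5000, seed = 1,
                                   alpha = 0.05) {
  check_scalar(B, "B", lower = 1, integerish = TRUE)
  if (is.list(alff_maps) && inherits(alff_maps[[1]], "alff_map")) {
    mask <- mask %||% alff_maps[[1]]$mask
    Y <- t(vapply(alff_maps, function(m) m$standardized[mask],
                  numeric(sum(mask))))
    voxel_size <- alff_maps[[1]]$voxel_size %||% 3
  } else {
    Y <- as.matrix(alff_maps)
    if (is.null(mask)) stopf("`mask` is required when maps are a matrix")
    voxel_size <- 3
  }
  nsub <- nrow(Y)
  if (is.character(group))
    group <- factor(group, levels = intersect(c("control", "patient"),
                                              unique(group)))
  group <- as.factor(group)
  if (nlevels(group) != 2 || min(table(group)) < 2)
    stopf("need two groups with at least 2 subjects each")
  g <- as.numeric(group == levels(group)[2])
  Z <- NULL
  if (!is.null(covariates)) {
    Z <- as.matrix(data.frame(covariates))
    if (nrow(Z) != nsub) stopf("covariate rows must match subject count")
  }
  X <- cbind(1, g, Z)
  Xr <- cbind(1, Z)
  const_vox <- apply(Y, 2, function(col) max(col) - min(col) == 0)
  xtxinv <- chol2inv(chol(crossprod(X)))
  t_obs <- vox_tstats(X, Y, 2L, xtxinv)
  t_obs[const_vox] <- 0
  abs_obs <- abs(t_obs)
  # reduced-model fit and residuals (Freedman-Lane)
  qr_r <- qr(Xr)
  fit_r <- Y - qr.resid(qr_r, Y)
  er <- Y - fit_r
  exceed <- numeric(ncol(Y))
  max_star <- numeric(B)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      Yb <- fit_r + er[sample.int(nsub), , drop = FALSE]
      tb <- vox_tstats(X, Yb, 2L, xtxinv)
      tb[const_vox] <- 0
      ab <- abs(tb)
      exceed <- exceed + (ab >= abs_obs)
      max_star[b] <- max(ab)
    }
  })
  p_unc <- (1 + exceed) / (B + 1)
  p_fwe <- (1 + vapply(abs_obs, function(a) sum(max_star >= a),
                       numeric(1))) / (B + 1)
  p_unc[const_vox] <- 1
  p_fwe[const_vox] <- 1
  dims <- dim(mask)
  to_arr <- function(v, fill = NA_real_) {
    a <- array(fill, dims); a[mask] <- v; a
  }
  tstat_map(t = to_arr(t_obs, 0), df = nsub - ncol(X),
            p_uncorrected = to_arr(p_unc, 1), p_fwe = to_arr(p_fwe, 1),
            n_permutations = B, mask = mask, voxel_size = voxel_size)
}

#' Threshold-wise overlap of two t-maps
#'
#' For each threshold, counts mask voxels where both maps are suprathreshold
#' with the same effect sign; for `"unthresholded"`, voxels where the two t
#' values simply agree in (nonzero) sign.
#'
#' @param tmap1,tmap2 [tstat_map()] objects on identical masks.
#' @param thresholds character vector from
#'   `c("fwe0.05", "p0.001", "p0.01", "p0.05", "unthresholded")`.
#' @return data frame: threshold, n_overlap, n_total, fraction.
#' @export
threshold_overlap <- function(tmap1, tmap2,
                              thresholds = c("fwe0.05", "p0.001", "p0.01",
                                             "p0.05", "unthresholded")) {
  stopifnot(inherits(tmap1, "tstat_map"), inherits(tmap2, "tstat_map"))
  if (!identical(tmap1$mask, tmap2$mask)) stopf("masks differ")
  m <- tmap1$mask
  t1 <- tmap1$t[m]; t2 <- tmap2$t[m]
  same_sign <- sign(t1) == sign(t2) & sign(t1) != 0
  rows <- lapply(thresholds, function(th) {
    if (th == "unthresholded") {
      ok <- same_sign
    } else if (th == "fwe0.05") {
      ok <- same_sign & tmap1$p_fwe[m] < 0.05 & tmap2$p_fwe[m] < 0.05
    } else {
      a <- as.numeric(sub("^p", "", th))
      if (is.na(a)) stopf("unknown threshold label '%s'", th)
      ok <- same_sign & tmap1$p_uncorrected[m] < a & tmap2$p_uncorrected[m] < a
    }
    data.frame(threshold = th, n_overlap = sum(ok), n_total = length(t1),
               fraction = sum(ok) / length(t1), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spatial correlation of two maps with a surrogate null
#'
#' Pearson correlation over mask voxels, with significance from
#' autocorrelation-preserving surrogates: the null pools correlations of
#' surrogates of map 1 with the real map 2 and surrogates of map 2 with the
#' real map 1 (`n_surrogates` each);
#' `p = (1 + #{|r_null| >= |r|}) / (n_null + 1)`.
#'
#' @param tmap1,tmap2 [tstat_map()] objects (or plain numeric vectors with
#'   `coords` supplied).
#' @param n_surrogates surrogates per map.
#' @param seed integer RNG seed.
#' @param coords point coordinates (required for vector input; for maps,
#'   in-mask voxel centers are used).
#' @param subsample_cap maximum number of points used (uniform subsample,
#'   applied to both maps identically, for tractability on large grids).
#' @param ... passed to [make_surrogates()].
#' @return list: `r`, `p_perm`, `n_null`.
#' @export
map_spatial_correlation <- function(tmap1, tmap2, n_surrogates = 1000,
                                    seed = 1, coords = NULL,
                                    subsample_cap = 5000, ...) {
  if (inherits(tmap1, "tstat_map")) {
    if (!identical(tmap1$mask, tmap2$mask)) stopf("masks differ")
    m <- tmap1$mask
    coords <- voxel_coords(dim(m), tmap1$voxel_size)[as.vector(m), ,
                                                     drop = FALSE]
    x <- tmap1$t[m]; y <- tmap2$t[m]
  } else {
    x <- as.numeric(tmap1); y <- as.numeric(tmap2)
    if (is.null(coords)) stopf("`coords` required for vector input")
  }
  if (length(x) < 3) stopf("need at least 3 voxels")
  if (var(x) == 0 || var(y) == 0) stopf("zero-variance map")
  if (length(x) > subsample_cap) {
    keep <- withr::with_seed(derive_seed(seed, 99),
                             sort(sample.int(length(x), subsample_cap)))
    message(sprintf("subsampling %d of %d points for surrogate null",
                    subsample_cap, length(x)))
    x <- x[keep]; y <- y[keep]; coords <- coords[keep, , drop = FALSE]
  }
  r <- cor(x, y)
  s1 <- make_surrogates(x, coords, n_surrogates, seed = derive_seed(seed, 1),
                        ...)
  s2 <- make_surrogates(y, coords, n_surrogates, seed = derive_seed(seed, 2),
                        ...)
  null_r <- c(cor(s1$values, y), cor(s2$values, x))
  p <- (1 + sum(abs(null_r) >= abs(r))) / (length(null_r) + 1)
  list(r = r, p_perm = p, n_null = length(null_r))
}

#' Pearson chi-square test for a 2 x 2 table
#'
#' No continuity correction, df = 1: `chi2 = N (ad - bc)^2 / (r1 r2 c1 c2)`.
#'
#' @param counts 2 x 2 matrix of non-negative counts with positive margins.
#' @return list: `chi2`, `p`.
#' @export
sex_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 2L)) || any(counts < 0))
    stopf("`counts` must be a non-negative 2 x 2 table")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) stopf("table has a zero margin")
  n <- sum(counts)
  chi2 <- n * (counts[1, 1] * counts[2, 2] -
                 counts[1, 2] * counts[2, 1])^2 / prod(rs, cs)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Mann-Whitney test with normal approximation
#'
#' Standardized U statistic with tie correction; by convention z > 0 when
#' `x` is stochastically larger than `y`. All-tied input returns z = 0,
#' p = 1. Two-sided p from the normal approximation.
#'
#' @param x,y numeric samples (>= 3 observations each).
#' @return list: `z`, `p`.
#' @export
mann_whitney_z <- function(x, y) {
  if (length(x) < 3 || length(y) < 3) stopf("need >= 3 observations per sample")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(z = 0, p = 1))
  z <- (u1 - mu) / sqrt(sigma2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# Monte-Carlo critical tables for the Lilliefors statistic, cached per
# (n, n_sim) within the session
.lillie_cache <- new.env(parent = emptyenv())

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  pz <- pnorm(z)
  max(max(seq_len(n) / n - pz), max(pz - (seq_len(n) - 1) / n))
}

#' Lilliefors test of normality
#'
#' Kolmogorov-Smirnov distance to the normal distribution with mean and SD
#' estimated from the data; the p-value comes from a Monte-Carlo null table
#' (standard normal samples of the same size, parameters re-estimated per
#' draw), cached per sample size within the session.
#'
#' @param values numeric sample (>= 4 observations).
#' @param n_sim Monte-Carlo draws for the null table.
#' @param seed seed for the null table (only used when the table for this
#'   `(n, n_sim)` is not yet cached).
#' @return list: `statistic` (D), `p`.
#' @export
lilliefors <- function(values, n_sim = 10000, seed = 20260909) {
  n <- length(values)
  if (n < 4) stopf("need at least 4 observations")
  if (sd(values) == 0) stopf("constant sample")
  d <- lilliefors_stat(values)
  key <- sprintf("n%d_s%d", n, n_sim)
  if (is.null(.lillie_cache[[key]])) {
    .lillie_cache[[key]] <- withr::with_seed(seed, {
      vapply(seq_len(n_sim), function(i) lilliefors_stat(rnorm(n)),
             numeric(1))
    })
  }
  null_d <- .lillie_cache[[key]]
  list(statistic = d, p = (1 + sum(null_d >= d)) / (n_sim + 1))
}
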