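# Synthetic-data generators: every pipeline input, with planted ground truth.
# All generators are pure functions of (parameters, seed): RNG state is
# scoped with withr::with_seed and restored on exit.

#' Generate a spatially smooth effect map
#'
#' A Gaussian random field on the voxel grid, built by smoothing white noise
#' with an exponentially decaying kernel `exp(-d / smoothness)` over voxel
#' centers, then standardized to zero mean, unit SD. `smoothness = 0` yields
#' voxel-wise white noise.
#'
#' @param grid_shape integer 3-vector of voxel dimensions.
#' @param smoothness spatial range of the exponential kernel, mm (>= 0).
#' @param voxel_size voxel edge, mm.
#' @param seed integer RNG seed.
#' @return 3D numeric array with attributes `voxel_size`, `smoothness`.
#' @export
gen_effect_map <- function(grid_shape, smoothness, voxel_size = 3, seed = 1) {
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stopf("`grid_shape` must be 3 positive integers")
  check_scalar(smoothness, "smoothness", lower = 0)
  v <- prod(grid_shape)
  x <- withr::with_seed(seed, {
    z <- rnorm(v)
    if (smoothness > 0) {
      coords <- voxel_coords(grid_shape, voxel_size)
      W <- exp(-as.matrix(dist(coords)) / smoothness)
      drop(W %*% z)
    } else z
  })
  x <- (x - mean(x)) / sd(x)
  structure(array(x, grid_shape), voxel_size = voxel_size,
            smoothness = smoothness)
}

#' Cohort specification for the synthetic BOLD generator
#'
#' Defaults give a desk-scale cohort: 20 subjects per group on a 16 x 16 x 12
#' grid of 3 mm voxels, 180 volumes at TR = 2 s, so that 170 volumes remain
#' after the standard 10-volume drop and the DFT grid resolves the
#' 0.01-0.08 Hz band.
#'
#' @param n_per_group subjects per group (patients and controls).
#' @param n_volumes volumes per run (>= 32).
#' @param tr repetition time, seconds.
#' @param grid_shape integer 3-vector.
#' @param voxel_size voxel edge, mm.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20, n_volumes = 180, tr = 2,
                        grid_shape = c(16, 16, 12), voxel_size = 3) {
  check_scalar(n_per_group, "n_per_group", lower = 1, integerish = TRUE)
  check_scalar(n_volumes, "n_volumes", lower = 32, integerish = TRUE)
  check_scalar(tr, "tr", lower = 1e-9)
  check_scalar(voxel_size, "voxel_size", lower = 1e-9)
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stopf("`grid_shape` must be 3 positive integers")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_volumes = as.integer(n_volumes), tr = tr,
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size),
            class = "cohort_spec")
}

#' Generate a synthetic two-group BOLD cohort
#'
#' Each voxel's series is broadband Gaussian noise plus in-band sinusoids
#' (0.02, 0.04, 0.06 Hz) with random per-voxel phases and amplitudes; in the
#' patient group the sinusoid amplitude at voxel v is scaled by
#' `1 + effect_scale * effect_map[v]`, so `effect_scale = 0` makes the two
#' groups exchangeable. Covariates (age, sex, mean FD) are drawn from fixed
#' distributions (age ~ N(37, 12^2) truncated to [18, 65]; sex ~
#' Bernoulli(0.5); mean FD ~ |N(0.06, 0.04^2)| mm) and do not enter the
#' series, so they act as pure nuisance structure.
#'
#' Volumes are spatially smoothed with a Gaussian kernel (`fwhm_mm`,
#' default 8 mm) so the voxel maps carry the spatial autocorrelation that
#' preprocessed BOLD data have; `fwhm_mm = 0` disables smoothing.
#'
#' @param spec a [cohort_spec()].
#' @param effect_map 3D array from [gen_effect_map()] matching
#'   `spec$grid_shape`.
#' @param effect_scale non-negative amplitude modulation of the patient group.
#' @param seed integer RNG seed.
#' @param fwhm_mm full-width-at-half-maximum of the spatial smoothing
#'   kernel, mm.
#' @return list with `subjects` (named list of [ts_image()]) and `covariates`
#'   (data frame: subject_id, group, age, sex, mean_fd).
#' @export
gen_cohort <- function(spec, effect_map, effect_scale, seed = 1,
                       fwhm_mm = 8) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_per_group < 2) stopf("n_per_group must be >= 2")
  check_scalar(effect_scale, "effect_scale", lower = 0)
  if (!identical(dim(effect_map), spec$grid_shape))
    stopf("effect_map dimensions must match spec$grid_shape")
  nsub <- 2L * spec$n_per_group
  v <- prod(spec$grid_shape)
  nt <- spec$n_volumes
  tsec <- (seq_len(nt) - 1) * spec$tr
  freqs <- c(0.02, 0.04, 0.06)
  S <- sin(2 * pi * outer(tsec, freqs))
  C <- cos(2 * pi * outer(tsec, freqs))
  amp0 <- 1
  eff <- as.vector(effect_map)
  withr::with_seed(seed, {
    group <- rep(c("control", "patient"), each = spec$n_per_group)
    age <- numeric(nsub)
    for (i in seq_len(nsub)) {
      repeat {
        a <- rnorm(1, 37, 12)
        if (a >= 18 && a <= 65) break
      }
      age[i] <- a
    }
    sex <- rbinom(nsub, 1, 0.5)
    mean_fd <- abs(rnorm(nsub, 0.06, 0.04))
    subjects <- vector("list", nsub)
    for (i in seq_len(nsub)) {
      mult <- if (group[i] == "patient")
        pmax(0, 1 + effect_scale * eff) else rep(1, v)
      u <- matrix(runif(v * 3, 0.5, 1.5), v, 3) * amp0 * mult
      phi <- matrix(runif(v * 3, 0, 2 * pi), v, 3)
      sig <- S %*% t(u * cos(phi)) + C %*% t(u * sin(phi))   # nt x v
      noise <- matrix(rnorm(nt * v), nt, v)
      vol <- gaussian_smooth_4d(array(t(sig + noise), c(spec$grid_shape, nt)),
                                fwhm_mm, spec$voxel_size)
      subjects[[i]] <- ts_image(vol, tr = spec$tr,
                                voxel_size = spec$voxel_size)
    }
    ids <- sprintf("sub%03d", seq_len(nsub))
    names(subjects) <- ids
    list(subjects = subjects,
         covariates = data.frame(subject_id = ids, group = group, age = age,
                                 sex = sex, mean_fd = mean_fd,
                                 stringsAsFactors = FALSE))
  })
}

#' Planted ground truth for a synthetic study
#'
#' Bundles the components downstream recovery tests need: the true effect
#' map, the identifier set of genes built to track it (with target spatial
#' correlation `signal_rho`), stage-specific gene sets, and cell-type marker
#' assignments.
#'
#' @param effect_map 3D array from [gen_effect_map()].
#' @param signal_genes character vector of gene ids.
#' @param signal_rho target correlation between signal-gene expression and
#'   the effect map sampled at expression sample coordinates, in [0, 1].
#' @param stage_specific_genes named list: stage label -> gene ids (each
#'   non-empty).
#' @param marker_assignments named list: cell type -> gene ids.
#' @param seed integer seed recorded for provenance.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(effect_map, signal_genes, signal_rho,
                            stage_specific_genes = list(),
                            marker_assignments = list(), seed = 1) {
  check_scalar(signal_rho, "signal_rho", lower = 0, upper = 1)
  if (length(stage_specific_genes) &&
      any(lengths(stage_specific_genes) == 0))
    stopf("every stage label must have at least one gene")
  structure(list(effect_map = effect_map,
                 signal_genes = as.character(signal_genes),
                 signal_rho = signal_rho,
                 stage_specific_genes = stage_specific_genes,
                 marker_assignments = marker_assignments,
                 seed = seed),
            class = "synthetic_truth")
}

#' Default planted truth at desk scale
#'
#' Builds an effect map and assigns the first `n_signal` gene ids as signal
#' genes, one stage-specific gene set per developmental stage (Roman labels
#' I..X), and five disjoint cell-type marker sets drawn from the gene
#' universe.
#'
#' @param n_genes size of the gene universe (ids `G0001` ...).
#' @param grid_shape,voxel_size,smoothness passed to [gen_effect_map()].
#' @param n_signal number of planted signal genes.
#' @param signal_rho target spatial correlation of signal genes.
#' @param n_stages number of developmental stages.
#' @param markers_per_type genes per cell-type marker list.
#' @param seed integer RNG seed.
#' @return a [synthetic_truth()].
#' @export
make_default_truth <- function(n_genes = 500, grid_shape = c(16, 16, 12),
                               voxel_size = 3, smoothness = 9, n_signal = 25,
                               signal_rho = 0.8, n_stages = 10,
                               markers_per_type = 30, seed = 1) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  emap <- gen_effect_map(grid_shape, smoothness, voxel_size,
                         seed = derive_seed(seed, 1))
  withr::with_seed(derive_seed(seed, 2), {
    signal <- genes[seq_len(n_signal)]
    stages <- as.character(utils::as.roman(seq_len(n_stages)))
    stage_pool <- sample(setdiff(genes, signal))
    stage_sets <- split(stage_pool[seq_len(5 * n_stages)],
                        rep(stages, each = 5))[stages]
    types <- c("neurons", "astrocytes", "oligodendrocytes", "microglia",
               "macrophage")
    marker_pool <- sample(genes)
    markers <- split(marker_pool[seq_len(markers_per_type * 5)],
                     rep(types, each = markers_per_type))[types]
    synthetic_truth(emap, signal, signal_rho, stage_sets, markers, seed)
  })
}

# separable 3D Gaussian smoothing of a 4D array (x, y, z, t), applied
# volume-wise; kernel truncated at 3 SD and renormalized at the edges
gaussian_smooth_4d <- function(arr, fwhm_mm, voxel_size) {
  if (fwhm_mm <= 0) return(arr)
  sdv <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  d <- dim(arr)
  kmat <- function(n) {
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-(i - j)^2 / (2 * sdv^2)))
    K[abs(row(K) - col(K)) > ceiling(3 * sdv)] <- 0
    K / rowSums(K)
  }
  # x axis
  m <- matrix(arr, d[1], prod(d[-1]))
  arr <- array(kmat(d[1]) %*% m, d)
  # y axis
  a <- aperm(arr, c(2, 1, 3, 4))
  m <- matrix(a, d[2], prod(d[-2]))
  arr <- aperm(array(kmat(d[2]) %*% m, d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  # z axis
  a <- aperm(arr, c(3, 1, 2, 4))
  m <- matrix(a, d[3], prod(d[-3]))
  aperm(array(kmat(d[3]) %*% m, d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
}

# effect map value at arbitrary mm coordinates (nearest-voxel lookup)
effect_at_coords <- function(effect_map, coords, voxel_size) {
  dims <- dim(effect_map)
  idx <- round(coords / voxel_size) + 1
  if (any(idx < 0.5) || any(t(t(idx) > dims + 0.5)))
    stopf("sample coordinates fall outside the effect-map grid")
  idx <- pmin(pmax(idx, 1), matrix(dims, nrow(idx), 3, byrow = TRUE))
  effect_map[cbind(idx[, 1], idx[, 2], idx[, 3])]
}

#' Generate probe-level expression data with planted spatial signal
#'
#' Background genes are spatially autocorrelated fields over the sample
#' coordinates, independent of the effect map; each mixes a donor-shared and
#' a donor-specific field (mixing weight drawn per gene) so differential
#' stability varies across genes. Signal genes follow
#' `rho * z(effect) + sqrt(1 - rho^2) * noise-field`, with a high shared
#' weight so they survive the DS filter. Every gene gets three probes: a
#' low-noise best probe, a noisier probe (a fraction of which fail the
#' intensity filter), and a planted anti-correlated probe that the
#' RNA-seq-guided selection step must discard. An RNA-seq reference matrix is
#' emitted for the first two donors' samples.
#'
#' @param n_genes gene universe size (must cover `truth$signal_genes`).
#' @param sample_coords numeric matrix n_samples x 3, mm, inside the
#'   effect-map grid.
#' @param n_donors number of donors; labels partition samples round-robin.
#' @param truth a [synthetic_truth()].
#' @param seed integer RNG seed.
#' @param range_mm spatial range of the expression autocorrelation kernel.
#' @param frac_low_quality fraction of second probes given a low
#'   above-background rate (planted intensity-filter failures).
#' @return list: `probes` (probe x sample matrix), `probe_info`
#'   (probe_id, gene), `pacall` (logical probe x sample), `rnaseq`
#'   (gene x subset matrix), `samples` (metadata data frame), `gene_values`
#'   (true gene x sample matrix), `best_probe` (gene -> probe id).
#' @export
gen_expression <- function(n_genes, sample_coords, n_donors, truth, seed = 1,
                           range_mm = 6, frac_low_quality = 0.15) {
  stopifnot(inherits(truth, "synthetic_truth"))
  sample_coords <- as.matrix(sample_coords)
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (!all(truth$signal_genes %in% genes))
    stopf("n_genes (%d) too small to cover the %d signal genes", n_genes,
          length(truth$signal_genes))
  ns <- nrow(sample_coords)
  vs <- attr(truth$effect_map, "voxel_size") %||% 3
  e <- effect_at_coords(truth$effect_map, sample_coords, vs)  # errors if outside
  e <- (e - mean(e)) / sd(e)
  withr::with_seed(seed, {
    W <- exp(-as.matrix(dist(sample_coords)) / range_mm)
    smooth_fields <- function(k) {
      f <- W %*% matrix(rnorm(ns * k), ns, k)
      scale(f)                      # samples x k, unit variance
    }
    donor <- paste0("donor", rep_len(seq_len(n_donors), ns))
    shared <- t(smooth_fields(n_genes))               # genes x samples
    donor_part <- matrix(0, n_genes, ns)
    for (d in unique(donor)) {
      sel <- donor == d
      f <- exp(-as.matrix(dist(sample_coords[sel, , drop = FALSE])) / range_mm)
      g <- f %*% matrix(rnorm(sum(sel) * n_genes), sum(sel), n_genes)
      donor_part[, sel] <- t(scale(g))
    }
    cw <- runif(n_genes, 0.3, 0.95)
    is_signal <- genes %in% truth$signal_genes
    cw[is_signal] <- 0.9
    noise_field <- sqrt(cw) * shared + sqrt(1 - cw) * donor_part
    noise_field <- t(scale(t(noise_field)))
    gene_values <- noise_field
    rho <- truth$signal_rho
    gene_values[is_signal, ] <-
      rho * matrix(e, sum(is_signal), ns, byrow = TRUE) +
      sqrt(1 - rho^2) * noise_field[is_signal, , drop = FALSE]
    rownames(gene_values) <- genes
    sample_ids <- sprintf("S%04d", seq_len(ns))
    colnames(gene_values) <- sample_ids

    p1 <- gene_values + matrix(rnorm(n_genes * ns, sd = 0.3), n_genes, ns)
    p2 <- gene_values + matrix(rnorm(n_genes * ns, sd = 0.8), n_genes, ns)
    p3 <- -gene_values + matrix(rnorm(n_genes * ns, sd = 0.5), n_genes, ns)
    probes <- rbind(p1, p2, p3)
    probe_ids <- c(paste0(genes, "_p1"), paste0(genes, "_p2"),
                   paste0(genes, "_p3"))
    rownames(probes) <- probe_ids
    colnames(probes) <- sample_ids
    probe_info <- data.frame(probe_id = probe_ids,
                             gene = rep(genes, 3), stringsAsFactors = FALSE)
    rate <- c(rep(0.95, n_genes), rep(0.7, n_genes), rep(0.9, n_genes))
    low <- n_genes + sample.int(n_genes, max(0, round(frac_low_quality * n_genes)))
    rate[low] <- 0.3
    pacall <- matrix(runif(length(rate) * ns) < rate, length(rate), ns)
    dimnames(pacall) <- dimnames(probes)

    rna_sel <- donor %in% paste0("donor", seq_len(min(2L, n_donors)))
    rnaseq <- gene_values[, rna_sel, drop = FALSE] +
      matrix(rnorm(n_genes * sum(rna_sel), sd = 0.3), n_genes, sum(rna_sel))
    samples <- data.frame(sample_id = sample_ids, donor = donor,
                          region = NA_character_,
                          x = sample_coords[, 1], y = sample_coords[, 2],
                          z = sample_coords[, 3], stringsAsFactors = FALSE)
    list(probes = probes, probe_info = probe_info, pacall = pacall,
         rnaseq = rnaseq, samples = samples, gene_values = gene_values,
         best_probe = setNames(paste0(genes, "_p1"), genes))
  })
}

#' Generate annotation resources (categories, DEG lists, markers, stages)
#'
#' Random gene categories of varying size plus one category planted to equal
#' the truth's signal genes; up/down differential-expression lists (the down
#' list is seeded with signal genes so DEG enrichment has signal to find);
#' the truth's cell-type marker lists; and a positive genes x stages
#' expression matrix in which each stage-specific gene is elevated
#' `elevation`-fold in its stage.
#'
#' @param n_categories number of random categories (>= 1), in addition to the
#'   planted one.
#' @param size_range integer 2-vector of category sizes, within
#'   `[1, n_genes]`.
#' @param n_stages number of stages (Roman labels); must match
#'   `truth$stage_specific_genes` if present.
#' @param truth a [synthetic_truth()].
#' @param genes character gene universe.
#' @param seed integer RNG seed.
#' @param elevation fold-elevation of stage-specific genes.
#' @return list: `categories` (named list of gene sets, first is
#'   `planted_signal`), `deg` (list up/down), `markers`, `stage_matrix`,
#'   `stage_labels`.
#' @export
gen_annotations <- function(n_categories, size_range, n_stages, truth, genes,
                            seed = 1, elevation = 10) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(size_range) != 2L || size_range[1] < 1 ||
      size_range[2] > length(genes) || size_range[1] > size_range[2])
    stopf("`size_range` must lie within [1, n_genes]")
  check_scalar(n_categories, "n_categories", lower = 1, integerish = TRUE)
  withr::with_seed(seed, {
    sizes <- sample(seq.int(size_range[1], size_range[2]), n_categories,
                    replace = TRUE)
    cats <- lapply(sizes, function(s) sample(genes, s))
    names(cats) <- sprintf("CAT%03d", seq_len(n_categories))
    categories <- c(list(planted_signal = truth$signal_genes), cats)

    nonsig <- setdiff(genes, truth$signal_genes)
    n_core <- max(1L, round(0.7 * length(truth$signal_genes)))
    n_fill <- min(25L, length(nonsig) %/% 2L)
    down <- unique(c(sample(truth$signal_genes, n_core),
                     sample(nonsig, n_fill)))
    up <- sample(setdiff(nonsig, down), min(40L, length(nonsig) - n_fill))

    stages <- as.character(utils::as.roman(seq_len(n_stages)))
    mat <- matrix(exp(rnorm(length(genes) * n_stages, sd = 0.25)),
                  length(genes), n_stages,
                  dimnames = list(genes, stages))
    for (s in names(truth$stage_specific_genes)) {
      if (!s %in% stages) next
      g <- intersect(truth$stage_specific_genes[[s]], genes)
      mat[g, s] <- mat[g, s] * elevation
    }
    list(categories = categories, deg = list(up = up, down = down),
         markers = truth$marker_assignments, stage_matrix = mat,
         stage_labels = stages)
  })
}

#' Uniform random sample coordinates inside a voxel grid
#'
#' @param n number of coordinates.
#' @param grid_shape,voxel_size grid geometry.
#' @param seed integer RNG seed.
#' @return n x 3 matrix of mm coordinates.
#' @export
gen_sample_coords <- function(n, grid_shape = c(16, 16, 12), voxel_size = 3,
                              seed = 1) {
  withr::with_seed(seed, {
    lo <- 0
    hi <- (grid_shape - 1) * voxel_size
    cbind(x = runif(n, lo, hi[1]), y = runif(n, lo, hi[2]),
          z = runif(n, lo, hi[3]))
  })
}
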