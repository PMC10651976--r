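# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a finite numeric scalar", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  if (integerish && abs(x - round(x)) > 1e-8)
    stopf("`%s` must be an integer", name)
  invisible(x)
}

# derive a stage seed from a master seed; kept within 32-bit signed range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483587L) + 1L
}

#' Voxel-center coordinates of a 3D grid in millimetres
#'
#' Voxel `(i, j, k)` (1-based) is placed at `((i-1)*vs, (j-1)*vs, (k-1)*vs)`.
#' This is the affine convention used throughout the package: axis-aligned,
#' isotropic voxels, origin at the first voxel center.
#'
#' @param grid_shape integer vector of length 3, voxel dimensions.
#' @param voxel_size voxel edge length in mm.
#' @return numeric matrix `prod(grid_shape)` x 3 of voxel-center coordinates,
#'   in column-major (R array) order, columns `x`, `y`, `z`.
#' @export
voxel_coords <- function(grid_shape, voxel_size) {
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stopf("`grid_shape` must be 3 positive integers")
  check_scalar(voxel_size, "voxel_size", lower = 1e-12)
  idx <- as.matrix(expand.grid(
    x = seq_len(grid_shape[1]),
    y = seq_len(grid_shape[2]),
    z = seq_len(grid_shape[3])
  ))
  (idx - 1) * voxel_size
}
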