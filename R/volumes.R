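#' Grayscale voxel volume
#'
#' A 3D grid of scalar intensities with isotropic voxel spacing, the in-memory
#' form of a micro-CT scene. The first array index is the slice (z) axis,
#' the second the within-slice row (y), the third the column (x).
#'
#' @param data numeric 3D array, `dim = c(nz, ny, nx)`, all dimensions >= 1.
#' @param spacing voxel edge length (isotropic, length units), > 0.
#' @param name sample identifier.
#' @return An object of class `volume3d` with fields `data`, `spacing`, `name`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)))
#' dim(v$data)
#' @export
volume3d <- function(data, spacing = 1.0, name = "volume") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three grid dimensions must be >= 1")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("`spacing` must be a single finite value > 0")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = as.numeric(spacing),
                 name = as.character(name)),
            class = "volume3d")
}

#' Binary voxel volume
#'
#' A strictly binary (0/1) voxel grid: masks and extracted plant bodies.
#' Stored internally as a logical array; written to disk as 8-bit 0/255.
#'
#' @param data logical 3D array, or numeric array with values in \{0, 1\}
#'   (any nonzero value is treated as 1 only by the TIFF reader, not here).
#' @inheritParams volume3d
#' @return An object of class `binary_volume` (also `volume3d`).
#' @examples
#' b <- binary_volume(array(c(TRUE, FALSE), c(2, 2, 2)))
#' sum(b$data)
#' @export
binary_volume <- function(data, spacing = 1.0, name = "mask") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three grid dimensions must be >= 1")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1)))
      stop("`data` must be strictly binary (0/1)")
    d <- dim(data)
    data <- as.logical(data)
    dim(data) <- d
  }
  if (!is.logical(data)) stop("`data` must be logical or 0/1 numeric")
  if (anyNA(data)) stop("`data` must not contain NA")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("`spacing` must be a single finite value > 0")
  structure(list(data = data, spacing = as.numeric(spacing),
                 name = as.character(name)),
            class = c("binary_volume", "volume3d"))
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  kind <- if (inherits(x, "binary_volume")) "binary_volume" else "volume3d"
  cat(sprintf("<%s '%s'> %d x %d x %d voxels, spacing %g\n",
              kind, x$name, d[1], d[2], d[3], x$spacing))
  if (inherits(x, "binary_volume")) {
    cat(sprintf("  foreground: %d voxels (%.2f%%)\n", sum(x$data),
                100 * mean(x$data)))
  } else {
    cat(sprintf("  intensity range: [%g, %g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

is_binary_volume <- function(x) inherits(x, "binary_volume")

stopifnot_volume <- function(v) {
  if (!inherits(v, "volume3d")) stop("expected a volume3d or binary_volume")
  invisible(v)
}
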