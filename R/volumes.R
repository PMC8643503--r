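#' Signal volume container
#'
#' A `signal_volume` is a 3-D (scalar image) or 4-D (multi-volume series)
#' array of non-negative signal intensities on a regular grid, carrying the
#' voxel spacing and a 4x4 affine (voxel index to world mm, RAS convention).
#' It is the common currency between the phantom simulator, the estimators
#' and the NIfTI reader/writers.
#'
#' @param data Numeric 3-D or 4-D array of finite, non-negative values.
#' @param voxel_size_mm Numeric length-3 vector of positive voxel edge
#'   lengths in millimetres.
#' @param affine Optional 4x4 numeric matrix mapping voxel indices (0-based)
#'   to world coordinates; defaults to a diagonal scaling by `voxel_size_mm`.
#' @return An object of class `signal_volume`.
#' @export
signal_volume <- function(data, voxel_size_mm = c(2, 2, 2), affine = NULL) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) {
    stop("signal_volume data must be a 3-D or 4-D array, got ", nd, " dims")
  }
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data))) {
    stop("signal_volume data must be finite and non-missing")
  }
  if (any(data < 0)) {
    stop("signal_volume data must be non-negative (magnitude images)")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be three positive reals")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, affine = affine),
    class = "signal_volume"
  )
}

#' @export
print.signal_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<signal_volume> ", paste(d, collapse = " x "),
      " | voxel ", paste(signif(x$voxel_size_mm, 4), collapse = "x"), " mm",
      " | range [", signif(min(x$data), 4), ", ", signif(max(x$data), 4), "]\n",
      sep = "")
  invisible(x)
}

#' @export
dim.signal_volume <- function(x) dim(x$data)

## Spatial grid (first three dims) of a signal volume or array.
grid_shape <- function(x) {
  d <- if (inherits(x, "signal_volume")) dim(x$data) else dim(x)
  d[1:3]
}

## Stop unless a and b share a spatial grid.
check_same_grid <- function(a, b, what = "inputs") {
  if (!identical(grid_shape(a), grid_shape(b))) {
    stop(what, " are not on the same spatial grid: ",
         paste(grid_shape(a), collapse = "x"), " vs ",
         paste(grid_shape(b), collapse = "x"))
  }
  invisible(TRUE)
}

## Coerce a mask argument to a logical array matching a reference grid;
## NULL means "everywhere".
as_mask <- function(mask, ref) {
  shape <- grid_shape(ref)
  if (is.null(mask)) {
    return(array(TRUE, dim = shape))
  }
  m <- if (inherits(mask, "signal_volume")) mask$data else mask
  m <- array(as.logical(m), dim = dim(m))
  if (!identical(dim(m), shape)) {
    stop("mask grid ", paste(dim(m), collapse = "x"),
         " does not match volume grid ", paste(shape, collapse = "x"))
  }
  m[is.na(m)] <- FALSE
  m
}

#' Write a volume or map to NIfTI-1
#'
#' Scalar maps (plain arrays) and `signal_volume` objects are written as
#' compressed NIfTI-1. Logical masks are written as 0/1 unsigned 8-bit.
#'
#' @param x A `signal_volume`, numeric array, or logical mask array.
#' @param path Output path; conventionally ending in `.nii.gz`.
#' @param voxel_size_mm Voxel spacing used when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = c(2, 2, 2)) {
  if (inherits(x, "signal_volume")) {
    data <- x$data
    voxel_size_mm <- x$voxel_size_mm
  } else {
    data <- x
  }
  nd <- length(dim(data))
  attr(data, "pixdim") <- c(voxel_size_mm, rep(1, nd - 3))
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
    img <- RNifti::asNifti(data, datatype = "uint8")
  } else {
    img <- RNifti::asNifti(data, datatype = "double")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path Path to a NIfTI-1 file.
#' @param as One of `"signal"` (a [signal_volume], for acquired magnitude
#'   images), `"map"` (a bare numeric array, for derived parameter maps that
#'   may be negative), or `"mask"` (a logical array of non-zero voxels).
#' @return A `signal_volume`, numeric array, or logical array per `as`.
#' @export
read_volume <- function(path, as = c("signal", "map", "mask")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  data <- array(as.numeric(img), dim = dim(img))
  switch(as,
    signal = signal_volume(data, voxel_size_mm = vox),
    map    = data,
    mask   = array(data != 0, dim = dim(data))
  )
}
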