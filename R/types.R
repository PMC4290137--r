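#' Construct a 3D image volume
#'
#' The basic container for a scalar volume: a 3D array of intensities plus
#' voxel spacing and physical origin metadata. Intensities are kept exactly as
#' supplied (no implicit normalization), so raw-unit thresholds such as a
#' global lower bound of 200 keep their meaning; use
#' [normalize_intensity()] for an explicit affine rescale.
#'
#' @param data 3D numeric array; axis order is (x, y, z) with x fastest.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, physical offset in mm.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `origin` and `intensity_range` (the observed min/max).
#' @examples
#' v <- image_volume(array(runif(64), c(4, 4, 4)))
#' v$intensity_range
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all axes must have length >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers", call. = FALSE)
  storage.mode(data) <- "double"
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         intensity_range = range(data)),
    class = "image_volume"
  )
}

#' Construct a binary mask
#'
#' @param data 3D array coercible to 0/1 (logical or numeric).
#' @param spacing numeric length-3 voxel size in mm.
#' @return An object of class `binary_mask`; `data` is an integer 0/1 array.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (is.logical(data)) {
    d <- array(as.integer(data), dim(data))
  } else {
    if (!all(data %in% c(0, 1)))
      stop("mask values must be exactly 0 or 1", call. = FALSE)
    d <- array(as.integer(data), dim(data))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers", call. = FALSE)
  structure(list(data = d, spacing = spacing), class = "binary_mask")
}

#' Construct a level-set field
#'
#' The implicit contour representation: a scalar field whose sign encodes
#' inside (>= 0) versus outside, evolved by the segmentation PDE. When
#' `is_sdf` is `TRUE` the magnitude equals the Euclidean distance (in voxels)
#' to the zero level set.
#'
#' @param data 3D numeric array.
#' @param is_sdf logical, whether the field is in signed-distance form.
#' @return An object of class `levelset_field`.
#' @export
levelset_field <- function(data, is_sdf = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, is_sdf = isTRUE(is_sdf)),
            class = "levelset_field")
}

# internal: accept an object of class cls or a bare 3D array
as_field_data <- function(x, cls) {
  if (inherits(x, cls)) return(x$data)
  if (is.array(x) && length(dim(x)) == 3L) {
    storage.mode(x) <- "double"
    return(x)
  }
  stop(sprintf("expected a `%s` or a 3D array", cls), call. = FALSE)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume: %s voxels, spacing %s mm, intensity [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              x$intensity_range[1], x$intensity_range[2]))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %s voxels, %d foreground\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' @export
print.levelset_field <- function(x, ...) {
  cat(sprintf("levelset_field: %s voxels, %sSDF, %d interior voxels\n",
              paste(dim(x$data), collapse = "x"),
              if (x$is_sdf) "" else "not ", sum(x$data >= 0)))
  invisible(x)
}
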