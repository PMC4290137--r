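#' Read a 3D medical volume
#'
#' Reads NIfTI-1 (`.nii` / `.nii.gz`), NRRD (`.nrrd`) or a directory of
#' single-series DICOM slices into an [image_volume()]. Arrays are indexed
#' (i, j, k) for (x, y, z) with the first index fastest; voxel spacing is
#' taken from file metadata and defaults to 1 mm per axis when absent.
#'
#' DICOM slices are ordered by ImagePositionPatient projected on the slice
#' normal, falling back to InstanceNumber; a directory mixing several
#' SeriesInstanceUIDs is an error.
#'
#' @param path file (NIfTI/NRRD) or directory (DICOM).
#' @param format one of `"auto"`, `"nifti"`, `"nrrd"`, `"dicom_dir"`.
#' @return An [image_volume()].
#' @seealso [write_volume()], [write_mask()], [mip()]
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd", "dicom_dir")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_dir"
      else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
      else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else stop("cannot infer format of ", path,
                "; pass `format` explicitly", call. = FALSE)
  }
  switch(format,
    nifti = read_nifti_volume(path),
    nrrd = read_nrrd(path),
    dicom_dir = read_dicom_series(path)
  )
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))  # drop RNifti attributes
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    data <- array(data, dim(data)[1:3])
  if (length(dim(data)) != 3L)
    stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  spacing <- abs(hdr$pixdim[2:4])
  spacing[spacing <= 0] <- 1
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  image_volume(data, spacing = spacing, origin = origin)
}

#' Write a 3D volume to NIfTI or NRRD
#'
#' @param volume an [image_volume()].
#' @param path output path; format inferred from the extension unless given.
#' @param format `"auto"`, `"nifti"` or `"nrrd"`.
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (!inherits(volume, "image_volume")) stop("`volume` must be an image_volume",
                                              call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  if (format == "nrrd") return(invisible(write_nrrd(volume, path)))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write / read a binary mask
#'
#' Masks are stored as 8-bit volumes; [read_mask()] binarizes on reload
#' (any nonzero voxel is foreground), so a write/read cycle is voxel-exact.
#'
#' @param mask a [binary_mask()].
#' @param path output path (`.nii`, `.nii.gz` or `.nrrd`).
#' @param format `"auto"`, `"nifti"` or `"nrrd"`.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask",
                                           call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  if (format == "nrrd") {
    vol <- image_volume(array(as.double(mask$data), dim(mask$data)),
                        spacing = mask$spacing)
    return(invisible(write_nrrd(vol, path, type = "uint8")))
  }
  img <- RNifti::asNifti(array(as.double(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, format = c("auto", "nifti", "nrrd")) {
  vol <- read_volume(path, match.arg(format))
  binary_mask(vol$data != 0, spacing = vol$spacing)
}

#' Maximum intensity projection
#'
#' Projects a volume to 2D by taking the maximum along one axis — the
#' standard rendering for inspecting angiographic volumes, where the overall
#' shapes and paths of bright vessels are visible at a glance.
#'
#' @param volume an [image_volume()] (or [binary_mask()], projected as 0/1).
#' @param axis projection axis, 1, 2 or 3.
#' @return a 2D matrix over the two remaining axes, in order.
#' @export
mip <- function(volume, axis = 2) {
  data <- if (inherits(volume, "binary_mask")) volume$data
    else as_field_data(volume, "image_volume")
  if (!axis %in% 1:3) stop("`axis` must be 1, 2 or 3", call. = FALSE)
  apply(data, setdiff(1:3, axis), max)
}

#' Save a maximum intensity projection as PNG
#'
#' @param volume volume or mask to project.
#' @param path output `.png` path.
#' @param axis projection axis.
#' @return the path, invisibly.
#' @export
write_mip_png <- function(volume, path, axis = 2) {
  m <- mip(volume, axis)
  rng <- range(m)
  img <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  # rows of the PNG run along the second remaining axis
  png::writePNG(t(img)[rev(seq_len(ncol(img))), , drop = FALSE], path)
  invisible(path)
}
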