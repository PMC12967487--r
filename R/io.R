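# Volume I/O: NIfTI via RNifti, NRRD via the bundled codec. Inside the
# package, voxel centers sit at origin + (i - 0.5) * spacing; both NIfTI's
# affine translation and NRRD's "space origin" give the center of the first
# voxel, so half a voxel is shifted off on read and restored on write.

infer_volume_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else if (grepl("\\.nrrd$", lp)) "nrrd"
  else if (grepl("\\.dcm$", lp)) "dicom-rtstruct"
  else stop(sprintf("cannot infer volume format from '%s'; pass `format`", path),
            call. = FALSE)
}

read_volume <- function(path, format = NULL) {
  if (is.null(format) && file.exists(path)) format <- infer_volume_format(path)
  if (!is.null(format)) {
    format <- match.arg(format, c("nifti", "nrrd", "dicom-rtstruct"))
    if (format == "dicom-rtstruct")
      stop("DICOM RT-STRUCT ingestion is not supported by this build; convert the structure set to NIfTI or NRRD first",
           call. = FALSE)
  }
  if (!file.exists(path))
    stop(sprintf("cannot read volume: file '%s' does not exist", path),
         call. = FALSE)
  if (is.null(format)) format <- infer_volume_format(path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L)
      stop(sprintf("'%s': expected a 3-D volume, got %d dimensions", path,
                   length(dim(img))), call. = FALSE)
    spacing <- RNifti::pixdim(img)[1:3]
    aff <- RNifti::xform(img)
    origin <- aff[1:3, 4] - spacing / 2
    list(values = array(as.numeric(img), dim = dim(img)),
         geometry = grid_geometry(dim(img), spacing, origin))
  } else {
    nrrd_read(path)
  }
}

write_volume_nifti <- function(values, geometry, path, datatype) {
  img <- RNifti::asNifti(array(values, dim = geometry$shape))
  RNifti::pixdim(img) <- geometry$spacing
  aff <- diag(c(geometry$spacing, 1))
  aff[1:3, 4] <- geometry$origin + geometry$spacing / 2
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Load a binary structure mask from a volume file
#'
#' Reads a NIfTI (\code{.nii}/\code{.nii.gz}) or NRRD (\code{.nrrd}) volume and
#' coerces it to a binary occupancy mask by a nonzero test. Grid spacing and
#' origin are taken from the file header.
#'
#' @param path file to read.
#' @param format one of \code{"nifti"}, \code{"nrrd"},
#'   \code{"dicom-rtstruct"}; inferred from the extension when omitted.
#'   RT-STRUCT input is not supported by this build and errors with advice.
#' @param label structure name to attach, defaults to the file stem.
#' @return A \code{\link{structure_mask}}; loading an empty structure is an
#'   error, since targets and organs must have positive volume.
#' @export
load_mask <- function(path, format = NULL, label = NULL) {
  vol <- read_volume(path, format)
  if (is.null(label))
    label <- sub("\\.(nii(\\.gz)?|nrrd)$", "", basename(path), ignore.case = TRUE)
  structure_mask(vol$values != 0, vol$geometry, label = label)
}

#' Load a dose grid (Gy) from a volume file
#'
#' @inheritParams load_mask
#' @return A \code{\link{scalar_field}} with unit \code{"Gy"}.
#' @export
load_dose <- function(path, format = NULL) {
  vol <- read_volume(path, format)
  scalar_field(vol$values, vol$geometry, unit = "Gy")
}

#' Write a mask or scalar field to NIfTI or NRRD
#'
#' Masks are stored as uint8, scalar fields as double precision.
#'
#' @param x a \code{structure_mask} or \code{scalar_field}.
#' @param path destination; \code{.nii}/\code{.nii.gz} or \code{.nrrd}.
#' @param format inferred from the extension when omitted.
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, format = NULL) {
  if (is.null(format)) format <- infer_volume_format(path)
  format <- match.arg(format, c("nifti", "nrrd"))
  if (inherits(x, "structure_mask")) {
    if (format == "nifti")
      write_volume_nifti(as.integer(x$voxels), x$geometry, path, "uint8")
    else nrrd_write(x$voxels, x$geometry, path, type = "uint8")
  } else if (inherits(x, "scalar_field")) {
    if (format == "nifti")
      write_volume_nifti(x$values, x$geometry, path, "double")
    else nrrd_write(x$values, x$geometry, path, type = "double")
  } else stop("`x` must be a structure_mask or scalar_field", call. = FALSE)
  invisible(path)
}
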