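#' CT volume container
#'
#' A minimal container for a 3D grid of CT attenuation values in Hounsfield
#' units (HU) together with its voxel spacing. The third array axis is the
#' cranio-caudal axis; the most cranial (apical) slice is the last index,
#' matching the usual NIfTI convention of z increasing towards the head.
#'
#' @param values 3D numeric array of attenuation values (HU). Must be finite.
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm, all
#'   strictly positive.
#' @return An object of class `ct_volume`: a list with elements `values`
#'   and `spacing`.
#' @examples
#' vol <- ct_volume(array(-800, c(4, 4, 4)), spacing = c(1, 1, 1.25))
#' dim(vol)
#' @export
ct_volume <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array of HU values", call. = FALSE)
  }
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite (no NA/Inf)", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive voxel sizes in mm", call. = FALSE)
  }
  structure(list(values = values, spacing = spacing), class = "ct_volume")
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
    d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Read a CT volume from a NIfTI file
#'
#' Reads a 3D volume and its voxel spacing from a `.nii` or `.nii.gz` file.
#' Fails loudly if the header carries no usable spacing (non-positive pixdim),
#' since densitometry without physical spacing is not meaningful.
#'
#' @param path Path to a NIfTI file.
#' @return A [ct_volume].
#' @export
read_ct_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("unrecognized volume format (expected .nii or .nii.gz): ", path,
         call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr)) # drop nifti header attributes
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D volume, got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[seq_len(3L)]
  if (anyNA(sp) || any(sp <= 0)) {
    stop("volume has no usable spacing metadata (pixdim = ",
         paste(sp, collapse = ", "), ")", call. = FALSE)
  }
  ct_volume(arr, sp)
}

#' Write a CT volume to a NIfTI file
#'
#' @param volume A [ct_volume].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask to a NIfTI file
#'
#' @param mask A [lung_mask] or logical 3D array.
#' @param spacing Voxel spacing in mm (taken from the mask's source volume by
#'   the caller).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, spacing, path) {
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  stopifnot(is.logical(m), length(dim(m)) == 3L)
  write_ct_volume(ct_volume(array(as.double(m), dim(m)), spacing), path)
}
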