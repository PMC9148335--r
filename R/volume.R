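#' 3D intensity volume
#'
#' Lightweight container for a skull-stripped, bias-corrected anatomical
#' volume: a 3D numeric array plus voxel spacing in mm and an orientation tag.
#' Grid axes follow a fixed anatomical convention: axis 1 indexes sagittal
#' slices (left-right), axis 2 coronal slices (posterior-anterior) and axis 3
#' axial slices (inferior-superior).
#'
#' @param voxels 3D numeric array of intensities (finite values only).
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param orientation axis-order tag; volumes are held in a canonical
#'   RAS-like order, so this is `"RAS"` unless a caller constructs otherwise.
#' @return An object of class `idseg_volume`.
#' @export
volume3d <- function(voxels, spacing = c(1, 1, 1), orientation = "RAS") {
  if (length(dim(voxels)) != 3L) stop("expected 3D volume")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (mm)")
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("voxels must be finite (no NaN/Inf)")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 orientation = orientation),
            class = "idseg_volume")
}

#' Integer label map
#'
#' Structure mask aligned to an [volume3d()] grid. The default label set codes
#' 0 = background, 1 = left hippocampus, 2 = right hippocampus,
#' 3 = left amygdala, 4 = right amygdala.
#'
#' @param codes 3D integer array of label codes.
#' @param label_set allowed codes (must include every value present).
#' @param spacing voxel spacing in mm.
#' @return An object of class `idseg_labels`.
#' @export
label_map <- function(codes, label_set = 0:4, spacing = c(1, 1, 1)) {
  if (length(dim(codes)) != 3L) stop("expected 3D label map")
  storage.mode(codes) <- "integer"
  if (!all(unique(as.vector(codes)) %in% label_set))
    stop("label map contains codes outside label_set")
  structure(list(codes = codes, label_set = as.integer(label_set),
                 spacing = as.numeric(spacing)),
            class = "idseg_labels")
}

#' @export
print.idseg_volume <- function(x, ...) {
  cat(sprintf("<idseg_volume> %s voxels, spacing %s mm, %s\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              x$orientation))
  invisible(x)
}

#' @export
print.idseg_labels <- function(x, ...) {
  tab <- table(factor(as.vector(x$codes), levels = x$label_set))
  cat(sprintf("<idseg_labels> %s voxels, labels {%s}\n",
              paste(dim(x$codes), collapse = "x"),
              paste(x$label_set, collapse = ",")))
  print(tab)
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' Loads a `.nii`/`.nii.gz` file, reorients the data grid to the canonical
#' RAS-like axis order, and validates the header. 4D inputs and non-positive
#' spacings are rejected.
#'
#' @param path path to a NIfTI file.
#' @param labels logical; read as an integer label map instead of intensities.
#' @param label_set allowed codes when `labels = TRUE`.
#' @return An [volume3d()] object, or [label_map()] when `labels = TRUE`.
#' @export
load_volume <- function(path, labels = FALSE, label_set = 0:4) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  suppressWarnings(try(RNifti::orientation(img) <- "RAS", silent = TRUE))
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim(arr))   # drop NIfTI attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L) stop("expected 3D volume, got ",
                                   length(dim(arr)), "D")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) stop("non-positive voxel spacing")
  if (labels) label_map(round(arr), label_set = label_set, spacing = sp)
  else volume3d(arr, spacing = sp)
}

#' Write a volume or label map to NIfTI
#'
#' @param x an `idseg_volume` or `idseg_labels`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(x, path) {
  arr <- if (inherits(x, "idseg_labels")) x$codes else x$voxels
  # qfac +1 with an identity quaternion encodes the canonical RAS order
  hdr <- list(pixdim = c(1, x$spacing, 0, 0, 0, 0), qform_code = 2L,
              quatern_b = 0, quatern_c = 0, quatern_d = 0,
              qoffset_x = 0, qoffset_y = 0, qoffset_z = 0)
  img <- RNifti::asNifti(arr, reference = hdr,
                         datatype = if (inherits(x, "idseg_labels"))
                           "int16" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Z-score intensity normalization
#'
#' Standardizes intensities to zero mean and unit standard deviation over the
#' nonzero-mask region (or the whole volume when no mask is given). Values
#' outside the mask are scaled with the same affine map so relative contrast
#' is preserved.
#'
#' @param vol an [volume3d()] object.
#' @param mask optional `idseg_labels` (or logical/integer array) on the same
#'   grid; normalization statistics are computed where the mask is nonzero.
#' @return A normalized `idseg_volume`.
#' @export
normalize_intensity <- function(vol, mask = NULL) {
  stopifnot(inherits(vol, "idseg_volume"))
  v <- vol$voxels
  if (is.null(mask)) {
    sel <- rep(TRUE, length(v))
  } else {
    m <- if (inherits(mask, "idseg_labels")) mask$codes else mask
    if (!identical(dim(m), dim(v))) stop("mask grid mismatch")
    sel <- as.vector(m) != 0
    if (!any(sel)) stop("mask is empty")
  }
  mu <- mean(v[sel])
  s <- sd(v[sel])
  if (!is.finite(s) || s == 0) stop("constant image: sd is zero")
  volume3d((v - mu) / s, spacing = vol$spacing, orientation = vol$orientation)
}
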