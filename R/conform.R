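#' Conform grid dimensions to a divisibility rule
#'
#' The multi-view network halves resolution four times, so every input axis
#' must be divisible by 16 (more generally, by `2^stages`). Axes are first
#' cropped to the largest smaller multiple, removing equal slabs from both
#' sides (the extra voxel comes off the high-index side when the remainder is
#' odd) -- but only when the removed slabs carry no foreground label and no
#' above-threshold intensity. Otherwise the axis is padded symmetrically with
#' the background value up to the next multiple. An invertible
#' `idseg_conform` record is returned alongside.
#'
#' @param vol an [volume3d()] object (intensities assumed normalized when the
#'   quiet-slab test is meaningful).
#' @param labels optional [label_map()] on the same grid, conformed jointly.
#' @param divisor required divisor of every output axis (default 16).
#' @param quiet_tol absolute-intensity threshold below which a border slab
#'   counts as background and may be cropped (default 0.1).
#' @param background value used for padding (default 0, the post
#'   skull-strip background).
#' @param upsample if `TRUE`, axes that would be padded are instead
#'   trilinearly interpolated (nearest-neighbour for labels) up to the next
#'   multiple; the record is then not invertible and [restore_size()] refuses
#'   it.
#' @return `list(volume, labels, record)`; `labels` is `NULL` when not given.
#' @export
conform_size <- function(vol, labels = NULL, divisor = 16, quiet_tol = 0.1,
                         background = 0, upsample = FALSE) {
  stopifnot(inherits(vol, "idseg_volume"), divisor >= 1)
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "idseg_labels"))
    if (!identical(dim(labels$codes), dim(vol$voxels)))
      stop("labels grid mismatch")
  }
  v <- vol$voxels
  lab <- if (is.null(labels)) NULL else labels$codes
  orig <- dim(v)
  crop_lo <- crop_hi <- pad_lo <- pad_hi <- integer(3)
  scaled <- logical(3)

  slab_quiet <- function(arr, labarr, axis, idx) {
    if (length(idx) == 0) return(TRUE)
    sl <- switch(axis, `1` = arr[idx, , , drop = FALSE],
                 `2` = arr[, idx, , drop = FALSE],
                 `3` = arr[, , idx, drop = FALSE])
    if (max(abs(sl)) >= quiet_tol) return(FALSE)
    if (!is.null(labarr)) {
      ll <- switch(axis, `1` = labarr[idx, , , drop = FALSE],
                   `2` = labarr[, idx, , drop = FALSE],
                   `3` = labarr[, , idx, drop = FALSE])
      if (any(ll != 0)) return(FALSE)
    }
    TRUE
  }

  for (ax in 1:3) {
    n <- dim(v)[ax]
    r <- n %% divisor
    if (r == 0) next
    lo <- r %/% 2
    hi <- r - lo                       # odd remainder: extra voxel high side
    can_crop <- n > divisor &&
      slab_quiet(v, lab, ax, seq_len(lo)) &&
      slab_quiet(v, lab, ax, seq(n - hi + 1, n))
    if (can_crop) {
      keep <- seq(lo + 1, n - hi)
      v <- switch(ax, v[keep, , , drop = FALSE], v[, keep, , drop = FALSE],
                  v[, , keep, drop = FALSE])
      if (!is.null(lab))
        lab <- switch(ax, lab[keep, , , drop = FALSE],
                      lab[, keep, , drop = FALSE],
                      lab[, , keep, drop = FALSE])
      crop_lo[ax] <- lo; crop_hi[ax] <- hi
    } else if (upsample) {
      target <- n + (divisor - r)
      v <- resample_axis(v, ax, target, nearest = FALSE)
      if (!is.null(lab)) lab <- resample_axis(lab, ax, target, nearest = TRUE)
      scaled[ax] <- TRUE
    } else {
      p <- divisor - r
      lo_p <- p %/% 2
      hi_p <- p - lo_p
      v <- pad_axis(v, ax, lo_p, hi_p, background)
      if (!is.null(lab)) lab <- pad_axis(lab, ax, lo_p, hi_p, 0L)
      pad_lo[ax] <- lo_p; pad_hi[ax] <- hi_p
    }
  }
  record <- structure(list(crop_lo = as.integer(crop_lo),
                           crop_hi = as.integer(crop_hi),
                           pad_lo = as.integer(pad_lo),
                           pad_hi = as.integer(pad_hi),
                           scaled = scaled,
                           original_shape = as.integer(orig),
                           conformed_shape = as.integer(dim(v)),
                           divisor = as.integer(divisor)),
                      class = "idseg_conform")
  out_lab <- if (is.null(lab)) NULL else
    label_map(lab, label_set = labels$label_set, spacing = labels$spacing)
  list(volume = volume3d(v, spacing = vol$spacing,
                         orientation = vol$orientation),
       labels = out_lab, record = record)
}

pad_axis <- function(arr, axis, lo, hi, value) {
  d <- dim(arr)
  d2 <- d; d2[axis] <- d[axis] + lo + hi
  out <- array(value, d2)
  idx <- seq(lo + 1, lo + d[axis])
  switch(axis,
         out[idx, , ] <- arr,
         out[, idx, ] <- arr,
         out[, , idx] <- arr)
  out
}

# Linear (or nearest) resampling of one axis to `target` samples.
resample_axis <- function(arr, axis, target, nearest = FALSE) {
  n <- dim(arr)[axis]
  pos <- seq(1, n, length.out = target)  # voxel-center mapping
  if (nearest) {
    idx <- pmin(pmax(round(pos), 1L), n)
    return(switch(axis, arr[idx, , , drop = FALSE],
                  arr[, idx, , drop = FALSE], arr[, , idx, drop = FALSE]))
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  i0 <- pmin(floor(pos), n - 1)
  w <- pos - i0
  out <- a[i0, , , drop = FALSE] * (1 - w) + a[i0 + 1, , , drop = FALSE] * w
  aperm(out, order(perm))
}

#' @export
print.idseg_conform <- function(x, ...) {
  cat(sprintf("<idseg_conform> %s -> %s (divisor %d)\n",
              paste(x$original_shape, collapse = "x"),
              paste(x$conformed_shape, collapse = "x"), x$divisor))
  for (ax in 1:3)
    cat(sprintf("  axis %d: crop (%d,%d) pad (%d,%d)%s\n", ax,
                x$crop_lo[ax], x$crop_hi[ax], x$pad_lo[ax], x$pad_hi[ax],
                if (x$scaled[ax]) " [resampled]" else ""))
  invisible(x)
}

#' Serialize / read a conform record as a JSON sidecar
#'
#' @param record an `idseg_conform` record.
#' @param path JSON file path.
#' @return `path` (write) or the record (read).
#' @export
write_conform_record <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_conform_record
#' @export
read_conform_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$original_shape <- as.integer(x$original_shape)
  x$conformed_shape <- as.integer(x$conformed_shape)
  structure(x, class = "idseg_conform")
}

#' Invert a conform operation on a label map
#'
#' Removes the padding and re-inserts the cropped background slabs so the
#' label map returns to the original acquisition grid. Voxels that were
#' cropped away come back as background.
#'
#' @param labels an [label_map()] on the conformed grid.
#' @param record the `idseg_conform` record from [conform_size()].
#' @return A `idseg_labels` on the original grid.
#' @export
restore_size <- function(labels, record) {
  stopifnot(inherits(labels, "idseg_labels"),
            inherits(record, "idseg_conform"))
  if (any(record$scaled))
    stop("record used up-sampling; not invertible on label coordinates")
  lab <- labels$codes
  if (!identical(dim(lab), record$conformed_shape))
    stop("labels shape does not match record's conformed shape")
  for (ax in 1:3) {
    d <- dim(lab)[ax]
    keep <- seq(record$pad_lo[ax] + 1, d - record$pad_hi[ax])
    lab <- switch(ax, lab[keep, , , drop = FALSE],
                  lab[, keep, , drop = FALSE], lab[, , keep, drop = FALSE])
    lab <- pad_axis(lab, ax, record$crop_lo[ax], record$crop_hi[ax], 0L)
  }
  stopifnot(identical(dim(lab), record$original_shape))
  label_map(lab, label_set = labels$label_set, spacing = labels$spacing)
}

#' Extract the 2D slice stack for one anatomical view
#'
#' Slicing directions follow the canonical axis order: sagittal slices index
#' axis 1, coronal axis 2, axial axis 3. The result is a 3D array whose third
#' dimension is the slice index; [restack_slices()] inverts the operation.
#'
#' @param x an `idseg_volume`, `idseg_labels`, or plain 3D array.
#' @param view one of `"axial"`, `"coronal"`, `"sagittal"`.
#' @return 3D array `(H, W, n_slices)` with attribute `view`.
#' @export
extract_slices <- function(x, view) {
  arr <- if (inherits(x, "idseg_volume")) x$voxels
  else if (inherits(x, "idseg_labels")) x$codes else x
  perm <- view_perm(view)
  out <- aperm(arr, perm)
  attr(out, "view") <- view
  out
}

#' @rdname extract_slices
#' @param stack a slice stack from [extract_slices()].
#' @export
restack_slices <- function(stack, view = attr(stack, "view")) {
  perm <- view_perm(view)
  out <- aperm(stack, order(perm))
  attr(out, "view") <- NULL
  out
}

view_perm <- function(view) {
  switch(match.arg(view, c("axial", "coronal", "sagittal")),
         axial = c(1L, 2L, 3L),
         coronal = c(1L, 3L, 2L),
         sagittal = c(2L, 3L, 1L))
}
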