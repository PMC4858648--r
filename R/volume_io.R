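#' Construct an image volume
#'
#' A light container for a 3-D scalar intensity grid (e.g. the mean
#' echo-planar imaging volume of an fMRI series) together with its voxel
#' spacing. Texture analysis is performed slice-wise along the axial
#' (third) array axis.
#'
#' @param data 3-D numeric array of intensities (arbitrary MR units).
#' @param spacing numeric length-3, voxel size per axis in mm.
#' @param slice_axis integer, the array axis treated as the slice (axial)
#'   axis. Default 3.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), slice_axis = 3L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("all volume dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume intensities must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values", call. = FALSE)
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("`slice_axis` must be 1, 2 or 3", call. = FALSE)
  structure(list(data = data, spacing = spacing, slice_axis = slice_axis),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, slice axis ", x$slice_axis, "\n", sep = "")
  invisible(x)
}

#' Read a 3-D NIfTI volume
#'
#' Reads a NIfTI-1 scalar image and returns it as an [image_volume] with
#' spacing taken from the header. Intensities are returned unmodified.
#' A 4-D input is rejected: the pipeline operates on the 3-D mean volume
#' of the functional series, not on the series itself.
#'
#' @param path path to a NIfTI-1 file (.nii or .nii.gz).
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI-1 file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { dim(img) <- d[1:3]; d <- d[1:3] }
  if (length(d) != 3L)
    stop("expected a 3-D mean volume, got a ", length(d), "-D image: ", path,
         call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim = d), spacing = sp)
}

#' Write an [image_volume] (or mask array) as NIfTI-1
#'
#' @param volume an [image_volume], or a 3-D array (written with the given
#'   `spacing`).
#' @param path output path (.nii or .nii.gz).
#' @param spacing voxel spacing used when `volume` is a bare array.
#' @param datatype NIfTI datatype; "auto" lets RNifti choose (integer grids
#'   round-trip bit-exactly).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing = c(1, 1, 1), datatype = "auto") {
  if (inherits(volume, "image_volume")) {
    arr <- volume$data
    spacing <- volume$spacing
  } else {
    arr <- volume
  }
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a region-of-interest mask
#'
#' Binds a binary mask congruent with its volume to a subject, an ROI
#' identifier, and a class label. Labels are `"E"` (expected — true
#' functional activity), `"NE"` (non-expected) or `"UNLABELED"`.
#'
#' @param mask 3-D array, logical or 0/1, same shape as the volume it masks.
#' @param subject_id,roi_id opaque identifiers.
#' @param label one of "E", "NE", "UNLABELED".
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, subject_id, roi_id, label = "UNLABELED") {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3-D array", call. = FALSE)
  m <- mask != 0
  if (sum(m) < 1L) stop("ROI mask is empty (no voxels set)", call. = FALSE)
  label <- match.arg(label, c("E", "NE", "UNLABELED"))
  structure(list(mask = m, subject_id = as.character(subject_id),
                 roi_id = as.character(roi_id), label = label),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", x$roi_id, " (subject ", x$subject_id, ", label ", x$label,
      "): ", sum(x$mask), " voxels\n", sep = "")
  invisible(x)
}

#' Extract per-slice ROI patches
#'
#' Splits an ROI into one 2-D patch per axial slice it intersects. Each
#' patch carries the raw intensities of a tight bounding box around the
#' in-slice ROI pixels plus an `inside` flag marking exactly the ROI
#' pixels; outside pixels are never used in pair counting. The
#' decomposition is lossless: the union of inside pixels over patches is
#' the mask's voxel set.
#'
#' @param volume an [image_volume].
#' @param roi an [roi_mask] (or bare 3-D binary array) congruent with
#'   `volume`.
#' @return A list of patches, each a list with `slice_index`, `values`
#'   (2-D numeric) and `inside` (2-D logical).
#' @export
extract_patches <- function(volume, roi) {
  stopifnot(inherits(volume, "image_volume"))
  m <- if (inherits(roi, "roi_mask")) roi$mask else (roi != 0)
  if (!identical(dim(m), dim(volume$data)))
    stop("mask shape ", paste(dim(m), collapse = "x"),
         " does not match volume shape ",
         paste(dim(volume$data), collapse = "x"), call. = FALSE)
  if (sum(m) < 1L) stop("ROI mask is empty (no voxels set)", call. = FALSE)

  ax <- volume$slice_axis
  perm <- switch(ax, `1` = c(2L, 3L, 1L), `2` = c(1L, 3L, 2L), `3` = c(1L, 2L, 3L))
  dat <- aperm(volume$data, perm)
  msk <- aperm(m, perm)

  slices <- which(apply(msk, 3L, any))
  lapply(slices, function(s) {
    ins <- msk[, , s]
    rows <- range(which(rowSums(ins) > 0))
    cols <- range(which(colSums(ins) > 0))
    list(slice_index = s,
         values = dat[rows[1]:rows[2], cols[1]:cols[2], s, drop = TRUE],
         inside = ins[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE])
  })
}

#' Place the fixed control ("inactivity") ROIs
#'
#' Draws two rectangular control ROIs per subject in areas of no
#' functional activity, at a size and location fixed across subjects, and
#' labels them NE. These serve as ground-truth homogeneous regions.
#'
#' @param volume an [image_volume] defining the grid.
#' @param subject_ids character vector of subjects to place ROIs for.
#' @param centers list of two integer length-3 voxel centres (fixed across
#'   subjects).
#' @param size integer length-3 ROI extent in voxels; default one 5x5
#'   in-plane square on a single slice.
#' @return A list of [roi_mask] objects, two per subject, labelled `"NE"`.
#' @export
place_control_rois <- function(volume, subject_ids,
                               centers = list(c(16L, 16L, 10L), c(48L, 48L, 10L)),
                               size = c(5L, 5L, 1L)) {
  stopifnot(inherits(volume, "image_volume"))
  dims <- dim(volume$data)
  size <- as.integer(size)
  half_lo <- (size - 1L) %/% 2L
  half_hi <- size - 1L - half_lo
  boxes <- lapply(centers, function(ctr) {
    ctr <- as.integer(ctr)
    lo <- ctr - half_lo
    hi <- ctr + half_hi
    if (any(lo < 1L) || any(hi > dims))
      stop("control ROI at centre (", paste(ctr, collapse = ","),
           ") with size (", paste(size, collapse = ","),
           ") exceeds the volume bounds ", paste(dims, collapse = "x"),
           call. = FALSE)
    list(lo = lo, hi = hi)
  })
  out <- list()
  for (sid in subject_ids) {
    for (k in seq_along(boxes)) {
      b <- boxes[[k]]
      m <- array(FALSE, dims)
      m[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <- TRUE
      out[[length(out) + 1L]] <- roi_mask(m, subject_id = sid,
                                          roi_id = sprintf("%s_ctrl%d", sid, k),
                                          label = "NE")
    }
  }
  out
}

#' Read / write an ROI manifest
#'
#' The manifest is a CSV with columns `subject_id`, `roi_id`, `mask_path`,
#' `label` linking each ROI mask file to its identity and class.
#'
#' @param path CSV path.
#' @return `read_roi_manifest`: a data.frame with the four columns.
#' @export
read_roi_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "roi_id", "mask_path", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_roi_manifest
#' @param manifest data.frame with columns `subject_id`, `roi_id`,
#'   `mask_path`, `label`.
#' @export
write_roi_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
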