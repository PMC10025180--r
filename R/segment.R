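# bone_segmentation: grayscale volume -> two labelled periosteal bone masks,
# with detection of bone-on-bone bridging and a programmatic analogue of the
# operator's manual correction step.

#' Segmentation outcome record
#'
#' @param status `"auto_success"`, `"needs_manual"` or `"failed"`.
#' @param reason short explanation (e.g. `"bridged"`).
#' @param attempts attempt count.
#' @return object of class `segmentation_outcome`.
#' @export
segmentation_outcome <- function(status = c("auto_success", "needs_manual", "failed"),
                                 reason = "", attempts = 1L) {
  status <- match.arg(status)
  structure(list(status = status, reason = reason, attempts = as.integer(attempts)),
            class = "segmentation_outcome")
}

#' @export
print.segmentation_outcome <- function(x, ...) {
  cat(sprintf("segmentation: %s%s (attempt %d)\n", x$status,
              if (nzchar(x$reason)) paste0(" [", x$reason, "]") else "",
              x$attempts))
  invisible(x)
}

#' Segment mineralized bone from a grayscale volume
#'
#' Classifies voxels as mineralized bone by global thresholding: either a
#' fixed calibrated threshold or Otsu's method on the intensity histogram.
#'
#' @param volume a [volume_image()].
#' @param threshold `"otsu"` (default) or a single numeric threshold.
#' @return logical 3D array (`TRUE` = bone).
#' @export
segment_bone <- function(volume, threshold = "otsu") {
  stopifnot(inherits(volume, "volume_image"))
  t <- if (identical(threshold, "otsu")) {
    otsu_threshold(volume$values)
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    threshold
  } else stop("threshold must be \"otsu\" or a single number")
  mask <- volume$values > t
  if (!any(mask)) stop("no bone found")
  mask
}

#' Split a bone mask into the two articulating bones
#'
#' Labels the 26-connected components of the bone mask. Components smaller
#' than `minor_fraction` of the total bone volume (sesamoid-like satellites)
#' are discarded. Two major components are labelled by position along the
#' joint axis (the distal-most, i.e. lowest-index, component becomes the
#' metacarpal/distal bone) and the split succeeds automatically. A single
#' bridged component is returned unsplit with status `"needs_manual"` and
#' reason `"bridged"` — the situation arising from direct bony contact — and
#' should be passed to [apply_manual_split()].
#'
#' @param mask logical 3D bone mask.
#' @param grid the [grid_spec()] of the mask.
#' @param axis joint (scan) axis, 1-3; default 3.
#' @param minor_fraction components below this fraction of the bone volume
#'   are discarded (default 0.01).
#' @return list with elements `bones` (a [bone_pair_mask()], or `NULL` when
#'   manual splitting is needed), `outcome` (a [segmentation_outcome()]) and
#'   `bridged_mask` (the cleaned single-component mask when bridged).
#' @export
split_joint_bones <- function(mask, grid, axis = 3L, minor_fraction = 0.01) {
  stopifnot(inherits(grid, "grid_spec"))
  mask <- as_mask_array(mask)
  if (!any(mask)) stop("no bone found")
  labels <- label_components(mask, connectivity = 26L)
  sizes <- tabulate(labels[labels > 0L])
  major <- which(sizes >= minor_fraction * sum(sizes))
  if (length(major) == 0L) stop("no bone found")
  if (length(major) > 2L) stop("ambiguous joint")

  if (length(major) == 1L) {
    cleaned <- labels == major
    return(list(bones = NULL,
                outcome = segmentation_outcome("needs_manual", "bridged"),
                bridged_mask = cleaned))
  }

  centroid_along <- function(lab) {
    idx <- which(labels == lab, arr.ind = TRUE)
    mean(idx[, axis])
  }
  cent <- vapply(major, centroid_along, numeric(1))
  distal_lab <- major[which.min(cent)]
  proximal_lab <- major[which.max(cent)]
  bones <- bone_pair_mask(labels == distal_lab, labels == proximal_lab, grid)
  list(bones = bones,
       outcome = segmentation_outcome("auto_success"),
       bridged_mask = NULL)
}

#' Split a bridged bone mask with a coarse operator contour
#'
#' Programmatic analogue of the semi-manual correction step: bone voxels
#' inside the supplied contour become the distal bone (metacarpal head), the
#' remainder the proximal bone.
#'
#' @param mask logical 3D bone mask (typically the bridged component from
#'   [split_joint_bones()]).
#' @param contour logical 3D array marking the region of the distal bone
#'   (e.g. a stack of discs around the metacarpal head, or a half-space at
#'   the mid-joint plane).
#' @param grid the [grid_spec()] of the mask.
#' @return a [bone_pair_mask()].
#' @export
apply_manual_split <- function(mask, contour, grid) {
  mask <- as_mask_array(mask)
  contour <- as_mask_array(contour)
  if (!identical(dim(mask), dim(contour))) stop("contour dimensions differ")
  distal <- mask & contour
  proximal <- mask & !contour
  if (!any(distal) || !any(proximal)) stop("non-separating contour")
  bone_pair_mask(distal, proximal, grid)
}

#' Fill a bone mask to its periosteal envelope
#'
#' Morphological closing with a Euclidean ball (default radius 5 voxels)
#' followed by hole filling, so that trabecular voids and cysts inside the
#' cortex become part of the solid periosteal mask. The operation is
#' extensive (output contains input) and idempotent on its own output.
#'
#' @param mask logical 3D bone mask (non-empty).
#' @param closing_radius_vox closing ball radius in voxels.
#' @return logical 3D array.
#' @export
periosteal_mask <- function(mask, closing_radius_vox = 5) {
  mask <- as_mask_array(mask)
  if (!any(mask)) stop("empty bone mask")
  fill_holes(close_ball(mask, closing_radius_vox))
}
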