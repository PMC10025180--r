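#' Isotropic 3D grid specification
#'
#' Defines the sampling grid every stage of the pipeline works on: the number
#' of voxels per axis and the isotropic voxel size in millimetres. The third
#' axis is the scan axis (slice direction); the default voxel size of
#' 0.082 mm and the 330-slice stack ceiling match first-generation HR-pQCT
#' hand protocols.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 4).
#' @param voxel_size voxel edge length in mm (> 0). Default 0.082.
#' @return An object of class `grid_spec` with elements `shape` and
#'   `voxel_size`.
#' @examples
#' g <- grid_spec(c(64, 64, 48))
#' g$voxel_size
#' @export
grid_spec <- function(shape, voxel_size = 0.082) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 4L))
    stop("shape must be 3 integers, each >= 4")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels @ %g mm (extent %.2f x %.2f x %.2f mm)\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size,
              x$shape[1] * x$voxel_size, x$shape[2] * x$voxel_size,
              x$shape[3] * x$voxel_size))
  invisible(x)
}

#' 3D scalar image on an isotropic grid
#'
#' @param values 3D numeric array of finite values.
#' @param grid a [grid_spec()] whose shape matches `dim(values)`.
#' @return An object of class `volume_image` with elements `values` and `grid`.
#' @export
volume_image <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (!all(dim(values) == grid$shape))
    stop("dim(values) does not match grid shape")
  if (!all(is.finite(values)))
    stop("values must be finite")
  structure(list(values = values, grid = grid), class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("volume_image\n")
  print(x$grid)
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Labelled mask pair for the two articulating bones
#'
#' Holds the distal (metacarpal head) and proximal (phalangeal base) bone
#' masks on a shared grid. Masks must be disjoint; connectivity of each mask
#' is the caller's contract (single 26-connected component for valid
#' segmentations) and can be checked with `validate = TRUE`.
#'
#' @param distal,proximal logical 3D arrays of equal dimension.
#' @param grid the shared [grid_spec()].
#' @param validate check disjointness, non-emptiness and single-component
#'   connectivity (26-connectivity). Default TRUE.
#' @return An object of class `bone_pair_mask`.
#' @export
bone_pair_mask <- function(distal, proximal, grid, validate = TRUE) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!identical(dim(distal), dim(proximal)))
    stop("mask dimensions differ")
  if (!all(dim(distal) == grid$shape))
    stop("mask dimensions do not match grid")
  distal <- array(as.logical(distal), dim = grid$shape)
  proximal <- array(as.logical(proximal), dim = grid$shape)
  if (validate) {
    if (any(distal & proximal)) stop("bone masks overlap")
    if (!any(distal) || !any(proximal)) stop("bone mask empty")
    for (m in list(distal, proximal)) {
      if (n_components(m, connectivity = 26L) != 1L)
        stop("bone mask is not a single 26-connected component")
    }
  }
  structure(list(distal = distal, proximal = proximal, grid = grid),
            class = "bone_pair_mask")
}

#' @export
print.bone_pair_mask <- function(x, ...) {
  cat(sprintf("bone_pair_mask: distal %d voxels, proximal %d voxels\n",
              sum(x$distal), sum(x$proximal)))
  print(x$grid)
  invisible(x)
}

#' Convert a bone pair mask to an integer label volume
#'
#' 0 = background, 1 = distal bone, 2 = proximal bone.
#' @param bones a [bone_pair_mask()].
#' @return integer 3D array.
#' @export
as_label_volume <- function(bones) {
  stopifnot(inherits(bones, "bone_pair_mask"))
  lab <- array(0L, dim = bones$grid$shape)
  lab[bones$distal] <- 1L
  lab[bones$proximal] <- 2L
  lab
}

#' Build a bone pair mask from an integer label volume
#'
#' @param labels integer 3D array coded 0 (background), 1 (distal), 2
#'   (proximal).
#' @param grid the [grid_spec()] of the volume.
#' @param validate passed to [bone_pair_mask()].
#' @return a [bone_pair_mask()].
#' @export
from_label_volume <- function(labels, grid, validate = TRUE) {
  bone_pair_mask(labels == 1L, labels == 2L, grid, validate = validate)
}
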