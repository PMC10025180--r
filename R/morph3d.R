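# Low-level 3D morphology built on the exact squared Euclidean distance
# transform in src/edt.cpp. All radii are in voxel units here; mm conversion
# happens at the caller.

as_mask_array <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  array(as.logical(mask), dim = dim(mask))
}

#' Squared Euclidean distance transform
#'
#' Exact squared distance (voxel units) from every voxel centre to the
#' nearest `TRUE` voxel centre. Voxels outside the grid do not act as sites.
#'
#' @param sites logical 3D array of sites.
#' @return numeric 3D array of squared distances (`Inf` if no site exists).
#' @export
sq_edt <- function(sites) {
  sites <- as_mask_array(sites)
  array(cpp_sq_edt(sites, dim(sites)), dim = dim(sites))
}

#' Binary dilation, erosion and closing with a Euclidean ball
#'
#' Center-sampled Euclidean morphology: dilation keeps voxels whose centre
#' lies within `radius` of a foreground voxel centre; erosion keeps voxels
#' farther than `radius` from any background voxel centre (grid borders are
#' not treated as background); closing is dilation followed by erosion.
#'
#' @param mask logical 3D array.
#' @param radius ball radius in voxel units (>= 0).
#' @return logical 3D array.
#' @export
dilate_ball <- function(mask, radius) {
  mask <- as_mask_array(mask)
  if (radius < 0) stop("radius must be >= 0")
  if (!any(mask)) return(mask)
  sq_edt(mask) <= radius^2
}

#' @rdname dilate_ball
#' @export
erode_ball <- function(mask, radius) {
  mask <- as_mask_array(mask)
  if (radius < 0) stop("radius must be >= 0")
  if (!any(!mask)) return(mask)
  sq_edt(!mask) > radius^2
}

#' @rdname dilate_ball
#' @export
close_ball <- function(mask, radius) {
  erode_ball(dilate_ball(mask, radius), radius)
}

#' Connected-component labelling
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26 (default 26, the convention for bone masks).
#' @return integer 3D array; 0 = background, components numbered from 1 in
#'   first-voxel order.
#' @export
label_components <- function(mask, connectivity = 26L) {
  mask <- as_mask_array(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  array(cpp_label_components(mask, dim(mask), connectivity), dim = dim(mask))
}

n_components <- function(mask, connectivity = 26L) {
  max(label_components(mask, connectivity))
}

#' Fill internal cavities of a binary volume
#'
#' Background voxels not 6-connected to the grid border are converted to
#' foreground.
#'
#' @param mask logical 3D array.
#' @return logical 3D array containing `mask`.
#' @export
fill_holes <- function(mask) {
  mask <- as_mask_array(mask)
  array(cpp_fill_holes(mask, dim(mask)), dim = dim(mask))
}

#' Local thickness by maximal inscribed spheres
#'
#' For every foreground voxel, the diameter of the largest sphere that stays
#' inside the structure and covers (intersects) that voxel. The structure
#' boundary is sampled as the discrete 0.5-isosurface of the binary field:
#' a half-voxel-grid point is a boundary sample when at least half of the
#' voxels containing it are background (out-of-grid voxels count as
#' continuation of the volume, not background). Sphere centres are sampled on
#' the half-voxel grid with radii equal to the exact Euclidean distance to the
#' boundary samples, and a sphere covers a voxel when it intersects the
#' voxel's cube; all three ingredients are integer-exact in doubled
#' coordinates. A slab of any integer thickness measures exactly its
#' thickness in voxels (a one-voxel gap measures exactly one voxel), and
#' curved gaps are measured without the staircase bias of cube-corner
#' clipping.
#'
#' @param mask logical 3D array: the structure whose boundary bounds the
#'   spheres.
#' @param voxel_size voxel edge (mm); thickness is returned in these units.
#' @param domain optional logical 3D array restricting where spheres are
#'   centred and which voxels receive values (default: the mask itself, the
#'   plain local-thickness transform). The joint-space pipeline passes the
#'   full non-bone space as `mask` and the joint-space mask as `domain`, so
#'   spheres are bounded by bone only.
#' @return numeric 3D array of diameters, 0 outside `domain`.
#' @seealso [local_thickness_oracle()] for the brute-force reference used in
#'   the test-suite equivalence checks.
#' @export
local_thickness <- function(mask, voxel_size = 1, domain = NULL) {
  mask <- as_mask_array(mask)
  domain <- if (is.null(domain)) mask else as_mask_array(domain)
  stopifnot(identical(dim(mask), dim(domain)))
  array(cpp_local_thickness(mask, domain, dim(mask)), dim = dim(mask)) * voxel_size
}

#' Brute-force local thickness oracle
#'
#' Same semantics as [local_thickness()], computed by exhaustive enumeration
#' of sphere centres and boundary points (no distance transform, no sphere
#' painting). Intended for validation on small masks; cost grows with the
#' square of the mask volume.
#'
#' @inheritParams local_thickness
#' @return numeric 3D array of diameters, 0 outside `domain`.
#' @export
local_thickness_oracle <- function(mask, voxel_size = 1, domain = NULL) {
  mask <- as_mask_array(mask)
  domain <- if (is.null(domain)) mask else as_mask_array(domain)
  stopifnot(identical(dim(mask), dim(domain)))
  array(cpp_local_thickness_brute(mask, domain, dim(mask)),
        dim = dim(mask)) * voxel_size
}

#' Otsu threshold of a grayscale volume
#'
#' Maximizes between-class variance over a 256-bin histogram of the intensity
#' range. Used as the default bone segmentation threshold when no calibrated
#' fixed threshold is available.
#'
#' @param values numeric array or vector of intensities.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold intensity (a bin boundary).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  rng <- range(v)
  if (!all(is.finite(rng))) stop("non-finite intensities")
  if (rng[1] == rng[2]) stop("degenerate histogram")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  denom <- w0 * (1 - w0)
  between <- (mu_t * w0 - mu0)^2 / ifelse(denom > 0, denom, NA_real_)
  # empty bins between well-separated modes give a plateau of equal
  # between-class variance; take its midpoint
  top <- which(between >= max(between, na.rm = TRUE) - 1e-12)
  k <- round(mean(range(top)))
  breaks[k + 1L]
}

# Separable Gaussian blur with zero padding (background intensity 0).
gaussian_blur3d <- function(values, sigma_vox) {
  if (sigma_vox <= 0) return(values)
  half <- max(1L, ceiling(3 * sigma_vox))
  kern <- dnorm(seq(-half, half), sd = sigma_vox)
  kern <- kern / sum(kern)
  out <- values
  d <- dim(values)
  for (axis in 1:3) {
    acc <- array(0, dim = d)
    for (t in seq_along(kern)) {
      off <- t - half - 1L
      w <- kern[t]
      src_idx <- seq_len(d[axis]) + off
      ok <- src_idx >= 1L & src_idx <= d[axis]
      dst <- which(ok)
      src <- src_idx[ok]
      if (axis == 1L) {
        acc[dst, , ] <- acc[dst, , ] + w * out[src, , ]
      } else if (axis == 2L) {
        acc[, dst, ] <- acc[, dst, ] + w * out[, src, ]
      } else {
        acc[, , dst] <- acc[, , dst] + w * out[, , src]
      }
    }
    out <- acc
  }
  out
}
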