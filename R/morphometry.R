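# joint_space_morphometry: joint-space mask between the periosteal masks,
# the local JSW map, and the six summary parameters.

#' Build the joint-space mask between two bones
#'
#' The intra-articular space is recovered by morphological closing of the
#' union of the two periosteal masks with a bridging ball (default radius
#' 2.5 mm, large enough to bridge any anatomical joint gap), subtracting the
#' bones, and keeping the connected components adjacent to both bones. A
#' final restriction keeps only voxels that lie between the articulating
#' surfaces along the joint axis (distal bone on one side, proximal on the
#' other), which removes spurious wings at the lateral aperture of curved
#' joints.
#'
#' @param bones a [bone_pair_mask()] of periosteal masks.
#' @param closing_radius bridging ball radius in mm.
#' @param axis joint (scan) axis, 1-3; default 3 with the distal bone at the
#'   low-index end.
#' @return object of class `joint_space_mask`: list with `mask` (logical 3D),
#'   `grid`, and `ankylotic` (`TRUE` when the bones are in contact and no
#'   joint space voxel remains). An empty mask with disjoint, non-touching
#'   bones raises `"no joint space"`.
#' @export
build_joint_space_mask <- function(bones, closing_radius = 2.5, axis = 3L) {
  stopifnot(inherits(bones, "bone_pair_mask"))
  h <- bones$grid$voxel_size
  u <- bones$distal | bones$proximal
  closed <- close_ball(u, closing_radius / h)
  candidate <- closed & !u

  touching <- any(dilate_ball(bones$distal, sqrt(3) + 1e-9) & bones$proximal)


  if (any(candidate)) {
    # keep components adjacent (26-connectivity) to both bones
    labels <- label_components(candidate, connectivity = 26L)
    near_d <- dilate_ball(bones$distal, sqrt(3) + 1e-9)
    near_p <- dilate_ball(bones$proximal, sqrt(3) + 1e-9)
    keep <- intersect(unique(labels[near_d & candidate]),
                      unique(labels[near_p & candidate]))
    keep <- setdiff(keep, 0L)
    mask <- array(labels %in% keep, dim = dim(candidate))
    # betweenness along the joint axis: distal bone below, proximal above
    mask <- mask & between_along_axis(bones$distal, bones$proximal, axis)
  } else {
    mask <- candidate
  }

  if (!any(mask)) {
    if (touching)
      return(structure(list(mask = mask, structure = !u, channel = mask,
                            grid = bones$grid, ankylotic = TRUE),
                       class = "joint_space_mask"))
    stop("no joint space")
  }
  # centre domain for the width spheres: non-bone voxels near the joint-space
  # mask. A sphere covering a mask voxel is centred within about half the
  # local width of it, so half the bridging radius bounds all useful centres
  # (in particular those lying radially outside the head footprint near the
  # joint equator); distant free-space spheres cannot see joint-space voxels
  # past the interposed bone and are skipped for cost.
  channel <- (!u) & dilate_ball(mask, closing_radius / (2 * h))
  structure(list(mask = mask, structure = !u, channel = channel,
                 grid = bones$grid, ankylotic = FALSE),
            class = "joint_space_mask")
}

# voxels with some distal bone at lower index and proximal bone at higher
# index along `axis`
between_along_axis <- function(distal, proximal, axis) {
  d <- dim(distal)
  perm <- c(setdiff(1:3, axis), axis)
  dd <- aperm(distal, perm); pp <- aperm(proximal, perm)
  n3 <- dim(dd)[3]
  below <- dd
  for (k in seq_len(n3)[-1]) below[, , k] <- below[, , k] | below[, , k - 1]
  above <- pp
  for (k in rev(seq_len(n3)[-n3])) above[, , k] <- above[, , k] | above[, , k + 1]
  aperm(below & above, order(perm))
}

#' Compute the local joint-space-width map
#'
#' Each joint-space voxel is assigned the diameter (mm) of the largest sphere
#' that fits between the bone surfaces and covers the voxel —
#' maximal-inscribed-sphere local thickness over the Euclidean distance
#' transform (see [local_thickness()] for the exact discrete semantics).
#' Spheres are bounded by bone only: they live in the full non-bone space of
#' the volume, with centres restricted to the articulating channel (non-bone
#' voxels between the two bones along the joint axis), so neither the
#' artificial lateral cut of the joint-space mask nor free space outside the
#' joint distorts the measurement. Values are reported on the joint-space
#' mask. A hand-built `space` object without `structure`/`channel` elements
#' falls back to measuring the mask itself.
#'
#' @param space a [build_joint_space_mask()] result with a non-empty mask.
#' @return object of class `jsw_map`: list with `values` (numeric 3D array,
#'   mm; 0 outside the mask), `mask`, `grid`.
#' @export
compute_jsw_map <- function(space) {
  stopifnot(inherits(space, "joint_space_mask"))
  if (!any(space$mask)) stop("empty joint space")
  structure_mask <- if (is.null(space$structure)) space$mask else space$structure
  centre_domain <- if (is.null(space$channel)) space$mask else space$channel
  values <- local_thickness(structure_mask, voxel_size = space$grid$voxel_size,
                            domain = centre_domain)
  values[!space$mask] <- 0
  structure(list(values = values, mask = space$mask, grid = space$grid),
            class = "jsw_map")
}

#' Summarize a JSW map into the six joint-space parameters
#'
#' Computes joint space volume `jsv` (exact voxel count times voxel volume,
#' mm^3), mean width `jsw` and its population SD `jsw_sd` (mm), extrema
#' `jsw_min`/`jsw_max` (mm), and the width asymmetry `jsw_as =
#' jsw_max / jsw_min`. When the joint is ankylotic (bones in contact) the
#' `ankylotic` flag is set and `jsw_as` is reported as `NA`; downstream
#' statistics exclude flagged joints.
#'
#' @param map a [compute_jsw_map()] result (or `NULL` for an ankylotic joint).
#' @param space the corresponding [build_joint_space_mask()] result.
#' @param ankylotic_contact set when segmentation detected bony contact.
#' @param robust_min report the 0.1th percentile of the map instead of the
#'   absolute minimum (off by default: published JSW.MIN values go down to a
#'   single voxel, implying no trimming).
#' @return object of class `joint_morphometry` (also a one-row data.frame)
#'   with columns `jsv`, `jsw`, `jsw_sd`, `jsw_min`, `jsw_max`, `jsw_as`,
#'   `ankylotic`.
#' @export
summarize_morphometry <- function(map, space, ankylotic_contact = FALSE,
                                  robust_min = FALSE) {
  stopifnot(inherits(space, "joint_space_mask"))
  h <- space$grid$voxel_size
  if (is.null(map) || !any(space$mask)) {
    if (!space$ankylotic && !ankylotic_contact) stop("empty joint space")
    out <- data.frame(jsv = 0, jsw = NA_real_, jsw_sd = NA_real_,
                      jsw_min = NA_real_, jsw_max = NA_real_,
                      jsw_as = NA_real_, ankylotic = TRUE)
    class(out) <- c("joint_morphometry", class(out))
    return(out)
  }
  stopifnot(inherits(map, "jsw_map"))
  v <- map$values[space$mask]
  n <- length(v)
  # robust variant: discard the lowest 0.1% of map voxels before the minimum
  jsw_min <- if (robust_min) sort(v)[floor(0.001 * n) + 1] else min(v)
  ank <- isTRUE(ankylotic_contact) || isTRUE(space$ankylotic) || jsw_min <= 0
  out <- data.frame(
    jsv = n * h^3,
    jsw = mean(v),
    jsw_sd = sqrt(sum((v - mean(v))^2) / n),   # population SD of the map
    jsw_min = jsw_min,
    jsw_max = max(v),
    jsw_as = if (ank || jsw_min <= 0) NA_real_ else max(v) / jsw_min,
    ankylotic = ank)
  class(out) <- c("joint_morphometry", class(out))
  out
}

#' Run the full morphometry chain on a segmented bone pair
#'
#' Convenience wrapper: periosteal filling of both masks, joint-space mask,
#' JSW map and the six summary parameters.
#'
#' @param bones a [bone_pair_mask()].
#' @param closing_radius bridging radius (mm) for the joint-space mask.
#' @param periosteal_radius_vox closing radius (voxels) for periosteal
#'   filling.
#' @param axis joint axis (1-3).
#' @param ankylotic_contact flag from segmentation (bridged bones).
#' @param robust_min see [summarize_morphometry()].
#' @return list with `bones` (periosteal-filled), `space`, `map` (`NULL` for
#'   ankylotic joints) and `morphometry`.
#' @export
measure_joint <- function(bones, closing_radius = 2.5,
                          periosteal_radius_vox = 5, axis = 3L,
                          ankylotic_contact = FALSE, robust_min = FALSE) {
  stopifnot(inherits(bones, "bone_pair_mask"))
  peri <- bone_pair_mask(periosteal_mask(bones$distal, periosteal_radius_vox),
                         periosteal_mask(bones$proximal, periosteal_radius_vox) &
                           !periosteal_mask(bones$distal, periosteal_radius_vox),
                         bones$grid, validate = FALSE)
  space <- build_joint_space_mask(peri, closing_radius = closing_radius, axis = axis)
  map <- if (any(space$mask)) compute_jsw_map(space) else NULL
  morph <- summarize_morphometry(map, space, ankylotic_contact = ankylotic_contact,
                                 robust_min = robust_min)
  list(bones = peri, space = space, map = map, morphometry = morph)
}
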