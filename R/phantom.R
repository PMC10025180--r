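# phantom_forge: synthetic articulating bone pairs with analytic ground truth.
#
# All geometry is defined in mm; voxelization is by center sampling (a voxel
# is bone iff its centre lies inside the analytic solid). Voxel centres sit at
# (i - 0.5) * voxel_size for 1-based index i, so integer voxel planes are the
# natural anchors: a plate gap anchored at a voxel plane discretizes a gap of
# g mm into round(g/h) one-voxel layers.

#' Osteophyte specification
#'
#' A hook-like bony outgrowth at a joint rim, modelled as a cone attached at a
#' rim point and tilted towards the opposing bone.
#'
#' @param bone `"distal"` (metacarpal head) or `"proximal"` (phalangeal base).
#' @param angle_deg position on the rim, degrees around the joint axis.
#' @param length spike length in mm (>= 0; 0 disables it).
#' @param base_width base diameter in mm (> 0 when `length > 0`).
#' @return An object of class `osteophyte_spec`.
#' @export
osteophyte_spec <- function(bone = c("distal", "proximal"), angle_deg = 0,
                            length = 0.5, base_width = 0.5) {
  bone <- match.arg(bone)
  if (length < 0) stop("osteophyte length must be >= 0")
  if (length > 0 && base_width <= 0) stop("base_width must be > 0")
  structure(list(bone = bone, angle_deg = angle_deg, length = length,
                 base_width = base_width), class = "osteophyte_spec")
}

#' Phantom specification
#'
#' Parameters of a synthetic two-bone joint phantom. Four geometries are
#' supported: `parallel_plate` (two slabs spanning the full lateral grid
#' cross-section, constant gap), `tilted_plate` (upper slab tilted so the gap
#' varies linearly across the first axis), `ball_and_cup` (convex metacarpal
#' head articulating with a concave hemispherical cup, optionally offset
#' along the joint axis) and `contact_patch` (a parallel plate pair whose gap
#' is bridged by bone over a central patch covering `contact_fraction` of the
#' facing area).
#'
#' @param geometry one of `"parallel_plate"`, `"tilted_plate"`,
#'   `"ball_and_cup"`, `"contact_patch"`.
#' @param gap joint-space gap in mm (>= 0). For `ball_and_cup` the concentric
#'   gap is `cup_radius - head_radius` and `gap` is ignored.
#' @param tilt_slope gap change in mm per mm along the first axis
#'   (`tilted_plate` only).
#' @param head_radius,cup_radius metacarpal head and cup cavity radii in mm
#'   (`ball_and_cup`; requires `cup_radius > head_radius`).
#' @param center_offset displacement of the cup cavity centre towards the head
#'   along the joint axis, mm; narrows the gap at the pole to
#'   `cup_radius - head_radius - center_offset`.
#' @param contact_fraction fraction in `[0, 1]` of the articulating area
#'   bridged by direct bony contact.
#' @param osteophytes list of [osteophyte_spec()] (ball-and-cup only).
#' @param blur_fwhm Gaussian blur FWHM in mm emulating the scanner point
#'   spread (default 0.130 mm, the effective spatial resolution of HR-pQCT);
#'   0 disables blurring.
#' @param noise_sd additive Gaussian noise SD in intensity units (bone = 1).
#' @param seed integer seed for the noise generator.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("parallel_plate", "tilted_plate",
                                      "ball_and_cup", "contact_patch"),
                         gap = 1.0, tilt_slope = 0.1,
                         head_radius = 5.0, cup_radius = 6.0,
                         center_offset = 0, contact_fraction = 0,
                         osteophytes = list(),
                         blur_fwhm = 0, noise_sd = 0, seed = 1L) {
  geometry <- match.arg(geometry)
  if (gap < 0) stop("gap must be >= 0")
  if (geometry == "ball_and_cup" && cup_radius <= head_radius)
    stop("invalid ball-and-cup: cup_radius must exceed head_radius")
  if (contact_fraction < 0 || contact_fraction > 1)
    stop("contact_fraction must be in [0, 1]")
  if (blur_fwhm < 0) stop("blur_fwhm must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(all(vapply(osteophytes, inherits, logical(1), "osteophyte_spec")))
  if (length(osteophytes) > 0 && geometry != "ball_and_cup")
    stop("osteophytes are only supported for ball_and_cup geometry")
  structure(list(geometry = geometry, gap = gap, tilt_slope = tilt_slope,
                 head_radius = head_radius, cup_radius = cup_radius,
                 center_offset = center_offset,
                 contact_fraction = contact_fraction,
                 osteophytes = osteophytes,
                 blur_fwhm = blur_fwhm, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

voxel_centers <- function(n, h) (seq_len(n) - 0.5) * h

# analytic mean gap over the articulating hemispherical cap for an
# axially offset ball-and-cup (area-weighted, t = cos(theta) uniform on (0,1])
ball_cup_mean_gap <- function(Rh, Rc, delta) {
  if (delta == 0) return(Rc - Rh)
  Rc - ((Rh + delta)^3 - (Rh^2 + delta^2)^1.5) / (3 * Rh * delta)
}

ball_cup_gap_theta <- function(Rh, Rc, delta, theta) {
  Rc - sqrt(Rh^2 + delta^2 + 2 * Rh * delta * cos(theta))
}

#' Generate a synthetic joint phantom
#'
#' Builds the grayscale volume (bone = 1, background = 0, optionally blurred
#' and degraded with Gaussian noise), the exact ground-truth bone masks and
#' the analytic gap statistics. With `blur_fwhm = 0` and `noise_sd = 0`,
#' thresholding the volume at 0.5 reproduces the ground-truth masks exactly.
#'
#' @param spec a [phantom_spec()].
#' @param grid a [grid_spec()]; the joint axis is the third (scan) axis and
#'   the distal bone (metacarpal) occupies the low-index end.
#' @return An object of class `joint_phantom`: a list with elements `volume`
#'   (a [volume_image()]), `bones` (the ground-truth [bone_pair_mask()]),
#'   `truth` (analytic gap statistics: `jsw_min`, `jsw_mean`, `jsw_max` in mm,
#'   `contact` flag, and `gap_field(x, y)` giving the local gap over the
#'   articulating region), plus the generating `spec` and `grid`.
#' @examples
#' ph <- make_phantom(phantom_spec("parallel_plate", gap = 0.984),
#'                    grid_spec(c(24, 24, 40)))
#' ph$truth$jsw_mean
#' @export
make_phantom <- function(spec, grid) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "grid_spec"))
  h <- grid$voxel_size
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]

  built <- switch(spec$geometry,
    parallel_plate = build_plates(spec, grid, tilted = FALSE),
    contact_patch  = build_plates(spec, grid, tilted = FALSE),
    tilted_plate   = build_plates(spec, grid, tilted = TRUE),
    ball_and_cup   = build_ball_cup(spec, grid))

  distal <- built$distal
  proximal <- built$proximal
  truth <- built$truth
  truth$contact <- isTRUE(truth$jsw_min <= 0)
  class(truth) <- "ground_truth"

  vol <- array(0, dim = grid$shape)
  vol[distal | proximal] <- 1.0
  if (spec$blur_fwhm > 0)
    vol <- gaussian_blur3d(vol, spec$blur_fwhm / (2 * sqrt(2 * log(2))) / h)
  if (spec$noise_sd > 0)
    vol <- withr::with_seed(spec$seed,
      vol + array(rnorm(length(vol), sd = spec$noise_sd), dim = dim(vol)))

  structure(list(
    volume = volume_image(vol, grid),
    bones = bone_pair_mask(distal, proximal, grid),
    truth = truth,
    spec = spec, grid = grid), class = "joint_phantom")
}

# two slabs along the scan axis spanning the full lateral cross-section;
# gap anchored at a voxel plane so integer-voxel gaps discretize exactly
build_plates <- function(spec, grid, tilted) {
  h <- grid$voxel_size
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  m <- ceiling(spec$gap / h - 0.5)          # gap layers
  if (m > nz - 4) stop("phantom exceeds grid")
  K <- floor((nz - m) / 2)                  # distal plate = layers 1..K
  if (K < 2 || nz - K - m < 2) stop("phantom exceeds grid")
  z_lo <- K * h                             # top of the distal plate (mm)

  xc <- voxel_centers(nx, h); yc <- voxel_centers(ny, h); zc <- voxel_centers(nz, h)
  cx <- nx * h / 2; cy <- ny * h / 2

  if (!tilted) {
    gap_at <- function(x, y) rep(spec$gap, length(x))
  } else {
    gap_at <- function(x, y) pmax(0, spec$gap + spec$tilt_slope * (x - cx))
  }

  distal <- array(FALSE, grid$shape)
  proximal <- array(FALSE, grid$shape)
  distal[, , seq_len(K)] <- TRUE
  gx <- outer(gap_at(xc, 0), rep(1, ny))    # gap depends on x only
  for (k in (K + 1):nz)
    proximal[, , k] <- zc[k] >= z_lo + gx
  # contact patch: central cylinder of the facing area bridged by bone
  contact_area <- 0
  if (spec$contact_fraction > 0 && m > 0) {
    A <- (nx * h) * (ny * h)
    rho <- sqrt(spec$contact_fraction * A / pi)
    lat2 <- outer((xc - cx)^2, (yc - cy)^2, "+")
    # central disc of the facing area; full contact bridges everything (a
    # disc of area A would otherwise be clipped at the square boundary)
    patch <- if (spec$contact_fraction >= 1) lat2 >= 0 else lat2 <= rho^2
    mid <- K + m / 2
    for (k in (K + 1):(K + m)) {
      sel <- patch & !(distal[, , k] | proximal[, , k])
      if (k <= mid) distal[, , k] <- distal[, , k] | sel
      else proximal[, , k] <- proximal[, , k] | sel
    }
    contact_area <- spec$contact_fraction
  }

  if (!tilted) {
    g <- spec$gap
    truth <- list(jsw_min = if (contact_area > 0 || m == 0) 0 else g,
                  jsw_mean = (1 - contact_area) * g,
                  jsw_max = g,
                  gap_field = function(x, y) gap_at(x, y))
  } else {
    gvals <- gap_at(xc, 0)
    truth <- list(jsw_min = min(gvals), jsw_mean = mean(gvals),
                  jsw_max = max(gvals),
                  gap_field = function(x, y) gap_at(x, y))
  }
  list(distal = distal, proximal = proximal, truth = truth)
}

# convex head (sphere + shaft) below, concave cup above; cavity centre offset
# towards the head narrows the polar gap
build_ball_cup <- function(spec, grid) {
  h <- grid$voxel_size
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  Rh <- spec$head_radius; Rc <- spec$cup_radius; delta <- spec$center_offset
  wall <- max(2 * h, 0.15 * Rc)             # cup wall / backing thickness
  Rout <- Rc + wall

  margin <- 2 * h
  if (2 * Rout + 2 * margin > nx * h || 2 * Rout + 2 * margin > ny * h)
    stop("phantom exceeds grid")
  cx <- nx * h / 2; cy <- ny * h / 2
  # head centre: head sphere below, cup + backing above, both inside margins
  # (the supporting shaft intentionally runs to the bottom of the stack, like
  # a metacarpal shaft leaving the scan region)
  cz_lo <- Rh + margin
  cz_hi <- nz * h - margin - (Rc + wall - delta)
  if (cz_lo > cz_hi) stop("phantom exceeds grid")
  cz <- (cz_lo + cz_hi) / 2

  xc <- voxel_centers(nx, h); yc <- voxel_centers(ny, h); zc <- voxel_centers(nz, h)
  dx2 <- (xc - cx)^2
  dy2 <- (yc - cy)^2
  lat2 <- outer(dx2, dy2, "+")              # nx x ny

  czc <- cz - delta                          # cavity centre (on the joint axis)
  distal <- array(FALSE, grid$shape)
  proximal <- array(FALSE, grid$shape)
  shaft_r2 <- (0.6 * Rh)^2
  for (k in seq_len(nz)) {
    dz <- zc[k] - cz
    head <- lat2 + dz^2 <= Rh^2
    if (dz < 0) head <- head | (lat2 <= shaft_r2)        # shaft below centre
    dzc <- zc[k] - czc
    cup <- (zc[k] >= czc) & (lat2 <= Rout^2) &
           (zc[k] <= czc + Rc + wall) & (lat2 + dzc^2 >= Rc^2)
    distal[, , k] <- head
    proximal[, , k] <- cup & !head
  }

  # osteophytes: cones attached at the rim, tilted toward the opposing bone
  for (os in spec$osteophytes) {
    if (os$length <= 0) next
    phi <- os$angle_deg * pi / 180
    u <- c(cos(phi), sin(phi), 0)
    if (os$bone == "distal") {
      p0 <- c(cx, cy, cz) + Rh * u
      dir <- (u + c(0, 0, 1)) / sqrt(2)
    } else {
      rim_rho <- sqrt(max(Rc^2 - 0^2, 0))
      p0 <- c(cx + rim_rho * cos(phi), cy + rim_rho * sin(phi), czc)
      dir <- (u * -1 + c(0, 0, -1)) / sqrt(2)
    }
    spike <- spike_mask(grid, p0, dir, os$length, os$base_width)
    if (os$bone == "distal") distal <- distal | (spike & !proximal)
    else proximal <- proximal | (spike & !distal)
  }

  # contact patch: bridge the gap over the polar cap theta <= acos(1 - f)
  if (spec$contact_fraction > 0) {
    f <- spec$contact_fraction
    cos_tf <- 1 - f
    for (k in seq_len(nz)) {
      dz <- zc[k] - cz
      if (dz <= 0) next
      r2 <- lat2 + dz^2
      dzc <- zc[k] - czc
      in_gap <- (r2 > Rh^2) & (lat2 + dzc^2 < Rc^2) & (zc[k] >= czc)
      cosq <- dz / sqrt(r2)
      sel <- in_gap & (cosq >= cos_tf)
      if (!any(sel)) next
      gap_here <- ball_cup_gap_theta(Rh, Rc, delta, acos(pmin(1, cosq)))
      to_distal <- sel & (sqrt(r2) <= Rh + gap_here / 2)
      distal[, , k] <- distal[, , k] | to_distal
      proximal[, , k] <- proximal[, , k] | (sel & !to_distal)
    }
  }

  f <- spec$contact_fraction
  th_lo <- if (f > 0) acos(1 - f) else 0     # cap below th_lo is in contact
  gaps <- ball_cup_gap_theta(Rh, Rc, delta, c(0, pi / 2))
  has_osteo <- any(vapply(spec$osteophytes, function(o) o$length > 0, logical(1)))
  truth <- list(
    jsw_min = if (f > 0) 0 else if (has_osteo) NA_real_ else gaps[1],
    jsw_max = if (has_osteo) NA_real_ else gaps[2],
    jsw_mean = if (has_osteo) NA_real_ else {
      base <- ball_cup_mean_gap(Rh, Rc, delta)
      if (f > 0) {
        # cap area fraction f has gap 0; remaining annulus keeps its gap
        mean_open <- (base - integrate(function(t)
          ball_cup_gap_theta(Rh, Rc, delta, acos(t)), 1 - f, 1)$value) / (1 - f)
        (1 - f) * mean_open
      } else base
    },
    gap_field = function(x, y) {
      rho <- sqrt((x - cx)^2 + (y - cy)^2)
      theta <- asin(pmin(1, rho / Rh))
      ifelse(rho <= Rh,
             ifelse(theta <= th_lo, 0,
                    ball_cup_gap_theta(Rh, Rc, delta, theta)),
             NA_real_)
    })
  list(distal = distal, proximal = proximal, truth = truth)
}

# cone solid: apex moves from p0 (base, diameter base_width) to p0 + length*dir
spike_mask <- function(grid, p0, dir, length, base_width) {
  h <- grid$voxel_size
  xc <- voxel_centers(grid$shape[1], h)
  yc <- voxel_centers(grid$shape[2], h)
  zc <- voxel_centers(grid$shape[3], h)
  out <- array(FALSE, grid$shape)
  # bounding box of the cone
  reach <- length + base_width
  sel <- list(which(abs(xc - p0[1]) <= reach),
              which(abs(yc - p0[2]) <= reach),
              which(abs(zc - p0[3]) <= reach))
  if (any(vapply(sel, base::length, integer(1)) == 0)) return(out)
  gr <- expand.grid(x = xc[sel[[1]]], y = yc[sel[[2]]], z = zc[sel[[3]]])
  rel <- cbind(gr$x - p0[1], gr$y - p0[2], gr$z - p0[3])
  t <- rel %*% dir
  perp2 <- rowSums(rel^2) - t^2
  rad <- (base_width / 2) * (1 - t / length)
  inside <- t >= 0 & t <= length & perp2 <= pmax(rad, 0)^2
  idx <- as.matrix(expand.grid(i = sel[[1]], j = sel[[2]], k = sel[[3]]))
  out[idx[inside, , drop = FALSE]] <- TRUE
  out
}

#' Bridge a fraction of the articulating area with bony contact
#'
#' Returns a new phantom regenerated from the same specification with
#' `contact_fraction` set to `fraction`; the stated fraction of the
#' articulating area has zero gap (bones touching) and the ground-truth
#' contact flag is set. `fraction = 0` returns an identical phantom;
#' `fraction = 1` produces a fully ankylotic pair whose bones form a single
#' connected component.
#'
#' @param phantom a [make_phantom()] result.
#' @param fraction contact fraction in `[0, 1]`.
#' @return a new `joint_phantom`.
#' @export
add_contact_patch <- function(phantom, fraction) {
  stopifnot(inherits(phantom, "joint_phantom"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  spec <- phantom$spec
  spec$contact_fraction <- fraction
  make_phantom(spec, phantom$grid)
}

#' @export
print.joint_phantom <- function(x, ...) {
  cat(sprintf("joint_phantom: %s\n", x$spec$geometry))
  print(x$grid)
  cat(sprintf("  true gap min/mean/max: %.3f / %.3f / %.3f mm%s\n",
              x$truth$jsw_min, x$truth$jsw_mean, x$truth$jsw_max,
              if (isTRUE(x$truth$contact)) " (contact)" else ""))
  invisible(x)
}
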