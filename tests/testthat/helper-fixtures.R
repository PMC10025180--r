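# Shared fixtures and independent oracles used across the test files.

default_grid <- function(shape = c(30, 30, 40), voxel = 0.082)
  grid_spec(shape, voxel_size = voxel)

plate_phantom <- function(gap, grid = default_grid(), ...)
  make_phantom(phantom_spec("parallel_plate", gap = gap, ...), grid)

# random connected mask: a 6-connected random walk with occasional thickening
random_connected_mask <- function(dims, n_steps = 5 * prod(dims)^(1/2),
                                  thicken = 0.3) {
  mask <- array(FALSE, dims)
  pos <- pmax(1, round(dims / 2))
  mask[pos[1], pos[2], pos[3]] <- TRUE
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(round(n_steps))) {
    pos <- pmin(pmax(pos + steps[sample.int(6, 1), ], 1), dims)
    mask[pos[1], pos[2], pos[3]] <- TRUE
    if (runif(1) < thicken) {
      lo <- pmax(pos - 1, 1); hi <- pmin(pos + 1, dims)
      mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    }
  }
  mask
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# rotate a 3D array by 90 degrees about the third axis
rot90_z <- function(a) {
  out <- aperm(a, c(2, 1, 3))
  out[dim(out)[1]:1, , , drop = FALSE]
}

# --- independent enumeration oracle for the exact Mann-Whitney p-value ---
# Counts, over all choose(n1+n2, n1) assignments of the pooled sample, how
# often U falls in the observed tail; two-sided p doubles the smaller-tail
# convention used for exact rank tests (lower tail when U <= n1*n2/2).
mw_enumeration_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_stat(a, b)
  combos <- combn(length(pool), n1)
  u_all <- apply(combos, 2, function(ix) u_stat(pool[ix], pool[-ix]))
  if (u_obs > n1 * length(b) / 2) p <- 2 * mean(u_all >= u_obs)
  else p <- 2 * mean(u_all <= u_obs)
  min(1, p)
}

# --- independent permutation oracle for the exact Spearman p-value ---
# rho from the classical 1 - 6*sum(d^2)/(n(n^2-1)) formula (tie-free inputs),
# enumerated over all n! orderings generated by element insertion (a
# different construction than the package's recursive-prefix enumerator).
all_permutations <- function(n) {
  perms <- matrix(1L, 1, 1)
  for (k in 2:n) {
    old_n <- nrow(perms)
    out <- matrix(0L, old_n * k, k)
    r <- 0L
    for (pos in 1:k) {
      block <- matrix(0L, old_n, k)
      if (pos > 1) block[, 1:(pos - 1)] <- perms[, 1:(pos - 1), drop = FALSE]
      block[, pos] <- k
      if (pos < k) block[, (pos + 1):k] <- perms[, pos:(k - 1), drop = FALSE]
      out[r + seq_len(old_n), ] <- block
      r <- r + old_n
    }
    perms <- out
  }
  perms
}

spearman_enumeration_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  perms <- all_permutations(n)
  d2 <- rowSums((matrix(rx, nrow(perms), n, byrow = TRUE) -
                   matrix(ry[t(perms)], nrow(perms), n, byrow = TRUE))^2)
  rhos <- 1 - 6 * d2 / (n * (n^2 - 1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# --- direct-definition local thickness oracle in R, for tiny masks ---
# Mirrors the documented semantics with no shared code: majority-rule
# boundary samples on the half grid, radii by brute-force minimum distance,
# coverage by the per-axis clamped (sphere-intersects-cube) test.
r_thickness_oracle <- function(mask) {
  d <- dim(mask)
  is_boundary_sample <- function(a, b, c) {  # doubled 0-based coords
    rng <- function(t, nmax) {
      lo <- if (t %% 2 == 1) (t - 1) / 2 else t / 2 - 1
      seq(max(0, lo), min(nmax - 1, t %/% 2))
    }
    v <- mask[rng(a, d[1]) + 1, rng(b, d[2]) + 1, rng(c, d[3]) + 1]
    2 * sum(v) <= length(v)
  }
  pts <- as.matrix(expand.grid(a = 0:(2 * d[1]), b = 0:(2 * d[2]),
                               c = 0:(2 * d[3])))
  bnd <- apply(pts, 1, function(p) is_boundary_sample(p[1], p[2], p[3]))
  sites <- pts[bnd, , drop = FALSE]
  cens <- pts[!bnd, , drop = FALSE]
  d2 <- apply(cens, 1, function(p)
    min(colSums((t(sites) - p)^2)))
  out <- array(0, d)
  for (idx in which(mask)) {
    ijk <- arrayInd(idx, d)
    x <- 2 * (ijk - 1) + 1
    best <- 0
    for (q in seq_len(nrow(cens))) {
      u <- pmax(0, abs(x - cens[q, ]) - 1)
      if (sum(u^2) <= d2[q] && d2[q] > best) best <- d2[q]
    }
    out[idx] <- sqrt(best)
  }
  out
}

# analytic mean of a normal truncated below at zero
truncated_normal_mean <- function(mean, sd) {
  if (sd == 0) return(mean)
  z <- mean / sd
  mean + sd * dnorm(z) / pnorm(z)
}
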