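test_that("parallel plates realize their analytic gap", {
  ph <- plate_phantom(1.0)
  expect_equal(ph$truth$jsw_min, 1.0)
  expect_equal(ph$truth$jsw_mean, 1.0)
  expect_equal(ph$truth$jsw_max, 1.0)
  expect_false(ph$truth$contact)
  # a 1.0 mm gap at 0.082 mm voxels discretizes to 12 empty layers
  lab <- as_label_volume(ph$bones)
  expect_equal(sum(apply(lab == 0, 3, all)), 12)
})

test_that("a one-voxel gap produces a single empty layer", {
  ph <- plate_phantom(0.082)
  lab <- as_label_volume(ph$bones)
  expect_equal(sum(apply(lab == 0, 3, all)), 1)
  expect_equal(ph$truth$jsw_min, 0.082)
})

test_that("noiseless volumes threshold back to the ground-truth masks", {
  ph <- plate_phantom(0.6)
  expect_identical(ph$volume$values > 0.5, ph$bones$distal | ph$bones$proximal)
})

test_that("concentric ball-and-cup has a uniform analytic gap", {
  ph <- make_phantom(phantom_spec("ball_and_cup", head_radius = 2, cup_radius = 3),
                     grid_spec(c(92, 92, 96)))
  expect_equal(ph$truth$jsw_min, 1.0)
  expect_equal(ph$truth$jsw_mean, 1.0)
  expect_equal(ph$truth$jsw_max, 1.0)
  expect_equal(n_components(ph$bones$distal), 1)
  expect_equal(n_components(ph$bones$proximal), 1)
  expect_false(any(ph$bones$distal & ph$bones$proximal))
})

test_that("axial cup offset narrows the polar gap as derived", {
  # gap(theta) = R_c - sqrt(R_h^2 + d^2 + 2 R_h d cos(theta)); min at the pole
  ph <- make_phantom(phantom_spec("ball_and_cup", head_radius = 2,
                                  cup_radius = 3, center_offset = 0.3),
                     grid_spec(c(92, 92, 96)))
  expect_equal(ph$truth$jsw_min, 0.7)
  expect_equal(ph$truth$jsw_max, 3 - sqrt(4 + 0.09), tolerance = 1e-12)
})

test_that("voxelized surface distances agree with the analytic gap field", {
  # brute-force nearest-surface distances on a coarse offset ball-and-cup,
  # over the articulating cap (theta <= 75 deg); estimator: centre-to-centre
  # distance minus one voxel (half a voxel of solid on each side)
  h <- 0.2
  grid <- grid_spec(c(46, 46, 48), voxel_size = h)
  ph <- make_phantom(phantom_spec("ball_and_cup", head_radius = 2,
                                  cup_radius = 3, center_offset = 0.3), grid)
  surf <- function(m) m & !erode_ball(m, sqrt(3) + 1e-9)
  sd_ <- which(surf(ph$bones$distal), arr.ind = TRUE)
  sp_ <- which(surf(ph$bones$proximal), arr.ind = TRUE)
  pd <- (sd_ - 0.5) * h
  pp <- (sp_ - 0.5) * h
  # head centre: recover from the distal mask (mean of the spherical cap ring
  # is biased by the shaft, so use the known lateral centre + pole)
  ctr <- c(23 * h, 23 * h, max(pd[, 3]) - 2)
  rel <- sweep(pd, 2, ctr)
  cosq <- rel[, 3] / sqrt(rowSums(rel^2))
  cap <- pd[cosq >= cos(75 * pi / 180), , drop = FALSE]
  gaps <- apply(cap, 1, function(q) sqrt(min(colSums((t(pp) - q)^2)))) - h
  expect_lt(abs(min(gaps) - ph$truth$jsw_min), h)
  expect_lt(abs(max(gaps) - ball_cup_gap_theta(2, 3, 0.3, 75 * pi / 180)), h)
})

test_that("contact patches zero the gap over the requested fraction", {
  ph <- plate_phantom(1.0)
  expect_identical(add_contact_patch(ph, 0)$bones, ph$bones)
  pc <- add_contact_patch(ph, 0.1)
  expect_equal(pc$truth$jsw_min, 0)
  expect_equal(pc$truth$jsw_max, 1.0)
  expect_true(pc$truth$contact)
  expect_equal(pc$truth$jsw_mean, 0.9)
  # bones remain disjoint sets but now form one connected body
  expect_false(any(pc$bones$distal & pc$bones$proximal))
  expect_equal(max(label_components(pc$bones$distal | pc$bones$proximal)), 1)
  # full contact: fully ankylotic single body
  pa <- add_contact_patch(ph, 1)
  expect_equal(max(label_components(pa$bones$distal | pa$bones$proximal)), 1)
  expect_equal(sum(as_label_volume(pa$bones) == 0), 0)  # no gap voxel remains
})

test_that("phantom generation is bit-identical under a fixed seed", {
  spec <- phantom_spec("parallel_plate", gap = 0.8, blur_fwhm = 0.13,
                       noise_sd = 0.05, seed = 123)
  g <- default_grid()
  p1 <- make_phantom(spec, g)
  p2 <- make_phantom(spec, g)
  expect_identical(p1$volume$values, p2$volume$values)
  p3 <- make_phantom(phantom_spec("parallel_plate", gap = 0.8,
                                  blur_fwhm = 0.13, noise_sd = 0.05,
                                  seed = 124), g)
  expect_false(identical(p1$volume$values, p3$volume$values))
})

test_that("osteophytes add bone at the head rim", {
  g <- grid_spec(c(92, 92, 96))
  base <- make_phantom(phantom_spec("ball_and_cup", head_radius = 2,
                                    cup_radius = 3), g)
  osteo <- make_phantom(phantom_spec("ball_and_cup", head_radius = 2,
                                     cup_radius = 3,
                                     osteophytes = list(
                                       osteophyte_spec("distal", 30, 0.8, 0.6))), g)
  expect_gt(sum(osteo$bones$distal), sum(base$bones$distal))
  expect_true(is.na(osteo$truth$jsw_min))
})

test_that("invalid specifications are rejected", {
  expect_error(phantom_spec("ball_and_cup", head_radius = 3, cup_radius = 3),
               "invalid ball-and-cup")
  expect_error(phantom_spec(gap = -1), "gap")
  expect_error(phantom_spec(contact_fraction = 1.2), "contact_fraction")
  expect_error(make_phantom(phantom_spec("parallel_plate", gap = 50),
                            default_grid()), "phantom exceeds grid")
  expect_error(make_phantom(phantom_spec("ball_and_cup", head_radius = 2,
                                         cup_radius = 3),
                            grid_spec(c(30, 30, 40))), "phantom exceeds grid")
  ph <- plate_phantom(0.5)
  expect_error(add_contact_patch(ph, -0.1), "fraction")
})
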