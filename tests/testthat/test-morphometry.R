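test_that("the joint-space mask of facing plates is the exact gap block", {
  ph <- plate_phantom(1.0, grid = default_grid(c(50, 50, 40)))
  space <- build_joint_space_mask(ph$bones)
  expect_false(space$ankylotic)
  expect_equal(sum(space$mask), 50 * 50 * 12)
  lab <- as_label_volume(ph$bones)
  expect_true(all(lab[space$mask] == 0))
})

test_that("a fully ankylotic pair yields an empty mask with the ankylosis signal", {
  pa <- add_contact_patch(plate_phantom(1.0), 1)
  space <- build_joint_space_mask(pa$bones)
  expect_true(space$ankylotic)
  expect_equal(sum(space$mask), 0)
  morph <- summarize_morphometry(NULL, space, ankylotic_contact = TRUE)
  expect_true(morph$ankylotic)
  expect_equal(morph$jsv, 0)
  expect_true(is.na(morph$jsw_as))
})

test_that("concentric ball-and-cup joint space approximates the shell sector", {
  ph <- make_phantom(phantom_spec("ball_and_cup", head_radius = 2, cup_radius = 3),
                     grid_spec(c(92, 92, 96)))
  space <- build_joint_space_mask(ph$bones)
  h <- 0.082
  # analytic volume of the articulating gap: hemispherical shell sector plus
  # the lateral skirt between head equator and cup wall; bound it instead of
  # pinning it: the mask must cover most of the polar shell sector (theta <=
  # 60 deg) and stay inside the dilated shell
  shell_sector <- 2 * pi / 3 * (3^3 - 2^3) * (1 - cos(pi / 3)) / 2
  vol <- sum(space$mask) * h^3
  expect_gt(vol, shell_sector)
  # every space voxel lies strictly between the bones (non-bone by build)
  expect_false(any(space$mask & (ph$bones$distal | ph$bones$proximal)))
})

test_that("plate JSW maps are constant to within half a voxel of the gap", {
  ph <- plate_phantom(1.0)
  space <- build_joint_space_mask(ph$bones)
  map <- compute_jsw_map(space)
  v <- map$values[space$mask]
  expect_true(all(abs(v - 1.0) <= 0.041))
})

test_that("the single-voxel-gap plate reports a mean JSW of exactly one voxel", {
  ph <- plate_phantom(0.082)
  res <- measure_joint(ph$bones)
  expect_equal(res$morphometry$jsw, 0.082)
  expect_equal(res$morphometry$jsw_min, 0.082)
  expect_equal(res$morphometry$jsw_max, 0.082)
})

test_that("concentric ball-and-cup widths are within a voxel over the cap", {
  ph <- make_phantom(phantom_spec("ball_and_cup", head_radius = 2, cup_radius = 3),
                     grid_spec(c(92, 92, 96)))
  res <- measure_joint(ph$bones)
  map <- res$map; space <- res$space
  h <- 0.082
  # central 80% of the articulating cap: theta in [0, 0.8 * 90 deg]
  idx <- which(space$mask, arr.ind = TRUE)
  ctr_xy <- c(92, 92) / 2 + 0.0
  cz_vox <- local({
    head <- which(ph$bones$distal, arr.ind = TRUE)
    # head centre z: pole minus radius
    max(head[, 3]) - 2 / h
  })
  rel <- cbind(idx[, 1] - 0.5 - ctr_xy[1], idx[, 2] - 0.5 - ctr_xy[2],
               idx[, 3] - 0.5 - cz_vox)
  cosq <- rel[, 3] / sqrt(rowSums(rel^2))
  cap <- cosq >= cos(0.8 * pi / 2)
  v <- map$values[space$mask][cap]
  expect_true(all(abs(v - 1.0) <= h))
})

test_that("summaries of constant and two-level maps follow the definitions", {
  # constant map: 1000 voxels of 1.2 mm at 0.1 mm voxels
  g <- grid_spec(c(10, 10, 12), voxel_size = 0.1)
  mask <- array(FALSE, g$shape); mask[, , 2:11] <- TRUE   # 10x10x10 block
  space <- structure(list(mask = mask, grid = g, ankylotic = FALSE),
                     class = "joint_space_mask")
  map <- structure(list(values = array(1.2 * mask, dim(mask)), mask = mask,
                        grid = g), class = "jsw_map")
  m <- summarize_morphometry(map, space)
  expect_equal(m$jsv, 1.0)
  expect_equal(m$jsw, 1.2); expect_equal(m$jsw_min, 1.2); expect_equal(m$jsw_max, 1.2)
  expect_equal(m$jsw_sd, 0); expect_equal(m$jsw_as, 1.0)
  expect_false(m$ankylotic)
  # asymmetry is max over min by definition
  vals <- array(0, dim(mask))
  vals[mask] <- rep(c(0.6, 2.4), length.out = sum(mask))
  map2 <- structure(list(values = vals, mask = mask, grid = g), class = "jsw_map")
  expect_equal(summarize_morphometry(map2, space)$jsw_as, 4.0)
})

test_that("empty joint spaces raise rather than return silent zeros", {
  g <- grid_spec(c(8, 8, 8))
  space <- structure(list(mask = array(FALSE, g$shape), grid = g,
                          ankylotic = FALSE), class = "joint_space_mask")
  expect_error(compute_jsw_map(space), "empty joint space")
  expect_error(summarize_morphometry(NULL, space), "empty joint space")
})

test_that("JSV is exact voxel-count conservation", {
  ph <- plate_phantom(0.75)
  res <- measure_joint(ph$bones)
  expect_identical(res$morphometry$jsv, sum(res$space$mask) * 0.082^3)
})

test_that("mean JSW grows monotonically with the plate gap", {
  gaps <- c(0.25, 0.5, 1.0, 1.5)
  means <- vapply(gaps, function(g)
    measure_joint(plate_phantom(g)$bones)$morphometry$jsw, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_true(all(means <= gaps + 0.082))
})

test_that("all six parameters are exactly invariant under 90-degree rotation", {
  ph <- make_phantom(phantom_spec("ball_and_cup", head_radius = 1.2,
                                  cup_radius = 1.8, center_offset = 0.2),
                     grid_spec(c(60, 60, 64)))
  rot_bones <- bone_pair_mask(rot90_z(ph$bones$distal),
                              rot90_z(ph$bones$proximal), ph$grid)
  m1 <- measure_joint(ph$bones)$morphometry
  m2 <- measure_joint(rot_bones)$morphometry
  for (p in c("jsv", "jsw", "jsw_sd", "jsw_min", "jsw_max", "jsw_as"))
    expect_identical(m1[[p]], m2[[p]])
})

test_that("the robust minimum trims isolated low-width voxels", {
  g <- grid_spec(c(10, 10, 12), voxel_size = 0.1)
  mask <- array(FALSE, g$shape); mask[, , 2:11] <- TRUE
  space <- structure(list(mask = mask, grid = g, ankylotic = FALSE),
                     class = "joint_space_mask")
  vals <- array(0, dim(mask)); vals[mask] <- 1.0
  vals[5, 5, 2] <- 0.2                       # one outlier voxel
  map <- structure(list(values = vals, mask = mask, grid = g), class = "jsw_map")
  expect_equal(summarize_morphometry(map, space)$jsw_min, 0.2)
  expect_equal(summarize_morphometry(map, space, robust_min = TRUE)$jsw_min, 1.0)
})
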