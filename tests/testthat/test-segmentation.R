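test_that("fixed-threshold segmentation of a noiseless phantom is exact", {
  ph <- plate_phantom(0.8)
  mask <- segment_bone(ph$volume, threshold = 0.5)
  expect_identical(mask, ph$bones$distal | ph$bones$proximal)
})

test_that("otsu segmentation of a degraded phantom stays accurate", {
  ph <- plate_phantom(0.8, blur_fwhm = 0.13, noise_sd = 0.05, seed = 2)
  mask <- segment_bone(ph$volume)
  truth <- ph$bones$distal | ph$bones$proximal
  expect_gte(dice(mask, truth), 0.95)
})

test_that("degenerate segmentation inputs raise the documented errors", {
  g <- grid_spec(c(6, 6, 6))
  zero <- volume_image(array(0, g$shape), g)
  expect_error(segment_bone(zero, threshold = 0.5), "no bone found")
  expect_error(segment_bone(zero, threshold = "otsu"), "degenerate histogram")
})

test_that("two separated bodies split automatically with positional labels", {
  ph <- plate_phantom(1.0)
  sp <- split_joint_bones(ph$bones$distal | ph$bones$proximal, ph$grid)
  expect_equal(sp$outcome$status, "auto_success")
  expect_identical(sp$bones$distal, ph$bones$distal)
  expect_identical(sp$bones$proximal, ph$bones$proximal)
})

test_that("small satellite bodies are discarded before splitting", {
  ph <- plate_phantom(1.0, grid = default_grid(c(20, 20, 40)))
  mask <- ph$bones$distal | ph$bones$proximal
  gap_k <- which(apply(!mask, 3, all))
  mask[3:4, 3:4, gap_k[5]] <- TRUE                    # sesamoid-like satellite
  sp <- split_joint_bones(mask, ph$grid)
  expect_equal(sp$outcome$status, "auto_success")
  expect_equal(sum(sp$bones$distal) + sum(sp$bones$proximal),
               sum(ph$bones$distal) + sum(ph$bones$proximal))
})

test_that("bony contact is detected as a bridged mask needing manual work", {
  pc <- add_contact_patch(plate_phantom(1.0), 0.1)
  sp <- split_joint_bones(pc$bones$distal | pc$bones$proximal, pc$grid)
  expect_equal(sp$outcome$status, "needs_manual")
  expect_equal(sp$outcome$reason, "bridged")
  expect_null(sp$bones)
})

test_that("three or more major bodies are ambiguous", {
  g <- grid_spec(c(10, 10, 30))
  m <- array(FALSE, g$shape)
  m[, , 2:8] <- TRUE; m[, , 12:18] <- TRUE; m[, , 22:28] <- TRUE
  expect_error(split_joint_bones(m, g), "ambiguous joint")
})

test_that("manual splitting with a separating plane matches the truth", {
  pc <- add_contact_patch(plate_phantom(1.0), 0.1)
  sp <- split_joint_bones(pc$bones$distal | pc$bones$proximal, pc$grid)
  contour <- array(FALSE, pc$grid$shape)
  gap_mid <- round(mean(which(apply(
    !(pc$bones$distal | pc$bones$proximal), 3, any))))
  contour[, , seq_len(gap_mid)] <- TRUE
  bones <- apply_manual_split(sp$bridged_mask, contour, pc$grid)
  # agreement with generator truth outside the contact patch
  patch <- pc$bones$distal & contour & dilate_ball(pc$bones$proximal, sqrt(3))
  expect_identical(bones$distal & !patch, pc$bones$distal & !patch)
  expect_false(any(bones$distal & bones$proximal))
})

test_that("manual splitting is identity for an exact contour, errors otherwise", {
  ph <- plate_phantom(1.0)
  mask <- ph$bones$distal | ph$bones$proximal
  bones <- apply_manual_split(mask, ph$bones$distal, ph$grid)
  expect_identical(bones$distal, ph$bones$distal)
  expect_identical(bones$proximal, ph$bones$proximal)
  expect_error(apply_manual_split(mask, array(FALSE, ph$grid$shape), ph$grid),
               "non-separating contour")
  expect_error(apply_manual_split(mask, array(TRUE, ph$grid$shape), ph$grid),
               "non-separating contour")
})

test_that("periosteal filling closes a hollow shell to a solid ball", {
  h <- 0.2
  g <- grid_spec(c(40, 40, 40), voxel_size = h)
  ctr <- 20.0 * h
  xc <- ((1:40) - 0.5) * h
  r2 <- outer(outer((xc - ctr)^2, (xc - ctr)^2, "+"), (xc - ctr)^2, "+")
  shell <- r2 <= 3.0^2 & r2 > 2.4^2
  filled <- periosteal_mask(shell, closing_radius_vox = 2)
  expect_equal(sum(filled), sum(r2 <= 3.0^2))       # voxelized ball volume
})

test_that("periosteal filling is extensive, idempotent and fills voids exactly", {
  ph <- plate_phantom(1.0, grid = default_grid(c(20, 20, 40)))
  solid <- ph$bones$distal
  expect_identical(periosteal_mask(solid), solid)    # solid plate unchanged
  withvoid <- solid
  withvoid[9:11, 9:11, 3:5] <- FALSE                 # 27-voxel internal void
  filled <- periosteal_mask(withvoid)
  expect_true(all(filled[withvoid]))
  expect_equal(sum(filled) - sum(withvoid), 27)
  expect_identical(periosteal_mask(filled), filled)
})
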