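test_that("inclusion rules exclude with the documented reason precedence", {
  rec <- quality_records(
    subject = c("s1", "s2", "s3", "s4", "s5"),
    joint = "MCP2",
    motion_grade = c(4, 3, 1, 5, 1),
    coverage_ok = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    ankylotic = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    status = "auto_success")
  qc <- apply_inclusion_rules(rec)
  expect_setequal(qc$included$subject, c("s2", "s5"))
  ex <- qc$exclusions[order(qc$exclusions$subject), ]
  expect_equal(ex$reason, c("motion", "ankylosis", "motion"))
  # grade-4 with coverage failure still logs motion first (precedence)
  expect_equal(ex$reason[ex$subject == "s4"], "motion")
  expect_error(quality_records("x", "MCP2", 6), "1..5")
})

test_that("inclusion is order-independent", {
  rec <- quality_records(sprintf("s%d", 1:6), "MCP3",
                         c(1, 4, 2, 5, 3, 1),
                         coverage_ok = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
                         ankylotic = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                         status = "auto_success")
  a <- apply_inclusion_rules(rec)
  b <- apply_inclusion_rules(rec[sample(nrow(rec)), ])
  expect_setequal(a$included$subject, b$included$subject)
  expect_setequal(paste(a$exclusions$subject, a$exclusions$reason),
                  paste(b$exclusions$subject, b$exclusions$reason))
})

test_that("coverage passes when the articulating surfaces are interior", {
  ph <- plate_phantom(1.0)
  expect_true(check_joint_coverage(ph$bones))
})

test_that("coverage fails when an articulating surface touches the stack end", {
  # translate the joint so the distal bone is a single slice at the stack
  # start: its articulating face lies on slice 1
  g <- grid_spec(c(16, 16, 30))
  distal <- array(FALSE, g$shape); distal[, , 1] <- TRUE
  proximal <- array(FALSE, g$shape); proximal[, , 4:14] <- TRUE
  bones <- bone_pair_mask(distal, proximal, g)
  expect_false(check_joint_coverage(bones))
  # same joint in the middle of the stack passes
  distal2 <- array(FALSE, g$shape); distal2[, , 8] <- TRUE
  proximal2 <- array(FALSE, g$shape); proximal2[, , 11:21] <- TRUE
  expect_true(check_joint_coverage(bone_pair_mask(distal2, proximal2, g)))
})

test_that("a non-articular shaft touching the stack end is tolerated", {
  # ball-and-cup: the head's supporting shaft runs to the bottom slice while
  # both articulating surfaces are interior
  ph <- make_phantom(phantom_spec("ball_and_cup", head_radius = 2, cup_radius = 3),
                     grid_spec(c(92, 92, 96)))
  expect_true(any(ph$bones$distal[, , 1]))        # shaft leaves the stack
  expect_true(check_joint_coverage(ph$bones))
})

test_that("success-rate tallies match the hand arithmetic", {
  status <- c(rep("auto_success", 55), rep("needs_manual", 14))
  rec <- quality_records(sprintf("s%02d", 1:69), "MCP2", 1, status = status)
  tal <- tally_success_rates(rec)
  ov <- tal[tal$stratum == "overall", ]
  expect_equal(ov$n, 69)
  expect_equal(ov$pct_auto, 79.7)
  expect_equal(ov$pct_manual, 20.3)
  expect_equal(ov$pct_auto + ov$pct_manual, 100, tolerance = 0.11)
  # all-success stratum reads 100.0
  rec2 <- quality_records(c("a", "b"), "MCP3", 1, status = "auto_success")
  expect_equal(tally_success_rates(rec2)$pct_auto, c(100, 100))
  expect_error(tally_success_rates(rec2[0, ]), "no records")
})

test_that("per-joint strata use their own denominators", {
  rec <- rbind(
    quality_records(sprintf("a%d", 1:4), "MCP2", 1,
                    status = c("auto_success", "auto_success", "auto_success",
                               "needs_manual")),
    quality_records(sprintf("b%d", 1:2), "MCP3", 1, status = "auto_success"))
  tal <- tally_success_rates(rec)
  expect_equal(tal$pct_auto[tal$stratum == "MCP2"], 75)
  expect_equal(tal$pct_auto[tal$stratum == "MCP3"], 100)
  expect_equal(tal$n[tal$stratum == "overall"], 6)
})
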