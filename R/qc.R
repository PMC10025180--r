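# quality_control: study inclusion/exclusion rules and segmentation-success
# bookkeeping. Motion grading (Pialat 1-5) is visual metadata, not computed
# from image content.

#' Quality records for scanned joints
#'
#' @param subject subject identifiers.
#' @param joint joint labels (`"MCP2"`, `"MCP3"`, `"MCP4"`).
#' @param motion_grade Pialat motion score, integer 1-5.
#' @param coverage_ok joint surfaces fully inside the slice stack.
#' @param ankylotic bony fusion detected.
#' @param status segmentation outcome status per joint
#'   (`"auto_success"`/`"needs_manual"`/`"failed"`), optional.
#' @return data.frame of class `quality_records`.
#' @export
quality_records <- function(subject, joint, motion_grade,
                            coverage_ok = TRUE, ankylotic = FALSE,
                            status = NA_character_) {
  if (any(!motion_grade %in% 1:5)) stop("motion_grade must be in 1..5")
  out <- data.frame(subject = as.character(subject),
                    joint = as.character(joint),
                    motion_grade = as.integer(motion_grade),
                    coverage_ok = as.logical(coverage_ok),
                    ankylotic = as.logical(ankylotic),
                    status = as.character(status),
                    stringsAsFactors = FALSE)
  class(out) <- c("quality_records", class(out))
  out
}

#' Apply the study inclusion rules
#'
#' Excludes joints with motion grade 4-5, joints whose articulating surfaces
#' are not fully contained in the slice stack, and ankylotic joints. Each
#' exclusion is logged with the first matching reason, in the fixed
#' precedence motion, coverage, ankylosis. Inclusion is order-independent.
#'
#' @param records a [quality_records()] data.frame.
#' @return list with `included` (rows kept) and `exclusions` (data.frame
#'   `subject`, `joint`, `reason`).
#' @export
apply_inclusion_rules <- function(records) {
  stopifnot(is.data.frame(records))
  if (any(!records$motion_grade %in% 1:5)) stop("motion_grade must be in 1..5")
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & records$motion_grade >= 4L] <- "motion"
  reason[is.na(reason) & !records$coverage_ok] <- "coverage"
  reason[is.na(reason) & records$ankylotic] <- "ankylosis"
  list(included = records[is.na(reason), , drop = FALSE],
       exclusions = data.frame(subject = records$subject[!is.na(reason)],
                               joint = records$joint[!is.na(reason)],
                               reason = reason[!is.na(reason)],
                               stringsAsFactors = FALSE))
}

#' Check that the articulating surfaces are inside the slice stack
#'
#' `TRUE` iff no articulating surface voxel of either bone lies on the first
#' or last slice along the scan axis. The articulating surface is the set of
#' bone voxels adjacent (26-connectivity) to the joint-space mask, so a bone
#' shaft running out of the stack does not fail the check.
#'
#' @param bones a [bone_pair_mask()].
#' @param space the joint's [build_joint_space_mask()] result; computed from
#'   `bones` when omitted.
#' @param axis scan axis (default 3).
#' @param closing_radius bridging radius (mm) used when `space` must be
#'   computed here.
#' @return logical flag.
#' @export
check_joint_coverage <- function(bones, space = NULL, axis = 3L,
                                 closing_radius = 2.5) {
  stopifnot(inherits(bones, "bone_pair_mask"))
  if (is.null(space))
    space <- build_joint_space_mask(bones, closing_radius = closing_radius,
                                    axis = axis)
  if (!any(space$mask)) return(TRUE)   # nothing to locate (ankylotic joint)
  n_ax <- bones$grid$shape[axis]
  near_space <- dilate_ball(space$mask, sqrt(3) + 1e-9)
  art <- (bones$distal | bones$proximal) & near_space
  idx <- which(art, arr.ind = TRUE)[, axis]
  !any(idx == 1L | idx == n_ax)
}

#' Tally first-attempt segmentation success rates
#'
#' Percentages (one decimal) of automatic first-attempt successes and of
#' joints needing manual intervention, per joint and overall, over the
#' supplied (included) records.
#'
#' @param records a [quality_records()] data.frame with `status` populated,
#'   typically the `included` element of [apply_inclusion_rules()].
#' @return data.frame with one row per joint plus `"overall"`: `n`,
#'   `n_auto`, `n_manual`, `pct_auto`, `pct_manual`.
#' @export
tally_success_rates <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("no records to tally")
  if (any(is.na(records$status))) stop("status not populated")
  strata <- c(sort(unique(records$joint)), "overall")
  rows <- lapply(strata, function(s) {
    sub <- if (s == "overall") records else records[records$joint == s, , drop = FALSE]
    n <- nrow(sub)
    n_auto <- sum(sub$status == "auto_success")
    n_manual <- sum(sub$status == "needs_manual")
    data.frame(stratum = s, n = n, n_auto = n_auto, n_manual = n_manual,
               pct_auto = round(100 * n_auto / n, 1),
               pct_manual = round(100 * n_manual / n, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
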