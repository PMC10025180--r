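# Synthetic cohorts: per-subject, per-joint morphometry drawn from group
# summary statistics (means +- SD), truncated below at zero.

MORPH_PARAMS <- c("jsv", "jsw", "jsw_min", "jsw_max", "jsw_as", "jsw_sd")

#' Cohort sampling parameters
#'
#' Bundles the group-level means and SDs from which [synthesize_cohort()]
#' draws per-subject, per-joint morphometry and demographics. Every group x
#' joint combination present must carry the complete set of six morphometry
#' parameters (JSV, JSW, JSW.SD, JSW.MIN, JSW.MAX, JSW.AS); demographic
#' parameters are attached with `joint = NA`.
#'
#' @param values data.frame with columns `group`, `joint` (`"MCP2"`, `"MCP3"`,
#'   `"MCP4"` or `NA` for demographics), `parameter`, `mean`, `sd`.
#' @param n named integer vector: subjects per group (>= 0).
#' @param sex named character vector giving each group's sex (`"M"`/`"F"`);
#'   by default inferred from the group name (`"women"`/`"men"`).
#' @param seed default seed used by [synthesize_cohort()].
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(values, n, sex = NULL, seed = 1L) {
  stopifnot(is.data.frame(values),
            all(c("group", "joint", "parameter", "mean", "sd") %in% names(values)))
  if (any(values$sd < 0)) stop("negative SD")
  if (any(n < 0)) stop("n must be >= 0")
  if (is.null(names(n)) || !all(names(n) %in% unique(values$group)))
    stop("n must be a named vector over groups present in values")
  for (g in names(n)) {
    sub <- values[values$group == g & !is.na(values$joint), ]
    for (j in unique(sub$joint)) {
      have <- sub$parameter[sub$joint == j]
      if (!all(MORPH_PARAMS %in% have))
        stop(sprintf("missing group x joint parameters: %s %s", g, j))
    }
  }
  if (is.null(sex)) {
    sex <- ifelse(grepl("women|female", names(n)), "F",
                  ifelse(grepl("men|male", names(n)), "M", "F"))
    names(sex) <- names(n)
  }
  structure(list(values = values, n = n, sex = sex, seed = as.integer(seed)),
            class = "cohort_params")
}

# normal draws truncated below at zero by rejection
rtrunc0 <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) {
    if (mean < 0) stop("cannot truncate a degenerate negative distribution")
    return(rep(mean, n))
  }
  x <- rnorm(n, mean, sd)
  for (iter in 1:1000) {
    bad <- x < 0
    if (!any(bad)) return(x)
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  stop("rejection sampling failed: distribution mass is almost entirely negative")
}

#' Draw a synthetic cohort from group summary statistics
#'
#' One row per subject x joint; morphometry values and demographics are drawn
#' independently from normal distributions with the configured group means
#' and SDs, truncated below at zero. Draws are independent across joints
#' (within-subject correlation between joints is not modelled). The same
#' `params` and `seed` always produce an identical table.
#'
#' @param params a [cohort_params()].
#' @param seed overrides `params$seed` when given.
#' @return data.frame with columns `id`, `group`, `sex`, `joint`, the six
#'   morphometry parameters, any demographic parameters present, and an
#'   `ankylotic` flag (always `FALSE` for synthesized joints).
#' @examples
#' p <- hh_reference_params()
#' coh <- synthesize_cohort(cohort_params(
#'   p[p$table == "cohort" & p$group %in% c("hh_men", "hh_women"), ],
#'   n = c(hh_men = 5, hh_women = 5)))
#' head(coh)
#' @export
synthesize_cohort <- function(params, seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (is.null(seed)) seed <- params$seed
  values <- params$values
  joints <- sort(unique(values$joint[!is.na(values$joint)]))
  demo_pars <- unique(values$parameter[is.na(values$joint)])

  withr::with_seed(as.integer(seed), {
    out <- list()
    for (g in names(params$n)) {
      ng <- params$n[[g]]
      if (ng == 0) next
      ids <- sprintf("%s_%03d", g, seq_len(ng))
      demo <- data.frame(id = ids, group = g, sex = params$sex[[g]],
                         stringsAsFactors = FALSE)
      for (p in demo_pars) {
        row <- values[values$group == g & is.na(values$joint) &
                        values$parameter == p, ]
        demo[[p]] <- if (nrow(row) == 1) rtrunc0(ng, row$mean, row$sd)
                     else NA_real_
      }
      gj <- unique(values$joint[values$group == g & !is.na(values$joint)])
      for (j in gj) {
        block <- demo
        block$joint <- j
        for (p in MORPH_PARAMS) {
          row <- values[values$group == g & values$parameter == p &
                          !is.na(values$joint) & values$joint == j, ]
          block[[p]] <- rtrunc0(ng, row$mean, row$sd)
        }
        out[[length(out) + 1]] <- block
      }
    }
    if (length(out) == 0) {
      res <- data.frame(id = character(0), group = character(0),
                        sex = character(0), joint = character(0))
      for (p in c(demo_pars, MORPH_PARAMS)) res[[p]] <- numeric(0)
    } else {
      res <- do.call(rbind, out)
      res <- res[order(res$group, res$id, res$joint), , drop = FALSE]
      rownames(res) <- NULL
    }
    res$ankylotic <- rep(FALSE, nrow(res))
    res
  })
}

#' Reference group statistics of the hemochromatosis MCP joint-space study
#'
#' Published group means and standard deviations of the six HR-pQCT
#' joint-space parameters (JSV mm^3, JSW mm, JSW.MIN mm, JSW.MAX mm, JSW.AS,
#' JSW.SD mm) and demographics, for the hereditary-hemochromatosis (HH)
#' cohort stratified by sex (`table = "cohort"`: 16 HH men, 8 HH women,
#' MCP 2-4) and for the sex- and age-matched case-control subanalyses
#' (`table = "women_matched"`: 8 HH women vs 8 control women, MCP 2-3,
#' consensus-algorithm values; `table = "men_matched"`: 5 HH men vs 5 control
#' men, MCP 2-3). These serve as generator inputs for synthetic cohorts and
#' as the reference means for the published percent contrasts.
#'
#' @return data.frame with columns `table`, `group`, `joint`, `parameter`,
#'   `mean`, `sd`, `n`.
#' @export
hh_reference_params <- function() {
  row <- function(table, group, joint, parameter, mean, sd, n)
    data.frame(table = table, joint = joint, group = group,
               parameter = parameter, mean = mean, sd = sd, n = n,
               stringsAsFactors = FALSE)
  L <- list()
  add <- function(...) L[[length(L) + 1]] <<- row(...)

  ## overall HH cohort, by sex
  demo <- list(
    age            = list(c(54.7, 10.8), c(53.1, 11.9), c(58.0, 7.8)),
    bmi            = list(c(26.6, 4.5),  c(27.3, 4.7),  c(25.1, 3.9)),
    height         = list(c(175.5, 11.2), c(180.1, 9.7), c(165.4, 6.8)),
    time_since_dx  = list(c(10.2, 9.2),  c(10.8, 11.1), c(9.0, 3.9)),
    phleb_total    = list(c(60.6, 66.0), c(80.8, 74.5), c(28.7, 33.9)),
    phleb_annual   = list(c(6.6, 11.1),  c(7.9, 13.4),  c(4.2, 4.8)))
  grp <- c("hh_all", "hh_men", "hh_women"); ngrp <- c(24L, 16L, 8L)
  for (p in names(demo)) for (i in 1:3)
    add("cohort", grp[i], NA_character_, p, demo[[p]][[i]][1], demo[[p]][[i]][2], ngrp[i])

  morph <- list(  # joint -> parameter -> (all, men, women) mean/sd
    MCP2 = list(jsv     = list(c(131.83, 32.13), c(141.39, 33.64), c(112.73, 18.48)),
                jsw     = list(c(1.65, 0.34), c(1.71, 0.39), c(1.53, 0.15)),
                jsw_min = list(c(0.67, 0.47), c(0.60, 0.49), c(0.80, 0.43)),
                jsw_max = list(c(2.18, 0.30), c(2.24, 0.33), c(2.05, 0.15)),
                jsw_as  = list(c(9.17, 10.35), c(10.95, 11.03), c(5.61, 8.34)),
                jsw_sd  = list(c(0.33, 0.10), c(0.35, 0.10), c(0.29, 0.08))),
    MCP3 = list(jsv     = list(c(124.51, 37.46), c(137.44, 40.13), c(101.89, 17.35)),
                jsw     = list(c(1.46, 0.25), c(1.49, 0.30), c(1.40, 0.15)),
                jsw_min = list(c(0.63, 0.42), c(0.62, 0.46), c(0.66, 0.38)),
                jsw_max = list(c(2.08, 0.28), c(2.18, 0.28), c(1.90, 0.15)),
                jsw_as  = list(c(7.77, 8.39), c(7.95, 8.00), c(7.47, 9.59)),
                jsw_sd  = list(c(0.33, 0.08), c(0.36, 0.08), c(0.29, 0.06))),
    MCP4 = list(jsv     = list(c(112.08, 23.24), c(124.88, 16.54), c(88.08, 11.84)),
                jsw     = list(c(1.42, 0.20), c(1.48, 0.21), c(1.31, 0.13)),
                jsw_min = list(c(0.75, 0.34), c(0.78, 0.40), c(0.69, 0.20)),
                jsw_max = list(c(1.94, 0.22), c(2.03, 0.18), c(1.77, 0.21)),
                jsw_as  = list(c(4.67, 6.47), c(5.66, 7.89), c(2.82, 1.05)),
                jsw_sd  = list(c(0.29, 0.09), c(0.31, 0.11), c(0.26, 0.06))))
  for (j in names(morph)) for (p in names(morph[[j]])) for (i in 1:3)
    add("cohort", grp[i], j, p, morph[[j]][[p]][[i]][1], morph[[j]][[p]][[i]][2], ngrp[i])

  ## matched subanalysis: HH women vs control women (n = 8 each, MCP 2-3)
  wm <- list(
    demo = list(age = list(c(58.0, 7.8), c(58.0, 8.2)),
                bmi = list(c(25.1, 3.9), c(25.4, 3.0)),
                height = list(c(165.4, 6.8), c(165.9, 6.5))),
    MCP2 = list(jsv     = list(c(81.52, 14.90), c(87.5, 11.6)),
                jsw     = list(c(1.56, 0.16), c(1.80, 0.26)),
                jsw_min = list(c(0.83, 0.41), c(1.27, 0.36)),
                jsw_max = list(c(2.64, 0.20), c(2.78, 0.12)),
                jsw_as  = list(c(5.06, 5.23), c(2.39, 0.83)),
                jsw_sd  = list(c(0.33, 0.06), c(0.28, 0.07))),
    MCP3 = list(jsv     = list(c(79.0, 7.77), c(87.8, 17.10)),
                jsw     = list(c(1.43, 0.16), c(1.66, 0.26)),
                jsw_min = list(c(0.71, 0.36), c(1.22, 0.21)),
                jsw_max = list(c(2.58, 0.31), c(2.65, 0.25)),
                jsw_as  = list(c(6.21, 6.07), c(2.21, 0.31)),
                jsw_sd  = list(c(0.33, 0.06), c(0.24, 0.07))))
  wgrp <- c("hh_women", "control_women")
  for (p in names(wm$demo)) for (i in 1:2)
    add("women_matched", wgrp[i], NA_character_, p, wm$demo[[p]][[i]][1], wm$demo[[p]][[i]][2], 8L)
  for (j in c("MCP2", "MCP3")) for (p in names(wm[[j]])) for (i in 1:2)
    add("women_matched", wgrp[i], j, p, wm[[j]][[p]][[i]][1], wm[[j]][[p]][[i]][2], 8L)

  ## matched subanalysis: HH men vs control men (n = 5 each, MCP 2-3)
  mm <- list(
    demo = list(age = list(c(59.8, 12.5), c(60.8, 15.7)),
                bmi = list(c(29.9, 6.1), c(28.0, 3.9)),
                height = list(c(175.8, 8.2), c(173.6, 10.5))),
    MCP2 = list(jsv     = list(c(106.33, 33.60), c(102.52, 21.81)),
                jsw     = list(c(1.56, 0.37), c(1.79, 0.04)),
                jsw_min = list(c(0.31, 0.33), c(1.00, 0.34)),
                jsw_max = list(c(2.77, 0.20), c(2.83, 0.10)),
                jsw_as  = list(c(14.2, 6.37), c(3.28, 1.66)),
                jsw_sd  = list(c(0.46, 0.14), c(0.37, 0.12))),
    MCP3 = list(jsv     = list(c(92.03, 29.36), c(117.85, 13.74)),
                jsw     = list(c(1.45, 0.28), c(1.72, 0.26)),
                jsw_min = list(c(0.34, 0.36), c(1.08, 0.36)),
                jsw_max = list(c(2.76, 0.24), c(2.76, 0.11)),
                jsw_as  = list(c(12.75, 6.28), c(2.78, 0.92)),
                jsw_sd  = list(c(0.49, 0.14), c(0.34, 0.10))))
  mgrp <- c("hh_men", "control_men")
  for (p in names(mm$demo)) for (i in 1:2)
    add("men_matched", mgrp[i], NA_character_, p, mm$demo[[p]][[i]][1], mm$demo[[p]][[i]][2], 5L)
  for (j in c("MCP2", "MCP3")) for (p in names(mm[[j]])) for (i in 1:2)
    add("men_matched", mgrp[i], j, p, mm[[j]][[p]][[i]][1], mm[[j]][[p]][[i]][2], 5L)

  out <- do.call(rbind, L)
  out[, c("table", "group", "joint", "parameter", "mean", "sd", "n")]
}
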