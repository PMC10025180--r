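# cohort_statistics: normality-routed two-group tests, matched-pair tests,
# chi-squared proportions, Spearman correlations with exact permutation p for
# small n, 1:1 sex/age-strata case-control matching, and percent contrasts.

new_stat_result <- function(test, statistic, p_value, n1, n2 = NA_integer_,
                            route = NA_character_, estimate = NA_real_) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 n1 = n1, n2 = n2, route = route, estimate = estimate),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s%s)%s\n", x$test,
              x$statistic, x$p_value, x$n1,
              if (!is.na(x$n2)) paste0("/", x$n2) else "",
              if (!is.na(x$route)) paste0(", route = ", x$route) else ""))
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' @param x numeric vector, n >= 3, non-constant.
#' @param alpha normality gate (default 0.05); `is_normal` attribute is
#'   `p >= alpha`.
#' @return `stat_result` with the W statistic and p-value; element
#'   `is_normal` gives the routing decision.
#' @export
shapiro_normality <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) == 1) stop("constant input")
  sw <- shapiro.test(x)
  out <- new_stat_result("shapiro_wilk", unname(sw$statistic), sw$p.value,
                         length(x))
  out$is_normal <- sw$p.value >= alpha
  out
}

# TRUE/FALSE normality for routing; NA when untestable (n < 3 or constant)
routable_normal <- function(x, alpha) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(unique(x)) == 1) return(NA)
  shapiro_normality(x, alpha)$is_normal
}

#' Two-group comparison with normality routing
#'
#' Follows the study's test selection: Shapiro-Wilk on both groups (paired:
#' on the differences) at `alpha`; when normal, Student's t-test (paired t
#' when `paired`), otherwise Mann-Whitney U (Wilcoxon signed-rank when
#' `paired`). The Mann-Whitney p-value is exact when there are no ties and
#' the smaller group has at most `exact_max` observations, otherwise the
#' mid-rank normal approximation (without continuity correction) is used.
#' Untestable normality (n < 3 or constant input) routes to the
#' nonparametric branch. Degenerate comparisons (no variation, or paired
#' differences all zero) report p = 1 with route `"degenerate"`.
#'
#' @param a,b numeric vectors (equal length when `paired`).
#' @param paired paired comparison flag.
#' @param alpha normality gate.
#' @param exact_max largest min-group size for exact Mann-Whitney /
#'   signed-rank p-values.
#' @param route `"auto"` (Shapiro-Wilk routing, the default), or force the
#'   `"parametric"` / `"nonparametric"` branch.
#' @return `stat_result` with the test used, statistic, two-sided p, group
#'   sizes and the normality route taken.
#' @export
compare_groups <- function(a, b, paired = FALSE, alpha = 0.05, exact_max = 8L,
                           route = c("auto", "parametric", "nonparametric")) {
  route <- match.arg(route)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  if (paired && length(a) != length(b)) stop("length mismatch for paired comparison")
  if (!paired && (length(a) < 2 || length(b) < 2)) stop("need n >= 2 per group")

  if (paired) {
    d <- a - b
    if (all(d == 0))
      return(new_stat_result("paired_t", 0, 1, length(a), length(b), "degenerate"))
    normal <- switch(route, auto = routable_normal(d, alpha),
                     parametric = TRUE, nonparametric = FALSE)
    if (isTRUE(normal)) {
      tt <- t.test(a, b, paired = TRUE)
      return(new_stat_result("paired_t", unname(tt$statistic), tt$p.value,
                             length(a), length(b), "normal",
                             unname(tt$estimate)))
    }
    dd <- d[d != 0]
    exact <- length(dd) <= exact_max && !any(duplicated(abs(dd)))
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = exact,
                                       correct = FALSE))
    return(new_stat_result("wilcoxon_signed_rank", unname(wt$statistic),
                           wt$p.value, length(a), length(b),
                           if (is.na(normal)) "non_normal (untestable)" else "non_normal"))
  }

  if (length(unique(c(a, b))) == 1)
    return(new_stat_result("t", 0, 1, length(a), length(b), "degenerate"))
  normal <- switch(route,
    auto = isTRUE(routable_normal(a, alpha)) && isTRUE(routable_normal(b, alpha)),
    parametric = TRUE, nonparametric = FALSE)
  if (normal) {
    tt <- t.test(a, b, var.equal = TRUE)
    return(new_stat_result("t", unname(tt$statistic), tt$p.value,
                           length(a), length(b), "normal",
                           unname(diff(rev(tt$estimate)))))
  }
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && min(length(a), length(b)) <= exact_max
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = FALSE))
  new_stat_result("mann_whitney", unname(wt$statistic), wt$p.value,
                  length(a), length(b), "non_normal")
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Pearson X^2 without continuity correction, df = 1, two-sided p.
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return `stat_result`.
#' @export
chi_squared_proportions <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) stop("zero margin")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  new_stat_result("chi_squared", unname(ct$statistic), ct$p.value,
                  sum(counts[1, ]), sum(counts[2, ]))
}

# all permutations of 1..n as an (n! x n) matrix
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[r + seq_len(nrow(sub)), 1] <- k
    out[r + seq_len(nrow(sub)), -1] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation
#'
#' Tie-safe rho via mid-ranked Pearson correlation. For n up to `exact_max`
#' the two-sided p-value is exact: the proportion of all n! permutations of
#' one variable with |rho| at least as large as observed. For larger n the
#' t approximation on n - 2 degrees of freedom is used. Constant input gives
#' an undefined rho, flagged with route `"degenerate"`.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param exact_max largest n for the exact permutation p-value (default 8).
#' @return `stat_result` with `estimate` = rho.
#' @export
spearman_corr <- function(x, y, exact_max = 8L) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(new_stat_result("spearman", NA_real_, NA_real_, n,
                           route = "degenerate"))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_max) {
    perms <- permutations_of(n)
    rho_perm <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    route <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
    route <- "t_approximation"
  }
  new_stat_result("spearman", rho, p, n, route = route, estimate = rho)
}

#' 1:1 case-control matching by sex and age strata
#'
#' Greedy 1:1 matching inside (sex, age-band) strata with bands of
#' `strata_width` years anchored at multiples of the width
#' (`floor(age/width) * width`). Within a stratum, candidate pairs are taken
#' in order of smallest absolute age difference, ties broken by
#' lexicographically smallest (case id, control id). Unmatched cases are
#' reported, not raised.
#'
#' @param cases,controls data.frames with columns `id`, `sex`, `age`.
#' @param strata_width age band width in years (default 5).
#' @return list with `pairs` (data.frame `case_id`, `control_id`, `sex`,
#'   `age_band`, `age_diff`) and `unmatched_cases` (ids).
#' @export
match_case_control <- function(cases, controls, strata_width = 5) {
  stopifnot(all(c("id", "sex", "age") %in% names(cases)),
            all(c("id", "sex", "age") %in% names(controls)))
  if (nrow(cases) == 0 || nrow(controls) == 0) stop("empty candidate pool")
  band <- function(age) floor(age / strata_width) * strata_width
  cand <- merge(
    data.frame(case_id = as.character(cases$id), sex = cases$sex,
               case_age = cases$age, band = band(cases$age),
               stringsAsFactors = FALSE),
    data.frame(control_id = as.character(controls$id), sex = controls$sex,
               control_age = controls$age, band = band(controls$age),
               stringsAsFactors = FALSE),
    by = c("sex", "band"))
  pairs <- NULL
  if (nrow(cand) > 0) {
    cand$age_diff <- abs(cand$case_age - cand$control_age)
    cand <- cand[order(cand$age_diff, cand$case_id, cand$control_id), , drop = FALSE]
    used_case <- character(0); used_control <- character(0)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (cand$case_id[i] %in% used_case || cand$control_id[i] %in% used_control)
        next
      keep[i] <- TRUE
      used_case <- c(used_case, cand$case_id[i])
      used_control <- c(used_control, cand$control_id[i])
    }
    pairs <- cand[keep, c("case_id", "control_id", "sex", "band", "age_diff"),
                  drop = FALSE]
    names(pairs)[4] <- "age_band"
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(case_id = character(0), control_id = character(0),
                        sex = character(0), age_band = numeric(0),
                        age_diff = numeric(0), stringsAsFactors = FALSE)
  }
  list(pairs = pairs,
       unmatched_cases = setdiff(as.character(cases$id), pairs$case_id))
}

#' Percent difference between two group means
#'
#' `100 * (comparison - reference) / reference`, rounded to one decimal for
#' reporting (the convention of the published contrasts).
#'
#' @param reference_mean reference group mean (non-zero).
#' @param comparison_mean comparison group mean.
#' @param digits decimals for reporting (default 1).
#' @return percent difference.
#' @export
percent_difference <- function(reference_mean, comparison_mean, digits = 1) {
  if (any(reference_mean == 0)) stop("zero reference")
  round(100 * (comparison_mean - reference_mean) / reference_mean, digits)
}

#' Group summary table with routed tests
#'
#' Mirrors the study's group comparison tables: per joint and morphometry
#' parameter, the unadjusted mean and SD of each group, the percent
#' difference of group `groups[1]` relative to `groups[2]`, and the p-value
#' of the normality-routed two-group test. Ankylotic joints are excluded.
#'
#' @param cohort cohort data.frame (see [synthesize_cohort()]).
#' @param groups length-2 character vector: (comparison, reference) levels of
#'   `cohort$group`.
#' @param paired run paired tests with rows aligned by subject id order
#'   within group (requires equal group sizes).
#' @param alpha normality gate for routing.
#' @return data.frame with one row per joint x parameter.
#' @export
assemble_group_table <- function(cohort, groups, paired = FALSE, alpha = 0.05) {
  stopifnot(is.data.frame(cohort), length(groups) == 2)
  if (!"group" %in% names(cohort)) stop("grouping column absent")
  if (nrow(cohort) == 0) stop("empty cohort")
  cohort <- cohort[!isTRUE(cohort$ankylotic) & cohort$group %in% groups, , drop = FALSE]
  cohort <- cohort[!cohort$ankylotic, , drop = FALSE]
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  rows <- list()
  for (j in sort(unique(cohort$joint))) {
    for (p in intersect(MORPH_PARAMS, names(cohort))) {
      a <- cohort[[p]][cohort$joint == j & cohort$group == groups[1]]
      b <- cohort[[p]][cohort$joint == j & cohort$group == groups[2]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) == 0 || length(b) == 0) next
      cmp <- if (length(a) >= 2 && length(b) >= 2 && (!paired || length(a) == length(b)))
        compare_groups(a, b, paired = paired, alpha = alpha)
      else NULL
      rows[[length(rows) + 1]] <- data.frame(
        joint = j, parameter = p,
        n_1 = length(a), mean_1 = mean(a), sd_1 = sd0(a),
        n_2 = length(b), mean_2 = mean(b), sd_2 = sd0(b),
        percent_diff = percent_difference(mean(b), mean(a)),
        test = if (is.null(cmp)) NA_character_ else cmp$test,
        p_value = if (is.null(cmp)) NA_real_ else cmp$p_value,
        route = if (is.null(cmp)) NA_character_ else cmp$route,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "groups") <- groups
  out
}

#' Published percent contrasts recomputed from the reference group means
#'
#' Recomputes, by exact arithmetic on the reference parameter table
#' ([hh_reference_params()]), the percent contrasts quoted in the study's
#' results: JSV, mean JSW and JSW.MAX of HH men relative to HH women (MCP
#' 2-4), and the matched-control contrasts of HH women (MCP 2-3) and HH men
#' (MCP 3).
#'
#' @param params reference table, defaults to [hh_reference_params()].
#' @return data.frame with columns `contrast`, `table`, `joint`, `parameter`,
#'   `reference_group`, `comparison_group`, `reference_mean`,
#'   `comparison_mean`, `percent`.
#' @export
published_contrasts <- function(params = hh_reference_params()) {
  want <- rbind(
    data.frame(contrast = "jsv_men_vs_women_mcp2",     table = "cohort", joint = "MCP2", parameter = "jsv",     cmp = "hh_men",   ref = "hh_women"),
    data.frame(contrast = "jsv_men_vs_women_mcp3",     table = "cohort", joint = "MCP3", parameter = "jsv",     cmp = "hh_men",   ref = "hh_women"),
    data.frame(contrast = "jsv_men_vs_women_mcp4",     table = "cohort", joint = "MCP4", parameter = "jsv",     cmp = "hh_men",   ref = "hh_women"),
    data.frame(contrast = "jsw_men_vs_women_mcp4",     table = "cohort", joint = "MCP4", parameter = "jsw",     cmp = "hh_men",   ref = "hh_women"),
    data.frame(contrast = "jswmax_men_vs_women_mcp3",  table = "cohort", joint = "MCP3", parameter = "jsw_max", cmp = "hh_men",   ref = "hh_women"),
    data.frame(contrast = "jswmax_men_vs_women_mcp2",  table = "cohort", joint = "MCP2", parameter = "jsw_max", cmp = "hh_men",   ref = "hh_women"),
    data.frame(contrast = "jswsd_women_vs_ctrl_mcp3",  table = "women_matched", joint = "MCP3", parameter = "jsw_sd",  cmp = "hh_women", ref = "control_women"),
    data.frame(contrast = "jswmin_women_vs_ctrl_mcp3", table = "women_matched", joint = "MCP3", parameter = "jsw_min", cmp = "hh_women", ref = "control_women"),
    data.frame(contrast = "jsw_women_vs_ctrl_mcp3",    table = "women_matched", joint = "MCP3", parameter = "jsw",     cmp = "hh_women", ref = "control_women"),
    data.frame(contrast = "jsw_women_vs_ctrl_mcp2",    table = "women_matched", joint = "MCP2", parameter = "jsw",     cmp = "hh_women", ref = "control_women"),
    data.frame(contrast = "jswas_men_vs_ctrl_mcp3",    table = "men_matched",   joint = "MCP3", parameter = "jsw_as",  cmp = "hh_men",   ref = "control_men"))
  get_mean <- function(tab, grp, j, p) {
    r <- params[params$table == tab & params$group == grp &
                  !is.na(params$joint) & params$joint == j &
                  params$parameter == p, ]
    stopifnot(nrow(r) == 1)
    r$mean
  }
  want$reference_mean <- mapply(get_mean, want$table, want$ref, want$joint, want$parameter)
  want$comparison_mean <- mapply(get_mean, want$table, want$cmp, want$joint, want$parameter)
  want$percent <- percent_difference(want$reference_mean, want$comparison_mean)
  names(want)[names(want) == "cmp"] <- "comparison_group"
  names(want)[names(want) == "ref"] <- "reference_group"
  want
}
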