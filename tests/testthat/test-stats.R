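test_that("shapiro routing flags a heavy outlier sample as non-normal", {
  r <- shapiro_normality(c(1, 1, 1, 1, 1, 1, 1, 100))
  expect_false(r$is_normal)
  set.seed(1)
  expect_true(shapiro_normality(rnorm(500))$is_normal)
  expect_error(shapiro_normality(rep(2, 10)), "constant")
  expect_error(shapiro_normality(c(1, 2)), "at least 3")
})

test_that("identical groups give a zero-effect parametric result", {
  r <- compare_groups(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$test, "t")
})

test_that("forced Mann-Whitney on fully separated triples is exact", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6), route = "nonparametric")
  expect_equal(r$test, "mann_whitney")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)       # 2/20 assignments at or beyond U = 0
})

test_that("paired comparisons with all-zero differences are degenerate", {
  r <- compare_groups(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(r$p_value, 1)
  expect_equal(r$route, "degenerate")
})

test_that("exact Mann-Whitney p matches full enumeration for small groups", {
  set.seed(14)
  for (n1 in c(2, 4, 6)) for (n2 in c(3, 5, 8)) {
    a <- round(runif(n1), 6); b <- round(runif(n2) + 0.2, 6)
    r <- compare_groups(a, b, route = "nonparametric")
    expect_equal(r$p_value, mw_enumeration_p(a, b), tolerance = 1e-12,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("tied samples fall back to the mid-rank normal approximation", {
  a <- c(1, 2, 2, 3, 5, 5)
  b <- c(2, 3, 3, 6, 7, 7)
  r <- compare_groups(a, b, route = "nonparametric")
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  expect_equal(r$p_value, ref$p.value)
})

test_that("chi-squared proportions follow the closed form", {
  expect_equal(chi_squared_proportions(matrix(c(20, 0, 0, 20), 2))$statistic, 40)
  r <- chi_squared_proportions(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(chi_squared_proportions(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(chi_squared_proportions(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("spearman rho hits the exact bounds on monotone data", {
  expect_equal(spearman_corr(1:5, (1:5)^3)$statistic, 1)
  expect_equal(spearman_corr(1:4, 4:1)$statistic, -1)
  r <- spearman_corr(c(3, 3, 3), c(1, 2, 3))
  expect_equal(r$route, "degenerate")
  expect_true(is.na(r$statistic))
})

test_that("exact spearman p equals the full permutation distribution", {
  set.seed(8)
  for (n in c(4, 5, 6)) {
    x <- runif(n); y <- runif(n)
    r <- spearman_corr(x, y)
    expect_equal(r$route, "exact_permutation")
    expect_equal(r$p_value, spearman_enumeration_p(x, y), tolerance = 1e-12)
  }
})

test_that("case-control matching respects strata and minimizes age gaps", {
  m <- match_case_control(
    data.frame(id = c("case56", "case59"), sex = "F", age = c(56, 59)),
    data.frame(id = c("ctl55", "ctl59"), sex = "F", age = c(55, 59)))
  expect_equal(nrow(m$pairs), 2)
  got <- m$pairs[order(m$pairs$case_id), ]
  expect_equal(got$control_id, c("ctl55", "ctl59"))
  expect_equal(sum(got$age_diff), 1)      # minimal total age difference
  # sex mismatch leaves the case unmatched
  m2 <- match_case_control(data.frame(id = "a", sex = "F", age = 58),
                           data.frame(id = "b", sex = "M", age = 58))
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_cases, "a")
  # a single in-stratum candidate matches
  m3 <- match_case_control(data.frame(id = "a", sex = "F", age = 58),
                           data.frame(id = "b", sex = "F", age = 57))
  expect_equal(m3$pairs$age_band, 55)
})

test_that("matched pairs always share sex and five-year band (property)", {
  set.seed(99)
  for (rep in 1:25) {
    cases <- data.frame(id = sprintf("c%02d", 1:12),
                        sex = sample(c("M", "F"), 12, TRUE),
                        age = runif(12, 35, 75))
    controls <- data.frame(id = sprintf("k%02d", 1:15),
                           sex = sample(c("M", "F"), 15, TRUE),
                           age = runif(15, 35, 75))
    m <- match_case_control(cases, controls)
    if (nrow(m$pairs) == 0) next
    ca <- cases[match(m$pairs$case_id, cases$id), ]
    co <- controls[match(m$pairs$control_id, controls$id), ]
    expect_true(all(ca$sex == co$sex))
    expect_true(all(floor(ca$age / 5) == floor(co$age / 5)))
    expect_false(any(duplicated(m$pairs$case_id)))
    expect_false(any(duplicated(m$pairs$control_id)))
  }
})

test_that("percent differences reproduce the published contrasts", {
  expect_equal(percent_difference(112.73, 141.39), 25.4)
  expect_equal(percent_difference(1.22, 0.71), -41.8)
  expect_equal(percent_difference(2.78, 12.75), 358.6)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(0, 1), "zero reference")
})

test_that("group tables summarize means, SDs and routed tests", {
  p <- hh_reference_params()
  pars <- cohort_params(
    p[p$table == "cohort" & p$group %in% c("hh_men", "hh_women"), ],
    n = c(hh_men = 12, hh_women = 12), seed = 3)
  coh <- synthesize_cohort(pars)
  tab <- assemble_group_table(coh, groups = c("hh_men", "hh_women"))
  expect_equal(nrow(tab), 3 * 6)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  expect_true(all(tab$test %in% c("t", "mann_whitney")))
  # single subject per group: means are the raw values, SD zero
  one <- coh[coh$id %in% c(coh$id[1], coh$id[coh$group == "hh_women"][1]), ]
  t1 <- assemble_group_table(one, groups = c("hh_men", "hh_women"))
  expect_true(all(t1$sd_1 == 0) && all(t1$sd_2 == 0))
  # ankylotic joints are excluded from the table
  coh2 <- coh
  coh2$ankylotic[coh2$joint == "MCP4"] <- TRUE
  t2 <- assemble_group_table(coh2, groups = c("hh_men", "hh_women"))
  expect_false("MCP4" %in% t2$joint)
})
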