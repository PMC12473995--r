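test_that("single-factor grading honours interval closure and the V+ flag", {
  expect_equal(single_factor_grade(0.058, "TP")$grade, 4L)
  expect_equal(single_factor_grade(9.28, "DO")$grade, 1L)

  g <- single_factor_grade(18.94, "TN")
  expect_equal(g$grade, 5L)
  expect_true(g$exceeds_v)

  # regulatory bounds are inclusive for grade I
  expect_equal(single_factor_grade(0.2, "TN")$grade, 1L)
  expect_equal(single_factor_grade(7.5, "DO")$grade, 1L)
  # (lower, upper] closure: a boundary value belongs to the lower grade
  expect_equal(single_factor_grade(0.5, "TN")$grade, 2L)
  expect_equal(single_factor_grade(0.5000001, "TN")$grade, 3L)
  expect_equal(single_factor_grade(6.5, "DO")$grade, 3L)
  # DO below the class-V floor still grades V, flagged
  g2 <- single_factor_grade(4.0, "DO", "customized")
  expect_equal(g2$grade, 5L)
  expect_true(g2$exceeds_v)
  # below-detection zero is grade I for cost indicators
  expect_equal(single_factor_grade(0, "TN")$grade, 1L)

  expect_error(single_factor_grade(-0.1, "TN"), "negative")

  # scheme difference: CODMn 1.5 is grade I under gb3838, II under customized
  expect_equal(single_factor_grade(1.5, "CODMn", "gb3838")$grade, 1L)
  expect_equal(single_factor_grade(1.5, "CODMn", "customized")$grade, 2L)
})

test_that("worst-factor grade takes the maximum over indicators", {
  clean <- c(DO = 9, TN = 0.1, NH3N = 0.05, TP = 0.008, CODMn = 0.5)
  expect_equal(worst_factor_grade(clean)$grade, 1L)

  one_bad <- clean
  one_bad["TP"] <- 0.18
  expect_equal(worst_factor_grade(one_bad)$grade, 5L)
  expect_equal(worst_factor_grade(one_bad)$worst_indicator, "TP")

  # high DO cannot mask severe TN pollution
  l8 <- c(DO = 9.0, TN = 4.54, NH3N = 0.25, TP = 0.09, CODMn = 4.51)
  w <- worst_factor_grade(l8)
  expect_equal(w$grade, 5L)
  expect_true(w$exceeds_v)
  expect_equal(w$worst_indicator, "TN")
  # max property: the call is >= every per-indicator grade
  expect_true(all(w$grade >= w$by_indicator))

  expect_error(worst_factor_grade(clean[-1]), "DO")
})

test_that("stratified compliance rates come from raw counts", {
  # 19 downstream sites with exactly one NH3N failure at class III
  n <- 19
  df <- data.frame(
    site_id = sprintf("L%d", 1:n), reach = "tributary", section = "downstream",
    DO = 9, TN = 0.1, NH3N = c(rep(0.2, n - 1), 1.6), TP = 0.01, CODMn = 0.5
  )
  rep3 <- compliance_stats(df, class_level = 3)
  nh <- rep3[rep3$indicator == "NH3N", ]
  expect_equal(nh$n, 19)
  expect_equal(nh$n_compliant, 18)
  expect_equal(nh$exceedance_rate, 1 / 19)
  expect_equal(round(100 * nh$exceedance_rate, 2), 5.26)
  # zero failures elsewhere
  expect_equal(rep3[rep3$indicator == "TN", ]$exceedance_rate, 0)

  # planted failures in a 65-site stratum: 13/65 = 20.0%
  n2 <- 65
  df2 <- data.frame(
    site_id = sprintf("S%d", 1:n2), reach = "tributary", section = "midstream",
    DO = 9, TN = c(rep(0.4, n2 - 13), rep(1.8, 13)), NH3N = 0.1, TP = 0.01,
    CODMn = 0.5
  )
  tn <- compliance_stats(df2)[compliance_stats(df2)$indicator == "TN", ]
  expect_equal(tn$exceedance_rate, 0.2)
  expect_equal(tn$n - tn$n_compliant, 13)

  # every printed rate regenerates its count
  all_rep <- compliance_stats(generate_sites(seed = 2))
  expect_equal(all_rep$compliance_rate * all_rep$n, all_rep$n_compliant)
  expect_true(all(all_rep$compliance_rate >= 0 & all_rep$compliance_rate <= 1))
})

test_that("descriptive statistics report sample sd and CV", {
  df <- toy_sites()
  df <- rbind(df, df, df)  # n = 6
  ds <- descriptive_stats(df)
  expect_equal(ds$indicator, wq_indicators())
  tn <- ds[ds$indicator == "TN", ]
  expect_equal(tn$mean, mean(df$TN))
  expect_equal(tn$sd, sd(df$TN))
  expect_equal(tn$cv, sd(df$TN) / mean(df$TN))

  # constant column: sd 0, CV 0; all-zero column: CV undefined
  cdf <- data.frame(site_id = c("a", "b"), DO = c(8, 8), TN = c(0, 0),
                    NH3N = c(1, 1), TP = c(0.01, 0.01), CODMn = c(2, 2))
  cds <- descriptive_stats(cdf)
  expect_equal(cds$sd[cds$indicator == "DO"], 0)
  expect_equal(cds$cv[cds$indicator == "DO"], 0)
  expect_true(cds$cv_undefined[cds$indicator == "TN"])
})

test_that("grade distributions recompute percentages from counts", {
  # published tributary grade counts
  trib <- grade_distribution(rep(1:5, c(9, 15, 8, 16, 17)))
  expect_equal(trib$count, c(9, 15, 8, 16, 17))
  expect_equal(trib$total, rep(65, 5))
  expect_equal(round(trib$percent, 1), c(13.8, 23.1, 12.3, 24.6, 26.2))

  # single site
  one <- grade_distribution(3L)
  expect_equal(one$percent, c(0, 0, 100, 0, 0))

  # stratified counts sum to their totals
  g <- c(rep(1:5, c(4, 5, 5, 4, 0)), rep(1:5, c(9, 15, 8, 16, 17)))
  by <- c(rep("main", 18), rep("tributary", 65))
  gd <- grade_distribution(g, by)
  totals <- tapply(gd$count, gd$stratum, sum)
  expect_equal(as.vector(totals[c("main", "tributary")]), c(18, 65))
  expect_equal(sum(gd$percent[gd$stratum == "main"]), 100)

  expect_error(grade_distribution(integer(0)), "no grades")
  expect_error(grade_distribution(c(1, 6)), "1-5")
})

test_that("fuzzy grade never beats the single-grade call on in-grade samples", {
  # when every indicator sits strictly inside one grade's interval the
  # fuzzy call cannot be worse than that grade
  sch <- load_scheme("customized")
  coh <- generate_planted_cohort(100, seed = 31, central = 0.4)
  res <- fce(coh$samples, weights = "uniform")
  wf <- vapply(seq_len(100), function(i)
    worst_factor_grade(coh$samples[i, wq_indicators()])$grade, integer(1))
  expect_true(all(res$results$grade <= wf))
})
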