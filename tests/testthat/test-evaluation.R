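make_R <- function(rows) {
  R <- do.call(rbind, rows)
  R <- rbind(R, matrix(rep(c(1, 0, 0, 0, 0), 5 - nrow(R)),
                       ncol = 5, byrow = TRUE))[1:5, ]
  dimnames(R) <- list(wq_indicators(), c("I", "II", "III", "IV", "V"))
  class(R) <- c("membership_matrix", class(R))
  R
}

test_that("composite vector is the weighted row mix, ties go to the worse grade", {
  # selector weight picks out one indicator row
  R <- make_R(list(c(0.2, 0.8, 0, 0, 0)))
  e <- evaluate_sample(R, c(1, 0, 0, 0, 0))
  expect_equal(unname(e$b), c(0.2, 0.8, 0, 0, 0))
  expect_equal(e$grade, 2L)

  # identical rows: B equals the common row for any valid weights
  d <- c(0.1, 0.2, 0.3, 0.25, 0.15)
  R2 <- make_R(rep(list(d), 5))
  for (w in list(rep(0.2, 5), c(0.5, 0.2, 0.1, 0.1, 0.1))) {
    expect_equal(unname(evaluate_sample(R2, w)$b), d)
  }

  # exact two-way tie resolves to the higher-numbered grade and is flagged
  R3 <- make_R(list(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0)))
  e3 <- evaluate_sample(R3, c(0.5, 0.5, 0, 0, 0))
  expect_equal(unname(e3$b[1:2]), c(0.5, 0.5))
  expect_equal(e3$grade, 2L)
  expect_true(e3$ambiguous)

  expect_error(evaluate_sample(R3, c(0.5, 0.5)), "match")
})

test_that("ambiguity margin is the gap between the top two normalized degrees", {
  a <- flag_ambiguity(c(0.5, 0.5, 0, 0, 0))
  expect_equal(a$margin, 0)
  expect_true(a$ambiguous)

  b <- flag_ambiguity(c(0.8, 0.1, 0.1, 0, 0))
  expect_equal(b$margin, 0.7)
  expect_false(b$ambiguous)

  c3 <- flag_ambiguity(c(0.45, 0.30, 0.25, 0, 0))
  expect_equal(c3$margin, 0.15, tolerance = 1e-12)
  expect_true(c3$ambiguous)

  # normalization happens before the margin is taken
  expect_equal(flag_ambiguity(c(9, 6, 5, 0, 0) * 0.05)$margin, 0.15,
               tolerance = 1e-12)
  expect_error(flag_ambiguity(c(0, 0, 0, 0, 0)), "zero")
})

test_that("composite memberships conserve mass across a cohort", {
  sites <- generate_sites(seed = 11)
  res <- fce(sites)
  bsum <- rowSums(res$results[, paste0("b", 1:5)])
  expect_lt(max(abs(bsum - 1)), 1e-9)
  expect_true(all(res$results$margin >= 0 & res$results$margin <= 1))
  expect_equal(res$results$ambiguous, res$results$margin < 0.2)
})

test_that("degrading every indicator degrades the composite vector", {
  # first-order stochastic dominance of B over the grade index: a
  # uniformly worse sample never has more cumulative mass on the clean
  # side, at any grade cutoff (the argmax grade itself is not monotone
  # in general: mass arriving in a middle grade from the clean side can
  # overtake a saturated worst-grade block)
  sch <- load_scheme("customized")
  fns <- build_membership_functions(sch)
  w <- rep(0.2, 5)
  set.seed(99)
  for (i in 1:50) {
    a <- c(DO = runif(1, 5, 10), TN = runif(1, 0, 2.5),
           NH3N = runif(1, 0, 2.5), TP = runif(1, 0, 0.25),
           CODMn = runif(1, 0, 5.5))
    # degrade every indicator (lower DO, raise the cost indicators)
    worse <- a
    worse["DO"] <- a["DO"] * runif(1, 0.6, 1)
    for (ind in c("TN", "NH3N", "TP", "CODMn")) {
      worse[ind] <- a[ind] * runif(1, 1, 1.8)
    }
    ba <- evaluate_sample(membership_matrix(a, fns), w)$b
    bw <- evaluate_sample(membership_matrix(worse, fns), w)$b
    expect_true(all(cumsum(bw) <= cumsum(ba) + 1e-12))
  }
})

test_that("near-ties within numerical noise resolve to the worse grade", {
  # composite masses that differ by less than 1e-9 count as tied, so a
  # sub-epsilon deficit on the worse grade cannot flip a conservative
  # call
  R <- make_R(list(c(0, 1, 0, 0, 0), c(0, 0, 0, 0, 1), c(1, 0, 0, 0, 0)))
  eps <- 1e-12
  e <- evaluate_sample(R, c(0.4, 0.4 - eps, 0.2 + eps, 0, 0))
  expect_gt(e$b[2], e$b[5])  # grade II leads, but only by eps
  expect_equal(e$grade, 5L)
})

test_that("EWQI is anchored at the class-III bounds and rises with pollution", {
  # every indicator exactly at its grade-III bound scores exactly 100
  s3 <- c(DO = 6.0, TN = 1.0, NH3N = 1.0, TP = 0.05, CODMn = 3.0)
  for (w in list(rep(0.2, 5), c(0.4, 0.3, 0.1, 0.1, 0.1))) {
    expect_equal(ewqi(s3, w, "customized")$score, 100, tolerance = 1e-12)
  }

  # doubling every cost concentration strictly raises the score
  s <- c(DO = 8, TN = 0.8, NH3N = 0.3, TP = 0.03, CODMn = 2)
  s2 <- s
  s2[-1] <- s2[-1] * 2
  w <- rep(0.2, 5)
  expect_gt(ewqi(s2, w)$score, ewqi(s, w)$score)

  # zero DO hits the rating cap rather than dividing by zero
  s0 <- s
  s0["DO"] <- 0
  expect_equal(unname(ewqi(s0, w)$q["DO"]), 500)

  # independent spreadsheet-style recomputation on random samples
  set.seed(7)
  sch <- load_scheme("customized")
  for (i in 1:20) {
    smp <- c(DO = runif(1, 0.5, 12), TN = rlnorm(1), NH3N = rlnorm(1, -1.5),
             TP = rlnorm(1, -3.5), CODMn = runif(1, 0.1, 6))
    wr <- runif(5)
    wr <- wr / sum(wr)
    expected <- sum(wr * pmin(c(
      100 * 6.0 / smp["DO"], 100 * smp["TN"] / 1.0, 100 * smp["NH3N"] / 1.0,
      100 * smp["TP"] / 0.05, 100 * smp["CODMn"] / 3.0
    ), 500))
    expect_equal(ewqi(smp, wr, sch)$score, expected, tolerance = 1e-12)
  }
})

test_that("method comparison tabulates agreement and discordance", {
  g <- data.frame(site_id = c("a", "b", "c"), grade = c(1L, 3L, 5L))
  cmp <- compare_methods(g, g)
  expect_equal(cmp$n_discordant, 0)
  expect_equal(diag(cmp$confusion), c(I = 1, II = 0, III = 1, IV = 0, V = 1))

  # maximal discordance: fuzzy V against index I
  h <- g
  h$grade[3] <- 1L
  cmp2 <- compare_methods(g, h)
  expect_equal(cmp2$discordant_sites, "c")
  expect_equal(cmp2$confusion["V", "I"], 1)

  expect_error(compare_methods(g, g[1:2, ]), "site set")
})

test_that("fuzzy grading issues more severe class-V calls than the index", {
  # the saturating class-V membership flags hotspot sites the averaging
  # index smooths over (the qualitative direction of disagreement)
  nv <- vapply(1:5, function(seed) {
    sites <- generate_sites(seed = seed)
    res <- fce(sites)
    eg <- vapply(seq_len(nrow(sites)),
                 function(i) ewqi(sites[i, ], res$weights)$grade, integer(1))
    c(sum(res$results$grade == 5), sum(eg == 5))
  }, numeric(2))
  expect_true(all(nv[1, ] >= nv[2, ]))
  expect_gt(sum(nv[1, ]), sum(nv[2, ]))
})

test_that("results export round-trips the grade table", {
  res <- fce(generate_sites(seed = 5))
  pc <- tempfile(fileext = ".csv")
  pj <- tempfile(fileext = ".json")
  write_results(res, pc)
  write_results(res, pj)
  back <- utils::read.csv(pc)
  expect_equal(back$grade, res$results$grade)
  rep <- jsonlite::read_json(pj)
  expect_equal(length(rep$sites), nrow(res$results))
  expect_equal(rep$sites[[1]]$grade, res$results$grade_label[1])
})
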