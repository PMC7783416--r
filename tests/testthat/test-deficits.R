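test_that("thresholds use the interpolated order-statistic convention", {
  set.seed(1)
  sf <- make_score_frame(data.frame(recognition = sample(1:100),
                                    learning = sample(1:100),
                                    regulation = sample(1:100)))
  th <- estimate_thresholds(sf$scores, sf$participants, q = 0.10)
  # sort-and-count oracle: type-7 h = (n-1)q + 1 = 10.9 on 1..100
  expect_equal(th$cutoff, rep(10.9, 3), tolerance = 1e-12)
  fl <- classify_deficits(sf$scores, th, sf$participants)
  expect_identical(sum(fl$rec_deficit), 10L)
  expect_true(all(sort(sf$scores$recognition)[1:10] <= th$cutoff[1]))
  # nearest-rank alternative
  th1 <- estimate_thresholds(sf$scores, sf$participants, q = 0.10, type = 1)
  expect_equal(th1$cutoff, rep(10, 3))
})

test_that("q = 0 flags nobody and large-n normal cutoff approaches -1.28", {
  set.seed(2)
  sf <- make_score_frame(data.frame(recognition = rnorm(50),
                                    learning = rnorm(50),
                                    regulation = rnorm(50)))
  th0 <- estimate_thresholds(sf$scores, sf$participants, q = 0)
  fl0 <- classify_deficits(sf$scores, th0, sf$participants)
  expect_identical(sum(fl0$n_deficits), 0L)

  set.seed(3)
  n <- 2e5
  sfn <- make_score_frame(data.frame(recognition = rnorm(n),
                                     learning = rnorm(n),
                                     regulation = rnorm(n)))
  thn <- estimate_thresholds(sfn$scores, sfn$participants, q = 0.10)
  expect_true(all(abs(thn$cutoff - qnorm(0.10)) < 0.02))
})

test_that("in-sample control flag rate equals q when n is divisible by 1/q", {
  set.seed(4)
  sf <- make_score_frame(data.frame(recognition = rnorm(200),
                                    learning = rnorm(200),
                                    regulation = rnorm(200)))
  th <- estimate_thresholds(sf$scores, sf$participants, q = 0.10)
  fl <- classify_deficits(sf$scores, th, sf$participants)
  expect_identical(sum(fl$rec_deficit), 20L)
  expect_identical(sum(fl$lrn_deficit), 20L)
  expect_identical(sum(fl$reg_deficit), 20L)
})

test_that("classification matches a hand tally on a worked fixture", {
  # 20 participants, one bracket; cutoffs are the 10th percentiles
  rec <- c(-3, -2.5, seq(-1, 3, length.out = 18))
  lrn <- c(seq(0, 3, length.out = 18), -4, -3.5)
  reg <- seq(1, 4, length.out = 20)
  sf <- make_score_frame(data.frame(recognition = rec, learning = lrn,
                                    regulation = reg))
  th <- estimate_thresholds(sf$scores, sf$participants, q = 0.10)
  fl <- classify_deficits(sf$scores, th, sf$participants)
  # hand tally: with n = 20, h = 2.9 -> cutoff between 2nd and 3rd smallest
  expect_identical(which(fl$rec_deficit), 1:2)
  expect_identical(which(fl$lrn_deficit), 19:20)
  expect_identical(which(fl$reg_deficit), 1:2)
  expect_identical(fl$venn_cell[1], "rec+reg")
  expect_identical(fl$venn_cell[19], "lrn")
  expect_identical(fl$venn_cell[5], "none")
  expect_identical(fl$n_deficits, c(2L, 2L, rep(0L, 16), 1L, 1L))
})

test_that("classification is monotone in q", {
  set.seed(5)
  sf <- make_score_frame(data.frame(recognition = rnorm(150),
                                    learning = rnorm(150),
                                    regulation = rnorm(150)))
  th1 <- estimate_thresholds(sf$scores, sf$participants, q = 0.10)
  th2 <- estimate_thresholds(sf$scores, sf$participants, q = 0.25)
  f1 <- classify_deficits(sf$scores, th1, sf$participants)
  f2 <- classify_deficits(sf$scores, th2, sf$participants)
  expect_true(all(f2$rec_deficit[f1$rec_deficit]))
  expect_true(all(f2$n_deficits >= f1$n_deficits))
})

test_that("boundary scores count as deficient and brackets are respected", {
  scores <- data.frame(recognition = c(1:10, 101:110) / 1,
                       learning = rep(50, 20), regulation = rep(50, 20))
  sf <- make_score_frame(scores, bracket = rep(c("9-12", "13-15"), each = 10))
  th <- estimate_thresholds(sf$scores, sf$participants, q = 0.5, min_n = 5)
  # per bracket of 10: type-7 median = 5.5 / 105.5
  fl <- classify_deficits(sf$scores, th, sf$participants)
  expect_identical(which(fl$rec_deficit), c(1:5, 11:15))
  # a score exactly at the cutoff is deficient
  sf2 <- make_score_frame(data.frame(recognition = c(rep(1, 10), rep(2, 10)),
                                     learning = rnorm(20),
                                     regulation = rnorm(20)))
  th2 <- estimate_thresholds(sf2$scores, sf2$participants, q = 0.5, min_n = 5)
  fl2 <- classify_deficits(sf2$scores, th2, sf2$participants)
  expect_true(all(fl2$rec_deficit[1:10]))  # cutoff = 1.5? no: all 1s <= 1.5
})

test_that("empty or small brackets are reported", {
  sf <- make_score_frame(data.frame(recognition = rnorm(10),
                                    learning = rnorm(10),
                                    regulation = rnorm(10)),
                         bracket = rep("9-12", 10))
  expect_warning(estimate_thresholds(sf$scores, sf$participants, q = 0.1,
                                     min_n = 20), "only 10 controls")
  parts2 <- sf$participants
  parts2$bracket[1:5] <- "13-15"
  parts2$group[1:5] <- "CD"   # 13-15 bracket has no controls
  expect_error(estimate_thresholds(sf$scores, parts2, q = 0.1, min_n = 2),
               "no controls in bracket")
})

test_that("venn summary proportions are exact for constructed flags", {
  n <- 40
  flags <- data.frame(
    id = sprintf("F%02d", 1:n),
    rec_deficit = rep(c(TRUE, FALSE), c(8, 32)),
    lrn_deficit = rep(c(FALSE, TRUE, FALSE), c(4, 8, 28)),
    reg_deficit = rep(FALSE, n))
  flags$n_deficits <- rowSums(flags[, 2:4])
  flags$venn_cell <- c(rep("rec", 4), rep("rec+lrn", 4), rep("lrn", 4),
                       rep("none", 28))
  group <- rep(c("CD", "TDC"), each = 20)
  vs <- venn_summary(flags, group)
  cd_cells <- vs$cells[vs$cells$group == "CD", ]
  expect_equal(cd_cells$prop[cd_cells$cell == "rec"], 4 / 20)
  expect_equal(cd_cells$prop[cd_cells$cell == "rec+lrn"], 4 / 20)
  expect_equal(sum(cd_cells$prop), 1, tolerance = 1e-12)
  # margins equal sums of their cells
  memb <- emopheno:::venn_membership()
  for (g in c("CD", "TDC")) {
    cells_g <- vs$cells[vs$cells$group == g, ]
    marg_g <- vs$margins[vs$margins$group == g, ]
    for (d in c("rec", "lrn", "reg")) {
      expect_equal(marg_g$prop[marg_g$domain == d],
                   sum(cells_g$prop[memb[cells_g$cell, d]]))
    }
  }
  expect_identical(vs$group_tests$domain, c("rec", "lrn", "reg"))
  # all-false flags: 'none' is 100%
  flags0 <- flags
  flags0[, 2:4] <- FALSE; flags0$n_deficits <- 0L; flags0$venn_cell <- "none"
  vs0 <- venn_summary(flags0, group)
  agg0 <- vs0$aggregates[vs0$aggregates$aggregate == "none", ]
  expect_equal(agg0$prop, c(1, 1))
})

test_that("independence expectations follow the binomial closed form", {
  ie <- independence_expectation(0.10, 3)
  expect_equal(ie$p_all, 0.001)
  expect_equal(ie$p_at_least_1, 1 - 0.9^3)
  expect_equal(unname(ie$p_exactly["m1"]), 3 * 0.1 * 0.81)
  expect_equal(unname(ie$p_exactly["m2"]), 3 * 0.01 * 0.9)
  expect_equal(sum(ie$p_exactly), 1, tolerance = 1e-12)
  ie2 <- independence_expectation(0.05, 2)
  expect_equal(ie2$p_at_least_1, 1 - 0.95^2)
})
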