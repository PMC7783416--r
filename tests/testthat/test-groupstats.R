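# Hand-computed sums of squares for a balanced 2-group x 3-domain design.
hand_mixed_ss <- function(y, group) {
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  subj_means <- rowMeans(y)
  gm <- tapply(subj_means, group, mean)
  ss_group <- k * sum((gm[group] - grand)^2)
  ss_subj <- k * sum((subj_means - gm[group])^2)
  dom_means <- colMeans(y)
  ss_dom <- n * sum((dom_means - grand)^2)
  cell <- apply(y, 2, function(col) tapply(col, group, mean))  # 2 x k
  ng <- table(group)
  ss_int <- sum(t(cell)^2 * rep(ng, each = k)) -
    k * sum(ng * gm^2) - n * sum(dom_means^2) + n * k * grand^2
  ss_tot <- sum((y - grand)^2)
  ss_within_err <- ss_tot - ss_group - ss_subj - ss_dom - ss_int
  c(group = ss_group, subj = ss_subj, domain = ss_dom, interaction = ss_int,
    within_err = ss_within_err, total = ss_tot)
}

make_fs <- function(y) {
  fs <- data.frame(id = sprintf("S%02d", seq_len(nrow(y))), y)
  class(fs) <- c("factor_scores", "data.frame")
  fs
}

test_that("mixed-ANOVA F statistics match hand-computed sums of squares", {
  y <- data.frame(recognition = c(1, 3, 2, 6, 5, 7),
                  learning = c(2, 4, 3, 5, 6, 8),
                  regulation = c(0, 2, 1, 7, 6, 9))
  group <- rep(c("CD", "TDC"), each = 3)
  res <- rm_anova(make_fs(y), group)
  h <- hand_mixed_ss(as.matrix(y), group)
  eff <- res$effects
  f_group <- (h["group"] / 1) / (h["subj"] / 4)
  f_dom <- (h["domain"] / 2) / (h["within_err"] / 8)
  f_int <- (h["interaction"] / 2) / (h["within_err"] / 8)
  expect_equal(eff$F[eff$effect == "group"], unname(f_group), tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "domain"], unname(f_dom), tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "group_domain"], unname(f_int),
               tolerance = 1e-10)
  expect_equal(eff$df1, c(1, 2, 2))
  expect_equal(eff$df2, c(4, 8, 8))
  # partial eta squared from the same SS
  expect_equal(eff$eta2p[eff$effect == "group"],
               unname(h["group"] / (h["group"] + h["subj"])), tolerance = 1e-10)
  # decomposition: components add to the total
  expect_equal(unname(sum(h[1:5])), unname(h["total"]), tolerance = 1e-8)
  expect_equal(sum(res$ss), unname(h["total"]), tolerance = 1e-8)
})

test_that("mixed-ANOVA agrees with stats::aov on an unbalanced sample", {
  set.seed(20)
  n1 <- 22; n2 <- 28; n <- n1 + n2
  y <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("recognition", "learning", "regulation")))
  y[seq_len(n1), 1] <- y[seq_len(n1), 1] - 0.8
  group <- rep(c("CD", "TDC"), c(n1, n2))
  res <- rm_anova(make_fs(as.data.frame(y)), group)
  long <- data.frame(y = as.vector(y), domain = factor(rep(colnames(y), each = n)),
                     group = factor(rep(group, 3)), id = factor(rep(1:n, 3)))
  s <- summary(stats::aov(y ~ group * domain + Error(id), data = long))
  tab_b <- as.data.frame(s[["Error: id"]][[1]])
  tab_w <- as.data.frame(s[["Error: Within"]][[1]])
  expect_equal(res$effects$F[res$effects$effect == "group"],
               tab_b$`F value`[1], tolerance = 1e-8)
  expect_equal(res$effects$F[res$effects$effect == "domain"],
               tab_w$`F value`[1], tolerance = 1e-8)
  expect_equal(res$effects$F[res$effects$effect == "group_domain"],
               tab_w$`F value`[2], tolerance = 1e-8)
  expect_equal(unname(res$ss[c("group", "subj_error")]),
               tab_b$`Sum Sq`, tolerance = 1e-8)
  expect_equal(unname(res$ss[c("domain", "group_domain", "within_error")]),
               tab_w$`Sum Sq`, tolerance = 1e-8)
})

test_that("partial eta squared CIs behave at the null and contain the estimate", {
  ci <- partial_eta_sq_ci(0.5, 1, 100)
  expect_equal(unname(ci["lower"]), 0)
  f <- 9; ci2 <- partial_eta_sq_ci(f, 2, 60)
  eta <- (f * 2) / (f * 2 + 61)  # rough point estimate from F
  expect_true(ci2["lower"] < eta && eta < ci2["upper"])
  expect_true(all(ci2 >= 0 & ci2 <= 1))
  expect_lt(ci2["lower"], ci2["upper"])
})

test_that("effect-size benchmarks label small/medium/large correctly", {
  expect_identical(as.character(emopheno:::effect_size_label(c(0.005, 0.03, 0.1, 0.2))),
                   c("negligible", "small", "medium", "large"))
})

test_that("permuted labels give a near-zero group effect", {
  set.seed(9)
  n <- 300
  y <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("recognition", "learning", "regulation")))
  res <- rm_anova(make_fs(as.data.frame(y)), sample(rep(c("CD", "TDC"), n / 2)))
  expect_lt(res$effects$eta2p[res$effects$effect == "group"], 0.03)
  expect_equal(res$effects$eta2p_lo[res$effects$effect == "group"], 0,
               tolerance = 1e-6)
})

test_that("Greenhouse-Geisser epsilon is 1 under sphericity", {
  expect_equal(emopheno:::gg_epsilon(diag(3)), 1, tolerance = 1e-12)
  S <- matrix(0.4, 3, 3); diag(S) <- 1   # compound symmetry
  expect_equal(emopheno:::gg_epsilon(S), 1, tolerance = 1e-12)
  S2 <- diag(c(1, 2, 5))
  expect_lt(emopheno:::gg_epsilon(S2), 1)
})

test_that("logistic coefficients match a brute-force likelihood grid", {
  set.seed(10)
  x <- c(-1.2, 0.4, 0.8, -0.6, 1.5, -2.0, 0.1, 0.9, -0.3, 1.1)
  y <- c(0, 1, 1, 0, 1, 0, 0, 1, 1, 1)
  fs <- make_fs(data.frame(recognition = x))
  res <- logistic_discrimination(fs, ifelse(y == 1, "CD", "TDC"))
  ll <- function(b0, b1) sum(y * (b0 + b1 * x) - log(1 + exp(b0 + b1 * x)))
  # nested grid refinement down to 1e-3 resolution
  ctr <- c(0, 0); width <- 8
  for (step in c(0.1, 0.01, 0.001)) {
    b0s <- seq(ctr[1] - width * step * 10, ctr[1] + width * step * 10, by = step)
    b1s <- seq(ctr[2] - width * step * 10, ctr[2] + width * step * 10, by = step)
    grid <- as.matrix(expand.grid(b0s, b1s))
    vals <- apply(grid, 1, function(g) ll(g[1], g[2]))
    ctr <- grid[which.max(vals), ]
  }
  est <- res$predictors$estimate
  expect_lt(abs(est[1] - ctr[1]), 2e-3)
  expect_lt(abs(est[2] - ctr[2]), 2e-3)
})

test_that("null predictors collapse to the majority class at cutoff 0.5", {
  set.seed(12)
  n_cd <- 300; n_tdc <- 700
  y <- data.frame(recognition = rnorm(n_cd + n_tdc),
                  learning = rnorm(n_cd + n_tdc),
                  regulation = rnorm(n_cd + n_tdc))
  group <- rep(c("CD", "TDC"), c(n_cd, n_tdc))
  res <- logistic_discrimination(make_fs(y), group)
  expect_lt(res$sensitivity, 0.05)
  expect_gt(res$specificity, 0.95)
  expect_lt(res$model_chi2, qchisq(0.999, 3))
  expect_identical(res$model_df, 3L)
})

test_that("complete separation raises an explicit error", {
  y <- data.frame(recognition = c(-3, -2.5, -2, 2, 2.5, 3, 3.5, 4),
                  learning = rnorm(8), regulation = rnorm(8))
  group <- rep(c("CD", "TDC"), each = 4)
  expect_error(logistic_discrimination(make_fs(y), group), "separation")
})

test_that("Hosmer-Lemeshow and Wilson intervals are well-formed", {
  set.seed(14)
  n <- 500
  x <- rnorm(n)
  p <- plogis(-0.5 + 0.8 * x)
  yy <- rbinom(n, 1, p)
  hl <- hosmer_lemeshow(yy, p, 10)
  expect_identical(hl$df, 8L)
  expect_true(hl$p >= 0 && hl$p <= 1)
  # Wilson interval equals prop.test's score interval without correction
  for (case in list(c(8, 10), c(36, 100), c(0, 25))) {
    w <- wilson_ci(case[1], case[2])
    pt <- prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(unname(w), as.numeric(pt), tolerance = 1e-10)
  }
})

test_that("effect-size ordering follows the configured domain contrasts", {
  res <- replicate_study(cohort_config(n_cd = 1500L, n_tdc = 2000L, seed = 8L),
                         n_boot = 0)
  ph <- res$anova$posthoc
  eta <- setNames(ph$eta2p, ph$domain)
  expect_gt(eta["recognition"], eta["regulation"])
  expect_gt(eta["regulation"], eta["learning"])
  # CD scores lower than TDC in every domain
  expect_true(all(ph$mean_diff < 0))
})
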