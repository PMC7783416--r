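# Raw varimax criterion (after Kaiser row normalization), used by the
# grid-search rotation oracle.
varimax_criterion <- function(L) {
  h <- sqrt(rowSums(L^2))
  Ln <- L / h
  sum(apply(Ln^2, 2, function(x) mean(x^2) - mean(x)^2))
}

test_that("Olkin-Pratt correction is unbiased-leaning and vanishes at large n", {
  set.seed(1)
  n <- 1e5
  x <- rnorm(n); y <- 0.4 * x + rnorm(n, 0, sqrt(1 - 0.16))
  r <- cor(x, y)
  expect_lt(abs(olkin_pratt(r, n) - r), 1e-3)
  # at small n the correction moves |r| upward (toward unbiasedness)
  expect_gt(abs(olkin_pratt(0.3, 20)), 0.3)
  expect_equal(olkin_pratt(0, 20), 0)
})

test_that("Bartlett statistic is zero for an identity correlation matrix", {
  bt <- bartlett_sphericity(diag(6), n = 50)
  expect_equal(bt$chi2, 0)
  expect_equal(bt$df, 15)
  expect_equal(bt$p, 1)
})

test_that("KMO and Bartlett match a long-hand computation on a small fixture", {
  set.seed(42)
  n <- 12; p <- 4
  f <- rnorm(n)
  X <- sapply(1:p, function(j) 0.7 * f + rnorm(n, 0, 0.8))
  R <- cor(X)

  # Bartlett oracle via eigenvalue determinant
  chi2_oracle <- -(n - 1 - (2 * p + 5) / 6) *
    sum(log(eigen(R, only.values = TRUE)$values))
  bt <- bartlett_sphericity(R, n)
  expect_equal(bt$chi2, chi2_oracle, tolerance = 1e-10)
  expect_equal(bt$df, p * (p - 1) / 2)

  # partial-correlation oracle via regression residuals
  part <- matrix(NA_real_, p, p)
  for (i in 1:p) for (j in 1:p) {
    if (i == j) next
    others <- setdiff(1:p, c(i, j))
    ri <- lm.fit(cbind(1, X[, others]), X[, i])$residuals
    rj <- lm.fit(cbind(1, X[, others]), X[, j])$residuals
    part[i, j] <- cor(ri, rj)
  }
  r2 <- R^2; diag(r2) <- 0
  a2 <- part^2; a2[is.na(a2)] <- 0
  kmo_oracle <- sum(r2) / (sum(r2) + sum(a2))
  km <- kmo(R)
  expect_equal(km$overall, kmo_oracle, tolerance = 1e-8)
  per_var_oracle <- rowSums(r2) / (rowSums(r2) + rowSums(a2))
  expect_equal(unname(km$per_variable), per_var_oracle, tolerance = 1e-8)
})

test_that("an exact three-factor structure is recovered without error", {
  set.seed(7)
  n <- 200
  # exactly orthogonal, zero-mean factors (QR of a centered matrix)
  f <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), scale = FALSE))) * sqrt(n - 1)
  Z <- f[, rep(1:3, each = 4)]      # 12 variables, zero unique variance
  colnames(Z) <- paste0("v", 1:12)
  sol <- fit_pca_varimax(Z, k = 3,
                         domain_partition = list(a = paste0("v", 1:4),
                                                 b = paste0("v", 5:8),
                                                 c = paste0("v", 9:12)))
  L <- abs(sol$loadings)
  target <- matrix(0, 12, 3)
  target[cbind(1:12, rep(1:3, each = 4))] <- 1
  # up to column permutation
  perm <- apply(L[c(1, 5, 9), ], 1, which.max)
  expect_setequal(perm, 1:3)
  # exact up to the rotation's numerical convergence tolerance
  expect_lt(max(abs(L[, perm] - target)), 1e-5)
})

test_that("rotation preserves communalities and total retained variance", {
  co <- generate_cohort(small_config())
  z <- residualize(simulate_scores(co), co$participants)
  sol <- fit_pca_varimax(z, k = 3)
  expect_lt(max(abs(rowSums(sol$loadings^2) - rowSums(sol$unrotated^2))),
            1e-10)
  expect_equal(sum(sol$eigenvalues), sum(sol$unrotated^2), tolerance = 1e-10)
  expect_equal(sol$total_variance_explained,
               sum(sol$eigenvalues) / 20, tolerance = 1e-12)
  # trace conservation of the full spectrum
  expect_equal(sum(sol$eigenvalues_all), 20, tolerance = 1e-8)
})

test_that("varimax matches an exhaustive planar rotation-angle search", {
  set.seed(11)
  n <- 80
  f <- matrix(rnorm(n * 2), n, 2)
  Z <- cbind(f[, 1] + 0.3 * rnorm(n), f[, 1] + 0.3 * rnorm(n),
             f[, 1] + 0.3 * rnorm(n), f[, 2] + 0.3 * rnorm(n),
             f[, 2] + 0.3 * rnorm(n), f[, 2] + 0.3 * rnorm(n))
  colnames(Z) <- paste0("v", 1:6)
  sol <- fit_pca_varimax(Z, k = 2,
                         domain_partition = list(a = paste0("v", 1:3),
                                                 b = paste0("v", 4:6)))
  L0 <- sol$unrotated
  # oracle: grid search over rotation angles at 1e-4 rad resolution
  angles <- seq(0, pi / 2, by = 1e-4)
  crits <- vapply(angles, function(th) {
    Rm <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    varimax_criterion(L0 %*% Rm)
  }, numeric(1))
  best <- max(crits)
  expect_lt(abs(varimax_criterion(sol$loadings) - best), 1e-6)
})

test_that("Anderson-Rubin scores are exactly standardized and orthogonal", {
  co <- generate_cohort(small_config(n_cd = 120L, n_tdc = 150L))
  z <- residualize(simulate_scores(co), co$participants)
  sol <- fit_pca_varimax(z, k = 3)
  fs <- anderson_rubin_scores(z, sol)
  sm <- emopheno:::score_matrix(fs)
  expect_true(all(abs(colMeans(sm)) < 1e-8))
  expect_true(all(abs(apply(sm, 2, sd) - 1) < 1e-8))
  cm <- cor(sm)
  expect_true(all(abs(cm[upper.tri(cm)]) < 1e-8))
  expect_setequal(colnames(sm), c("recognition", "learning", "regulation"))
})

test_that("one-factor AR scores equal rescaled regression scores", {
  set.seed(13)
  n <- 60
  f <- rnorm(n)
  Z <- sapply(1:4, function(j) 0.8 * f + rnorm(n, 0, 0.6))
  colnames(Z) <- paste0("v", 1:4)
  sol <- fit_pca_varimax(Z, k = 1, domain_partition = list(a = colnames(Z)))
  fs <- anderson_rubin_scores(Z, sol, orient = "raw")
  reg <- scale(Z, scale = FALSE) %*% solve(cor(Z), sol$loadings)
  reg <- reg / sd(reg)
  expect_equal(abs(cor(emopheno:::score_matrix(fs)[, 1], reg[, 1])), 1,
               tolerance = 1e-10)
  expect_equal(unname(abs(emopheno:::score_matrix(fs)[, 1])),
               unname(abs(reg[, 1])), tolerance = 1e-8)
})

test_that("performance orientation makes factor scores track ability", {
  co <- generate_cohort(cohort_config(n_cd = 600L, n_tdc = 800L, seed = 3L))
  z <- residualize(simulate_scores(co), co$participants)
  sol <- fit_pca_varimax(z, k = 3)
  fs <- anderson_rubin_scores(z, sol)
  sm <- emopheno:::score_matrix(fs)
  expect_gt(cor(sm[, "recognition"], co$latent$ability_rec), 0.7)
  expect_gt(cor(sm[, "regulation"], co$latent$ability_reg), 0.7)
  expect_gt(cor(sm[, "learning"], co$latent$ability_lrn), 0.4)
})

test_that("within-domain correlations exceed between-domain correlations", {
  co <- generate_cohort(small_config(n_cd = 300L, n_tdc = 400L))
  z <- residualize(simulate_scores(co), co$participants)
  d <- corr_diagnostics(z, n_boot = 100, seed = 5L)
  expect_gt(d$mean_r_within, d$mean_r_between)
  expect_gt(d$fisher_z, 2)
  expect_true(d$kmo_overall >= 0 && d$kmo_overall <= 1)
  expect_true(all(d$kmo_per_variable >= 0 & d$kmo_per_variable <= 1))
  expect_identical(d$bartlett_df, 190)
  expect_true(d$ci_within[1] <= d$mean_r_within &&
                d$mean_r_within <= d$ci_within[2])
})
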