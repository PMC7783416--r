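## Dimensional group comparison and logistic discrimination.

#' Confidence interval for partial eta squared via noncentral-F inversion
#'
#' Finds the noncentrality parameters whose noncentral-F distribution places
#' the observed F at the upper/lower tail probability, then maps them to
#' partial eta squared by `ncp / (ncp + df1 + df2 + 1)`. A degenerate
#' zero-effect case yields a lower bound of 0.
#'
#' @param f observed F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @param conf confidence level.
#' @return numeric `c(lower, upper)` within `[0, 1]`.
#' @export
partial_eta_sq_ci <- function(f, df1, df2, conf = 0.95) {
  f <- unname(f); df1 <- unname(df1); df2 <- unname(df2)
  alpha <- (1 - conf) / 2
  ncp_limit <- function(prob) {
    ## ncp with P(F_{df1,df2,ncp} <= f) = prob
    if (stats::pf(f, df1, df2, ncp = 0) <= prob) return(0)
    hi <- 10
    while (stats::pf(f, df1, df2, ncp = hi) > prob && hi < 1e7) hi <- hi * 2
    stats::uniroot(function(nc) stats::pf(f, df1, df2, ncp = nc) - prob,
                   c(0, hi), tol = 1e-8)$root
  }
  lo_ncp <- ncp_limit(1 - alpha)
  hi_ncp <- ncp_limit(alpha)
  eta <- function(nc) nc / (nc + df1 + df2 + 1)
  c(lower = eta(lo_ncp), upper = eta(hi_ncp))
}

#' @keywords internal
effect_size_label <- function(eta2) {
  cut(eta2, c(-Inf, 0.01, 0.06, 0.14, Inf),
      labels = c("negligible", "small", "medium", "large"),
      right = FALSE)
}

#' Greenhouse-Geisser epsilon for a within-subject covariance matrix
#' @keywords internal
gg_epsilon <- function(S) {
  k <- ncol(S)
  J <- diag(k) - 1 / k
  Sc <- J %*% S %*% J
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' Mixed-design (repeated-measures) ANOVA of factor scores by group
#'
#' A 3 (domain, within-subject) x 2 (group, between-subject) mixed ANOVA on
#' the factor scores, with partial eta squared (`SS_effect / (SS_effect +
#' SS_error)`) and noncentral-F 95% CIs per effect, Greenhouse-Geisser epsilon
#' for the within effects, and Bonferroni-corrected per-domain group
#' contrasts.
#'
#' @param scores `factor_scores` (id + one column per domain).
#' @param group character/factor group labels aligned with `scores` rows.
#' @param conf confidence level for effect-size CIs.
#' @return list of class `anova_result` with `effects` and `posthoc`
#'   data.frames, `gg_epsilon`, and the `ss` decomposition.
#' @export
rm_anova <- function(scores, group, conf = 0.95) {
  sm <- score_matrix(scores)
  if (anyNA(sm)) stop("complete cases required for the repeated-measures ANOVA")
  k <- ncol(sm)
  n <- nrow(sm)
  group <- factor(group)
  stopifnot(nlevels(group) == 2, length(group) == n)

  ## Split-plot sums of squares computed directly (an explicit aov() with an
  ## Error(id) stratum materializes a dense n-level subject design and does
  ## not scale to cohort-sized samples). Between-subject part: group and
  ## subjects-within-group; within-subject part: the per-subject deviations
  ## decompose orthogonally into domain, group x domain, and error.
  grand <- mean(sm)
  subj_means <- rowMeans(sm)
  gm <- tapply(subj_means, group, mean)
  ng <- tabulate(group)
  ss_group <- k * sum(ng * (gm - grand)^2)
  ss_subj <- k * sum((subj_means - gm[group])^2)

  w <- sm - subj_means                       # within-subject deviations
  d_j <- colMeans(w)
  ss_domain <- n * sum(d_j^2)
  d_gj <- rbind(colMeans(w[group == levels(group)[1], , drop = FALSE]),
                colMeans(w[group == levels(group)[2], , drop = FALSE]))
  ss_int <- sum(ng * rowSums((d_gj - rep(d_j, each = 2))^2))
  ss_werr <- sum((w - d_gj[as.integer(group), ])^2)

  ss <- c(group = ss_group, subj_error = ss_subj, domain = ss_domain,
          group_domain = ss_int, within_error = ss_werr)
  df <- c(group = 1, subj_error = n - 2, domain = k - 1,
          group_domain = k - 1, within_error = (n - 2) * (k - 1))

  mk_effect <- function(name, err) {
    f <- (ss[name] / df[name]) / (ss[err] / df[err])
    p <- stats::pf(f, df[name], df[err], lower.tail = FALSE)
    eta <- ss[name] / (ss[name] + ss[err])
    ci <- partial_eta_sq_ci(f, df[name], df[err], conf)
    data.frame(effect = name, F = unname(f), df1 = unname(df[name]),
               df2 = unname(df[err]), p = unname(p), eta2p = unname(eta),
               eta2p_lo = unname(ci["lower"]), eta2p_hi = unname(ci["upper"]),
               label = as.character(effect_size_label(eta)),
               stringsAsFactors = FALSE)
  }
  effects <- rbind(mk_effect("group", "subj_error"),
                   mk_effect("domain", "within_error"),
                   mk_effect("group_domain", "within_error"))

  ## Greenhouse-Geisser epsilon from the pooled within-group covariance
  Sw <- Reduce(`+`, lapply(levels(group), function(g) {
    (sum(group == g) - 1) * stats::cov(sm[group == g, , drop = FALSE])
  })) / (n - 2)
  eps <- gg_epsilon(Sw)

  ## per-domain group contrasts, Bonferroni over the k domains
  posthoc <- do.call(rbind, lapply(colnames(sm), function(d) {
    tt <- stats::t.test(sm[, d] ~ group, var.equal = TRUE)
    tstat <- unname(tt$statistic); dfc <- unname(tt$parameter)
    eta <- tstat^2 / (tstat^2 + dfc)
    ci <- partial_eta_sq_ci(tstat^2, 1, dfc, conf)
    data.frame(domain = d,
               mean_diff = unname(diff(rev(tt$estimate))),
               t = tstat, df = dfc,
               p_bonferroni = min(1, tt$p.value * k),
               eta2p = eta, eta2p_lo = unname(ci["lower"]),
               eta2p_hi = unname(ci["upper"]),
               label = as.character(effect_size_label(eta)),
               stringsAsFactors = FALSE)
  }))

  structure(list(effects = effects, posthoc = posthoc, gg_epsilon = eps,
                 ss = ss, df = df, n = n),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result> n =", x$n, " GG epsilon =", round(x$gg_epsilon, 3), "\n")
  print(x$effects, row.names = FALSE, digits = 4)
  cat("post-hoc group contrasts (Bonferroni):\n")
  print(x$posthoc, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Logistic discrimination of group membership from factor scores
#'
#' Maximum-likelihood logistic regression of case status on the domain factor
#' scores, with a likelihood-ratio model chi-square, per-predictor Wald
#' chi-squares and odds ratios, the Hosmer-Lemeshow goodness-of-fit test
#' (10 risk deciles), and sensitivity/specificity at a posterior-probability
#' cutoff with Wilson score CIs.
#'
#' @param scores `factor_scores`.
#' @param group group labels; `positive` names the case level.
#' @param positive the level coded 1 (default "CD").
#' @param cutoff classification cutoff on the fitted probability.
#' @param n_hl_groups Hosmer-Lemeshow groups.
#' @return list of class `logistic_result`.
#' @export
logistic_discrimination <- function(scores, group, positive = "CD",
                                    cutoff = 0.5, n_hl_groups = 10) {
  sm <- score_matrix(scores)
  y <- as.integer(group == positive)
  stopifnot(length(unique(y)) == 2)
  dat <- data.frame(y = y, sm)
  fit <- stats::glm(y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) stop("logistic fit did not converge")
  mu <- stats::fitted(fit)
  if (max(mu[y == 0]) < min(mu[y == 1]) ||
      any(mu > 1 - 1e-10) || any(mu < 1e-10)) {
    worst <- names(which.max(abs(stats::coef(fit)[-1])))
    stop("complete or quasi-complete separation detected (strongest ",
         "predictor: ", worst, ")")
  }
  cf <- summary(fit)$coefficients
  wald <- (cf[, "Estimate"] / cf[, "Std. Error"])^2
  predictors <- data.frame(
    term = rownames(cf), estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"], wald_chi2 = wald,
    p = stats::pchisq(wald, 1, lower.tail = FALSE),
    odds_ratio = exp(cf[, "Estimate"]),
    row.names = NULL, stringsAsFactors = FALSE)

  model_chi2 <- unname(fit$null.deviance - fit$deviance)
  model_df <- unname(fit$df.null - fit$df.residual)
  model_p <- stats::pchisq(model_chi2, model_df, lower.tail = FALSE)

  hl <- hosmer_lemeshow(y, mu, n_hl_groups)

  pred <- as.integer(mu >= cutoff)
  sens_x <- sum(pred == 1 & y == 1); sens_n <- sum(y == 1)
  spec_x <- sum(pred == 0 & y == 0); spec_n <- sum(y == 0)

  structure(list(model_chi2 = model_chi2, model_df = model_df,
                 model_p = model_p, predictors = predictors,
                 hosmer_lemeshow = hl, cutoff = cutoff,
                 sensitivity = sens_x / sens_n,
                 sensitivity_ci = wilson_ci(sens_x, sens_n),
                 specificity = spec_x / spec_n,
                 specificity_ci = wilson_ci(spec_x, spec_n),
                 n = length(y)),
            class = "logistic_result")
}

#' Hosmer-Lemeshow goodness-of-fit test
#' @param y binary outcomes; @param mu fitted probabilities;
#' @param g number of risk groups.
#' @return list with `chi2`, `df`, `p`.
#' @export
hosmer_lemeshow <- function(y, mu, g = 10) {
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = g + 1)))
  grp <- cut(mu, breaks = br, include.lowest = TRUE)
  o1 <- tapply(y, grp, sum); n_g <- tapply(y, grp, length)
  e1 <- tapply(mu, grp, sum)
  chi2 <- sum((o1 - e1)^2 / e1 + ((n_g - o1) - (n_g - e1))^2 / (n_g - e1))
  df <- length(levels(grp)) - 2L
  list(chi2 = unname(chi2), df = df,
       p = stats::pchisq(unname(chi2), df, lower.tail = FALSE))
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("<logistic_result> model chi2(%d) = %.2f, p = %.3g\n",
              x$model_df, x$model_chi2, x$model_p))
  print(x$predictors, row.names = FALSE, digits = 4)
  cat(sprintf("  HL chi2(%d) = %.2f (p = %.3g); sensitivity %.1f%% [%.1f, %.1f], specificity %.1f%% [%.1f, %.1f] at cutoff %.2f\n",
              x$hosmer_lemeshow$df, x$hosmer_lemeshow$chi2,
              x$hosmer_lemeshow$p,
              100 * x$sensitivity, 100 * x$sensitivity_ci[1],
              100 * x$sensitivity_ci[2],
              100 * x$specificity, 100 * x$specificity_ci[1],
              100 * x$specificity_ci[2], x$cutoff))
  invisible(x)
}
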