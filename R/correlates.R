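## Clinical scale scoring (YPI CU traits / LPE proxy, RPQ) and association
## tests between deficit flags and clinical/risk variables.

#' Score the YPI callous-unemotional subscales and the LPE proxy
#'
#' A CU trait (remorselessness, unemotionality, callousness) is endorsed when
#' at least one item of its five-item subscale (see [ypi_cu_map()]) is
#' answered 4 ("applies very well"); the Limited Prosocial Emotions proxy
#' holds when two or more traits are endorsed. `cu_total` is the sum of the
#' 15 CU items.
#'
#' @param ypi_items numeric vector of 50 responses in 1..4, or a matrix /
#'   data.frame with 50 columns (one row per participant).
#' @return For a vector, a list of class `lpe_result` (`trait_endorsed`,
#'   `n_traits`, `lpe`, `cu_total`); for a matrix, a data.frame with one row
#'   per participant.
#' @export
score_lpe <- function(ypi_items) {
  if (is.matrix(ypi_items) || is.data.frame(ypi_items)) {
    m <- as.matrix(ypi_items)
    stopifnot(ncol(m) == 50)
    if (any(!m %in% 1:4)) stop("YPI responses must lie in 1-4")
    map <- ypi_cu_map()
    tr <- sapply(c("remorselessness", "unemotionality", "callousness"),
                 function(s) {
                   idx <- map$item[map$subscale == s]
                   rowSums(m[, idx, drop = FALSE] == 4) > 0
                 })
    n_traits <- rowSums(tr)
    return(data.frame(tr, n_traits = n_traits, lpe = n_traits >= 2,
                      cu_total = rowSums(m[, map$item, drop = FALSE])))
  }
  if (length(ypi_items) != 50) stop("YPI requires exactly 50 item responses")
  bad <- which(!ypi_items %in% 1:4)
  if (length(bad)) {
    stop("YPI item(s) out of range 1-4 at index: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  map <- ypi_cu_map()
  traits <- vapply(split(map$item, map$subscale), function(idx) {
    any(ypi_items[idx] == 4)
  }, logical(1))
  traits <- traits[c("remorselessness", "unemotionality", "callousness")]
  structure(list(trait_endorsed = traits,
                 n_traits = sum(traits),
                 lpe = sum(traits) >= 2,
                 cu_total = sum(ypi_items[map$item])),
            class = "lpe_result")
}

#' Score the RPQ into reactive and proactive aggression sums
#'
#' @param rpq_items numeric vector of 23 responses in 0..2, or a matrix /
#'   data.frame with 23 columns.
#' @return named numeric vector `c(reactive, proactive)` (vector input) or a
#'   two-column data.frame (matrix input).
#' @export
score_rpq <- function(rpq_items) {
  if (is.matrix(rpq_items) || is.data.frame(rpq_items)) {
    m <- as.matrix(rpq_items)
    stopifnot(ncol(m) == 23)
    map <- rpq_map()
    return(data.frame(
      reactive = rowSums(m[, map$item[map$subscale == "reactive"], drop = FALSE]),
      proactive = rowSums(m[, map$item[map$subscale == "proactive"], drop = FALSE])))
  }
  if (length(rpq_items) != 23) stop("RPQ requires exactly 23 item responses")
  bad <- which(!rpq_items %in% 0:2)
  if (length(bad)) {
    stop("RPQ item(s) out of range 0-2 at index: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  map <- rpq_map()
  c(reactive = sum(rpq_items[map$item[map$subscale == "reactive"]]),
    proactive = sum(rpq_items[map$item[map$subscale == "proactive"]]))
}

#' Score a cohort's clinical table (LPE proxy, CU total, RPQ subscales)
#'
#' @param clinical clinical data.frame from [generate_cohort()].
#' @return data.frame: `id`, trait flags, `n_traits`, `lpe`, `cu_total`,
#'   `rpq_reactive`, `rpq_proactive`.
#' @export
score_clinical <- function(clinical) {
  ypi <- as.matrix(clinical[, paste0("ypi_", 1:50)])
  rpq <- as.matrix(clinical[, paste0("rpq_", 1:23)])
  lpe <- score_lpe(ypi)
  rp <- score_rpq(rpq)
  cbind(data.frame(id = clinical$id, stringsAsFactors = FALSE), lpe,
        rpq_reactive = rp$reactive, rpq_proactive = rp$proactive)
}

#' Associations between deficit flags and clinical outcomes (CD subset)
#'
#' For each outcome, one model with the three deficit flags as predictors:
#' linear regression for continuous outcomes, logistic regression for binary
#' ones. Additionally, per deficit flag, a two-group contrast of the outcome
#' between deficient and intact participants (Pearson chi-square without
#' continuity correction for binary outcomes, Welch t-test for continuous
#' ones). P-values are uncorrected.
#'
#' @param flags `deficit_flags` table.
#' @param outcomes data.frame of outcome variables aligned with `flags` rows.
#' @param subset optional logical vector restricting rows (e.g. CD only).
#' @return list of class `association_result`: `models` and `contrasts`
#'   (tidy data.frames).
#' @export
deficit_associations <- function(flags, outcomes, subset = NULL) {
  if (is.null(subset)) subset <- rep(TRUE, nrow(flags))
  stopifnot(nrow(outcomes) == nrow(flags), length(subset) == nrow(flags))
  fl <- flags[subset, ]; out <- outcomes[subset, , drop = FALSE]
  if (!nrow(fl)) stop("empty analysis subset")
  preds <- data.frame(rec = as.numeric(fl$rec_deficit),
                      lrn = as.numeric(fl$lrn_deficit),
                      reg = as.numeric(fl$reg_deficit))
  models <- list(); contrasts <- list()
  for (v in names(out)) {
    y <- out[[v]]
    if (is.logical(y)) y <- as.numeric(y)
    if (length(unique(y[!is.na(y)])) < 2) {
      warning("outcome ", v, " is constant in the subset; skipped")
      next
    }
    binary <- all(y[!is.na(y)] %in% c(0, 1))
    if (all(vapply(preds, function(p) length(unique(p)) < 2, logical(1)))) {
      warning("all deficit flags constant; regression for ", v, " skipped")
      next
    }
    dat <- cbind(data.frame(y = y), preds)
    fit <- if (binary) {
      stats::glm(y ~ rec + lrn + reg, data = dat, family = stats::binomial())
    } else {
      stats::lm(y ~ rec + lrn + reg, data = dat)
    }
    cf <- summary(fit)$coefficients
    stat_col <- if (binary) "z value" else "t value"
    models[[v]] <- data.frame(
      outcome = v, model = if (binary) "logistic" else "linear",
      predictor = rownames(cf), estimate = cf[, "Estimate"],
      statistic = if (binary) cf[, stat_col]^2 else cf[, stat_col],
      stat_type = if (binary) "wald_chi2" else "t",
      odds_ratio = if (binary) exp(cf[, "Estimate"]) else NA_real_,
      p = if (binary) {
        stats::pchisq(cf[, stat_col]^2, 1, lower.tail = FALSE)
      } else cf[, "Pr(>|t|)"],
      row.names = NULL, stringsAsFactors = FALSE)

    for (d in domain_names()) {
      f <- fl[[paste0(d, "_deficit")]]
      if (length(unique(f)) < 2) next
      if (binary) {
        tb <- table(factor(f, levels = c(FALSE, TRUE)),
                    factor(y, levels = c(0, 1)))
        ct <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
        contrasts[[paste(v, d)]] <- data.frame(
          outcome = v, domain = d, test = "chi2",
          deficient = mean(y[f]), intact = mean(y[!f]),
          statistic = unname(ct$statistic), p = ct$p.value,
          stringsAsFactors = FALSE)
      } else {
        tt <- stats::t.test(y[f], y[!f])
        contrasts[[paste(v, d)]] <- data.frame(
          outcome = v, domain = d, test = "welch_t",
          deficient = mean(y[f], na.rm = TRUE),
          intact = mean(y[!f], na.rm = TRUE),
          statistic = unname(tt$statistic), p = tt$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(models = do.call(rbind, models),
                 contrasts = do.call(rbind, contrasts)),
            class = "association_result")
}

#' Risk-factor logistic models per deficit domain (CD subset)
#'
#' One logistic regression per domain flag (deficient = 1) on sex, IQ,
#' maternal smoking, SES, parental delinquency, CECA total and SAHA deviant
#' peers, reporting Wald chi-squares and odds ratios.
#'
#' @param flags `deficit_flags` table.
#' @param risk data.frame with columns `sex`, `iq`, `ses`,
#'   `maternal_smoking`, `parental_delinquency`, `ceca_total`,
#'   `saha_deviant_peers`, aligned with `flags` rows.
#' @param subset optional logical vector (e.g. CD subset).
#' @return data.frame of class `risk_result` (tidy: domain, predictor,
#'   estimate, odds_ratio, wald_chi2, p).
#' @export
risk_factor_models <- function(flags, risk, subset = NULL) {
  if (is.null(subset)) subset <- rep(TRUE, nrow(flags))
  fl <- flags[subset, ]; rk <- risk[subset, , drop = FALSE]
  need <- c("sex", "iq", "ses", "maternal_smoking", "parental_delinquency",
            "ceca_total", "saha_deviant_peers")
  miss <- setdiff(need, names(rk))
  if (length(miss)) stop("risk table is missing: ", paste(miss, collapse = ", "))
  dat <- data.frame(male = as.numeric(rk$sex == "M"), iq = rk$iq,
                    ses = rk$ses,
                    maternal_smoking = as.numeric(rk$maternal_smoking),
                    parental_delinquency = as.numeric(rk$parental_delinquency),
                    ceca_total = rk$ceca_total,
                    saha_deviant_peers = rk$saha_deviant_peers)
  const <- vapply(dat, function(x) length(unique(x)) < 2, logical(1))
  if (any(const)) {
    warning("constant predictor(s) dropped: ",
            paste(names(dat)[const], collapse = ", "))
    dat <- dat[, !const, drop = FALSE]
  }
  out <- lapply(domain_names(), function(d) {
    y <- as.numeric(fl[[paste0(d, "_deficit")]])
    if (length(unique(y)) < 2) {
      warning("deficit flag ", d, " constant in subset; model skipped")
      return(NULL)
    }
    fit <- stats::glm(y ~ ., data = cbind(data.frame(y = y), dat),
                      family = stats::binomial())
    cf <- summary(fit)$coefficients
    wald <- (cf[, "Estimate"] / cf[, "Std. Error"])^2
    data.frame(domain = d, predictor = rownames(cf),
               estimate = cf[, "Estimate"], odds_ratio = exp(cf[, "Estimate"]),
               wald_chi2 = wald,
               p = stats::pchisq(wald, 1, lower.tail = FALSE),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("risk_result", "data.frame"))
}
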