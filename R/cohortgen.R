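## Synthetic case-control cohort generation.
##
## The generative model: each participant belongs to one of eight latent
## deficit classes (subsets of {recognition, learning, regulation}); the
## three latent domain abilities are
##   ability_d = beta_age * (age - 14) + beta_iq * (iq - 100) + beta_sex * male
##               - deficit_shift * 1{d in class}
##               + group_shift    * 1{CD and d not in class}
##               + noise_sd * z_d,   z ~ MVN(0, domain_corr).
## Abilities are in SD-like units; higher = better performance.

#' Generate a synthetic case-control cohort
#'
#' Draws demographics (age, sex, IQ, SES), latent deficit classes and domain
#' abilities, and clinical records (YPI, RPQ, comorbidities, risk factors) for
#' `n_cd` conduct-disorder cases and `n_tdc` typically developing controls.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A list of class `cohort` with data.frames `participants`
#'   (id, group, age, sex, iq, ses, bracket), `latent` (abilities per domain
#'   and the generating `deficit_class`), and `clinical` (questionnaire items,
#'   symptom counts, comorbidity flags, risk factors).
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(unclass(config))
  set.seed(derive_seed(config$seed, "cohort"))
  n <- config$n_cd + config$n_tdc
  group <- rep(c("CD", "TDC"), c(config$n_cd, config$n_tdc))

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  p_female <- ifelse(group == "CD", config$sex_ratio_by_group$cd,
                     config$sex_ratio_by_group$tdc)
  sex <- ifelse(stats::runif(n) < p_female, "F", "M")
  iq_par <- config$iq_mean_sd_by_group
  iq <- ifelse(group == "CD",
               stats::rnorm(n, iq_par$cd[1], iq_par$cd[2]),
               stats::rnorm(n, iq_par$tdc[1], iq_par$tdc[2]))
  ## exclusion criterion: IQ < iq_min; redraw by truncation
  while (any(bad <- iq < config$iq_min)) {
    m <- ifelse(group[bad] == "CD", iq_par$cd[1], iq_par$tdc[1])
    s <- ifelse(group[bad] == "CD", iq_par$cd[2], iq_par$tdc[2])
    iq[bad] <- stats::rnorm(sum(bad), m, s)
  }
  ses_par <- config$ses_mean_sd_by_group
  ses <- ifelse(group == "CD",
                stats::rnorm(n, ses_par$cd[1], ses_par$cd[2]),
                stats::rnorm(n, ses_par$tdc[1], ses_par$tdc[2]))

  participants <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    group = group, age = age, sex = sex, iq = iq, ses = ses,
    bracket = age_bracket(age, config$bracket_edges),
    stringsAsFactors = FALSE
  )

  latent <- draw_latent_profiles(participants, config)
  clinical <- simulate_clinical(participants, latent, config)

  structure(list(participants = participants, latent = latent,
                 clinical = clinical, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$participants), "participants (",
      sum(x$participants$group == "CD"), "CD /",
      sum(x$participants$group == "TDC"), "TDC )\n")
  print(table(x$participants$group, x$latent$deficit_class))
  invisible(x)
}

#' Draw latent deficit classes and domain abilities
#'
#' @param participants data.frame as in [generate_cohort()].
#' @param config a `cohort_config`.
#' @return data.frame with `id`, `deficit_class`, and `ability_rec`,
#'   `ability_lrn`, `ability_reg`.
#' @keywords internal
draw_latent_profiles <- function(participants, config) {
  n <- nrow(participants)
  cells <- venn_cells()
  p_cd <- config$deficit_class_probs_cd[cells]
  p_tdc <- config$deficit_class_probs_tdc[cells]
  u <- stats::runif(n)
  cls <- character(n)
  is_cd <- participants$group == "CD"
  cls[is_cd] <- cells[findInterval(u[is_cd], cumsum(p_cd), left.open = TRUE) + 1L]
  cls[!is_cd] <- cells[findInterval(u[!is_cd], cumsum(p_tdc), left.open = TRUE) + 1L]

  memb <- venn_membership()[cls, , drop = FALSE]  # n x 3 logical
  b <- config$covariate_betas
  male <- as.numeric(participants$sex == "M")
  covar <- b[["age"]] * (participants$age - 14) +
    b[["iq"]] * (participants$iq - 100) + b[["sex_male"]] * male

  ch <- chol(config$domain_corr)
  z <- matrix(stats::rnorm(n * 3), n, 3) %*% ch
  abilities <- matrix(covar, n, 3) + config$noise_sd * z
  abilities <- abilities - config$deficit_shift * memb
  abilities <- abilities + config$group_shift * (is_cd * !memb)
  colnames(abilities) <- paste0("ability_", domain_names())

  data.frame(id = participants$id, deficit_class = cls, abilities,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Clinical records

#' Solve the per-item YPI threshold probability for an LPE prevalence target
#'
#' With independent subscales, a subscale is endorsed with probability
#' e = 1 - (1 - p4)^5 and the LPE proxy holds with probability
#' 3 e^2 (1 - e) + e^3 = 3 e^2 - 2 e^3. Given a target prevalence this is
#' inverted for e and then for the per-item probability p4 of answering 4.
#'
#' @param target LPE prevalence in (0, 1).
#' @param items_per_subscale number of items per CU subscale.
#' @return probability that a single CU item is answered 4.
#' @export
calibrate_lpe_p4 <- function(target, items_per_subscale = 5) {
  stopifnot(target > 0, target < 1)
  e <- stats::uniroot(function(e) 3 * e^2 - 2 * e^3 - target,
                      c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  1 - (1 - e)^(1 / items_per_subscale)
}

#' Simulate clinical records for a cohort
#'
#' YPI items (50, answered 1-4) are drawn so that the probability of a CU
#' item reaching the endorsement threshold (a response of 4) is calibrated to
#' the configured group LPE prevalence targets; RPQ items (23, answered 0-2)
#' from configured ordinal response probabilities; CD cases receive a symptom
#' count >= 3 and controls 0 with rare subthreshold exceptions; comorbidity
#' flags and risk factors follow configured rates. The maternal-smoking rate
#' is tilted on the learning-deficit class by the configured odds ratio.
#'
#' @param participants,latent data.frames from [generate_cohort()].
#' @param config a `cohort_config`.
#' @return data.frame with one row per participant: `ypi_1..ypi_50`,
#'   `rpq_1..rpq_23`, `cd_symptom_count`, `onset_type`, comorbidity flags,
#'   and risk factors.
#' @export
simulate_clinical <- function(participants, latent, config) {
  n <- nrow(participants)
  is_cd <- participants$group == "CD"

  ## --- YPI -----------------------------------------------------------------
  p4 <- ifelse(is_cd, calibrate_lpe_p4(config$lpe_target$cd),
               calibrate_lpe_p4(config$lpe_target$tdc))
  ypi <- matrix(0L, n, 50)
  cu_items <- ypi_cu_map()$item
  for (j in seq_len(50)) {
    if (j %in% cu_items) {
      four <- stats::runif(n) < p4
      sub <- draw_ordinal(n, config$ypi_nonfour_probs, is_cd, values = 1:3)
      ypi[, j] <- ifelse(four, 4L, sub)
    } else {
      ypi[, j] <- draw_ordinal(n, config$ypi_noncu_probs, is_cd, values = 1:4)
    }
  }
  colnames(ypi) <- paste0("ypi_", seq_len(50))

  ## --- RPQ -----------------------------------------------------------------
  rpq <- matrix(0L, n, 23)
  map <- rpq_map()
  for (j in seq_len(23)) {
    sub <- map$subscale[j]
    probs <- list(cd = config$rpq_probs$cd[[sub]], tdc = config$rpq_probs$tdc[[sub]])
    rpq[, j] <- draw_ordinal(n, probs, is_cd, values = 0:2)
  }
  colnames(rpq) <- paste0("rpq_", seq_len(23))

  ## --- CD symptoms and onset -----------------------------------------------
  extra_p <- min(1, max(0, (config$cd_symptom_mean - 3) / 12))
  cd_symptoms <- integer(n)
  cd_symptoms[is_cd] <- 3L + stats::rbinom(sum(is_cd), 12, extra_p)
  cd_symptoms[!is_cd] <- stats::rbinom(sum(!is_cd), 2, 0.025)  # subthreshold
  onset <- rep("none", n)
  onset[is_cd] <- sample(names(config$onset_probs), sum(is_cd), replace = TRUE,
                         prob = config$onset_probs)

  ## --- comorbidities --------------------------------------------------------
  com <- sapply(names(config$comorbidity_rates_cd), function(d) {
    out <- logical(n)
    out[is_cd] <- stats::runif(sum(is_cd)) < config$comorbidity_rates_cd[[d]]
    out
  })
  colnames(com) <- paste0("comorbid_", colnames(com))

  ## --- risk factors ---------------------------------------------------------
  rk <- config$risk
  lrn_def <- venn_membership()[latent$deficit_class, "lrn"]
  base <- ifelse(is_cd, rk$maternal_smoking_base$cd, rk$maternal_smoking_base$tdc)
  p_smoke <- stats::plogis(stats::qlogis(base) + log(rk$smoking_lrn_or) * lrn_def)
  maternal_smoking <- stats::runif(n) < p_smoke
  parental_delinquency <- stats::runif(n) <
    ifelse(is_cd, rk$parental_delinquency$cd, rk$parental_delinquency$tdc)
  ceca <- pmax(0, round(ifelse(is_cd,
                               stats::rnorm(n, rk$ceca_mean_sd$cd[1], rk$ceca_mean_sd$cd[2]),
                               stats::rnorm(n, rk$ceca_mean_sd$tdc[1], rk$ceca_mean_sd$tdc[2]))))
  saha <- 9L + stats::rbinom(n, 27, ifelse(is_cd, rk$saha_p$cd, rk$saha_p$tdc))

  data.frame(id = participants$id, ypi, rpq,
             cd_symptom_count = cd_symptoms, onset_type = onset, com,
             maternal_smoking = maternal_smoking,
             parental_delinquency = parental_delinquency,
             ceca_total = ceca, saha_deviant_peers = saha,
             stringsAsFactors = FALSE)
}

#' Draw ordinal responses with group-specific probabilities
#' @keywords internal
draw_ordinal <- function(n, probs, is_cd, values) {
  pc <- probs$cd / sum(probs$cd)
  pt <- probs$tdc / sum(probs$tdc)
  stopifnot(length(pc) == length(values), length(pt) == length(values))
  u <- stats::runif(n)
  out <- integer(n)
  out[is_cd] <- values[findInterval(u[is_cd], cumsum(pc), left.open = TRUE) + 1L]
  out[!is_cd] <- values[findInterval(u[!is_cd], cumsum(pt), left.open = TRUE) + 1L]
  out
}
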