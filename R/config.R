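## Cohort configuration: defaults, YAML reading, validation.

#' Default cohort configuration (replication design)
#'
#' Returns the configuration used throughout the package's replication runs.
#' Sample sizes, demographics, the CD deficit-class mixture margins and
#' aggregate cell proportions, and the LPE prevalence targets follow the
#' published study design (CD n = 542, TDC n = 710, ages 9-18, recognition /
#' learning / regulation deficit margins 23% / 13% / 18%, no-deficit 56.3%,
#' pervasive cell 1%, LPE prevalence 43.7% CD / 18.3% TDC). The TDC mixture is
#' independence at 10% per domain. Quantities the study does not determine
#' (latent domain correlations, the deficit shift, measurement parameters) are
#' package design choices documented in the methods vignette.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @export
default_cohort_config <- function() {
  cfg <- list(
    name = "replication",
    n_cd = 542L,
    n_tdc = 710L,
    age_range = c(9, 19),
    bracket_edges = c(9, 13, 16, 19),
    sex_ratio_by_group = list(cd = 0.585, tdc = 0.675),
    iq_mean_sd_by_group = list(cd = c(94.9, 12.4), tdc = c(103.5, 12.2)),
    iq_min = 70,
    ses_mean_sd_by_group = list(cd = c(-0.29, 0.93), tdc = c(0.28, 1.03)),
    deficit_class_probs_cd = c(
      none = 0.563, rec = 0.155, lrn = 0.077, reg = 0.112,
      `rec+lrn` = 0.025, `rec+reg` = 0.040, `lrn+reg` = 0.018,
      `rec+lrn+reg` = 0.010),
    deficit_class_probs_tdc = c(
      none = 0.729, rec = 0.081, lrn = 0.081, reg = 0.081,
      `rec+lrn` = 0.009, `rec+reg` = 0.009, `lrn+reg` = 0.009,
      `rec+lrn+reg` = 0.001),
    domain_corr = matrix(c(1, 0.3, 0.3,
                           0.3, 1, 0.3,
                           0.3, 0.3, 1), 3, 3,
                         dimnames = list(domain_names(), domain_names())),
    deficit_shift = 1.8,
    group_shift = -0.15,
    covariate_betas = c(age = 0.08, iq = 0.015, sex_male = -0.10),
    noise_sd = 0.5,
    lpe_target = list(cd = 0.437, tdc = 0.183),
    cd_symptom_mean = 5.45,
    onset_probs = c(childhood = 0.430, adolescence = 0.533, unspecified = 0.037),
    comorbidity_rates_cd = c(ODD = 0.782, ADHD = 0.384, SUD = 0.174,
                             MDD = 0.148, PTSD = 0.067, GAD = 0.030),
    rpq_probs = list(
      cd = list(reactive = c(0.25, 0.40, 0.35), proactive = c(0.82, 0.16, 0.02)),
      tdc = list(reactive = c(0.55, 0.35, 0.10), proactive = c(0.95, 0.045, 0.005))),
    ypi_noncu_probs = list(cd = c(0.35, 0.30, 0.22, 0.13),
                           tdc = c(0.55, 0.28, 0.13, 0.04)),
    ypi_nonfour_probs = list(cd = c(0.40, 0.35, 0.25), tdc = c(0.60, 0.28, 0.12)),
    risk = list(
      maternal_smoking_base = list(cd = 0.25, tdc = 0.12),
      smoking_lrn_or = 3.2,
      parental_delinquency = list(cd = 0.20, tdc = 0.05),
      ceca_mean_sd = list(cd = c(6, 4), tdc = c(3, 2.5)),
      saha_p = list(cd = 0.35, tdc = 0.15)),
    tasks = list(
      hexagon = list(slope = 1.5, icpt_90 = 2.5, icpt_70 = 1.3,
                     other_proto_mass = 0.75, timeout_prob = 0.01),
      pa = list(init_propensity = 0.5, base_lr = 1.0, lr_ability_slope = 1.8,
                magnitude_weights = c(`1` = 0.4, `700` = 0.7,
                                      `1400` = 0.85, `2000` = 1.0),
                bias_sd = 0.10),
      gonogo = list(fa_icpt = -0.8, fa_ability_slope = 1.3, go_hit = 0.95,
                    pair_offsets = c(`neutral-happy` = 0.15,
                                     `neutral-fearful` = 0.15,
                                     `happy-neutral` = -0.10,
                                     `fearful-neutral` = -0.10,
                                     `happy-fearful` = 0.05,
                                     `fearful-happy` = 0.05))),
    seed = 1L
  )
  validate_cohort_config(cfg)
}

#' Build a cohort configuration from a list of overrides
#'
#' @param ... named fields overriding [default_cohort_config()].
#' @return A validated `cohort_config`.
#' @export
cohort_config <- function(...) {
  over <- list(...)
  cfg <- unclass(default_cohort_config())
  if (length(over)) {
    stopifnot(!is.null(names(over)), all(nzchar(names(over))))
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    }
    for (nm in names(over)) {
      if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
        cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
      } else {
        cfg[[nm]] <- over[[nm]]
      }
    }
  }
  validate_cohort_config(cfg)
}

#' Read a cohort configuration from a YAML (or JSON) file
#'
#' Fields omitted from the file inherit the replication defaults.
#' @param path path to a YAML/JSON configuration file.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$domain_corr)) {
    dc <- raw$domain_corr
    if (!is.matrix(dc)) {
      dc <- if (length(dc) == 1) {
        m <- matrix(as.numeric(dc), 3, 3); diag(m) <- 1; m
      } else {
        matrix(as.numeric(unlist(dc)), 3, 3)
      }
    }
    dimnames(dc) <- list(domain_names(), domain_names())
    raw$domain_corr <- dc
  }
  for (f in c("deficit_class_probs_cd", "deficit_class_probs_tdc")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  for (f in c("covariate_betas", "comorbidity_rates_cd", "onset_probs")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(cohort_config, raw)
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants: mixture probability vectors over the
#' eight Venn cells sum to one (1e-12), the latent domain correlation matrix
#' is symmetric positive definite, group sizes are positive counts, and the
#' age brackets partition the age range.
#'
#' @param cfg named list of configuration fields.
#' @return The validated config, classed `cohort_config`.
#' @export
validate_cohort_config <- function(cfg) {
  if (!is_count(cfg$n_cd) || !is_count(cfg$n_tdc) ||
      cfg$n_cd <= 0 || cfg$n_tdc <= 0) {
    stop("configuration error: n_cd and n_tdc must be positive counts")
  }
  for (f in c("deficit_class_probs_cd", "deficit_class_probs_tdc")) {
    p <- cfg[[f]]
    if (is.null(names(p)) || !setequal(names(p), venn_cells())) {
      stop("configuration error: ", f, " must be named by the 8 Venn cells")
    }
    p <- p[venn_cells()]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop("configuration error: ", f,
           " must be non-negative and sum to 1 (within 1e-12); got sum ",
           format(sum(p), digits = 15))
    }
    cfg[[f]] <- p
  }
  dc <- cfg$domain_corr
  if (!is.matrix(dc) || !all(dim(dc) == c(3, 3)) ||
      max(abs(dc - t(dc))) > 1e-12 || max(abs(diag(dc) - 1)) > 1e-12) {
    stop("configuration error: domain_corr must be a symmetric 3x3 correlation matrix")
  }
  ev <- eigen(dc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("configuration error: domain_corr is not positive definite ",
         "(smallest eigenvalue ", format(min(ev), digits = 6), ")")
  }
  edges <- cfg$bracket_edges
  if (length(edges) < 2 || is.unsorted(edges, strictly = TRUE) ||
      abs(edges[1] - cfg$age_range[1]) > 1e-12 ||
      abs(edges[length(edges)] - cfg$age_range[2]) > 1e-12) {
    stop("configuration error: bracket_edges must strictly increase and ",
         "partition age_range")
  }
  stopifnot(cfg$noise_sd >= 0, cfg$deficit_shift >= 0 || TRUE)
  if (!is_count(abs(cfg$seed))) stop("configuration error: seed must be an integer")
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", x$name %||% "", "\n")
  cat("  n_cd:", x$n_cd, " n_tdc:", x$n_tdc,
      " ages:", paste(x$age_range, collapse = "-"), "\n")
  marg <- drop(crossprod(venn_membership(), x$deficit_class_probs_cd[venn_cells()]))
  cat("  deficit margins (CD):",
      paste(sprintf("%s=%.3f", names(marg), marg), collapse = " "), "\n")
  cat("  deficit_shift:", x$deficit_shift, " group_shift:", x$group_shift,
      " noise_sd:", x$noise_sd, " seed:", x$seed, "\n")
  invisible(x)
}

#' Age bracket labels for a set of ages
#'
#' Brackets are closed on the left: with the default edges 9, 13, 16, 19 the
#' brackets are 9-12, 13-15 and 16-18 years.
#' @param age numeric ages.
#' @param edges bracket edges.
#' @return character bracket labels.
#' @export
age_bracket <- function(age, edges = c(9, 13, 16, 19)) {
  if (any(age < edges[1] | age >= edges[length(edges)])) {
    stop("age outside the bracketed range")
  }
  labs <- paste0(edges[-length(edges)], "-", ceiling(edges[-1]) - 1)
  labs[findInterval(age, edges, rightmost.closed = FALSE)]
}
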