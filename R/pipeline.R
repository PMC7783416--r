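## End-to-end orchestration: simulate -> score -> adjust -> factor ->
## classify -> stats -> correlates, with CSV stage outputs, a consolidated
## report and a run manifest.

#' Run the full analysis in memory
#'
#' Executes every stage on a freshly simulated cohort and returns all
#' intermediate and final results. This is the computational core used by
#' [run_pipeline()]; it writes nothing to disk.
#'
#' @param config a `cohort_config` (or path to a YAML config).
#' @param seed optional master seed overriding `config$seed`.
#' @param q deficit proportion for the normative cutoffs.
#' @param fit_sample adjustment fit sample, `"pooled"` or `"controls_only"`.
#' @param n_boot bootstrap resamples for correlation CIs (0 skips).
#' @return list of class `study_replication` with elements `cohort`, `scores`,
#'   `z`, `diagnostics`, `solution`, `factor_scores`, `thresholds`, `flags`,
#'   `venn`, `independence`, `anova`, `logistic`, `clinical_scores`,
#'   `associations`, `risk_models`.
#' @export
replicate_study <- function(config = default_cohort_config(), seed = NULL,
                            q = 0.10, fit_sample = "pooled", n_boot = 2000) {
  if (is.character(config)) config <- read_cohort_config(config)
  config <- unclass(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config <- validate_cohort_config(config)

  cohort <- generate_cohort(config)
  scores <- simulate_scores(cohort)
  z <- residualize(scores, cohort$participants, fit_sample = fit_sample)
  diagnostics <- corr_diagnostics(z, n_boot = n_boot, seed = config$seed)
  solution <- fit_pca_varimax(z, k = 3)
  fscores <- anderson_rubin_scores(z, solution)
  thresholds <- estimate_thresholds(fscores, cohort$participants, q = q)
  flags <- classify_deficits(fscores, thresholds, cohort$participants)
  venn <- venn_summary(flags, cohort$participants$group)
  anova <- rm_anova(fscores, cohort$participants$group)
  logistic <- logistic_discrimination(fscores, cohort$participants$group)

  clin <- score_clinical(cohort$clinical)
  is_cd <- cohort$participants$group == "CD"
  outcomes <- data.frame(
    cd_symptom_count = cohort$clinical$cd_symptom_count,
    lpe = as.numeric(clin$lpe),
    childhood_onset = as.numeric(cohort$clinical$onset_type == "childhood"),
    rpq_proactive = clin$rpq_proactive,
    rpq_reactive = clin$rpq_reactive,
    comorbid_ADHD = as.numeric(cohort$clinical$comorbid_ADHD),
    comorbid_GAD = as.numeric(cohort$clinical$comorbid_GAD))
  associations <- deficit_associations(flags, outcomes, subset = is_cd)
  risk <- data.frame(sex = cohort$participants$sex,
                     iq = cohort$participants$iq,
                     ses = cohort$participants$ses,
                     maternal_smoking = cohort$clinical$maternal_smoking,
                     parental_delinquency = cohort$clinical$parental_delinquency,
                     ceca_total = cohort$clinical$ceca_total,
                     saha_deviant_peers = cohort$clinical$saha_deviant_peers)
  risk_models <- risk_factor_models(flags, risk, subset = is_cd)

  structure(list(cohort = cohort, scores = scores, z = z,
                 diagnostics = diagnostics, solution = solution,
                 factor_scores = fscores, thresholds = thresholds,
                 flags = flags, venn = venn,
                 independence = independence_expectation(q, 3),
                 anova = anova, logistic = logistic,
                 clinical_scores = clin, associations = associations,
                 risk_models = risk_models, q = q, config = config),
            class = "study_replication")
}

#' Run the pipeline and write stage outputs, report and manifest
#'
#' @param config a `cohort_config` or path to a YAML/JSON config file.
#' @param out_dir output directory (created if absent).
#' @param seed optional master seed overriding the config's.
#' @param q deficit proportion.
#' @param fit_sample `"pooled"` or `"controls_only"`.
#' @param n_boot bootstrap resamples for correlation CIs.
#' @return the run manifest, invisibly; side effect: CSV/JSON/text outputs in
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, q = 0.10,
                         fit_sample = "pooled", n_boot = 2000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- replicate_study(config, seed = seed, q = q, fit_sample = fit_sample,
                         n_boot = n_boot)
  files <- write_stage_outputs(res, out_dir)
  report <- build_report(res)
  rp_json <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, rp_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  rp_txt <- file.path(out_dir, "report.txt")
  writeLines(format_report(report), rp_txt)
  files <- c(files, rp_json, rp_txt)

  cfg_file <- file.path(out_dir, "config_used.yaml")
  cfg_out <- unclass(res$config)
  cfg_out$domain_corr <- as.vector(cfg_out$domain_corr)
  yaml::write_yaml(cfg_out, cfg_file)
  files <- c(files, cfg_file)

  manifest <- list(
    package_version = as.character(utils::packageVersion("emopheno")),
    seed = res$config$seed, q = q, fit_sample = fit_sample,
    config_hash = unname(tools::md5sum(cfg_file)),
    timestamp = format(Sys.time(), tz = "UTC"),
    stages = data.frame(file = basename(files),
                        md5 = unname(tools::md5sum(files)),
                        rows = vapply(files, function(f) {
                          if (grepl("[.]csv$", f)) length(readLines(f)) - 1L else NA_integer_
                        }, integer(1)),
                        row.names = NULL, stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @keywords internal
write_stage_outputs <- function(res, out_dir) {
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  files <- c(
    w(res$cohort$participants, "cohort.csv"),
    w(res$cohort$latent, "latent.csv"),
    w(res$cohort$clinical, "clinical.csv"),
    w(res$scores, "scores.csv"),
    w(res$z$z, "zscores.csv"),
    w(res$z$coefficients, "adjust_coefficients.csv"),
    w(loadings_table(res$solution), "loadings.csv"),
    w(res$factor_scores, "factor_scores.csv"),
    w(as.data.frame(res$thresholds), "thresholds.csv"),
    w(res$flags, "flags.csv"),
    w(res$venn$cells, "venn_cells.csv"),
    w(res$venn$margins, "venn_margins.csv"),
    w(res$venn$aggregates, "venn_aggregates.csv"),
    w(res$clinical_scores, "clinical_scores.csv"))
  if (!is.null(res$associations$models)) {
    files <- c(files, w(res$associations$models, "associations.csv"))
  }
  if (!is.null(res$associations$contrasts)) {
    files <- c(files, w(res$associations$contrasts, "association_contrasts.csv"))
  }
  if (!is.null(res$risk_models)) {
    files <- c(files, w(as.data.frame(res$risk_models), "risk_models.csv"))
  }
  files
}

#' Loadings in tabular form (variables x components plus eigenvalue and
#' variance rows)
#' @keywords internal
loadings_table <- function(solution) {
  L <- solution$loadings
  df <- data.frame(variable = rownames(L), round(as.data.frame(L), 6),
                   stringsAsFactors = FALSE)
  extra <- data.frame(variable = c("eigenvalue", "variance_explained"),
                      rbind(solution$eigenvalues,
                            solution$variance_explained),
                      stringsAsFactors = FALSE)
  names(extra) <- names(df)
  rownames(df) <- rownames(extra) <- NULL
  rbind(df, extra)
}

#' Assemble the consolidated machine-readable report
#' @keywords internal
build_report <- function(res) {
  d <- res$diagnostics
  list(
    design = list(n_cd = res$config$n_cd, n_tdc = res$config$n_tdc,
                  seed = res$config$seed, q = res$q),
    diagnostics = list(
      mean_r_within = d$mean_r_within, ci_within = d$ci_within,
      mean_r_between = d$mean_r_between, ci_between = d$ci_between,
      fisher_z = d$fisher_z, fisher_p = d$fisher_p,
      kmo_overall = d$kmo_overall,
      kmo_min = min(d$kmo_per_variable),
      bartlett_chi2 = d$bartlett_chi2, bartlett_df = d$bartlett_df,
      bartlett_p = d$bartlett_p),
    factor_solution = list(
      eigenvalues = as.list(res$solution$eigenvalues),
      variance_explained = as.list(res$solution$variance_explained),
      total_variance_explained = res$solution$total_variance_explained,
      domain_assignment = as.list(res$solution$domain_assignment)),
    anova = list(effects = res$anova$effects, posthoc = res$anova$posthoc,
                 gg_epsilon = res$anova$gg_epsilon),
    logistic = list(model_chi2 = res$logistic$model_chi2,
                    model_df = res$logistic$model_df,
                    model_p = res$logistic$model_p,
                    predictors = res$logistic$predictors,
                    hosmer_lemeshow = res$logistic$hosmer_lemeshow,
                    sensitivity = res$logistic$sensitivity,
                    sensitivity_ci = res$logistic$sensitivity_ci,
                    specificity = res$logistic$specificity,
                    specificity_ci = res$logistic$specificity_ci),
    venn = list(cells = res$venn$cells, margins = res$venn$margins,
                aggregates = res$venn$aggregates,
                group_tests = res$venn$group_tests),
    independence_expectation = res$independence,
    clinical_correlates = list(models = res$associations$models,
                               contrasts = res$associations$contrasts),
    risk_factors = as.data.frame(res$risk_models)
  )
}

#' Format the report as readable text
#' @keywords internal
format_report <- function(rp) {
  f <- function(x, d = 3) formatC(x, format = "f", digits = d)
  lines <- c(
    "==== Person-centered emotion-processing analysis ====",
    sprintf("Design: %d CD / %d TDC, seed %s, deficit cutoff q = %s",
            rp$design$n_cd, rp$design$n_tdc, rp$design$seed, rp$design$q),
    "",
    "-- Correlation diagnostics --",
    sprintf("mean r within %s [%s, %s], between %s [%s, %s]; Fisher z %s (p %s)",
            f(rp$diagnostics$mean_r_within), f(rp$diagnostics$ci_within[1]),
            f(rp$diagnostics$ci_within[2]), f(rp$diagnostics$mean_r_between),
            f(rp$diagnostics$ci_between[1]), f(rp$diagnostics$ci_between[2]),
            f(rp$diagnostics$fisher_z, 2), format.pval(rp$diagnostics$fisher_p)),
    sprintf("KMO %s (min per-variable %s); Bartlett chi2(%d) = %s, p %s",
            f(rp$diagnostics$kmo_overall), f(rp$diagnostics$kmo_min),
            rp$diagnostics$bartlett_df, f(rp$diagnostics$bartlett_chi2, 2),
            format.pval(rp$diagnostics$bartlett_p)),
    "",
    "-- Factor solution (3 components, varimax) --",
    sprintf("rotated eigenvalues: %s; total variance explained %s%%",
            paste(f(unlist(rp$factor_solution$eigenvalues), 2), collapse = ", "),
            f(100 * rp$factor_solution$total_variance_explained, 1)),
    sprintf("domain assignment: %s",
            paste(names(rp$factor_solution$domain_assignment),
                  unlist(rp$factor_solution$domain_assignment),
                  sep = "=", collapse = ", ")),
    "",
    "-- Dimensional comparison (mixed ANOVA) --",
    utils::capture.output(print(rp$anova$effects, row.names = FALSE, digits = 4)),
    "post-hoc per-domain contrasts (Bonferroni):",
    utils::capture.output(print(rp$anova$posthoc, row.names = FALSE, digits = 4)),
    "",
    "-- Logistic group discrimination --",
    sprintf("model chi2(%d) = %s (p %s); HL chi2(%d) = %s (p %s)",
            rp$logistic$model_df, f(rp$logistic$model_chi2, 2),
            format.pval(rp$logistic$model_p), rp$logistic$hosmer_lemeshow$df,
            f(rp$logistic$hosmer_lemeshow$chi2, 2),
            format.pval(rp$logistic$hosmer_lemeshow$p)),
    sprintf("sensitivity %s%% [%s, %s], specificity %s%% [%s, %s]",
            f(100 * rp$logistic$sensitivity, 1),
            f(100 * rp$logistic$sensitivity_ci[1], 1),
            f(100 * rp$logistic$sensitivity_ci[2], 1),
            f(100 * rp$logistic$specificity, 1),
            f(100 * rp$logistic$specificity_ci[1], 1),
            f(100 * rp$logistic$specificity_ci[2], 1)),
    "",
    "-- Deficit overlap (Venn) --",
    utils::capture.output(print(rp$venn$aggregates, row.names = FALSE, digits = 4)),
    utils::capture.output(print(rp$venn$margins, row.names = FALSE, digits = 4)),
    sprintf("independence expectation at q: >=1 %s%%, all 3 %s%%",
            f(100 * rp$independence_expectation$p_at_least_1, 1),
            f(100 * rp$independence_expectation$p_all, 2)),
    "",
    "-- Clinical correlates (CD subset) --",
    if (!is.null(rp$clinical_correlates$contrasts)) {
      utils::capture.output(print(rp$clinical_correlates$contrasts,
                                  row.names = FALSE, digits = 4))
    } else "(none)",
    "",
    "-- Risk-factor models (CD subset) --",
    if (!is.null(rp$risk_factors) && nrow(rp$risk_factors)) {
      utils::capture.output(print(rp$risk_factors, row.names = FALSE, digits = 4))
    } else "(none)")
  unlist(lines)
}
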