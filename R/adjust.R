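## Regression adjustment of raw performance scores for age, IQ and sex.

#' Residualize performance scores on age, IQ and sex
#'
#' Per variable, an ordinary least-squares regression on age, IQ and a sex
#' indicator is fitted on the chosen fit sample (all participants by default,
#' or controls only for a normative variant); residuals are computed for all
#' rows and standardized by the fit-sample residual standard deviation, so
#' each adjusted column has mean 0 and SD 1 over the fit sample.
#'
#' @param scores ScoreTable data.frame (`id` + 20 performance variables).
#' @param participants participant table with `id`, `age`, `iq`, `sex`
#'   (and `group` when `fit_sample = "controls_only"`).
#' @param fit_sample `"pooled"` (default) or `"controls_only"`.
#' @param check_ranges verify raw-score ranges (disable when re-adjusting an
#'   already standardized table).
#' @return A list of class `zscore_table`: `z` (data.frame, `id` + adjusted
#'   columns suffixed `_z`) and `coefficients` (tidy data.frame: variable,
#'   term, estimate).
#' @export
residualize <- function(scores, participants,
                        fit_sample = c("pooled", "controls_only"),
                        check_ranges = TRUE) {
  fit_sample <- match.arg(fit_sample)
  validate_score_table(scores, check_ranges = check_ranges)
  stopifnot(all(scores$id == participants$id))
  covars <- data.frame(age = participants$age, iq = participants$iq,
                       sex_male = as.numeric(participants$sex == "M"))
  if (anyNA(covars)) stop("missing covariates: complete cases required")
  fit_rows <- if (fit_sample == "pooled") {
    rep(TRUE, nrow(covars))
  } else {
    participants$group == "TDC"
  }
  if (!any(fit_rows)) stop("empty fit sample")
  X <- cbind(1, as.matrix(covars))
  if (qr(X[fit_rows, , drop = FALSE])$rank < ncol(X)) {
    stop("rank-deficient adjustment design: collinear covariates")
  }
  vars <- score_variable_names()
  zcols <- matrix(NA_real_, nrow(scores), length(vars),
                  dimnames = list(NULL, paste0(vars, "_z")))
  coefs <- vector("list", length(vars))
  for (i in seq_along(vars)) {
    y <- scores[[vars[i]]]
    if (stats::sd(y[fit_rows]) == 0) {
      stop("degenerate input: variable ", vars[i],
           " has zero variance in the fit sample")
    }
    fit <- stats::lm(y ~ age + iq + sex_male, data = covars,
                     subset = which(fit_rows))
    res_all <- y - as.numeric(X %*% stats::coef(fit))
    s <- stats::sd(res_all[fit_rows])
    if (s < .Machine$double.eps^0.5) {
      warning("variable ", vars[i], " is (near-)exactly linear in the ",
              "covariates; adjusted column is degenerate")
      zcols[, i] <- 0
    } else {
      zcols[, i] <- res_all / s
    }
    coefs[[i]] <- data.frame(variable = vars[i],
                             term = c("(Intercept)", "age", "iq", "sex_male"),
                             estimate = as.numeric(stats::coef(fit)),
                             stringsAsFactors = FALSE)
  }
  structure(list(z = data.frame(id = scores$id, zcols,
                                stringsAsFactors = FALSE),
                 coefficients = do.call(rbind, coefs),
                 fit_sample = fit_sample),
            class = "zscore_table")
}

#' @export
print.zscore_table <- function(x, ...) {
  cat("<zscore_table>", nrow(x$z), "participants x",
      ncol(x$z) - 1, "adjusted variables (fit sample:", x$fit_sample, ")\n")
  invisible(x)
}

#' Extract the adjusted-score matrix from a `zscore_table`
#' @param z a `zscore_table` (or a data.frame already holding `_z` columns).
#' @return numeric matrix, rows in participant order.
#' @export
z_matrix <- function(z) {
  if (inherits(z, "zscore_table")) z <- z$z
  if (is.matrix(z)) return(z)
  as.matrix(z[, setdiff(names(z), "id"), drop = FALSE])
}
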