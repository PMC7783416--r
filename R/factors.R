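## Correlation diagnostics and the confirmatory three-component model.

#' Olkin-Pratt approximately unbiased correlation estimate
#'
#' The standard unbiased-estimator series truncated at the leading
#' hypergeometric term: `r * (1 + (1 - r^2) / (2 * (n - 3)))`.
#'
#' @param r sample Pearson correlation(s).
#' @param n sample size.
#' @return corrected correlation(s).
#' @export
olkin_pratt <- function(r, n) {
  stopifnot(n > 3)
  r * (1 + (1 - r^2) / (2 * (n - 3)))
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Compares squared correlations to squared partial correlations (computed
#' from the inverse correlation matrix; a pseudo-inverse with a warning when
#' the matrix is singular).
#'
#' @param R correlation matrix.
#' @return list with `overall` and per-variable `per_variable` KMO values.
#' @export
kmo <- function(R) {
  p <- ncol(R)
  inv <- tryCatch(solve(R), error = function(e) {
    warning("singular correlation matrix: KMO computed with pseudo-inverse")
    e <- eigen(R, symmetric = TRUE)
    pos <- e$values > 1e-10 * max(e$values)
    e$vectors[, pos] %*% diag(1 / e$values[pos], sum(pos)) %*% t(e$vectors[, pos])
  })
  a <- -inv / sqrt(outer(diag(inv), diag(inv)))
  diag(a) <- 0
  r2 <- R^2; diag(r2) <- 0
  a2 <- a^2
  list(overall = sum(r2) / (sum(r2) + sum(a2)),
       per_variable = stats::setNames(rowSums(r2) / (rowSums(r2) + rowSums(a2)),
                                      colnames(R)))
}

#' Bartlett's test of sphericity
#'
#' Chi-square statistic `-(n - 1 - (2p + 5)/6) * log|R|` with
#' `p(p - 1)/2` degrees of freedom.
#'
#' @param R correlation matrix.
#' @param n number of observations.
#' @return list with `chi2`, `df`, `p`.
#' @export
bartlett_sphericity <- function(R, n) {
  p <- ncol(R)
  detR <- det(R)
  if (!is.finite(log(detR))) {
    stop("singular correlation matrix: Bartlett's statistic is undefined")
  }
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Correlation-structure diagnostics for the adjusted score battery
#'
#' Computes the Pearson correlation matrix, Olkin-Pratt-corrected mean
#' correlations within and between the three task domains (with percentile
#' bootstrap CIs over participants), a Fisher r-to-z contrast of the two
#' means, KMO overall and per variable, and Bartlett's test of sphericity.
#'
#' @param z a `zscore_table` or matrix/data.frame of adjusted scores.
#' @param domain_partition named list mapping domain names to column names
#'   (defaults to the score-variable groups with `_z` suffixes stripped as
#'   needed).
#' @param n_boot bootstrap resamples for the CIs (0 skips them).
#' @param conf confidence level.
#' @param seed seed for the bootstrap substream.
#' @return list of class `corr_diagnostics`.
#' @export
corr_diagnostics <- function(z, domain_partition = NULL, n_boot = 2000,
                             conf = 0.95, seed = 1L) {
  zm <- z_matrix(z)
  n <- nrow(zm); p <- ncol(zm)
  if (is.null(domain_partition)) {
    grp <- score_variable_groups()
    domain_partition <- lapply(grp, function(v) {
      cand <- intersect(c(v, paste0(v, "_z")), colnames(zm))
      cand
    })
  }
  sizes <- lengths(domain_partition)
  if (any(sizes < 3)) stop("each domain block needs at least 3 variables")
  if (n <= p) warning("n <= p: correlation diagnostics are unstable")

  vars <- unlist(domain_partition, use.names = FALSE)
  stopifnot(all(vars %in% colnames(zm)))
  zm <- zm[, vars, drop = FALSE]
  block <- rep(names(domain_partition), sizes)

  R <- stats::cor(zm)
  within_mask <- outer(block, block, "==")
  ut <- upper.tri(R)

  mean_rs <- function(mat, nn) {
    rc <- olkin_pratt(mat, nn)
    c(within = mean(rc[ut & within_mask]), between = mean(rc[ut & !within_mask]))
  }
  est <- mean_rs(R, n)

  ci_w <- ci_b <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(derive_seed(seed, "corr-boot"))
    boots <- matrix(NA_real_, n_boot, 2)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      boots[b, ] <- mean_rs(stats::cor(zm[idx, , drop = FALSE]), n)
    }
    alpha <- (1 - conf) / 2
    ci_w <- stats::quantile(boots[, 1], c(alpha, 1 - alpha), names = FALSE)
    ci_b <- stats::quantile(boots[, 2], c(alpha, 1 - alpha), names = FALSE)
  }

  ## Fisher r-to-z two-sample contrast of the two mean correlations
  fz <- (atanh(est["within"]) - atanh(est["between"])) / sqrt(2 / (n - 3))

  km <- kmo(R)
  bt <- bartlett_sphericity(R, n)

  structure(list(corr_matrix = R,
                 mean_r_within = unname(est["within"]), ci_within = ci_w,
                 mean_r_between = unname(est["between"]), ci_between = ci_b,
                 fisher_z = unname(fz),
                 fisher_p = 2 * stats::pnorm(-abs(unname(fz))),
                 kmo_overall = km$overall, kmo_per_variable = km$per_variable,
                 bartlett_chi2 = bt$chi2, bartlett_df = bt$df,
                 bartlett_p = bt$p, n = n, n_boot = n_boot),
            class = "corr_diagnostics")
}

#' @export
print.corr_diagnostics <- function(x, ...) {
  cat("<corr_diagnostics> n =", x$n, "\n")
  cat(sprintf("  mean r (Olkin-Pratt) within %.3f [%.3f, %.3f], between %.3f [%.3f, %.3f]\n",
              x$mean_r_within, x$ci_within[1], x$ci_within[2],
              x$mean_r_between, x$ci_between[1], x$ci_between[2]))
  cat(sprintf("  Fisher z = %.2f (p = %.3g); KMO = %.3f; Bartlett chi2(%d) = %.2f, p = %.3g\n",
              x$fisher_z, x$fisher_p, x$kmo_overall, x$bartlett_df,
              x$bartlett_chi2, x$bartlett_p))
  invisible(x)
}

#' Confirmatory principal-component model with varimax rotation
#'
#' Eigendecomposition of the correlation matrix; the first `k` components are
#' retained (confirmatory, fixed `k`), scaled to loadings, and rotated by
#' varimax with Kaiser normalization. Column signs are oriented so salient
#' loadings (|loading| >= 0.30) are majority-positive, and components are
#' assigned to domains by the task group carrying the largest mean absolute
#' loading (a bijection chosen over all assignments).
#'
#' @param z a `zscore_table` or matrix of adjusted scores.
#' @param k number of retained components (default 3).
#' @param domain_partition named list mapping domains to variable columns
#'   (defaults as in [corr_diagnostics()]).
#' @return list of class `factor_solution`: `loadings` (p x k), `rotmat`,
#'   `eigenvalues` (rotated sums of squared loadings), `variance_explained`,
#'   `communalities`, `unrotated` loadings, `domain_assignment`.
#' @export
fit_pca_varimax <- function(z, k = 3, domain_partition = NULL) {
  zm <- z_matrix(z)
  p <- ncol(zm)
  stopifnot(k >= 1, k <= p)
  R <- stats::cor(zm)
  e <- eigen(R, symmetric = TRUE)
  L0 <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  rownames(L0) <- colnames(zm)

  if (k > 1) {
    rot <- stats::varimax(L0, normalize = TRUE, eps = 1e-10)
    L <- unclass(rot$loadings)
    rotmat <- rot$rotmat
  } else {
    L <- L0
    rotmat <- matrix(1, 1, 1)
  }

  ## orient columns: salient loadings majority-positive
  for (j in seq_len(k)) {
    sal <- L[abs(L[, j]) >= 0.30, j]
    if (!length(sal)) sal <- L[, j]
    if (sum(sal) < 0) {
      L[, j] <- -L[, j]
      rotmat[, j] <- -rotmat[, j]
    }
  }

  eig_rot <- colSums(L^2)
  comm <- rowSums(L^2)

  if (is.null(domain_partition)) {
    grp <- score_variable_groups()
    domain_partition <- lapply(grp, function(v) {
      intersect(c(v, paste0(v, "_z")), colnames(zm))
    })
    domain_partition <- domain_partition[lengths(domain_partition) > 0]
  }
  assignment <- assign_domains(L, domain_partition)

  colnames(L) <- paste0("PC", seq_len(k))
  structure(list(loadings = L, rotmat = rotmat,
                 eigenvalues = stats::setNames(eig_rot, colnames(L)),
                 variance_explained = stats::setNames(eig_rot / p, colnames(L)),
                 total_variance_explained = sum(eig_rot) / p,
                 communalities = comm,
                 unrotated = L0,
                 eigenvalues_all = e$values,
                 domain_assignment = assignment, k = k, p = p),
            class = "factor_solution")
}

#' Assign rotated components to domains by mean absolute loading
#'
#' Evaluates every bijection between components and domains and keeps the one
#' maximizing the total mean |loading| of each component on its domain's
#' variables (sign-agnostic).
#' @keywords internal
assign_domains <- function(L, domain_partition) {
  k <- ncol(L)
  doms <- names(domain_partition)
  if (length(doms) != k) {
    ## fall back: label by strongest block per component, non-unique allowed
    lab <- vapply(seq_len(k), function(j) {
      m <- vapply(domain_partition, function(v) mean(abs(L[v, j])), numeric(1))
      names(which.max(m))
    }, character(1))
    return(stats::setNames(lab, paste0("PC", seq_len(k))))
  }
  strength <- sapply(domain_partition, function(v) {
    colMeans(abs(L[v, , drop = FALSE]))
  })  # k x domains
  perms <- all_permutations(k)
  best <- perms[[which.max(vapply(perms, function(pp) {
    sum(strength[cbind(seq_len(k), pp)])
  }, numeric(1)))]]
  stats::setNames(doms[best], paste0("PC", seq_len(k)))
}

#' @keywords internal
all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (sub in all_permutations(k - 1)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1]] <- c(i, rest[sub])
    }
  }
  out
}

#' @export
print.factor_solution <- function(x, digits = 3, threshold = 0.30, ...) {
  cat("<factor_solution>", x$p, "variables,", x$k, "components;",
      sprintf("%.1f%% total variance\n", 100 * x$total_variance_explained))
  disp <- formatC(round(x$loadings, digits), format = "f", digits = digits)
  disp[abs(x$loadings) < threshold] <- ""
  hdr <- sprintf("%s (%s)", colnames(x$loadings), x$domain_assignment)
  colnames(disp) <- hdr
  print(disp, quote = FALSE)
  cat("rotated eigenvalues:",
      paste(sprintf("%.2f", x$eigenvalues), collapse = ", "), "\n")
  invisible(x)
}

#' Anderson-Rubin factor scores
#'
#' The loading-weighted regression transform orthogonalized by the symmetric
#' inverse square root, guaranteeing exactly zero mean, unit variance and
#' zero pairwise correlation over the estimation sample.
#'
#' All 20 battery variables are error scores, so a component whose salient
#' loadings are positive indexes poor performance. With
#' `orient = "performance"` (the default) each score column is reflected, if
#' necessary, so that higher scores mean better performance — the orientation
#' the normative bottom-percentile deficit rule presupposes. `orient = "raw"`
#' keeps the rotated-loading orientation.
#'
#' @param z a `zscore_table` or matrix of adjusted scores (the estimation
#'   sample of the fitted solution).
#' @param solution a `factor_solution` fitted on the same variables.
#' @param orient `"performance"` (default) or `"raw"`.
#' @return data.frame of class `factor_scores`: `id` (if available) plus one
#'   standardized score column per domain (named by the domain assignment).
#' @export
anderson_rubin_scores <- function(z, solution,
                                  orient = c("performance", "raw")) {
  orient <- match.arg(orient)
  zm <- z_matrix(z)
  if (!identical(rownames(solution$loadings), colnames(zm))) {
    stop("solution was fitted on a different variable set")
  }
  S <- stats::cov(zm)
  B <- solve(stats::cor(zm), solution$loadings)
  M <- t(B) %*% S %*% B
  W <- B %*% inv_sqrt_sym(M)
  fs <- scale(zm, center = TRUE, scale = FALSE) %*% W
  colnames(fs) <- unname(solution$domain_assignment[colnames(solution$loadings)])
  if (orient == "performance") {
    ## mean adjusted error level over the component's salient variables;
    ## a performance-oriented score must correlate negatively with it
    for (j in seq_len(ncol(fs))) {
      lj <- solution$loadings[, j]
      sal <- names(lj)[abs(lj) >= 0.30]
      if (!length(sal)) sal <- names(sort(abs(lj), decreasing = TRUE))[1:3]
      err <- rowMeans(zm[, sal, drop = FALSE])
      if (stats::cor(fs[, j], err) > 0) fs[, j] <- -fs[, j]
    }
  }
  ids <- if (inherits(z, "zscore_table")) {
    z$z$id
  } else if (is.data.frame(z) && "id" %in% names(z)) {
    z$id
  } else {
    rownames(zm)
  }
  out <- data.frame(fs, stringsAsFactors = FALSE)
  if (!is.null(ids)) out <- cbind(data.frame(id = ids, stringsAsFactors = FALSE), out)
  class(out) <- c("factor_scores", "data.frame")
  out
}

#' Extract the score matrix from a `factor_scores` object
#' @keywords internal
score_matrix <- function(scores) {
  as.matrix(scores[, setdiff(names(scores), "id"), drop = FALSE])
}
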