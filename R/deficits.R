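## Age-bracketed normative deficit classification and Venn overlap analytics.

#' Estimate normative deficit thresholds from controls
#'
#' Per domain and age bracket, the cutoff is the empirical `q`-quantile of the
#' control factor scores, using the linear-interpolation order-statistic
#' convention (R quantile type 7) by default, or the nearest-rank (type 1)
#' alternative. For standard-normal scores and `q = 0.10` the cutoff converges
#' to -1.28 SD, i.e. roughly 1.3 SD below the control mean.
#'
#' @param scores `factor_scores` (or data.frame with `id` + domain columns).
#' @param participants participant table with `id` and `bracket` (controls are
#'   selected by `group == "TDC"` unless `controls` is given).
#' @param q deficit proportion in `[0, 1)`; default 0.10. `q = 0` yields a
#'   cutoff below every control score, so nobody is flagged.
#' @param controls optional logical vector marking the normative sample.
#' @param type quantile convention: 7 (interpolated, default) or 1
#'   (nearest rank).
#' @param min_n warn when a bracket has fewer controls than this.
#' @return data.frame of class `normative_thresholds`: domain, bracket,
#'   cutoff, n_controls.
#' @export
estimate_thresholds <- function(scores, participants, q = 0.10,
                                controls = NULL, type = 7, min_n = 20) {
  stopifnot(q >= 0, q < 1, type %in% c(1, 7))
  sm <- score_matrix(scores)
  stopifnot(all(scores$id == participants$id))
  if (is.null(controls)) controls <- participants$group == "TDC"
  brackets <- sort(unique(participants$bracket))
  doms <- colnames(sm)
  out <- expand.grid(domain = doms, bracket = brackets,
                     stringsAsFactors = FALSE)
  out$cutoff <- NA_real_
  out$n_controls <- NA_integer_
  for (b in brackets) {
    nb <- sum(controls & participants$bracket == b)
    if (nb == 0) {
      stop("no controls in bracket ", b,
           ": cannot estimate a normative threshold")
    }
    if (nb < min_n) {
      warning("bracket ", b, " has only ", nb, " controls (minimum ",
              min_n, ")")
    }
  }
  for (i in seq_len(nrow(out))) {
    sel <- controls & participants$bracket == out$bracket[i]
    nb <- sum(sel)
    out$cutoff[i] <- if (q == 0) -Inf else {
      unname(stats::quantile(sm[sel, out$domain[i]], q, type = type))
    }
    out$n_controls[i] <- nb
  }
  structure(out, class = c("normative_thresholds", "data.frame"),
            q = q, quantile_type = type)
}

#' Classify participants as deficient or intact per domain
#'
#' A domain flag is true iff the participant's factor score is less than or
#' equal to the cutoff of their age bracket for that domain (boundary
#' inclusive: "within the bottom 10%"). The rule applies identically to cases
#' and controls.
#'
#' @param scores `factor_scores`.
#' @param thresholds `normative_thresholds` from [estimate_thresholds()].
#' @param participants participant table with `id` and `bracket`.
#' @return data.frame of class `deficit_flags`: `id`, `rec_deficit`,
#'   `lrn_deficit`, `reg_deficit`, `n_deficits`, `venn_cell`.
#' @export
classify_deficits <- function(scores, thresholds, participants) {
  sm <- score_matrix(scores)
  stopifnot(all(scores$id == participants$id))
  if (anyNA(sm)) {
    drop_ids <- scores$id[apply(is.na(sm), 1, any)]
    message("excluding ", length(drop_ids),
            " participant(s) with missing scores: ",
            paste(utils::head(drop_ids, 5), collapse = ", "))
    keep <- !scores$id %in% drop_ids
    scores <- scores[keep, ]; participants <- participants[keep, ]
    sm <- score_matrix(scores)
  }
  missing_br <- setdiff(unique(participants$bracket),
                        unique(thresholds$bracket))
  if (length(missing_br)) {
    stop("no thresholds for bracket(s): ", paste(missing_br, collapse = ", "))
  }
  long <- domain_long()
  flags <- sapply(names(long), function(d) {
    col <- if (long[[d]] %in% colnames(sm)) long[[d]] else d
    th <- thresholds[thresholds$domain == col, ]
    cut <- th$cutoff[match(participants$bracket, th$bracket)]
    sm[, col] <= cut
  })
  colnames(flags) <- paste0(names(long), "_deficit")
  n_def <- as.integer(rowSums(flags))
  cell <- vapply(seq_len(nrow(flags)), function(i) {
    on <- names(long)[flags[i, ]]
    if (!length(on)) "none" else paste(on, collapse = "+")
  }, character(1))
  out <- data.frame(id = scores$id, flags, n_deficits = n_def,
                    venn_cell = cell, stringsAsFactors = FALSE)
  class(out) <- c("deficit_flags", "data.frame")
  out
}

#' Summarize deficit overlap (Venn cells) per group
#'
#' Per group: counts and proportions for the eight Venn cells, the three
#' domain margins, and the aggregates none / >=1 / exactly 1 / exactly 2 /
#' all 3. Also runs a Pearson chi-square test (no continuity correction) of
#' per-domain deficit frequency between the two groups.
#'
#' @param flags a `deficit_flags` table.
#' @param group character vector of group labels aligned with `flags`.
#' @return list of class `venn_summary`: `cells`, `margins`, `aggregates`
#'   (data.frames with counts and proportions per group), and `group_tests`.
#' @export
venn_summary <- function(flags, group) {
  stopifnot(nrow(flags) == length(group))
  groups <- unique(group)
  cells <- venn_cells()
  cell_tab <- lapply(groups, function(g) {
    n_g <- sum(group == g)
    cnt <- vapply(cells, function(cl) sum(flags$venn_cell[group == g] == cl),
                  integer(1))
    data.frame(group = g, cell = cells, count = cnt, prop = cnt / n_g,
               stringsAsFactors = FALSE)
  })
  cell_tab <- do.call(rbind, cell_tab)

  doms <- domain_names()
  margin_tab <- lapply(groups, function(g) {
    sel <- group == g
    cnt <- vapply(doms, function(d) sum(flags[[paste0(d, "_deficit")]][sel]),
                  integer(1))
    data.frame(group = g, domain = doms, count = cnt, prop = cnt / sum(sel),
               stringsAsFactors = FALSE)
  })
  margin_tab <- do.call(rbind, margin_tab)

  agg_tab <- lapply(groups, function(g) {
    nd <- flags$n_deficits[group == g]
    cnt <- c(none = sum(nd == 0), at_least_1 = sum(nd >= 1),
             exactly_1 = sum(nd == 1), exactly_2 = sum(nd == 2),
             all_3 = sum(nd == 3))
    data.frame(group = g, aggregate = names(cnt), count = as.integer(cnt),
               prop = as.numeric(cnt) / length(nd), stringsAsFactors = FALSE)
  })
  agg_tab <- do.call(rbind, agg_tab)

  tests <- NULL
  if (length(groups) == 2) {
    tests <- do.call(rbind, lapply(doms, function(d) {
      f <- flags[[paste0(d, "_deficit")]]
      tb <- table(factor(group, levels = groups), factor(f, levels = c(FALSE, TRUE)))
      ct <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
      data.frame(domain = d, chi2 = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(cells = cell_tab, margins = margin_tab, aggregates = agg_tab,
                 group_tests = tests),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("<venn_summary>\n")
  for (g in unique(x$cells$group)) {
    cc <- x$cells[x$cells$group == g, ]
    cat(sprintf("  %s: %s\n", g,
                paste(sprintf("%s %.1f%%", cc$cell, 100 * cc$prop),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Closed-form deficit-overlap expectations under independence
#'
#' If the `k` domain classifications were mutually independent, each flagging
#' a proportion `q`, the expected proportions follow the binomial law:
#' `P(>= 1) = 1 - (1 - q)^k` and `P(exactly m) = C(k, m) q^m (1 - q)^(k - m)`.
#' With `q = 0.10, k = 3`: 27.1% at least one, 0.1% all three.
#'
#' @param q per-domain deficit proportion in (0, 1).
#' @param k number of domains.
#' @return list with `p_at_least_1`, `p_exactly` (named vector over 0..k),
#'   `p_all`.
#' @export
independence_expectation <- function(q = 0.10, k = 3) {
  stopifnot(q > 0, q < 1, k >= 1)
  m <- 0:k
  pe <- stats::dbinom(m, k, q)
  list(p_at_least_1 = 1 - (1 - q)^k,
       p_exactly = stats::setNames(pe, paste0("m", m)),
       p_all = q^k)
}
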