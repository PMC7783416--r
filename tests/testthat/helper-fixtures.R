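# Shared fixtures, built in code.

small_config <- function(n_cd = 60L, n_tdc = 90L, seed = 42L, ...) {
  cohort_config(n_cd = n_cd, n_tdc = n_tdc, seed = seed, ...)
}

# A structurally valid hexagon log in which every scored morph is answered
# with its majority prototype and 50:50 morphs with the first prototype.
make_perfect_hexagon_log <- function() {
  pairs <- hexagon_pairs()
  grid <- expand.grid(block = 1:5, row = seq_len(nrow(pairs)),
                      morph = hexagon_morphs())
  resp <- ifelse(grid$morph >= 50, pairs$proto1[grid$row],
                 pairs$proto2[grid$row])
  structure(data.frame(block = grid$block, pair = pairs$pair[grid$row],
                       morph = grid$morph, response = resp,
                       stringsAsFactors = FALSE),
            class = c("hexagon_log", "data.frame"))
}

# Mislabel every scored (non-50:50) trial: answer with the minority prototype.
make_all_wrong_hexagon_log <- function() {
  log <- make_perfect_hexagon_log()
  pairs <- hexagon_pairs()
  idx <- match(log$pair, pairs$pair)
  minority <- ifelse(log$morph > 50, pairs$proto2[idx], pairs$proto1[idx])
  log$response[log$morph != 50] <- minority[log$morph != 50]
  log
}

# PA log with a fixed response pattern (default: always press).
make_pa_log <- function(respond = TRUE) {
  des <- pa_design()
  grid <- expand.grid(s = 1:8, block = 1:10)
  structure(data.frame(block = grid$block, stimulus = des$stimulus[grid$s],
                       valence = des$valence[grid$s],
                       magnitude = des$magnitude[grid$s],
                       responded = rep_len(respond, nrow(grid)),
                       bank = NA_real_, practice = grid$block == 1,
                       stringsAsFactors = FALSE),
            class = c("pa_log", "data.frame"))
}

# Go/nogo log with a given number of false alarms per pairing block.
make_gonogo_log <- function(fa = rep(0L, 6)) {
  prs <- gonogo_pairings()
  rows <- lapply(seq_along(prs), function(i) {
    data.frame(block = prs[i],
               trial_type = rep(c("go", "nogo"), c(35, 13)),
               responded = c(rep(TRUE, 35),
                             rep(c(TRUE, FALSE), c(fa[i], 13 - fa[i]))),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("gonogo_log", "data.frame"))
}

# Factor-score table + participant frame for deficit-classification tests.
make_score_frame <- function(scores_by_domain, bracket = NULL, group = NULL) {
  n <- nrow(scores_by_domain)
  fs <- data.frame(id = sprintf("X%03d", seq_len(n)), scores_by_domain,
                   stringsAsFactors = FALSE)
  class(fs) <- c("factor_scores", "data.frame")
  parts <- data.frame(id = fs$id,
                      group = group %||% rep("TDC", n),
                      bracket = bracket %||% rep("9-12", n),
                      stringsAsFactors = FALSE)
  list(scores = fs, participants = parts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
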