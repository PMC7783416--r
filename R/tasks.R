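## Trial-level task simulation and scoring.
##
## Per-participant simulators return full response logs (used for testing and
## small worked examples); `simulate_scores()` draws the 20 performance
## variables for a whole cohort from the identical per-trial model, vectorized
## across participants (the per-trial distributions are binomial sums /
## sequential learning chains, so score-level sampling is exact, not an
## approximation).

## ---------------------------------------------------------------------------
## Emotion Hexagon

#' Simulate an Emotion Hexagon response log
#'
#' One practice-free run: 5 blocks x 30 morphs (6 continua x 5 morph levels).
#' The probability of choosing the correct (majority-prototype) label is a
#' logistic function of recognition ability with a harder intercept for 70:30
#' than 90:10 morphs; errors fall mostly on the continuum's other prototype.
#' 50:50 morphs have no correct label: the response is drawn between the two
#' prototypes. A small timeout probability yields `"timeout"` responses.
#'
#' @param ability recognition ability, SD units (higher = better).
#' @param seed optional integer seed.
#' @param params hexagon parameter list (see [default_cohort_config()]).
#' @return data.frame of class `hexagon_log`: block, pair, morph, response.
#' @export
simulate_hexagon <- function(ability, seed = NULL,
                             params = default_cohort_config()$tasks$hexagon) {
  stopifnot(is.finite(ability))
  if (!is.null(seed)) set.seed(seed)
  pairs <- hexagon_pairs()
  grid <- expand.grid(block = 1:5, row = seq_len(nrow(pairs)),
                      morph = hexagon_morphs())
  grid <- grid[sample(nrow(grid)), ]  # random presentation order
  labels <- emotion_labels()
  resp <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p1 <- pairs$proto1[grid$row[i]]; p2 <- pairs$proto2[grid$row[i]]
    m <- grid$morph[i]
    if (stats::runif(1) < params$timeout_prob) {
      resp[i] <- "timeout"
      next
    }
    if (m == 50L) {
      resp[i] <- if (stats::runif(1) < 0.5) p1 else p2
      next
    }
    majority <- if (m > 50L) p1 else p2
    minority <- if (m > 50L) p2 else p1
    icpt <- if (m %in% c(90L, 10L)) params$icpt_90 else params$icpt_70
    if (stats::runif(1) < stats::plogis(icpt + params$slope * ability)) {
      resp[i] <- majority
    } else if (stats::runif(1) < params$other_proto_mass) {
      resp[i] <- minority
    } else {
      resp[i] <- sample(setdiff(labels, c(majority, minority)), 1)
    }
  }
  out <- data.frame(block = grid$block, pair = pairs$pair[grid$row],
                    morph = grid$morph, response = resp,
                    stringsAsFactors = FALSE)
  class(out) <- c("hexagon_log", "data.frame")
  out
}

#' Score an Emotion Hexagon log into six per-expression error counts
#'
#' For each of the six expressions the 20 scored trials are the 90:10 and
#' 70:30 morphs whose majority prototype is that expression, over both
#' continua containing it and all five blocks. 50:50 morphs are not scored;
#' timeouts count as incorrect.
#'
#' @param log a `hexagon_log`.
#' @return named integer vector of six error counts in `[0, 20]`.
#' @export
score_hexagon <- function(log) {
  validate_hexagon_log(log)
  pairs <- hexagon_pairs()
  idx <- match(log$pair, pairs$pair)
  majority <- ifelse(log$morph > 50L, pairs$proto1[idx], pairs$proto2[idx])
  scored <- log$morph != 50L
  err <- log$response != majority
  counts <- vapply(emotion_labels(), function(e) {
    sum(scored & majority == e & err)
  }, integer(1))
  names(counts) <- paste0("hex_", emotion_labels())
  counts
}

#' @keywords internal
validate_hexagon_log <- function(log) {
  req <- c("block", "pair", "morph", "response")
  if (!all(req %in% names(log))) stop("malformed hexagon log: missing columns")
  if (nrow(log) != 150) {
    stop("malformed hexagon log: expected 150 trials, got ", nrow(log))
  }
  tab <- table(log$block, log$pair, log$morph)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    stop("malformed hexagon log: block ", dimnames(tab)[[1]][bad[1]],
         ", pair ", dimnames(tab)[[2]][bad[2]],
         " does not show each morph exactly once")
  }
  invisible(TRUE)
}

#' @keywords internal
hexagon_error_probs <- function(ability, params) {
  pc90 <- (1 - params$timeout_prob) *
    stats::plogis(params$icpt_90 + params$slope * ability)
  pc70 <- (1 - params$timeout_prob) *
    stats::plogis(params$icpt_70 + params$slope * ability)
  list(err90 = 1 - pc90, err70 = 1 - pc70)
}

## ---------------------------------------------------------------------------
## Passive Avoidance Learning

#' Simulate a Passive Avoidance Learning log
#'
#' Eight novel stimuli (four rewarded, four punished; magnitudes 1, 700,
#' 1,400, 2,000 points) are each shown once per block over ten blocks, the
#' first being practice. The response propensity of each stimulus starts at a
#' participant-specific baseline (a response-bias draw) and is updated toward
#' respond/avoid only on trials with feedback (i.e., when the participant
#' responded), with learning rate `base_lr * plogis(lr_ability_slope *
#' ability) * magnitude_weight`. The running point bank (start 10,000) is
#' tracked in the log.
#'
#' @param ability learning ability, SD units.
#' @param seed optional integer seed.
#' @param params PA parameter list.
#' @return data.frame of class `pa_log`: block, stimulus, valence, magnitude,
#'   responded, bank, practice.
#' @export
simulate_pa <- function(ability, seed = NULL,
                        params = default_cohort_config()$tasks$pa) {
  stopifnot(is.finite(ability))
  if (!is.null(seed)) set.seed(seed)
  des <- pa_design()
  bias <- stats::rnorm(1, 0, params$bias_sd)
  p <- rep(stats::plogis(stats::qlogis(params$init_propensity) + bias), 8)
  rate <- params$base_lr * stats::plogis(params$lr_ability_slope * ability) *
    params$magnitude_weights[as.character(des$magnitude)]
  target <- as.numeric(des$valence == "reward")
  bank <- pa_start_bank()
  rows <- vector("list", pa_n_blocks() * 8)
  k <- 0
  for (b in seq_len(pa_n_blocks())) {
    for (s in sample(8)) {
      responded <- stats::runif(1) < p[s]
      if (responded) {
        bank <- bank + if (des$valence[s] == "reward") des$magnitude[s] else -des$magnitude[s]
        p[s] <- p[s] + rate[s] * (target[s] - p[s])
      }
      k <- k + 1
      rows[[k]] <- data.frame(block = b, stimulus = des$stimulus[s],
                              valence = des$valence[s],
                              magnitude = des$magnitude[s],
                              responded = responded, bank = bank,
                              practice = b == 1L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pa_log", "data.frame")
  out
}

#' Score a Passive Avoidance log into eight error rates (%)
#'
#' The practice block is excluded. Per punishment magnitude, the commission
#' (avoidance-error) rate is the percentage of its nine scored trials with a
#' response; per reward magnitude, the omission rate is the percentage of its
#' nine scored trials without a response.
#'
#' @param log a `pa_log`.
#' @return named numeric vector of eight rates in `[0, 100]` (losing then
#'   gaining, by magnitude).
#' @export
score_pa <- function(log) {
  validate_pa_log(log)
  scored <- log[log$block != 1L, ]
  out <- numeric(8)
  nm <- character(8)
  mags <- c(1L, 700L, 1400L, 2000L)
  for (i in seq_along(mags)) {
    pun <- scored$valence == "punishment" & scored$magnitude == mags[i]
    rew <- scored$valence == "reward" & scored$magnitude == mags[i]
    out[i] <- 100 * mean(scored$responded[pun])
    out[i + 4] <- 100 * mean(!scored$responded[rew])
    nm[i] <- paste0("pa_lose_", mags[i])
    nm[i + 4] <- paste0("pa_gain_", mags[i])
  }
  stats::setNames(out, nm)
}

#' @keywords internal
validate_pa_log <- function(log) {
  req <- c("block", "stimulus", "valence", "magnitude", "responded")
  if (!all(req %in% names(log))) stop("malformed PA log: missing columns")
  if (nrow(log) != pa_n_blocks() * 8) {
    stop("malformed PA log: expected ", pa_n_blocks() * 8, " trials, got ",
         nrow(log))
  }
  tab <- table(log$block, log$stimulus)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    stop("malformed PA log: block ", dimnames(tab)[[1]][bad[1]],
         " does not show stimulus ", dimnames(tab)[[2]][bad[2]],
         " exactly once")
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Emotional Go/Nogo

#' Simulate an Emotional Go/Nogo response log
#'
#' Six go-nogo pairing blocks; each block has 35 go and 13 nogo trials in
#' random order. The probability of a false alarm (responding on nogo) is a
#' logistic function of regulation ability with a per-pairing emotional
#' interference offset; go trials are answered with a constant hit rate (go
#' omissions are logged but not analyzed).
#'
#' @param ability regulation ability, SD units.
#' @param seed optional integer seed.
#' @param params go/nogo parameter list.
#' @return data.frame of class `gonogo_log`: block (pairing), trial_type,
#'   responded.
#' @export
simulate_gonogo <- function(ability, seed = NULL,
                            params = default_cohort_config()$tasks$gonogo) {
  stopifnot(is.finite(ability))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(gonogo_pairings(), function(pr) {
    p_fa <- stats::plogis(params$fa_icpt + params$pair_offsets[[pr]] -
                            params$fa_ability_slope * ability)
    tt <- sample(rep(c("go", "nogo"), c(gonogo_n_go(), gonogo_n_nogo())))
    responded <- ifelse(tt == "go",
                        stats::runif(length(tt)) < params$go_hit,
                        stats::runif(length(tt)) < p_fa)
    data.frame(block = pr, trial_type = tt, responded = responded,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gonogo_log", "data.frame")
  out
}

#' Score a Go/Nogo log into six false-alarm rates (%)
#'
#' Per pairing block, the false-alarm rate is 100 x (nogo responses) / 13.
#'
#' @param log a `gonogo_log`.
#' @return named numeric vector of six rates in `[0, 100]`.
#' @export
score_gonogo <- function(log) {
  validate_gonogo_log(log)
  out <- vapply(gonogo_pairings(), function(pr) {
    sel <- log$block == pr & log$trial_type == "nogo"
    100 * sum(log$responded[sel]) / gonogo_n_nogo()
  }, numeric(1))
  names(out) <- paste0("gng_", gsub("-", "_", gonogo_pairings()))
  out
}

#' @keywords internal
validate_gonogo_log <- function(log) {
  req <- c("block", "trial_type", "responded")
  if (!all(req %in% names(log))) stop("malformed go/nogo log: missing columns")
  for (pr in gonogo_pairings()) {
    sel <- log$block == pr
    if (sum(log$trial_type[sel] == "go") != gonogo_n_go() ||
        sum(log$trial_type[sel] == "nogo") != gonogo_n_nogo()) {
      stop("malformed go/nogo log: block ", pr, " must have ",
           gonogo_n_go(), " go and ", gonogo_n_nogo(), " nogo trials")
    }
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Batch score simulation for whole cohorts

#' Simulate the 20-variable score table for a cohort
#'
#' Draws every participant's scores from the per-trial task models, vectorized
#' across participants: hexagon error counts are binomial sums over the 10
#' scored 90:10 and 10 scored 70:30 trials per expression; go/nogo false-alarm
#' counts are binomial over 13 nogo trials per pairing; passive-avoidance
#' propensity chains are iterated trial by trial across all participants at
#' once. Reproducible from `seed`.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param seed optional seed; defaults to a substream of the cohort's seed.
#' @return data.frame (ScoreTable): `id` plus the 20 performance variables in
#'   the order of [score_variable_groups()] (regulation, learning,
#'   recognition).
#' @export
simulate_scores <- function(cohort, seed = NULL) {
  cfg <- cohort$config
  set.seed(seed %||% derive_seed(cfg$seed, "tasks"))
  n <- nrow(cohort$participants)
  lat <- cohort$latent

  ## go/nogo
  gp <- cfg$tasks$gonogo
  gng <- sapply(gonogo_pairings(), function(pr) {
    p_fa <- stats::plogis(gp$fa_icpt + gp$pair_offsets[[pr]] -
                            gp$fa_ability_slope * lat$ability_reg)
    100 * stats::rbinom(n, gonogo_n_nogo(), p_fa) / gonogo_n_nogo()
  })
  colnames(gng) <- paste0("gng_", gsub("-", "_", gonogo_pairings()))

  ## passive avoidance
  pa <- simulate_pa_batch(lat$ability_lrn, cfg$tasks$pa)

  ## hexagon
  hp <- cfg$tasks$hexagon
  ep <- hexagon_error_probs(lat$ability_rec, hp)
  hx <- sapply(emotion_labels(), function(e) {
    stats::rbinom(n, 10, ep$err90) + stats::rbinom(n, 10, ep$err70)
  })
  colnames(hx) <- paste0("hex_", emotion_labels())

  out <- data.frame(id = cohort$participants$id, gng, pa, hx,
                    stringsAsFactors = FALSE)
  out[, c("id", score_variable_names())]
}

#' Vectorized passive-avoidance chain across participants
#' @keywords internal
simulate_pa_batch <- function(ability, params) {
  n <- length(ability)
  des <- pa_design()
  lr_ab <- params$base_lr * stats::plogis(params$lr_ability_slope * ability)
  bias <- stats::rnorm(n, 0, params$bias_sd)
  p0 <- stats::plogis(stats::qlogis(params$init_propensity) + bias)
  out <- matrix(NA_real_, n, 8)
  for (s in seq_len(8)) {
    rate <- lr_ab * params$magnitude_weights[[as.character(des$magnitude[s])]]
    target <- as.numeric(des$valence[s] == "reward")
    p <- p0
    responses <- 0L
    for (b in seq_len(pa_n_blocks())) {
      responded <- stats::runif(n) < p
      if (b > 1L) responses <- responses + responded
      p <- ifelse(responded, p + rate * (target - p), p)
    }
    out[, s] <- if (des$valence[s] == "punishment") {
      100 * responses / (pa_n_blocks() - 1)
    } else {
      100 * ((pa_n_blocks() - 1) - responses) / (pa_n_blocks() - 1)
    }
  }
  colnames(out) <- ifelse(des$valence == "punishment",
                          paste0("pa_lose_", des$magnitude),
                          paste0("pa_gain_", des$magnitude))
  out[, c(paste0("pa_lose_", c(1, 700, 1400, 2000)),
          paste0("pa_gain_", c(1, 700, 1400, 2000)))]
}

#' Validate a ScoreTable
#' @param scores data.frame with `id` and the 20 performance variables.
#' @param check_ranges verify raw-score ranges (skip for already-adjusted
#'   tables).
#' @keywords internal
validate_score_table <- function(scores, check_ranges = TRUE) {
  miss <- setdiff(c("id", score_variable_names()), names(scores))
  if (length(miss)) {
    stop("score table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!check_ranges) return(invisible(TRUE))
  hex <- as.matrix(scores[, score_variable_groups()$recognition])
  if (any(hex < 0 | hex > 20)) stop("hexagon scores must lie in [0, 20]")
  rates <- as.matrix(scores[, c(score_variable_groups()$regulation,
                                score_variable_groups()$learning)])
  if (any(rates < 0 | rates > 100)) stop("error rates must lie in [0, 100]")
  invisible(TRUE)
}
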