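#' @keywords internal
"_PACKAGE"

## Task design constants -----------------------------------------------------

#' Emotion Hexagon design
#'
#' Six morphed-expression continua, each sampled at five mixture levels.
#' `morph` is the percentage of the first prototype in the morph
#' (90 means 90:10 toward `proto1`). The 50:50 morph is presented but never
#' scored. Each of the five test blocks shows all 30 morphs once.
#' @keywords internal
hexagon_pairs <- function() {
  data.frame(
    pair   = c("happy-surprised", "surprised-fearful", "fearful-sad",
               "sad-disgusted", "disgusted-angry", "angry-happy"),
    proto1 = c("happy", "surprised", "fearful", "sad", "disgusted", "angry"),
    proto2 = c("surprised", "fearful", "sad", "disgusted", "angry", "happy"),
    stringsAsFactors = FALSE
  )
}

#' Morph levels: percentage of the first prototype in the blend.
#' @keywords internal
hexagon_morphs <- function() c(90L, 70L, 50L, 30L, 10L)

#' Emotion labels used in the Hexagon task
#' @keywords internal
emotion_labels <- function() {
  c("happy", "surprised", "fearful", "sad", "disgusted", "angry")
}

#' Passive Avoidance design: 8 stimuli (4 reward, 4 punishment) crossed with
#' point magnitudes; one practice block plus nine scored blocks; the bank
#' starts at 10,000 points.
#' @keywords internal
pa_design <- function() {
  data.frame(
    stimulus  = paste0("S", 1:8),
    valence   = rep(c("reward", "punishment"), each = 4),
    magnitude = rep(c(1L, 700L, 1400L, 2000L), 2),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
pa_n_blocks <- function() 10L

#' @keywords internal
pa_start_bank <- function() 10000L

#' Emotional Go/Nogo design: six go-nogo pairing blocks, each with 35 go and
#' 13 nogo trials.
#' @keywords internal
gonogo_pairings <- function() {
  c("neutral-happy", "neutral-fearful", "happy-neutral",
    "fearful-neutral", "happy-fearful", "fearful-happy")
}

#' @keywords internal
gonogo_n_go <- function() 35L

#' @keywords internal
gonogo_n_nogo <- function() 13L

## Score table layout ---------------------------------------------------------

#' Names of the 20 performance variables, grouped by task
#'
#' Six go/nogo false-alarm rates (%), eight passive-avoidance error rates (%)
#' (commission per punishment magnitude, omission per reward magnitude), and
#' six per-expression recognition error counts (0-20).
#' @return Named list with elements `regulation`, `learning`, `recognition`,
#'   each a character vector of column names.
#' @export
score_variable_groups <- function() {
  list(
    regulation = paste0("gng_", gsub("-", "_", gonogo_pairings())),
    learning = c(paste0("pa_lose_", c(1, 700, 1400, 2000)),
                 paste0("pa_gain_", c(1, 700, 1400, 2000))),
    recognition = paste0("hex_", c("happy", "surprised", "fearful",
                                   "sad", "disgusted", "angry"))
  )
}

#' @keywords internal
score_variable_names <- function() unlist(score_variable_groups(), use.names = FALSE)

## Venn cells ------------------------------------------------------------------

#' The eight deficit-class (Venn cell) labels
#'
#' Cells are subsets of \{rec, lrn, reg\}: `none`, single domains, pairwise
#' overlaps, and the pervasive `rec+lrn+reg` cell.
#' @export
venn_cells <- function() {
  c("none", "rec", "lrn", "reg", "rec+lrn", "rec+reg", "lrn+reg", "rec+lrn+reg")
}

#' @keywords internal
domain_names <- function() c("rec", "lrn", "reg")

#' Long domain labels keyed by short codes
#' @keywords internal
domain_long <- function() {
  c(rec = "recognition", lrn = "learning", reg = "regulation")
}

#' Membership matrix of Venn cells (8 cells x 3 domains, logical)
#' @keywords internal
venn_membership <- function() {
  cells <- venn_cells()
  m <- sapply(domain_names(), function(d) {
    vapply(strsplit(cells, "+", fixed = TRUE),
           function(parts) d %in% parts, logical(1))
  })
  rownames(m) <- cells
  m
}

## Questionnaire item maps ------------------------------------------------------

#' YPI callous-unemotional subscale item map
#'
#' The YPI has 50 items answered 1-4. The three CU-trait subscales
#' (remorselessness, unemotionality, callousness) have five items each; this
#' package fixes a documented 3 x 5 map that is the single source of truth
#' for both the item generator and the scorer. A trait is endorsed when at
#' least one of its items is answered 4 ("applies very well"); the LPE proxy
#' requires two or more endorsed traits.
#'
#' @return data.frame with columns `item` (1-50 index) and `subscale`.
#' @export
ypi_cu_map <- function() {
  data.frame(
    item = c(4L, 12L, 20L, 28L, 36L,
             8L, 16L, 24L, 32L, 40L,
             2L, 10L, 18L, 26L, 34L),
    subscale = rep(c("remorselessness", "unemotionality", "callousness"),
                   each = 5),
    stringsAsFactors = FALSE
  )
}

#' RPQ item map: 11 reactive and 12 proactive aggression items (0-2 each)
#' @return data.frame with columns `item` (1-23) and `subscale`.
#' @export
rpq_map <- function() {
  data.frame(
    item = 1:23,
    subscale = rep(c("reactive", "proactive"), c(11, 12)),
    stringsAsFactors = FALSE
  )
}
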