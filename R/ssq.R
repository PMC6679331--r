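#' Simulator Sickness Questionnaire item table
#'
#' The 16 SSQ symptoms with their subscale memberships in the standard
#' instrument (Kennedy et al., 1993). Each subscale (nausea, oculomotor,
#' disorientation) sums exactly 7 item ratings; some symptoms load on
#' two subscales.
#'
#' @return A tibble with columns `item`, `symptom`, `nausea`,
#'   `oculomotor`, `disorientation` (logical memberships).
#' @export
ssq_items <- function() {
  tibble::tribble(
    ~item, ~symptom,                   ~nausea, ~oculomotor, ~disorientation,
    1L, "General discomfort",           TRUE,  TRUE,  FALSE,
    2L, "Fatigue",                      FALSE, TRUE,  FALSE,
    3L, "Headache",                     FALSE, TRUE,  FALSE,
    4L, "Eye strain",                   FALSE, TRUE,  FALSE,
    5L, "Difficulty focusing",          FALSE, TRUE,  TRUE,
    6L, "Increased salivation",         TRUE,  FALSE, FALSE,
    7L, "Sweating",                     TRUE,  FALSE, FALSE,
    8L, "Nausea",                       TRUE,  FALSE, TRUE,
    9L, "Difficulty concentrating",     TRUE,  TRUE,  FALSE,
    10L, "Fullness of head",            FALSE, FALSE, TRUE,
    11L, "Blurred vision",              FALSE, TRUE,  TRUE,
    12L, "Dizzy (eyes open)",           FALSE, FALSE, TRUE,
    13L, "Dizzy (eyes closed)",         FALSE, FALSE, TRUE,
    14L, "Vertigo",                     FALSE, FALSE, TRUE,
    15L, "Stomach awareness",           TRUE,  FALSE, FALSE,
    16L, "Burping",                     TRUE,  FALSE, FALSE
  )
}

ssq_weights <- c(nausea = 9.54, oculomotor = 7.58,
                 disorientation = 13.92, total = 3.74)

#' Score Simulator Sickness Questionnaire responses
#'
#' Each of the 16 symptoms is rated on a 4-point scale (0 = none,
#' 1 = slight/mild, 2 = moderate, 3 = severe). Subscale raw scores are
#' the sums of the 7 member-item ratings; the reported scores apply the
#' standard weights: nausea = raw_N x 9.54, oculomotor = raw_O x 7.58,
#' disorientation = raw_D x 13.92, total = (raw_N + raw_O + raw_D) x
#' 3.74. The total therefore ranges from 0 to 235.62 and the nausea
#' sub-score from 0 to 200.34.
#'
#' @param responses A data frame with columns `item_1` ... `item_16`
#'   (integer ratings in 0-3); any other columns (e.g. `subject`,
#'   `stage`) are carried through.
#' @return The input tibble with item columns replaced by `nausea`,
#'   `oculomotor`, `disorientation` and `total` score columns.
#' @export
#' @examples
#' score_ssq(data.frame(t(setNames(rep(1, 16), paste0("item_", 1:16)))))
score_ssq <- function(responses) {
  responses <- tibble::as_tibble(responses)
  item_cols <- paste0("item_", 1:16)
  missing <- setdiff(item_cols, names(responses))
  if (length(missing) > 0) {
    stop("validation error: missing item column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ratings <- as.matrix(responses[item_cols])
  if (any(is.na(ratings)) || any(ratings != round(ratings)) ||
      any(ratings < 0) || any(ratings > 3)) {
    stop("validation error: ratings must be integers in 0..3", call. = FALSE)
  }
  items <- ssq_items()
  raw_n <- ratings %*% items$nausea
  raw_o <- ratings %*% items$oculomotor
  raw_d <- ratings %*% items$disorientation
  out <- responses[setdiff(names(responses), item_cols)]
  out$nausea <- as.numeric(raw_n * ssq_weights[["nausea"]])
  out$oculomotor <- as.numeric(raw_o * ssq_weights[["oculomotor"]])
  out$disorientation <- as.numeric(raw_d * ssq_weights[["disorientation"]])
  out$total <- as.numeric((raw_n + raw_o + raw_d) * ssq_weights[["total"]])
  out
}

#' Build a uniform SSQ response row
#'
#' Convenience constructor for a response rating every symptom at the
#' same level, e.g. to reproduce the scale anchors (all-severe gives
#' total 235.62, nausea 200.34).
#'
#' @param rating Integer in 0-3 applied to all 16 items.
#' @param ... Extra columns (e.g. `subject`, `stage`).
#' @return A one-row tibble with `item_1` ... `item_16`.
#' @export
uniform_ssq_response <- function(rating, ...) {
  stopifnot(length(rating) == 1, rating %in% 0:3)
  out <- tibble::as_tibble(as.list(stats::setNames(rep(as.integer(rating), 16),
                                                   paste0("item_", 1:16))))
  extra <- list(...)
  if (length(extra) > 0) out <- dplyr::bind_cols(tibble::as_tibble(extra), out)
  out
}
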