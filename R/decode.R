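#' Nearest concept by cosine similarity
#'
#' Returns the concept whose hierarchy-encoded vector has the highest cosine
#' similarity with a model output vector. Ties break toward the
#' lexicographically smallest concept id. A zero output vector carries no
#' direction, so the (lexicographically first) root-most concept of the
#' space is returned as a designated fallback with confidence 0 and a
#' `fallback` flag.
#'
#' @param output Numeric vector of length N.
#' @param space A `cn_concept_space`.
#' @param fallback Concept id used for zero outputs; default the first
#'   concept id in lexicographic order.
#' @return List with `concept_id`, `cosine`, and `fallback` (logical).
#' @export
nearest_concept <- function(output, space, fallback = NULL) {
  if (length(output) != length(space$ids)) {
    stop("output dimension ", length(output), " != concept-space size ",
         length(space$ids))
  }
  onorm <- sqrt(sum(output^2))
  if (onorm == 0) {
    fb <- if (is.null(fallback)) sort(space$ids)[[1L]] else fallback
    return(list(concept_id = fb, cosine = 0, fallback = TRUE))
  }
  cos <- as.numeric(space$M %*% output) / (space$row_norms * onorm)
  best <- max(cos)
  cand <- space$ids[cos >= best - 1e-12]
  list(concept_id = sort(cand)[[1L]], cosine = best, fallback = FALSE)
}

#' Decode a matrix of output vectors into a prediction table
#'
#' Vectorized wrapper around [nearest_concept()].
#'
#' @param outputs `n x N` matrix (rownames used as mention ids when present).
#' @param space A `cn_concept_space`.
#' @param source Label recorded in the `source` column (`"slfnn"`, `"cnn"`,
#'   `"cnorm"`, ...).
#' @return Data frame: `mention_id`, `concept_id`, `confidence` (cosine),
#'   `source`, `fallback`.
#' @export
decode_predictions <- function(outputs, space, source = "model") {
  n <- nrow(outputs)
  ids <- rownames(outputs)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  rows <- lapply(seq_len(n), function(i) nearest_concept(outputs[i, ], space))
  data.frame(
    mention_id = ids,
    concept_id = vapply(rows, `[[`, character(1), "concept_id"),
    confidence = vapply(rows, `[[`, numeric(1), "cosine"),
    source = source,
    fallback = vapply(rows, `[[`, logical(1), "fallback"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Sieve combination of two prediction sets
#'
#' For each mention, keeps the primary model's prediction when its cosine
#' confidence is strictly above the threshold, and otherwise falls back to
#' the second model's prediction. The shallow CNN is conventionally the
#' primary component and the SLFNN the fallback, with a threshold of 0.4.
#'
#' @param primary,fallback Prediction data frames over the same mention ids
#'   (as produced by [decode_predictions()]).
#' @param threshold Confidence threshold; kept iff `confidence > threshold`.
#' @return Combined prediction data frame with `source = "sieve"` and
#'   attributes `kept` / `replaced` (counts).
#' @export
sieve_combine <- function(primary, fallback, threshold = 0.4) {
  if (!setequal(primary$mention_id, fallback$mention_id) ||
      nrow(primary) != nrow(fallback)) {
    only_p <- setdiff(primary$mention_id, fallback$mention_id)
    only_f <- setdiff(fallback$mention_id, primary$mention_id)
    stop("primary and fallback predictions cover different mentions: ",
         paste(utils::head(c(only_p, only_f), 5L), collapse = ", "))
  }
  fb <- fallback[match(primary$mention_id, fallback$mention_id), ]
  keep <- primary$confidence > threshold
  out <- primary
  out[!keep, ] <- fb[!keep, ]
  out$source <- "sieve"
  attr(out, "kept") <- sum(keep)
  attr(out, "replaced") <- sum(!keep)
  out
}
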