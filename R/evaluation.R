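#' Strict exact-match score for one mention
#'
#' 1 if the predicted concept equals a reference concept, 0 otherwise. When
#' a mention carries several reference concepts, membership in the reference
#' set counts as a match (the single-reference definition generalized by set
#' membership).
#'
#' @param predicted Predicted concept id.
#' @param gold Character vector of reference concept ids (non-empty).
#' @param ontology A `cn_ontology` used to resolve ids (alt_ids allowed).
#' @return 0 or 1.
#' @export
strict_score <- function(predicted, gold, ontology) {
  p <- resolve_concept(ontology, predicted)
  g <- vapply(gold, resolve_concept, character(1), ontology = ontology)
  as.numeric(p %in% g)
}

#' Wang similarity score for one mention
#'
#' Maximum Wang similarity between the predicted concept and any reference
#' concept; equals 1 exactly when the strict score is 1.
#'
#' @inheritParams strict_score
#' @param edge_contribution Per-edge S-value multiplier, see
#'   [wang_similarity()].
#' @return Similarity in (0, 1].
#' @export
wang_score <- function(predicted, gold, ontology, edge_contribution = 0.8) {
  p <- resolve_concept(ontology, predicted)
  max(vapply(gold, function(g) {
    wang_similarity(ontology, p, resolve_concept(ontology, g), edge_contribution)
  }, numeric(1)))
}

#' Evaluate a prediction set against gold normalizations
#'
#' Computes per-mention strict and Wang scores, their means over mentions,
#' and an error typology: `correct` (strict match), `overgeneralization`
#' (predicted a proper ancestor of the single reference),
#' `overspecification` (a proper descendant), `partial` (multi-reference
#' mention where the prediction is an ancestor or descendant of at least one
#' reference without matching any exactly), `off_path` (anything else).
#' For single-reference overshoots the is_a distance between prediction and
#' reference is recorded.
#'
#' @param predictions Data frame with `mention_id`, `concept_id` (one row
#'   per mention).
#' @param gold Data frame with `mention_id`, `concept_id` (several rows per
#'   mention allowed for multi-concept references).
#' @param ontology A `cn_ontology`.
#' @param edge_contribution Wang per-edge multiplier.
#' @return A `cn_eval_report`: list with `n_mentions`, `strict_mean`,
#'   `wang_mean`, `per_mention` data frame (mention_id, strict, wang,
#'   predicted, gold, typology, distance) and `error_typology` counts.
#' @export
evaluate_predictions <- function(predictions, gold, ontology,
                                 edge_contribution = 0.8) {
  gold_sets <- split(gold$concept_id, gold$mention_id)
  missing <- setdiff(names(gold_sets), predictions$mention_id)
  if (length(missing)) {
    stop("no prediction for gold mention(s): ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  mids <- names(gold_sets)
  pred_map <- stats::setNames(predictions$concept_id, predictions$mention_id)

  rows <- lapply(mids, function(mid) {
    g <- unique(vapply(gold_sets[[mid]], resolve_concept, character(1),
                       ontology = ontology))
    p <- resolve_concept(ontology, pred_map[[mid]])
    s <- as.numeric(p %in% g)
    w <- max(vapply(g, function(gi) {
      wang_similarity(ontology, p, gi, edge_contribution)
    }, numeric(1)))

    anc_of_p <- ancestor_distances(ontology, p)     # p up to its ancestors
    up <- vapply(g, function(gi) {                  # p ancestor of gi?
      d <- ancestor_distances(ontology, gi)
      if (p %in% names(d)) d[[p]] else NA_integer_
    }, integer(1))
    down <- vapply(g, function(gi) {                # p descendant of gi?
      if (gi %in% names(anc_of_p)) anc_of_p[[gi]] else NA_integer_
    }, integer(1))

    if (s == 1) {
      typ <- "correct"; dist <- 0L
    } else if (length(g) > 1L && any(!is.na(up) | !is.na(down))) {
      typ <- "partial"; dist <- min(c(up, down), na.rm = TRUE)
    } else if (any(!is.na(up))) {
      typ <- "overgeneralization"; dist <- min(up, na.rm = TRUE)
    } else if (any(!is.na(down))) {
      typ <- "overspecification"; dist <- min(down, na.rm = TRUE)
    } else {
      typ <- "off_path"; dist <- NA_integer_
    }
    list(mention_id = mid, strict = s, wang = w, predicted = p,
         gold = paste(g, collapse = ","), typology = typ, distance = dist)
  })

  per_mention <- data.frame(
    mention_id = vapply(rows, `[[`, character(1), "mention_id"),
    strict = vapply(rows, `[[`, numeric(1), "strict"),
    wang = vapply(rows, `[[`, numeric(1), "wang"),
    predicted = vapply(rows, `[[`, character(1), "predicted"),
    gold = vapply(rows, `[[`, character(1), "gold"),
    typology = vapply(rows, `[[`, character(1), "typology"),
    distance = vapply(rows, `[[`, integer(1), "distance"),
    stringsAsFactors = FALSE)

  levels <- c("correct", "overgeneralization", "overspecification",
              "partial", "off_path")
  typology <- table(factor(per_mention$typology, levels = levels))

  structure(list(n_mentions = nrow(per_mention),
                 strict_mean = mean(per_mention$strict),
                 wang_mean = mean(per_mention$wang),
                 per_mention = per_mention,
                 error_typology = as.list(typology)),
            class = "cn_eval_report")
}

#' @export
print.cn_eval_report <- function(x, ...) {
  cat(sprintf("cn_eval_report: %d mentions | strict %.3f | Wang %.3f\n",
              x$n_mentions, x$strict_mean, x$wang_mean))
  t <- unlist(x$error_typology)
  cat(paste(sprintf("  %s: %d", names(t), t), collapse = "\n"), "\n")
  invisible(x)
}

#' Write an evaluation report as JSON plus a per-mention TSV
#'
#' @param report A `cn_eval_report`.
#' @param json_path,tsv_path Output paths (`NULL` skips that output).
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    summary <- list(n_mentions = report$n_mentions,
                    strict_mean = report$strict_mean,
                    wang_mean = report$wang_mean,
                    error_typology = report$error_typology)
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA),
               json_path, useBytes = TRUE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(report$per_mention, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
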