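#' Read one BioNLP-ST standoff document
#'
#' Parses the entity (`.a1`, `T` lines) and normalization (`.a2`, `N` lines
#' with a `Referent:` attribute) annotations of a single document.
#' Discontinuous spans (`start end;start end`) are supported; a mention's
#' surface is the document text at its spans, fragments joined by single
#' spaces. Offsets are 0-based, end-exclusive character offsets into the
#' UTF-8 text. A mention may receive several referent concepts through
#' repeated `N` lines.
#'
#' @param txt Document text (single string).
#' @param a1 Character vector of entity lines
#'   (`Tn<TAB>Type start end[;start end]*<TAB>surface`).
#' @param a2 Character vector of normalization lines
#'   (`Nn<TAB>Resource Annotation:Tk Referent:CONCEPT`).
#' @param doc_id Document identifier recorded on every row.
#' @param types Entity types to keep (`NULL` = all).
#' @return List with `mentions` (data.frame: doc_id, mention_id, type,
#'   surface, and a `spans` list-column of 2-column start/end matrices) and
#'   `gold` (data.frame: doc_id, mention_id, concept_id — one row per
#'   (mention, referent) pair).
#' @export
read_standoff <- function(txt, a1, a2 = character(0), doc_id = "doc", types = NULL) {
  a1 <- a1[nzchar(trimws(a1))]
  a2 <- a2[nzchar(trimws(a2))]

  ment <- list()
  for (line in a1) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("malformed a1 line (need >= 2 tab fields): ", line)
    mid <- f[[1L]]
    if (!grepl("^T", mid)) next  # only entity annotations
    head_parts <- strsplit(f[[2L]], " ", fixed = TRUE)[[1L]]
    type <- head_parts[[1L]]
    span_str <- paste(head_parts[-1L], collapse = " ")
    frags <- strsplit(span_str, ";", fixed = TRUE)[[1L]]
    spans <- t(vapply(frags, function(fr) {
      se <- suppressWarnings(as.integer(strsplit(trimws(fr), " ")[[1L]]))
      if (length(se) != 2L || anyNA(se) || se[[1L]] >= se[[2L]]) {
        stop("malformed offsets in a1 line: ", line)
      }
      se
    }, integer(2)))
    dimnames(spans) <- list(NULL, c("start", "end"))
    if (max(spans[, "end"]) > nchar(txt)) {
      stop("offset beyond document end in a1 line: ", line)
    }
    surface <- paste(vapply(seq_len(nrow(spans)), function(k) {
      substr(txt, spans[k, "start"] + 1L, spans[k, "end"])
    }, character(1)), collapse = " ")
    if (length(f) >= 3L && !identical(f[[3L]], surface)) {
      warning("a1 surface differs from document text for ", mid,
              " (using document text)")
    }
    ment[[mid]] <- list(mention_id = mid, type = type, spans = spans,
                        surface = surface)
  }

  gold_rows <- list()
  for (line in a2) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L || !grepl("^N", f[[1L]])) next
    ann <- regmatches(f[[2L]], regexpr("Annotation:\\S+", f[[2L]]))
    ref <- regmatches(f[[2L]], regexpr("Referent:\\S+", f[[2L]]))
    if (length(ann) == 0L || length(ref) == 0L) {
      stop("malformed a2 line (need Annotation: and Referent:): ", line)
    }
    tid <- sub("^Annotation:", "", ann)
    cid <- sub("^Referent:", "", ref)
    if (is.null(ment[[tid]])) {
      stop("a2 line refers to unknown entity ", tid, ": ", line)
    }
    gold_rows[[length(gold_rows) + 1L]] <- c(tid, cid)
  }

  if (!is.null(types)) ment <- Filter(function(m) m$type %in% types, ment)

  mentions <- if (length(ment)) {
    data.frame(doc_id = doc_id,
               mention_id = vapply(ment, `[[`, character(1), "mention_id"),
               type = vapply(ment, `[[`, character(1), "type"),
               surface = vapply(ment, `[[`, character(1), "surface"),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(doc_id = character(0), mention_id = character(0),
               type = character(0), surface = character(0))
  }
  mentions$spans <- unname(lapply(ment, `[[`, "spans"))

  keep <- vapply(gold_rows, function(g) g[[1L]] %in% mentions$mention_id, TRUE)
  gold_rows <- gold_rows[keep]
  gold <- if (length(gold_rows)) {
    g <- do.call(rbind, gold_rows)
    data.frame(doc_id = doc_id, mention_id = g[, 1L], concept_id = g[, 2L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(doc_id = character(0), mention_id = character(0),
               concept_id = character(0))
  }
  gold <- unique(gold)
  list(mentions = mentions, gold = gold)
}

#' Read a directory of standoff documents
#'
#' Expects `<name>.txt` files with sibling `<name>.a1` and (optionally)
#' `<name>.a2` files.
#'
#' @param dir Directory path.
#' @param types Entity types to keep (`NULL` = all).
#' @return List with row-bound `mentions` and `gold` data frames (mention
#'   keys are unique within a document only; pair with `doc_id`).
#' @export
read_corpus_dir <- function(dir, types = NULL) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(txts) == 0L) {
    return(list(mentions = data.frame(doc_id = character(0),
                                      mention_id = character(0),
                                      type = character(0),
                                      surface = character(0)),
                gold = data.frame(doc_id = character(0),
                                  mention_id = character(0),
                                  concept_id = character(0))))
  }
  docs <- lapply(txts, function(tp) {
    base <- sub("\\.txt$", "", tp)
    txt <- paste(readLines(tp, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    a1 <- if (file.exists(paste0(base, ".a1"))) {
      readLines(paste0(base, ".a1"), encoding = "UTF-8", warn = FALSE)
    } else character(0)
    a2 <- if (file.exists(paste0(base, ".a2"))) {
      readLines(paste0(base, ".a2"), encoding = "UTF-8", warn = FALSE)
    } else character(0)
    read_standoff(txt, a1, a2, doc_id = basename(base), types = types)
  })
  list(mentions = do.call(rbind, lapply(docs, `[[`, "mentions")),
       gold = do.call(rbind, lapply(docs, `[[`, "gold")))
}

#' Weak-supervision examples from ontology labels
#'
#' Treats each concept label (and optionally each synonym) as an entity
#' mention normalized with that concept. This guarantees that every ontology
#' concept — including concepts with no gold example — has at least one
#' training example. Labels that tokenize to nothing after stop-word
#' filtering fall back to unfiltered tokenization so coverage stays at 100%.
#'
#' @param ontology A `cn_ontology`.
#' @param include_synonyms Add one example per synonym too (default `TRUE`).
#' @param stopwords Stop-word list passed to [tokenize_filter()].
#' @return Data frame of training examples: `tokens` (list-column),
#'   `target_concept`, `provenance` (`"weak"`), `mention_key`.
#' @export
labels_as_examples <- function(ontology, include_synonyms = TRUE,
                               stopwords = character(0)) {
  rows <- list()
  for (id in ontology$ids) {
    texts <- ontology$labels[[id]]
    if (include_synonyms) texts <- c(texts, ontology$synonyms[[id]])
    for (k in seq_along(texts)) {
      toks <- tokenize_filter(texts[[k]], stopwords)
      if (length(toks) == 0L) toks <- tokenize_filter(texts[[k]])
      rows[[length(rows) + 1L]] <- list(
        tokens = toks, target_concept = id, provenance = "weak",
        mention_key = paste0("weak:", id, ":", k))
    }
  }
  .examples_df(rows)
}

.examples_df <- function(rows) {
  df <- data.frame(
    target_concept = vapply(rows, `[[`, character(1), "target_concept"),
    provenance = vapply(rows, `[[`, character(1), "provenance"),
    mention_key = vapply(rows, `[[`, character(1), "mention_key"),
    stringsAsFactors = FALSE)
  df$tokens <- lapply(rows, `[[`, "tokens")
  df[c("tokens", "target_concept", "provenance", "mention_key")]
}

#' Assemble a training set from gold corpora, optionally with weak supervision
#'
#' Gold mentions expand to one single-target example per (mention, gold
#' concept) pair; in `"standard+weak"` mode, one weak example per ontology
#' label (and synonym) is appended, so the target multiset covers every
#' concept. Mentions whose token list is empty after filtering are dropped
#' from training with a warning (they still get predictions at decode time).
#'
#' @param gold_corpora List of corpora as returned by [read_standoff()] /
#'   [read_corpus_dir()].
#' @param ontology A `cn_ontology`; gold concept ids must resolve in it
#'   (alt_ids allowed).
#' @param mode `"standard"` or `"standard+weak"`.
#' @param stopwords Stop-word list for tokenization.
#' @param include_synonyms Use synonyms as weak examples too.
#' @return Data frame of examples (`tokens` list-column, `target_concept`,
#'   `provenance`, `mention_key`), deterministic order.
#' @export
assemble_training <- function(gold_corpora, ontology,
                              mode = c("standard", "standard+weak"),
                              stopwords = character(0),
                              include_synonyms = TRUE) {
  mode <- match.arg(mode)
  if (!is.null(gold_corpora$mentions)) gold_corpora <- list(gold_corpora)

  rows <- list()
  dropped <- 0L
  for (corpus in gold_corpora) {
    m <- corpus$mentions
    surf <- stats::setNames(m$surface, paste(m$doc_id, m$mention_id))
    g <- corpus$gold
    bad <- setdiff(unique(g$concept_id),
                   c(ontology$ids, names(ontology$alt_ids)))
    if (length(bad)) {
      stop("gold concept id(s) not in ontology: ", paste(bad, collapse = ", "))
    }
    for (i in seq_len(nrow(g))) {
      key <- paste(g$doc_id[[i]], g$mention_id[[i]])
      toks <- tokenize_filter(surf[[key]], stopwords)
      if (length(toks) == 0L) { dropped <- dropped + 1L; next }
      rows[[length(rows) + 1L]] <- list(
        tokens = toks,
        target_concept = resolve_concept(ontology, g$concept_id[[i]]),
        provenance = "gold",
        mention_key = key)
    }
  }
  if (dropped > 0L) {
    warning(dropped, " gold mention(s) with empty token lists dropped from training")
  }
  out <- .examples_df(rows)
  if (mode == "standard+weak") {
    out <- rbind(out, labels_as_examples(ontology, include_synonyms, stopwords))
  }
  out
}

#' Write predictions as a2-format normalization lines
#'
#' Emits sequentially numbered `N` lines in the standoff dialect read back
#' by [read_standoff()].
#'
#' @param predictions Data frame with columns `mention_id` and `concept_id`.
#' @param resource_name Annotation resource field (default `"OntoBiotope"`).
#' @return Character vector of a2 lines (empty for an empty prediction set).
#' @export
write_predictions <- function(predictions, resource_name = "OntoBiotope") {
  if (nrow(predictions) == 0L) return(character(0))
  vapply(seq_len(nrow(predictions)), function(i) {
    sprintf("N%d\t%s Annotation:%s Referent:%s", i, resource_name,
            predictions$mention_id[[i]], predictions$concept_id[[i]])
  }, character(1))
}
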