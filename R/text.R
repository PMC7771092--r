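#' Load word embeddings in word2vec text or binary format
#'
#' Both serializations start with a header line "V D" (vocabulary size,
#' dimension). The text format then has one `token v1 ... vD` line per word;
#' the binary format stores the token as a space-terminated byte string
#' followed by D little-endian float32 values. Token casing is preserved as
#' stored. Duplicate tokens keep the last occurrence, with a warning.
#'
#' @param path File path.
#' @param format One of `"word2vec-text"`, `"word2vec-binary"`.
#' @return A `cn_embeddings` object: list with `dim` (D), `vectors`
#'   (V x D numeric matrix, rownames = tokens), `unit_normalized` (logical).
#' @export
load_embeddings <- function(path, format = c("word2vec-text", "word2vec-binary")) {
  format <- match.arg(format)
  if (format == "word2vec-text") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]))
    if (length(hdr) != 2L || anyNA(hdr)) stop("unreadable word2vec header: ", lines[[1L]])
    v <- hdr[[1L]]; d <- hdr[[2L]]
    body <- lines[-1L]
    body <- body[nzchar(trimws(body))]
    if (length(body) != v) stop("header declares ", v, " tokens but file has ", length(body))
    parts <- strsplit(body, "[ \t]+")
    tokens <- vapply(parts, `[[`, character(1), 1L)
    mats <- lapply(parts, function(p) suppressWarnings(as.numeric(p[-1L])))
    bad <- which(vapply(mats, length, 1L) != d | vapply(mats, anyNA, TRUE))
    if (length(bad)) {
      stop("embedding row ", bad[[1L]], " (token '", tokens[[bad[[1L]]]],
           "') does not have ", d, " numeric values")
    }
    vecs <- do.call(rbind, mats)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr_chars <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("unreadable header in binary embedding file")
      if (ch == "\n") break
      hdr_chars <- c(hdr_chars, ch)
    }
    hdr <- suppressWarnings(as.integer(strsplit(trimws(paste(hdr_chars, collapse = "")),
                                                "\\s+")[[1L]]))
    if (length(hdr) != 2L || anyNA(hdr)) stop("unreadable word2vec binary header")
    v <- hdr[[1L]]; d <- hdr[[2L]]
    tokens <- character(v)
    vecs <- matrix(0, v, d)
    for (i in seq_len(v)) {
      tok <- raw(0)
      repeat {
        b <- readBin(con, "raw", 1L)
        if (length(b) == 0L) stop("truncated binary embedding file at row ", i)
        if (b == charToRaw(" ")) break
        if (b != charToRaw("\n")) tok <- c(tok, b)
      }
      tokens[[i]] <- rawToChar(tok)
      row <- readBin(con, "numeric", d, size = 4L, endian = "little")
      if (length(row) != d) stop("truncated vector for token '", tokens[[i]], "'")
      vecs[i, ] <- row
    }
  }
  if (anyDuplicated(tokens)) {
    dup <- unique(tokens[duplicated(tokens)])
    warning("duplicate embedding token(s), keeping last occurrence: ",
            paste(utils::head(dup, 5L), collapse = ", "))
    keep <- !duplicated(tokens, fromLast = TRUE)
    tokens <- tokens[keep]
    vecs <- vecs[keep, , drop = FALSE]
  }
  rownames(vecs) <- tokens
  structure(list(dim = ncol(vecs), vectors = vecs, unit_normalized = FALSE),
            class = "cn_embeddings")
}

#' Write an embedding table in word2vec text format
#'
#' @param table A `cn_embeddings`.
#' @param path Output path.
#' @param digits Significant digits for the text serialization.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path, digits = 8L) {
  v <- nrow(table$vectors)
  lines <- c(paste(v, table$dim),
             vapply(seq_len(v), function(i) {
               paste(rownames(table$vectors)[[i]],
                     paste(formatC(table$vectors[i, ], digits = digits,
                                   format = "g"), collapse = " "))
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Scale every embedding vector to unit Euclidean norm
#'
#' Zero vectors cannot be normalized and are left as-is with a warning.
#' Idempotent.
#'
#' @param table A `cn_embeddings`.
#' @return The table with unit-norm rows and `unit_normalized = TRUE`.
#' @export
normalize_unit <- function(table) {
  norms <- sqrt(rowSums(table$vectors^2))
  zero <- norms == 0
  if (any(zero)) {
    warning(sum(zero), " zero embedding vector(s) left unnormalized")
    norms[zero] <- 1
  }
  table$vectors <- table$vectors / norms
  table$unit_normalized <- TRUE
  table
}

#' @export
print.cn_embeddings <- function(x, ...) {
  cat(sprintf("cn_embeddings: %d tokens, dimension %d%s\n",
              nrow(x$vectors), x$dim,
              if (isTRUE(x$unit_normalized)) ", unit-normalized" else ""))
  invisible(x)
}

#' Tokenize a mention and drop stop-words
#'
#' Lowercases, splits on any non-alphanumeric boundary (so punctuation-only
#' tokens vanish), then removes stop-words. Deterministic and idempotent on
#' its own output. Embedding files must have been produced with compatible
#' segmentation for the vocabulary lookup to succeed.
#'
#' @param text Character scalar.
#' @param stopwords Character vector of stop-word tokens (already lowercase).
#' @return Character vector of tokens, order preserved; may be empty.
#' @export
tokenize_filter <- function(text, stopwords = character(0)) {
  if (length(text) != 1L) stop("tokenize_filter expects a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- regmatches(tolower(text), gregexpr("[[:alnum:]]+", tolower(text)))[[1L]]
  toks[!(toks %in% stopwords)]
}

#' The packaged default English stop-word list
#'
#' A small standard list of non-content words (determiners, prepositions,
#' conjunctions, auxiliaries) shipped under `inst/extdata`.
#'
#' @return Character vector of lowercase stop-words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "cnormr")
  if (!nzchar(path)) stop("stop-word list not found in installed package")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Averaged mention embedding
#'
#' Arithmetic mean of the embedding vectors of the in-vocabulary tokens.
#' Out-of-vocabulary tokens are skipped; a mention with no in-vocabulary
#' token gets the zero vector, flagged via the `"oov"` attribute.
#'
#' @param tokens Character vector of tokens.
#' @param table A `cn_embeddings`.
#' @return Numeric vector of length `table$dim`; attribute `oov = TRUE` when
#'   no token was found.
#' @export
mention_average <- function(tokens, table) {
  iv <- tokens[tokens %in% rownames(table$vectors)]
  if (length(iv) == 0L) {
    return(structure(numeric(table$dim), oov = TRUE))
  }
  colMeans(table$vectors[iv, , drop = FALSE])
}

#' Padded token-embedding matrix for a mention
#'
#' Stacks the embedding vectors of the first in-vocabulary tokens into an
#' `L x D` matrix; remaining rows are zero padding. Mentions with more than
#' `pad_length` in-vocabulary tokens are truncated with a warning.
#'
#' @param tokens Character vector of tokens.
#' @param table A `cn_embeddings`.
#' @param pad_length Number of rows L (>= 1).
#' @return `L x D` matrix with attribute `n_tokens` (count of real rows) and,
#'   when no token is in vocabulary, `oov = TRUE`.
#' @export
mention_matrix <- function(tokens, table, pad_length) {
  if (pad_length < 1L) stop("pad_length must be >= 1")
  iv <- tokens[tokens %in% rownames(table$vectors)]
  if (length(iv) > pad_length) {
    warning("mention has ", length(iv), " in-vocabulary tokens; truncating to ",
            pad_length)
    iv <- iv[seq_len(pad_length)]
  }
  M <- matrix(0, pad_length, table$dim)
  if (length(iv)) M[seq_along(iv), ] <- table$vectors[iv, , drop = FALSE]
  attr(M, "n_tokens") <- length(iv)
  if (length(iv) == 0L) attr(M, "oov") <- TRUE
  M
}
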