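#' Specification for synthetic normalization fixtures
#'
#' The generator emulates the structure of habitat/phenotype normalization
#' corpora: a modest ontology, hierarchical lexical overlap between parent
#' and child labels, very few gold examples per concept, and a large
#' zero-shot fraction (concepts with no gold example at all). Defaults
#' mirror the published habitat statistics: 0.6 gold examples per ontology
#' concept on average (sd 4.3) and ~90% zero-shot concepts.
#'
#' @param n_concepts Number of ontology concepts.
#' @param branching Children per concept in the tree skeleton.
#' @param vocab_per_concept Distinctive tokens per concept.
#' @param embedding_dim Embedding dimension D.
#' @param n_mentions Number of test-split mentions (sampled uniformly over
#'   all concepts, so zero-shot concepts do appear at test time).
#' @param examples_per_concept_mean,examples_per_concept_sd Mean/sd of the
#'   per-concept gold example counts for the train+dev pool (a negative
#'   binomial when overdispersed, Poisson otherwise; sd 0 = exact count).
#' @param zero_shot_fraction Fraction of concepts excluded from train/dev
#'   gold annotation.
#' @param variation_ops Subset of `"synonym_swap"`, `"suffix_inflection"`,
#'   `"token_dropout"`, `"modifier_insertion"` applied when realizing a
#'   mention from a concept; empty = mentions are verbatim labels.
#' @param seed Integer seed.
#' @return A list of class `cn_synth_spec`.
#' @export
synthetic_spec <- function(n_concepts = 50L,
                           branching = 3L,
                           vocab_per_concept = 2L,
                           embedding_dim = 20L,
                           n_mentions = 200L,
                           examples_per_concept_mean = 0.6,
                           examples_per_concept_sd = 4.3,
                           zero_shot_fraction = 0.9,
                           variation_ops = c("synonym_swap", "modifier_insertion"),
                           seed = 1L) {
  ops_all <- c("synonym_swap", "suffix_inflection", "token_dropout",
               "modifier_insertion")
  if (length(variation_ops) && !all(variation_ops %in% ops_all)) {
    stop("unknown variation op(s): ",
         paste(setdiff(variation_ops, ops_all), collapse = ", "))
  }
  stopifnot(n_concepts >= 2L, branching >= 1L, vocab_per_concept >= 1L,
            embedding_dim >= 2L, n_mentions >= 1L,
            zero_shot_fraction >= 0, zero_shot_fraction <= 1)
  structure(list(n_concepts = as.integer(n_concepts),
                 branching = as.integer(branching),
                 vocab_per_concept = as.integer(vocab_per_concept),
                 embedding_dim = as.integer(embedding_dim),
                 n_mentions = as.integer(n_mentions),
                 examples_per_concept_mean = examples_per_concept_mean,
                 examples_per_concept_sd = examples_per_concept_sd,
                 zero_shot_fraction = zero_shot_fraction,
                 variation_ops = variation_ops,
                 seed = as.integer(seed)),
            class = "cn_synth_spec")
}

#' Generate a toy ontology with hierarchical lexical overlap
#'
#' Builds a `branching`-ary tree skeleton over `n_concepts` concepts (single
#' root), then adds an occasional extra is_a parent (to an earlier concept,
#' so the graph stays acyclic) to exercise DAG code paths. Each concept owns
#' `vocab_per_concept` distinctive tokens; its preferred label starts with
#' its own head token and, with probability 1/2, appends the parent's head
#' token — mimicking the head-sharing of real biotope labels ("cheese" /
#' "soft cheese"). Concepts get 0-2 synonyms built from their own tokens.
#'
#' @param spec A `cn_synth_spec`.
#' @return A `cn_ontology` with attribute `token_concept` (named character
#'   mapping each base vocabulary token to the id of the concept it belongs
#'   to).
#' @export
generate_ontology <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_concepts
  ids <- sprintf("SYN:%06d", seq_len(n))
  tok <- function(c, k) sprintf("w%03dx%d", c, k)

  parents <- stats::setNames(rep(list(character(0)), n), ids)
  token_concept <- character(0)
  labels <- character(0)
  synonyms <- stats::setNames(vector("list", n), ids)

  for (c in seq_len(n)) {
    own <- vapply(seq_len(spec$vocab_per_concept), function(k) tok(c, k),
                  character(1))
    token_concept[own] <- ids[[c]]
    p <- if (c > 1L) (c - 2L) %/% spec$branching + 1L else NA_integer_
    if (c > 1L) {
      parents[[ids[[c]]]] <- ids[[p]]
      # occasional extra parent among earlier concepts keeps the graph a DAG
      if (c > 2L && stats::runif(1) < 0.1) {
        extra <- sample(setdiff(seq_len(c - 1L), p), 1L)
        parents[[ids[[c]]]] <- unique(c(parents[[ids[[c]]]], ids[[extra]]))
      }
    }
    lab <- own[[1L]]
    if (length(own) > 1L && stats::runif(1) < 0.5) lab <- paste(lab, own[[2L]])
    if (c > 1L && stats::runif(1) < 0.5) lab <- paste(lab, tok(p, 1L))
    labels[[ids[[c]]]] <- lab

    n_syn <- sample(0:2, 1L)
    syns <- character(0)
    if (n_syn >= 1L && length(own) > 1L) syns <- c(syns, own[[2L]])
    if (n_syn >= 2L) syns <- c(syns, paste(own[[1L]], "s", sep = ""))
    synonyms[[ids[[c]]]] <- syns
  }

  ont <- structure(
    list(ids = ids, labels = labels, synonyms = synonyms, parents = parents,
         children = .invert_edges(ids, parents),
         roots = ids[vapply(parents[ids], length, 1L) == 0L],
         alt_ids = character(0)),
    class = "cn_ontology")
  attr(ont, "token_concept") <- token_concept
  ont
}

#' Generate an embedding table matched to a synthetic ontology
#'
#' Each concept gets a random unit direction; the vectors of its tokens
#' (including "s"-inflected variants used by the `suffix_inflection`
#' variation operator) are drawn close to that direction (pairwise cosine
#' around 0.9 within a concept), while unrelated concepts are near
#' orthogonal in expectation. Twenty "filler" tokens with independent random
#' directions support the `modifier_insertion` operator. All vectors have
#' unit norm, so normalization is learnable by construction.
#'
#' @param ontology A `cn_ontology` from [generate_ontology()].
#' @param D Embedding dimension.
#' @param seed Integer seed.
#' @return A `cn_embeddings` table (already unit-normalized).
#' @export
generate_embeddings <- function(ontology, D = 20L, seed = 1L) {
  token_concept <- attr(ontology, "token_concept")
  if (is.null(token_concept)) stop("ontology lacks the token_concept attribute")
  set.seed(seed)
  runit <- function() { v <- stats::rnorm(D); v / sqrt(sum(v^2)) }

  dirs <- lapply(ontology$ids, function(id) runit())
  names(dirs) <- ontology$ids

  a <- 0.95  # within-concept alignment; pairwise cosine ~ a^2
  vocab <- c(names(token_concept), paste0(names(token_concept), "s"),
             paste0("filler", letters[1:20]))
  vecs <- matrix(0, length(vocab), D, dimnames = list(vocab, NULL))
  for (tokname in names(token_concept)) {
    u <- dirs[[token_concept[[tokname]]]]
    for (variant in c(tokname, paste0(tokname, "s"))) {
      eps <- runit()
      eps <- eps - sum(eps * u) * u
      eps <- eps / sqrt(sum(eps^2))
      v <- a * u + sqrt(1 - a^2) * eps
      vecs[variant, ] <- v / sqrt(sum(v^2))
    }
  }
  for (f in paste0("filler", letters[1:20])) vecs[f, ] <- runit()

  structure(list(dim = D, vectors = vecs, unit_normalized = TRUE),
            class = "cn_embeddings")
}

.realize_mention <- function(ontology, concept, ops) {
  texts <- ontology$labels[[concept]]
  if ("synonym_swap" %in% ops && length(ontology$synonyms[[concept]])) {
    texts <- c(texts, ontology$synonyms[[concept]])
  }
  toks <- strsplit(sample(texts, 1L), " ", fixed = TRUE)[[1L]]
  if ("suffix_inflection" %in% ops && stats::runif(1) < 0.3) {
    k <- sample(seq_along(toks), 1L)
    if (!endsWith(toks[[k]], "s")) toks[[k]] <- paste0(toks[[k]], "s")
  }
  if ("token_dropout" %in% ops && length(toks) > 1L && stats::runif(1) < 0.3) {
    toks <- toks[-sample(seq_along(toks), 1L)]
  }
  if ("modifier_insertion" %in% ops && stats::runif(1) < 0.3) {
    pos <- sample(0:length(toks), 1L)
    toks <- append(toks, paste0("filler", sample(letters[1:20], 1L)), after = pos)
  }
  paste(toks, collapse = " ")
}

# assemble standoff documents from (concept, surface) pairs
.make_docs <- function(pairs, doc_prefix, entity_type, mentions_per_doc = 8L) {
  docs <- list()
  if (nrow(pairs) == 0L) return(docs)
  groups <- split(seq_len(nrow(pairs)),
                  (seq_len(nrow(pairs)) - 1L) %/% mentions_per_doc)
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    txt <- ""
    a1 <- character(0)
    a2 <- character(0)
    for (k in seq_along(idx)) {
      surface <- pairs$surface[[idx[[k]]]]
      start <- nchar(txt)
      txt <- paste0(txt, surface, " . ")
      a1 <- c(a1, sprintf("T%d\t%s %d %d\t%s", k, entity_type, start,
                          start + nchar(surface), surface))
      a2 <- c(a2, sprintf("N%d\tOntoBiotope Annotation:T%d Referent:%s",
                          k, k, pairs$concept[[idx[[k]]]]))
    }
    docs[[sprintf("%s%03d", doc_prefix, gi)]] <-
      list(txt = txt, a1 = a1, a2 = a2)
  }
  docs
}

#' Generate a standoff corpus with few-shot / zero-shot structure
#'
#' Samples per-concept gold example counts for the train+dev pool (zero-shot
#' concepts are excluded from this pool but not from the test split),
#' realizes each mention from a concept label via the configured variation
#' operators, groups mentions into documents, and splits them train/dev 3:1
#' with a separate test split of `spec$n_mentions` mentions whose concepts
#' are sampled uniformly over the whole ontology.
#'
#' @param ontology A `cn_ontology` from [generate_ontology()].
#' @param spec The `cn_synth_spec` controlling sizes and variation.
#' @param entity_type Entity type written on the a1 lines.
#' @return List with elements `train`, `dev`, `test` — each a list of
#'   `docs` (named list of `txt`/`a1`/`a2`), `mentions`, `gold` (parsed back
#'   through [read_standoff()], guaranteeing round-trip validity) — plus
#'   `zero_shot` (the excluded concept ids).
#' @export
generate_corpus <- function(ontology, spec, entity_type = "Habitat") {
  set.seed(spec$seed + 1L)
  n <- length(ontology$ids)
  n_zs <- floor(spec$zero_shot_fraction * n)
  zero_shot <- if (n_zs > 0L) sample(ontology$ids, n_zs) else character(0)
  eligible <- setdiff(ontology$ids, zero_shot)

  mu <- spec$examples_per_concept_mean
  sdv <- spec$examples_per_concept_sd
  counts <- if (sdv == 0) {
    rep(round(mu), length(eligible))
  } else if (sdv^2 > mu) {
    stats::rnbinom(length(eligible), mu = mu, size = mu^2 / (sdv^2 - mu))
  } else {
    stats::rpois(length(eligible), mu)
  }
  if (length(eligible) && sum(counts) == 0L) counts[[1L]] <- 1L

  pool_concepts <- rep(eligible, counts)
  pool_concepts <- sample(pool_concepts)
  pool <- data.frame(
    concept = pool_concepts,
    surface = vapply(pool_concepts, function(cc) {
      .realize_mention(ontology, cc, spec$variation_ops)
    }, character(1)),
    stringsAsFactors = FALSE)

  # 3:1 document split of the gold pool into train/dev
  n_pool <- nrow(pool)
  train_rows <- if (n_pool) seq_len(n_pool) %% 4L != 0L else logical(0)
  test_concepts <- sample(ontology$ids, spec$n_mentions, replace = TRUE)
  test <- data.frame(
    concept = test_concepts,
    surface = vapply(test_concepts, function(cc) {
      .realize_mention(ontology, cc, spec$variation_ops)
    }, character(1)),
    stringsAsFactors = FALSE)

  splits <- list(
    train = .make_docs(pool[train_rows, , drop = FALSE], "train", entity_type),
    dev = .make_docs(pool[!train_rows, , drop = FALSE], "dev", entity_type),
    test = .make_docs(test, "test", entity_type))

  out <- lapply(names(splits), function(nm) {
    docs <- splits[[nm]]
    parsed <- lapply(names(docs), function(did) {
      read_standoff(docs[[did]]$txt, docs[[did]]$a1, docs[[did]]$a2,
                    doc_id = did)
    })
    list(docs = docs,
         mentions = do.call(rbind, c(lapply(parsed, `[[`, "mentions"),
                                     list(make.row.names = FALSE))),
         gold = do.call(rbind, c(lapply(parsed, `[[`, "gold"),
                                 list(make.row.names = FALSE))))
  })
  names(out) <- names(splits)
  out$zero_shot <- zero_shot
  out
}

#' Write one corpus split as standoff files
#'
#' @param split One element (`train`/`dev`/`test`) of a [generate_corpus()]
#'   result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus_dir <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (did in names(split$docs)) {
    doc <- split$docs[[did]]
    writeLines(doc$txt, file.path(dir, paste0(did, ".txt")), useBytes = TRUE)
    writeLines(doc$a1, file.path(dir, paste0(did, ".a1")), useBytes = TRUE)
    writeLines(doc$a2, file.path(dir, paste0(did, ".a2")), useBytes = TRUE)
  }
  invisible(dir)
}

#' Serialize an ontology to OBO format
#'
#' Writes the subset of OBO that [parse_obo()] reads: `[Term]` stanzas with
#' `id`, `name`, `synonym` and `is_a` lines.
#'
#' @param ontology A `cn_ontology`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  lines <- c("format-version: 1.2", "")
  for (id in ontology$ids) {
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("name: ", ontology$labels[[id]]))
    for (s in ontology$synonyms[[id]]) {
      lines <- c(lines, sprintf("synonym: \"%s\" EXACT []", s))
    }
    for (p in ontology$parents[[id]]) {
      lines <- c(lines, paste0("is_a: ", p))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
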