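#' Parse an OBO flat file into an ontology
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas and returns the is_a hierarchy used by
#' all downstream concept-vector and similarity computations. Only `id`,
#' `name`, `synonym` (any scope), `is_a`, `alt_id` and `is_obsolete` fields
#' are interpreted; every other line is ignored. Obsolete terms are dropped,
#' but their `alt_id`s do not survive either; `alt_id`s of live terms map to
#' the canonical id and are used when resolving annotation referents.
#'
#' @param source Path to an OBO file, or a character vector of OBO lines
#'   (anything containing a newline or more than one element is treated as
#'   content rather than a path).
#' @return An object of class `cn_ontology`: a list with elements `ids`
#'   (concept ids in file order), `labels` (named character), `synonyms`
#'   (named list of character vectors), `parents` (named list of character
#'   vectors of is_a parents), `children` (inverse of `parents`), `roots`
#'   (ids with no parents) and `alt_ids` (named character, alt id ->
#'   canonical id).
#' @examples
#' obo <- c("[Term]", "id: A:1", "name: root",
#'          "[Term]", "id: A:2", "name: leaf", "is_a: A:1")
#' ont <- parse_obo(obo)
#' ont$roots
#' @export
parse_obo <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, encoding = "UTF-8", warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }

  # split into stanzas; lines before the first header belong to the OBO header
  header_idx <- grep("^\\[", lines)
  terms <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[[i]]) == "[Term]") {
      j <- i + 1L
      while (j <= length(lines) && !grepl("^\\[", lines[[j]])) j <- j + 1L
      terms[[length(terms) + 1L]] <- lines[(i + 1L):(j - 1L)]
      i <- j
    } else {
      i <- i + 1L
    }
  }

  ids <- character(0)
  labels <- character(0)
  synonyms <- list()
  parents <- list()
  alt_ids <- character(0)

  field <- function(stanza, key) {
    hits <- grep(paste0("^", key, ":"), stanza, value = TRUE)
    trimws(sub(paste0("^", key, ":"), "", hits))
  }

  for (stanza in terms) {
    if (any(grepl("^is_obsolete:\\s*true", stanza))) next
    id <- field(stanza, "id")
    if (length(id) == 0L) stop("OBO [Term] stanza without an id line")
    id <- id[[1L]]
    name <- field(stanza, "name")
    name <- if (length(name)) name[[1L]] else id
    if (!nzchar(name)) stop("concept ", id, " has an empty name")

    syn_raw <- field(stanza, "synonym")
    syns <- vapply(syn_raw, function(s) {
      m <- regmatches(s, regexpr('"(\\\\.|[^"\\\\])*"', s))
      if (length(m)) gsub('\\\\(.)', "\\1", substr(m, 2L, nchar(m) - 1L)) else s
    }, character(1), USE.NAMES = FALSE)

    isa_raw <- field(stanza, "is_a")
    isa <- trimws(sub("!.*$", "", isa_raw))  # strip trailing "! comment"
    isa <- isa[nzchar(isa)]

    if (id %in% ids) stop("duplicate concept id in OBO input: ", id)
    ids <- c(ids, id)
    labels[[id]] <- name
    synonyms[[id]] <- unname(syns)
    parents[[id]] <- unique(isa)
    for (alt in field(stanza, "alt_id")) alt_ids[[alt]] <- id
  }

  if (length(ids) == 0L) stop("no non-obsolete [Term] stanzas found")

  dangling <- setdiff(unique(unlist(parents, use.names = FALSE)), ids)
  if (length(dangling)) {
    stop("is_a target(s) not defined in ontology: ",
         paste(dangling, collapse = ", "))
  }

  ont <- structure(
    list(ids = ids, labels = labels, synonyms = synonyms, parents = parents,
         children = .invert_edges(ids, parents),
         roots = ids[vapply(parents[ids], length, 1L) == 0L],
         alt_ids = alt_ids),
    class = "cn_ontology")

  cyc <- .find_cycle(ont)
  if (!is.null(cyc)) {
    stop("is_a graph contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  if (length(ont$roots) == 0L) stop("ontology has no root concept")
  ont
}

.invert_edges <- function(ids, parents) {
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  children
}

# Kahn's algorithm; on failure, walk the residual graph to print one cycle.
.find_cycle <- function(ont) {
  indeg <- vapply(ont$parents[ont$ids], length, 1L)
  names(indeg) <- ont$ids
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in ont$children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(ont$ids)) return(NULL)
  start <- names(indeg)[indeg > 0L][[1L]]
  path <- start
  v <- start
  repeat {
    v <- intersect(ont$parents[[v]], names(indeg)[indeg > 0L])[[1L]]
    if (v %in% path) {
      k <- match(v, path)
      return(c(path[k:length(path)], v))
    }
    path <- c(path, v)
  }
}

#' @export
print.cn_ontology <- function(x, ...) {
  cat(sprintf("cn_ontology: %d concepts, %d root(s)\n",
              length(x$ids), length(x$roots)))
  cat("roots:", paste(utils::head(x$roots, 5L), collapse = ", "),
      if (length(x$roots) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Resolve a concept id, mapping alt_ids to their canonical concept
#'
#' @param ontology A `cn_ontology`.
#' @param id Concept id (possibly an alt_id).
#' @return The canonical concept id.
#' @export
resolve_concept <- function(ontology, id) {
  if (id %in% ontology$ids) return(id)
  if (id %in% names(ontology$alt_ids)) return(ontology$alt_ids[[id]])
  stop("unknown concept id: ", id)
}

#' Minimum is_a distances from a concept to each of its ancestors
#'
#' Distance is the minimum number of subsumption (is_a) steps; the concept
#' itself is at distance 0. On a DAG with several upward paths to the same
#' ancestor, the shortest one wins.
#'
#' @param ontology A `cn_ontology`.
#' @param concept A concept id present in the ontology.
#' @return Named integer vector: ancestor id -> minimum step count. Contains
#'   the concept itself (0) and nothing outside its ancestor closure.
#' @export
ancestor_distances <- function(ontology, concept) {
  concept <- resolve_concept(ontology, concept)
  dist <- stats::setNames(0L, concept)
  frontier <- concept
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(ontology$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, names(dist))  # BFS: first visit is the minimum
    if (length(nxt)) dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Build decay-weighted concept vectors
#'
#' Each concept gets an N-dimensional vector (N = number of concepts) with
#' weight `decay^d` on itself (d = 0, so weight 1) and on each ancestor at
#' minimum is_a distance d, and 0 elsewhere. `decay = 0` yields exact one-hot
#' vectors (0^0 := 1); `decay = 1` gives every ancestor the same weight as
#' the concept itself.
#'
#' @param ontology A `cn_ontology`.
#' @param decay Decay factor in \[0, 1\]. Default 0.6, a value that balances
#'   strict and hierarchy-aware accuracy in habitat normalization.
#' @return A `cn_concept_space`: list with `ids` (dimension order), `M`
#'   (N x N matrix, one row per concept, rows/cols named by id), `decay`.
#' @export
build_concept_vectors <- function(ontology, decay = 0.6) {
  if (!is.numeric(decay) || length(decay) != 1L || is.na(decay) ||
      decay < 0 || decay > 1) {
    stop("decay must be a single number in [0, 1]")
  }
  n <- length(ontology$ids)
  M <- matrix(0, n, n, dimnames = list(ontology$ids, ontology$ids))
  for (id in ontology$ids) {
    d <- ancestor_distances(ontology, id)
    w <- ifelse(d == 0L, 1, decay^d)
    M[id, names(d)] <- w
  }
  structure(list(ids = ontology$ids, M = M, decay = decay,
                 row_norms = sqrt(rowSums(M^2))),
            class = "cn_concept_space")
}

#' @export
print.cn_concept_space <- function(x, ...) {
  cat(sprintf("cn_concept_space: %d concepts, decay = %g\n",
              length(x$ids), x$decay))
  invisible(x)
}

#' Wang semantic similarity between two concepts
#'
#' Hierarchy-aware similarity in (0, 1]. Each concept assigns an S-value to
#' every term of its ancestor closure: 1 for itself, and for an ancestor the
#' maximum over upward paths of `edge_contribution` per step — with a uniform
#' per-edge contribution this is `edge_contribution^d` for minimum distance
#' d. The similarity is the S-mass both concepts place on their shared
#' closure, normalized by their total S-masses. Equals 1 iff the concepts
#' are identical; decreases toward 0 as they grow apart in the hierarchy.
#'
#' @param ontology A `cn_ontology`.
#' @param a,b Concept ids.
#' @param edge_contribution Per-is_a-edge S-value multiplier in (0, 1);
#'   default 0.8, the classical is_a weight of the measure.
#' @return Similarity in (0, 1].
#' @export
wang_similarity <- function(ontology, a, b, edge_contribution = 0.8) {
  if (!is.numeric(edge_contribution) || edge_contribution <= 0 ||
      edge_contribution >= 1) {
    stop("edge_contribution must lie strictly between 0 and 1")
  }
  da <- ancestor_distances(ontology, a)
  db <- ancestor_distances(ontology, b)
  sa <- edge_contribution^da
  sb <- edge_contribution^db
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0L) return(0)
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}
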