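# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written as plain loops / exhaustive enumeration so it shares
# no code path with the implementation it checks.

# ---- fixture builders -------------------------------------------------------

chain_obo <- function() c(
  "[Term]", "id: A:1", "name: alpha", "",
  "[Term]", "id: B:1", "name: beta", "is_a: A:1", "",
  "[Term]", "id: C:1", "name: gamma", "is_a: B:1")

diamond_obo <- function() c(
  "[Term]", "id: A:1", "name: top", "",
  "[Term]", "id: B:1", "name: left", "is_a: A:1", "",
  "[Term]", "id: C:1", "name: right", "is_a: A:1", "",
  "[Term]", "id: D:1", "name: bottom", "is_a: B:1", "is_a: C:1")

# random rooted DAG ontology built as OBO text and parsed, so every property
# test also exercises the parser; each node beyond the first gets one parent
# among earlier nodes and sometimes a second (graph stays acyclic).
random_dag_ontology <- function(n, seed, p_extra = 0.1) {
  set.seed(seed)
  ids <- sprintf("R:%04d", seq_len(n))
  lines <- character(0)
  for (i in seq_len(n)) {
    lines <- c(lines, "[Term]", paste0("id: ", ids[[i]]),
               paste0("name: node ", i))
    if (i > 1L) {
      p <- sample.int(i - 1L, 1L)
      lines <- c(lines, paste0("is_a: ", ids[[p]]))
      if (i > 2L && stats::runif(1) < p_extra) {
        q <- sample(setdiff(seq_len(i - 1L), p), 1L)
        lines <- c(lines, paste0("is_a: ", ids[[q]]))
      }
    }
    lines <- c(lines, "")
  }
  parse_obo(lines)
}

toy_embeddings <- function(tokens, D, seed = 1) {
  set.seed(seed)
  vecs <- matrix(stats::rnorm(length(tokens) * D), length(tokens), D,
                 dimnames = list(tokens, NULL))
  structure(list(dim = D, vectors = vecs, unit_normalized = FALSE),
            class = "cn_embeddings")
}

# ---- upward-path enumeration ------------------------------------------------

# all upward is_a paths from `id` (each path a vector of ids starting at id)
all_upward_paths <- function(ont, id) {
  ps <- ont$parents[[id]]
  if (length(ps) == 0L) return(list(id))
  out <- list(id)
  for (p in ps) {
    for (path in all_upward_paths(ont, p)) out <- c(out, list(c(id, path)))
  }
  out
}

# oracle: minimum step count to each ancestor via exhaustive path enumeration
oracle_min_distances <- function(ont, id) {
  best <- list()
  for (path in all_upward_paths(ont, id)) {
    for (k in seq_along(path)) {
      node <- path[[k]]
      d <- k - 1L
      if (is.null(best[[node]]) || d < best[[node]]) best[[node]] <- d
    }
  }
  unlist(best)
}

# oracle: full concept-vector matrix via the enumeration above
oracle_concept_vectors <- function(ont, decay) {
  n <- length(ont$ids)
  M <- matrix(0, n, n, dimnames = list(ont$ids, ont$ids))
  for (id in ont$ids) {
    d <- oracle_min_distances(ont, id)
    for (nm in names(d)) {
      M[id, nm] <- if (d[[nm]] == 0L) 1 else decay^d[[nm]]
    }
  }
  M
}

# oracle: Wang similarity via exhaustive path enumeration of S-values
oracle_wang <- function(ont, a, b, w) {
  svals <- function(id) {
    s <- list()
    for (path in all_upward_paths(ont, id)) {
      for (k in seq_along(path)) {
        v <- w^(k - 1L)
        node <- path[[k]]
        if (is.null(s[[node]]) || v > s[[node]]) s[[node]] <- v
      }
    }
    unlist(s)
  }
  sa <- svals(a); sb <- svals(b)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0L) return(0)
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

# ---- straight-line forward passes (explicit loops, no matrix algebra) ------

oracle_slfnn_forward <- function(W, b, X) {
  D <- ncol(X); N <- length(b)
  avg <- numeric(D)
  if (nrow(X) > 0L) for (j in seq_len(D)) avg[[j]] <- mean(X[, j])
  out <- numeric(N)
  for (k in seq_len(N)) {
    s <- b[[k]]
    for (j in seq_len(D)) s <- s + W[k, j] * avg[[j]]
    out[[k]] <- s
  }
  out
}

oracle_cnn_forward <- function(Fm, cv, X, filter_size, slope) {
  D <- ncol(X); N <- length(cv)
  if (nrow(X) < filter_size) {
    X <- rbind(X, matrix(0, filter_size - nrow(X), D))
  }
  npos <- nrow(X) - filter_size + 1L
  out <- numeric(N)
  for (k in seq_len(N)) {
    best <- -Inf
    for (t in seq_len(npos)) {
      s <- cv[[k]]
      col <- 0L
      for (r in t:(t + filter_size - 1L)) {
        for (j in seq_len(D)) {
          col <- col + 1L
          s <- s + Fm[k, col] * X[r, j]
        }
      }
      if (s > best) best <- s
    }
    out[[k]] <- if (best > 0) best else slope * best
  }
  out
}

oracle_cnorm_forward <- function(params, X, filter_size, slope) {
  o1 <- oracle_slfnn_forward(params$sW, params$sb, X)
  o2 <- oracle_cnn_forward(params$cF, params$cc, X, filter_size, slope)
  out <- numeric(length(o1))
  for (k in seq_along(o1)) out[[k]] <- (o1[[k]] + o2[[k]]) / 2
  out
}

# strict accuracy of a trained model on (token list, concept) pairs
strict_accuracy <- function(model, token_lists, gold_concepts, space, emb) {
  names(token_lists) <- as.character(seq_along(token_lists))
  out <- predict_vectors(model, token_lists, emb)
  preds <- decode_predictions(out, space)
  mean(preds$concept_id == gold_concepts)
}

# gold concept aligned to the mention table of one corpus split
split_gold_concepts <- function(split) {
  key_m <- paste(split$mentions$doc_id, split$mentions$mention_id)
  key_g <- paste(split$gold$doc_id, split$gold$mention_id)
  split$gold$concept_id[match(key_m, key_g)]
}
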