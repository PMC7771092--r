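test_that("generated ontologies are deterministic, rooted DAGs with labels", {
  spec <- synthetic_spec(n_concepts = 50, seed = 13)
  o1 <- generate_ontology(spec)
  o2 <- generate_ontology(spec)
  expect_identical(o1, o2)
  expect_length(o1$ids, 50)
  expect_length(o1$roots, 1)  # single-root construction; parse checks acyclicity
  expect_true(all(nchar(unlist(o1$labels)) > 0))
  # every concept reaches the root
  for (id in sample(o1$ids, 10)) {
    expect_true(o1$roots %in% names(ancestor_distances(o1, id)))
  }
  # round-trips through the OBO writer/parser
  p <- withr::local_tempfile(fileext = ".obo")
  write_obo(o1, p)
  o3 <- parse_obo(p)
  expect_equal(o3$ids, o1$ids)
  expect_equal(o3$labels, o1$labels)
  expect_equal(o3$parents[o3$ids], o1$parents[o1$ids])
})

test_that("generated embeddings separate concepts geometrically", {
  spec <- synthetic_spec(n_concepts = 30, embedding_dim = 20, seed = 3)
  ont <- generate_ontology(spec)
  emb <- generate_embeddings(ont, D = 20, seed = 3)
  norms <- sqrt(rowSums(emb$vectors^2))
  expect_equal(unname(norms), rep(1, nrow(emb$vectors)), tolerance = 1e-9)
  expect_identical(emb$vectors,
                   generate_embeddings(ont, D = 20, seed = 3)$vectors)

  tc <- attr(ont, "token_concept")
  by_concept <- split(names(tc), tc)
  within <- unlist(lapply(by_concept, function(toks) {
    if (length(toks) < 2) return(NULL)
    combn(toks, 2, function(p) sum(emb$vectors[p[1], ] * emb$vectors[p[2], ]))
  }))
  set.seed(1)
  across <- replicate(300, {
    cs <- sample(names(by_concept), 2)
    sum(emb$vectors[by_concept[[cs[1]]][1], ] *
        emb$vectors[by_concept[[cs[2]]][1], ])
  })
  expect_gt(mean(within) - mean(across), 0.3)
})

test_that("generated corpora respect zero-shot structure and round-trip as standoff", {
  spec <- synthetic_spec(n_concepts = 40, zero_shot_fraction = 0.9,
                         examples_per_concept_mean = 3,
                         examples_per_concept_sd = 0, n_mentions = 80, seed = 21)
  ont <- generate_ontology(spec)
  corpus <- generate_corpus(ont, spec)
  expect_length(corpus$zero_shot, 36)
  train_concepts <- unique(corpus$train$gold$concept_id)
  expect_length(intersect(train_concepts, corpus$zero_shot), 0)
  expect_gte(length(corpus$zero_shot) / 40, 0.9)
  # test split samples all concepts, including zero-shot ones
  expect_gt(length(intersect(corpus$test$gold$concept_id, corpus$zero_shot)), 0)

  d <- withr::local_tempdir()
  write_corpus_dir(corpus$dev, d)
  back <- read_corpus_dir(d)
  expect_setequal(paste(back$gold$doc_id, back$gold$mention_id,
                        back$gold$concept_id),
                  paste(corpus$dev$gold$doc_id, corpus$dev$gold$mention_id,
                        corpus$dev$gold$concept_id))
  expect_setequal(back$mentions$surface, corpus$dev$mentions$surface)
})

test_that("examples-per-concept sampling tracks the requested mean", {
  spec <- synthetic_spec(n_concepts = 50, zero_shot_fraction = 0,
                         examples_per_concept_mean = 10,
                         examples_per_concept_sd = 3, n_mentions = 10, seed = 4)
  ont <- generate_ontology(spec)
  corpus <- generate_corpus(ont, spec)
  n_gold <- nrow(corpus$train$gold) + nrow(corpus$dev$gold)
  emp_mean <- n_gold / 50
  expect_lt(abs(emp_mean - 10) / 10, 0.2)
})

test_that("variation operators produce learnable-but-varied mentions", {
  spec <- synthetic_spec(n_concepts = 15, zero_shot_fraction = 0,
                         examples_per_concept_mean = 6,
                         examples_per_concept_sd = 0, n_mentions = 20,
                         variation_ops = c("synonym_swap", "suffix_inflection",
                                           "token_dropout", "modifier_insertion"),
                         seed = 31)
  ont <- generate_ontology(spec)
  emb <- generate_embeddings(ont, D = 20, seed = 31)
  corpus <- generate_corpus(ont, spec)
  surfaces <- corpus$train$mentions$surface
  expect_gt(length(setdiff(surfaces, unlist(ont$labels))), 0)
  # every mention token the ops can emit is in the embedding vocabulary
  toks <- unique(unlist(lapply(surfaces, tokenize_filter)))
  expect_true(all(toks %in% rownames(emb$vectors)))
})

test_that("memorization check: weak supervision alone solves verbatim labels", {
  spec <- synthetic_spec(n_concepts = 25, embedding_dim = 20,
                         variation_ops = character(0), n_mentions = 40,
                         zero_shot_fraction = 0, examples_per_concept_mean = 1,
                         examples_per_concept_sd = 0, seed = 17)
  ont <- generate_ontology(spec)
  emb <- generate_embeddings(ont, D = 20, seed = 17)
  space <- build_concept_vectors(ont, 0.6)
  weak <- labels_as_examples(ont)
  # ~40 weak examples is a single minibatch, so one optimizer step per
  # epoch; give the run enough steps to memorize
  m <- train_model(build_cnorm(20, 25), weak, space, emb,
                   model_config("cnorm", epochs = 500, seed = 2))
  label_toks <- lapply(ont$labels, tokenize_filter)
  acc <- strict_accuracy(m, label_toks, ont$ids, space, emb)
  expect_gte(acc, 0.95)
})
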