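rand_mentions <- function(n, D, seed, max_tok = 5L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    nt <- sample(0:max_tok, 1)
    matrix(rnorm(nt * D), nt, D)
  })
}

test_that("builders produce the declared shapes and parameter counts", {
  m <- build_slfnn(3, 5)
  expect_equal(dim(m$params$W), c(5, 3))
  expect_length(m$params$b, 5)
  expect_equal(length(m$params$W) + length(m$params$b), 3 * 5 + 5)  # D*N + N
  c1 <- build_cnn(4, 6, filter_size = 2)
  expect_equal(dim(c1$params$F), c(6, 8))
  e <- build_cnorm(4, 6)
  expect_named(e$params, c("sW", "sb", "cF", "cc"))
  expect_error(build_cnn(4, 6, pad_length = 1, filter_size = 2), "filter_size")
})

test_that("SLFNN output is a linear function of the token average only", {
  m <- build_slfnn(4, 3, seed = 1)
  X1 <- matrix(c(1, 0, 0, 0, 0, 2, 0, 0), 2, 4, byrow = TRUE)
  X2 <- matrix(c(0.5, 1, 0, 0), 1, 4)  # same column means as X1
  out <- forward_pass(m, list(X1, X2))
  expect_equal(out[1, ], out[2, ], tolerance = 1e-12)
  # identity-block weights reproduce embedding coordinates
  m$params$W <- cbind(diag(3), 0)
  m$params$b <- numeric(3)
  x <- matrix(c(7, -2, 3, 9), 1, 4)
  expect_equal(unname(forward_pass(m, list(x))[1, ]), c(7, -2, 3))
})

test_that("width-1 CNN is token-order and duplication invariant", {
  m <- build_cnn(5, 4, filter_size = 1, seed = 3)
  set.seed(8)
  for (trial in 1:20) {
    X <- matrix(rnorm(4 * 5), 4, 5)
    o1 <- forward_pass(m, list(X))
    o2 <- forward_pass(m, list(X[sample(4), , drop = FALSE]))
    expect_equal(o1, o2, tolerance = 1e-12)
    # appending a duplicated token never changes a max over a multiset
    o3 <- forward_pass(m, list(rbind(X, X[sample(4, 1), ])))
    expect_equal(o1, o3, tolerance = 1e-12)
  }
  # single-token mention: pooling is the identity over one position
  x <- matrix(rnorm(5), 1, 5)
  z <- as.numeric(m$params$F %*% x[1, ] + m$params$c)
  expect_equal(unname(forward_pass(m, list(x))[1, ]),
               ifelse(z > 0, z, 0.3 * z), tolerance = 1e-12)
})

test_that("forward passes match straight-line loop re-implementations", {
  D <- 6; N <- 7
  ms <- build_slfnn(D, N, seed = 11)
  mc <- build_cnn(D, N, filter_size = 2, seed = 12)
  me <- build_cnorm(D, N, filter_size = 1, seed = 13)
  for (X in rand_mentions(25, D, seed = 14)) {
    expect_equal(unname(forward_pass(ms, list(X))[1, ]),
                 oracle_slfnn_forward(ms$params$W, ms$params$b, X),
                 tolerance = 1e-5)
    expect_equal(unname(forward_pass(mc, list(X))[1, ]),
                 oracle_cnn_forward(mc$params$F, mc$params$c, X, 2L, 0.3),
                 tolerance = 1e-5)
    expect_equal(unname(forward_pass(me, list(X))[1, ]),
                 oracle_cnorm_forward(me$params, X, 1L, 0.3),
                 tolerance = 1e-5)
  }
})

test_that("C-Norm output is exactly the mean of its two branch outputs", {
  D <- 5; N <- 4
  e <- build_cnorm(D, N, seed = 21)
  s <- build_slfnn(D, N, seed = 22)
  cn <- build_cnn(D, N, seed = 23)
  # freeze the branches to the standalone models' parameters
  e$params$sW <- s$params$W; e$params$sb <- s$params$b
  e$params$cF <- cn$params$F; e$params$cc <- cn$params$c
  Xs <- rand_mentions(15, D, seed = 24)
  expect_equal(forward_pass(e, Xs),
               (forward_pass(s, Xs) + forward_pass(cn, Xs)) / 2,
               tolerance = 1e-12)
  # equal branches pass through; zero branches yield the (zero) bias image
  e$params$cF <- matrix(0, N, D); e$params$cc <- numeric(N)
  e$params$sW <- matrix(0, N, D); e$params$sb <- numeric(N)
  expect_equal(unname(forward_pass(e, Xs[1])[1, ]), rep(0, N))
})

toy_training_world <- function(n_concepts = 8, D = 10, seed = 31) {
  spec <- synthetic_spec(n_concepts = n_concepts, embedding_dim = D,
                         examples_per_concept_mean = 3,
                         examples_per_concept_sd = 0, zero_shot_fraction = 0,
                         n_mentions = 10, variation_ops = character(0),
                         seed = seed)
  ont <- generate_ontology(spec)
  emb <- generate_embeddings(ont, D = D, seed = seed)
  corpus <- generate_corpus(ont, spec)
  ex <- assemble_training(list(corpus$train), ont, mode = "standard+weak")
  list(ont = ont, emb = emb, ex = ex,
       space = build_concept_vectors(ont, 0.6))
}

test_that("training reduces the loss, overfits a single example, and is deterministic", {
  w <- toy_training_world()
  cfg <- model_config("cnorm", epochs = 25, seed = 5)
  m1 <- train_model(build_cnorm(10, 8), w$ex, w$space, w$emb, cfg)
  expect_length(m1$loss_history, 25)
  expect_lt(m1$loss_history[25], m1$loss_history[1])

  m2 <- train_model(build_cnorm(10, 8), w$ex, w$space, w$emb, cfg)
  expect_identical(m1$params, m2$params)

  one <- w$ex[3, ]
  for (arch in c("slfnn", "cnn", "cnorm")) {
    builder <- switch(arch, slfnn = build_slfnn, cnn = build_cnn,
                      cnorm = build_cnorm)
    cfg1 <- model_config(arch, epochs = 200, seed = 5)
    mo <- train_model(builder(10, 8), one, w$space, w$emb, cfg1)
    out <- predict_vectors(mo, one$tokens, w$emb)
    expect_equal(nearest_concept(out[1, ], w$space)$concept_id,
                 one$target_concept)
  }

  expect_error(train_model(build_cnorm(10, 8), w$ex[0, ], w$space, w$emb, cfg),
               "empty")
  bad <- w$ex; bad$target_concept[1] <- "NOPE:1"
  expect_error(train_model(build_cnorm(10, 8), bad, w$space, w$emb, cfg),
               "NOPE:1")
})

test_that("prediction is batch-invariant, deterministic, and guards dimensions", {
  w <- toy_training_world()
  cfg <- model_config("cnorm", epochs = 10, seed = 5)
  m <- train_model(build_cnorm(10, 8), w$ex, w$space, w$emb, cfg)
  toks <- w$ex$tokens[1:6]
  batched <- predict_vectors(m, toks, w$emb)
  single <- t(vapply(toks, function(tk) {
    predict_vectors(m, list(tk), w$emb)[1, ]
  }, numeric(8)))
  expect_equal(unname(batched), unname(single), tolerance = 1e-6)
  expect_equal(batched, predict_vectors(m, toks, w$emb))
  expect_equal(nrow(predict_vectors(m, list(), w$emb)), 0)
  emb_bad <- w$emb; emb_bad$dim <- 99
  expect_error(predict_vectors(m, toks, emb_bad), "dimension")
})

test_that("model archives round-trip to identical predictions", {
  w <- toy_training_world()
  cfg <- model_config("cnn", epochs = 10, seed = 5)
  m <- train_model(build_cnn(10, 8), w$ex, w$space, w$emb, cfg)
  p <- withr::local_tempfile(fileext = ".json")
  save_model(m, p)
  m2 <- load_model(p)
  expect_equal(m2$concept_ids, m$concept_ids)
  expect_identical(predict_vectors(m2, w$ex$tokens, w$emb),
                   predict_vectors(m, w$ex$tokens, w$emb))
})
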