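#' Model configuration for training
#'
#' Collects the hyperparameters of the three architectures. Defaults follow
#' the habitat-normalization setting: Nadam optimizer, log-cosh regression
#' loss, a single convolution filter width of 1 with one filter per ontology
#' concept, leaky-ReLU after max-pooling, and per-architecture epoch counts
#' (SLFNN 50, shallow CNN 150, C-Norm 200; the smaller phenotype corpora use
#' 100/50/30 instead — pass `epochs` explicitly for those). Batch size and
#' learning rate are the usual library defaults of the ecosystem the method
#' grew up in; they are recorded here so a run can be reproduced exactly.
#'
#' @param architecture `"slfnn"`, `"cnn"` or `"cnorm"`.
#' @param epochs Training epochs; `NULL` picks the per-architecture default.
#' @param optimizer Only `"nadam"` is implemented.
#' @param loss Only `"log_cosh"` is implemented.
#' @param filter_size Convolution filter width in tokens (default 1).
#' @param activation Post-pooling activation: `"leaky_relu"`, `"relu"`,
#'   `"tanh"` or `"linear"`.
#' @param leaky_slope Negative-side slope of leaky ReLU (default 0.3).
#' @param batch_size Minibatch size (default 64).
#' @param learning_rate Nadam step size (default 0.002).
#' @param seed Integer seed controlling parameter initialization and
#'   minibatch shuffling.
#' @param decay Concept-vector decay factor, recorded for provenance.
#' @param pad_length Token-matrix padding length; `NULL` = maximum token
#'   count observed in the training examples.
#' @return A list of class `cn_config`.
#' @export
model_config <- function(architecture = c("cnorm", "slfnn", "cnn"),
                         epochs = NULL,
                         optimizer = "nadam",
                         loss = "log_cosh",
                         filter_size = 1L,
                         activation = "leaky_relu",
                         leaky_slope = 0.3,
                         batch_size = 64L,
                         learning_rate = 0.002,
                         seed = 1L,
                         decay = 0.6,
                         pad_length = NULL) {
  architecture <- match.arg(architecture)
  if (is.null(epochs)) {
    epochs <- c(slfnn = 50L, cnn = 150L, cnorm = 200L)[[architecture]]
  }
  stopifnot(epochs >= 1L, filter_size >= 1L, batch_size >= 1L)
  if (!identical(optimizer, "nadam")) stop("only the nadam optimizer is implemented")
  if (!identical(loss, "log_cosh")) stop("only the log_cosh loss is implemented")
  structure(list(architecture = architecture, epochs = as.integer(epochs),
                 optimizer = optimizer, loss = loss,
                 filter_size = as.integer(filter_size),
                 activation = activation, leaky_slope = leaky_slope,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 decay = decay, pad_length = pad_length),
            class = "cn_config")
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained single-layer feedforward network (SLFNN)
#'
#' A bias-augmented linear projection from the averaged mention embedding
#' (dimension D) to the concept-vector space (dimension N): `W x_mean + b`,
#' no nonlinearity. Trainable parameter count is `D*N + N`.
#'
#' @param D Embedding dimension.
#' @param N Concept-space dimension (number of ontology concepts).
#' @param seed Seed for Glorot-uniform weight initialization.
#' @return A `cn_model` with `params$W` (N x D) and `params$b` (length N).
#' @export
build_slfnn <- function(D, N, seed = 0L) {
  stopifnot(D >= 1L, N >= 1L)
  set.seed(seed)
  structure(list(architecture = "slfnn", D = D, N = N, pad_length = NULL,
                 params = list(W = .glorot(N, D), b = numeric(N))),
            class = "cn_model")
}

#' Build an untrained shallow CNN
#'
#' One 1-D convolution over the token axis with N filters (one per ontology
#' concept) of width `filter_size`, max-pooling over valid (non-pad) window
#' positions per filter, then the activation — no dense or softmax layer on
#' top. With width-1 filters each filter acts as a learned token-trigger
#' detector for its concept, and the output is invariant to token order.
#'
#' @param D Embedding dimension.
#' @param N Concept-space dimension; equals the number of filters.
#' @param pad_length Padding length recorded for provenance (may be `NULL`
#'   until training).
#' @param filter_size Filter width in tokens.
#' @param activation,leaky_slope Post-pooling activation and its negative
#'   slope.
#' @param seed Seed for initialization.
#' @return A `cn_model` with `params$F` (N x filter_size*D) and `params$c`
#'   (length N).
#' @export
build_cnn <- function(D, N, pad_length = NULL, filter_size = 1L,
                      activation = "leaky_relu", leaky_slope = 0.3,
                      seed = 0L) {
  stopifnot(D >= 1L, N >= 1L, filter_size >= 1L)
  if (!is.null(pad_length) && filter_size > pad_length) {
    stop("filter_size must not exceed pad_length")
  }
  set.seed(seed)
  structure(list(architecture = "cnn", D = D, N = N, pad_length = pad_length,
                 filter_size = as.integer(filter_size),
                 activation = activation, leaky_slope = leaky_slope,
                 params = list(F = .glorot(N, filter_size * D), c = numeric(N))),
            class = "cn_model")
}

#' Build an untrained C-Norm ensemble
#'
#' One mention matrix feeds two parallel branches — the SLFNN (internal
#' masked averaging, then linear map) and the shallow CNN — and the output
#' is the elementwise mean of the branch outputs. The branches share no
#' parameters and are trained end to end through the single averaged output,
#' so the combination layer feeds gradient back into both components.
#'
#' @inheritParams build_cnn
#' @return A `cn_model` with `params` `sW`, `sb` (SLFNN branch) and `cF`,
#'   `cc` (CNN branch).
#' @export
build_cnorm <- function(D, N, pad_length = NULL, filter_size = 1L,
                        activation = "leaky_relu", leaky_slope = 0.3,
                        seed = 0L) {
  stopifnot(D >= 1L, N >= 1L, filter_size >= 1L)
  set.seed(seed)
  structure(list(architecture = "cnorm", D = D, N = N, pad_length = pad_length,
                 filter_size = as.integer(filter_size),
                 activation = activation, leaky_slope = leaky_slope,
                 params = list(sW = .glorot(N, D), sb = numeric(N),
                               cF = .glorot(N, filter_size * D), cc = numeric(N))),
            class = "cn_model")
}

#' @export
print.cn_model <- function(x, ...) {
  cat(sprintf("cn_model <%s>: D=%d -> N=%d%s%s\n", x$architecture, x$D, x$N,
              if (!is.null(x$pad_length)) sprintf(", pad_length=%d", x$pad_length) else "",
              if (isTRUE(x$trained)) ", trained" else ""))
  invisible(x)
}

.activation_fun <- function(name, slope) {
  switch(name,
         leaky_relu = list(f = function(z) ifelse(z > 0, z, slope * z),
                           df = function(z) ifelse(z > 0, 1, slope)),
         relu = list(f = function(z) pmax(z, 0), df = function(z) as.numeric(z > 0)),
         tanh = list(f = tanh, df = function(z) 1 - tanh(z)^2),
         linear = list(f = identity, df = function(z) rep(1, length(z))),
         stop("unknown activation: ", name))
}

# Window matrix for the convolution: rows are flattened windows of
# `filter_size` consecutive token rows. Mentions shorter than the filter are
# pooled over a single zero-padded window (contract: warning handled by the
# caller at data-preparation time).
.conv_windows <- function(X, filter_size) {
  n <- nrow(X)
  D <- ncol(X)
  if (n < filter_size) {
    pad <- matrix(0, filter_size - n, D)
    X <- rbind(X, pad)
    n <- filter_size
  }
  npos <- n - filter_size + 1L
  if (filter_size == 1L) return(X)
  out <- matrix(0, npos, filter_size * D)
  for (t in seq_len(npos)) {
    out[t, ] <- as.numeric(t(X[t:(t + filter_size - 1L), , drop = FALSE]))
  }
  out
}

.forward_cnn_one <- function(Fm, cv, X, filter_size, act) {
  Xw <- .conv_windows(X, filter_size)
  scores <- Xw %*% t(Fm) + rep(cv, each = nrow(Xw))
  idx <- max.col(t(scores), ties.method = "first")
  z <- scores[cbind(idx, seq_along(cv))]
  list(out = act$f(z), z = z, idx = idx, Xw = Xw)
}

# Forward pass over a list of mention matrices (real token rows only; a
# 0-row matrix stands for an all-pad mention). Returns a B x N matrix.
.forward <- function(model, Xlist) {
  B <- length(Xlist)
  N <- model$N
  avg <- t(vapply(Xlist, function(X) {
    if (nrow(X) == 0L) numeric(model$D) else colMeans(X)
  }, numeric(model$D)))
  if (model$architecture == "slfnn") {
    return(avg %*% t(model$params$W) + rep(model$params$b, each = B))
  }
  act <- .activation_fun(model$activation, model$leaky_slope)
  if (model$architecture == "cnn") {
    out <- matrix(0, B, N)
    for (i in seq_len(B)) {
      out[i, ] <- .forward_cnn_one(model$params$F, model$params$c,
                                   Xlist[[i]], model$filter_size, act)$out
    }
    return(out)
  }
  # cnorm: elementwise mean of the two branch outputs
  o1 <- avg %*% t(model$params$sW) + rep(model$params$sb, each = B)
  o2 <- matrix(0, B, N)
  for (i in seq_len(B)) {
    o2[i, ] <- .forward_cnn_one(model$params$cF, model$params$cc,
                                Xlist[[i]], model$filter_size, act)$out
  }
  (o1 + o2) / 2
}

#' Forward pass of a model on explicit mention matrices
#'
#' Mainly exposed for testing the architectures against independent
#' re-implementations; end users normally call [predict_vectors()].
#'
#' @param model A `cn_model`.
#' @param mention_matrices List of matrices (`n_tokens x D`, real token rows
#'   only; a 0-row matrix denotes an empty mention).
#' @return `length(mention_matrices) x N` output matrix.
#' @export
forward_pass <- function(model, mention_matrices) {
  if (length(mention_matrices) == 0L) return(matrix(0, 0L, model$N))
  bad <- vapply(mention_matrices, function(X) ncol(X) != model$D, TRUE)
  if (any(bad)) stop("mention matrix dimension does not match model D = ", model$D)
  .forward(model, mention_matrices)
}

.logcosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)

# One Nadam step for a single tensor. Classical bias-corrected Nadam:
# a momentum-lookahead variant of Adam (betas 0.9/0.999, eps 1e-7).
.nadam_step <- function(p, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-7) {
  st$t <- st$t + 1L
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mbar <- b1 * st$m / (1 - b1^(st$t + 1L)) + (1 - b1) * g / (1 - b1^st$t)
  vhat <- st$v / (1 - b2^st$t)
  list(p = p - lr * mbar / (sqrt(vhat) + eps), st = st)
}

# Token lists -> list of in-vocabulary embedding matrices, truncated to
# pad_length. Returns the matrices plus an OOV flag per mention.
.mention_matrices <- function(token_lists, table, pad_length = NULL) {
  vocab <- rownames(table$vectors)
  lapply(token_lists, function(toks) {
    iv <- toks[toks %in% vocab]
    if (!is.null(pad_length) && length(iv) > pad_length) iv <- iv[seq_len(pad_length)]
    table$vectors[iv, , drop = FALSE]
  })
}

#' Train a model against a concept-vector space
#'
#' Minimizes the log-cosh regression loss between the model output and the
#' target concept's hierarchy-encoded vector with the Nadam optimizer,
#' minibatch shuffling and parameter initialization both controlled by
#' `config$seed`. Single-threaded and deterministic for a fixed seed.
#'
#' @param model An untrained `cn_model` from one of the builders (its
#'   parameters are re-initialized from `config$seed` so that a training run
#'   is a pure function of data + config).
#' @param examples Training-example data frame from [assemble_training()] /
#'   [labels_as_examples()] (`tokens` list-column + `target_concept`).
#' @param space A `cn_concept_space`; every target concept must be in it.
#' @param embeddings A `cn_embeddings` providing the input vectors.
#' @param config A `cn_config` whose architecture matches the model.
#' @return The trained `cn_model`, with `pad_length`, `concept_ids`,
#'   `loss_history` (one mean loss per epoch) and `config` attached.
#' @export
train_model <- function(model, examples, space, embeddings, config) {
  if (!inherits(model, "cn_model")) stop("model must be a cn_model")
  if (!identical(model$architecture, config$architecture)) {
    stop("config architecture (", config$architecture,
         ") does not match model (", model$architecture, ")")
  }
  if (nrow(examples) == 0L) stop("empty training-example list")
  if (model$N != length(space$ids)) {
    stop("model output dimension ", model$N, " != concept-space size ",
         length(space$ids))
  }
  if (model$D != embeddings$dim) {
    stop("model input dimension ", model$D, " != embedding dimension ",
         embeddings$dim)
  }
  missing <- setdiff(unique(examples$target_concept), space$ids)
  if (length(missing)) {
    stop("target concept(s) missing from concept space: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }

  Xall <- .mention_matrices(examples$tokens, embeddings)
  n_tok <- vapply(Xall, nrow, 1L)
  pad_length <- config$pad_length
  if (is.null(pad_length)) pad_length <- max(1L, n_tok)
  Xall <- lapply(Xall, function(X) {
    if (nrow(X) > pad_length) X[seq_len(pad_length), , drop = FALSE] else X
  })
  Yall <- space$M[examples$target_concept, , drop = FALSE]
  B_total <- length(Xall)
  N <- model$N

  set.seed(config$seed)
  # fresh Glorot initialization under the training seed
  model$params <- lapply(model$params, function(p) {
    if (is.matrix(p)) .glorot(nrow(p), ncol(p)) else numeric(length(p))
  })

  opt <- lapply(model$params, function(p) list(t = 0L, m = p * 0, v = p * 0))
  lr <- config$learning_rate
  act <- if (model$architecture != "slfnn") {
    .activation_fun(model$activation, model$leaky_slope)
  }
  avg_all <- t(vapply(Xall, function(X) {
    if (nrow(X) == 0L) numeric(model$D) else colMeans(X)
  }, numeric(model$D)))

  loss_history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(B_total)
    epoch_loss <- 0
    for (start in seq(1L, B_total, by = config$batch_size)) {
      S <- ord[start:min(start + config$batch_size - 1L, B_total)]
      B <- length(S)
      Y <- Yall[S, , drop = FALSE]
      grads <- lapply(model$params, function(p) p * 0)

      if (model$architecture == "slfnn") {
        A <- avg_all[S, , drop = FALSE]
        O <- A %*% t(model$params$W) + rep(model$params$b, each = B)
        diff <- O - Y
        G <- tanh(diff) / (N * B)
        grads$W <- t(G) %*% A
        grads$b <- colSums(G)
        epoch_loss <- epoch_loss + sum(.logcosh(diff)) / N
      } else if (model$architecture == "cnn") {
        for (i in seq_len(B)) {
          fw <- .forward_cnn_one(model$params$F, model$params$c, Xall[[S[i]]],
                                 model$filter_size, act)
          diff <- fw$out - Y[i, ]
          g <- tanh(diff) / (N * B)
          dz <- g * act$df(fw$z)
          grads$F <- grads$F + dz * fw$Xw[fw$idx, , drop = FALSE]
          grads$c <- grads$c + dz
          epoch_loss <- epoch_loss + sum(.logcosh(diff)) / N
        }
      } else {  # cnorm
        A <- avg_all[S, , drop = FALSE]
        O1 <- A %*% t(model$params$sW) + rep(model$params$sb, each = B)
        cnn_fw <- lapply(S, function(j) {
          .forward_cnn_one(model$params$cF, model$params$cc, Xall[[j]],
                           model$filter_size, act)
        })
        O2 <- t(vapply(cnn_fw, `[[`, numeric(N), "out"))
        O <- (O1 + O2) / 2
        diff <- O - Y
        G <- tanh(diff) / (N * B)
        G1 <- G / 2
        grads$sW <- t(G1) %*% A
        grads$sb <- colSums(G1)
        for (i in seq_len(B)) {
          dz <- G1[i, ] * act$df(cnn_fw[[i]]$z)
          grads$cF <- grads$cF + dz * cnn_fw[[i]]$Xw[cnn_fw[[i]]$idx, , drop = FALSE]
          grads$cc <- grads$cc + dz
        }
        epoch_loss <- epoch_loss + sum(.logcosh(diff)) / N
      }

      for (nm in names(model$params)) {
        stepped <- .nadam_step(model$params[[nm]], grads[[nm]], opt[[nm]], lr)
        model$params[[nm]] <- stepped$p
        opt[[nm]] <- stepped$st
      }
    }
    loss_history[[epoch]] <- epoch_loss / B_total
    if (!is.finite(loss_history[[epoch]])) {
      stop("training loss became non-finite at epoch ", epoch)
    }
  }

  model$trained <- TRUE
  model$pad_length <- pad_length
  model$concept_ids <- space$ids
  model$decay <- space$decay
  model$embedding_dim <- embeddings$dim
  model$config <- config
  model$loss_history <- loss_history
  model
}

#' Predict concept-space output vectors for mentions
#'
#' Runs the trained model's forward pass on each mention's token list,
#' using the embedding table and the pad length stored at training time.
#'
#' @param model A trained `cn_model`.
#' @param token_lists List of token vectors (one per mention, possibly
#'   named by mention id).
#' @param embeddings The `cn_embeddings` the model was trained with.
#' @return `length(token_lists) x N` matrix, one row per mention in input
#'   order (rownames = list names if present).
#' @export
predict_vectors <- function(model, token_lists, embeddings) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  if (model$D != embeddings$dim) {
    stop("embedding dimension ", embeddings$dim, " != model input dimension ",
         model$D)
  }
  if (length(token_lists) == 0L) {
    return(matrix(0, 0L, model$N, dimnames = list(NULL, model$concept_ids)))
  }
  Xlist <- .mention_matrices(token_lists, embeddings, model$pad_length)
  out <- .forward(model, Xlist)
  dimnames(out) <- list(names(token_lists), model$concept_ids)
  out
}

#' Serialize a model (config + weights + concept index) to a JSON archive
#'
#' @param model A `cn_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  payload <- unclass(model)
  payload$config <- if (!is.null(model$config)) unclass(model$config)
  payload$params <- lapply(model$params, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p)) else
      list(dim = NULL, data = as.numeric(p))
  })
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Load a model archive written by [save_model()]
#'
#' @param path Archive path.
#' @return The reconstructed `cn_model`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyVector = TRUE)
  payload$params <- lapply(payload$params, function(p) {
    if (!is.null(p$dim)) matrix(p$data, p$dim[[1L]], p$dim[[2L]]) else
      as.numeric(p$data)
  })
  if (!is.null(payload$config)) class(payload$config) <- "cn_config"
  structure(payload, class = "cn_model")
}
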