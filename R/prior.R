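#' @include tokenizer.R
NULL

.encode_corpus <- function(corpus, vocab) {
  lapply(corpus, function(s) {
    toks <- tokenize_smiles(s, vocab)
    match(c(vocab$begin_token, toks, vocab$end_token), vocab$tokens)
  })
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# ---------------------------------------------------------------------------
# n-gram back-off model: interpolated add-alpha counts, orders 1..k.
# Deterministic; "training" is a single counting pass.
# ---------------------------------------------------------------------------

.ngram_fit <- function(seqs, n_tokens, order, alpha) {
  counts <- vector("list", order)
  for (o in seq_len(order)) counts[[o]] <- new.env(parent = emptyenv())
  for (s in seqs) {
    n <- length(s)
    for (t in 2:n) {
      for (o in seq_len(order)) {
        if (t - o < 0L) next
        ctx <- if (o == 1L) "." else paste(s[(t - o + 1L):(t - 1L)], collapse = ",")
        e <- counts[[o]]
        cur <- e[[ctx]]
        if (is.null(cur)) cur <- numeric(n_tokens)
        cur[s[t]] <- cur[s[t]] + 1
        e[[ctx]] <- cur
      }
    }
  }
  list(counts = counts, order = order, alpha = alpha, n_tokens = n_tokens)
}

.ngram_dist <- function(fit, prefix_ids) {
  n_tokens <- fit$n_tokens
  p <- rep(1 / n_tokens, n_tokens)           # order-0 base: uniform
  for (o in seq_len(fit$order)) {
    if (length(prefix_ids) < o - 1L) break
    ctx <- if (o == 1L) "." else {
      paste(prefix_ids[(length(prefix_ids) - o + 2L):length(prefix_ids)],
            collapse = ",")
    }
    cnt <- fit$counts[[o]][[ctx]]
    if (is.null(cnt)) break
    p <- (cnt + fit$alpha * p) / (sum(cnt) + fit$alpha)
  }
  p
}

# ---------------------------------------------------------------------------
# single-layer Elman RNN over one-hot token inputs, trained by full BPTT with
# Adagrad. Small enough to train on desk-scale corpora in seconds.
# ---------------------------------------------------------------------------

.rnn_init <- function(n_tokens, hidden, seed) {
  set.seed(seed)
  sd0 <- 0.1
  list(
    Wxh = matrix(stats::rnorm(hidden * n_tokens, 0, sd0), hidden, n_tokens),
    Whh = matrix(stats::rnorm(hidden * hidden, 0, sd0), hidden, hidden),
    Why = matrix(stats::rnorm(n_tokens * hidden, 0, sd0), n_tokens, hidden),
    bh = numeric(hidden),
    by = numeric(n_tokens),
    hidden = hidden, n_tokens = n_tokens
  )
}

.rnn_forward <- function(par, ids) {
  # ids: full sequence incl. begin/end; predicts ids[2..n] from ids[1..n-1]
  n <- length(ids)
  H <- par$hidden
  hs <- matrix(0, H, n)        # hs[, t] = hidden after consuming ids[t]
  ps <- matrix(0, par$n_tokens, n - 1L)
  h <- numeric(H)
  nll <- 0
  for (t in seq_len(n - 1L)) {
    h <- tanh(par$Wxh[, ids[t]] + par$Whh %*% h + par$bh)
    hs[, t] <- h
    p <- .softmax(par$Why %*% h + par$by)
    ps[, t] <- p
    nll <- nll - log(p[ids[t + 1L]] + 1e-300)
  }
  list(hs = hs, ps = ps, nll = nll, n_pred = n - 1L)
}

.rnn_train <- function(par, seqs, epochs, lr, seed, holdout) {
  acc <- lapply(par[c("Wxh", "Whh", "Why", "bh", "by")], function(m) m * 0 + 1e-8)
  clip <- function(g) pmin(pmax(g, -5), 5)
  history <- vector("list", epochs)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample(seq_along(seqs))
    for (si in ord) {
      ids <- seqs[[si]]
      n <- length(ids)
      fw <- .rnn_forward(par, ids)
      gWxh <- par$Wxh * 0; gWhh <- par$Whh * 0; gWhy <- par$Why * 0
      gbh <- par$bh * 0; gby <- par$by * 0
      dh_next <- numeric(par$hidden)
      for (t in (n - 1L):1L) {
        dy <- fw$ps[, t]
        dy[ids[t + 1L]] <- dy[ids[t + 1L]] - 1
        gWhy <- gWhy + dy %o% fw$hs[, t]
        gby <- gby + dy
        dh <- as.numeric(crossprod(par$Why, dy)) + dh_next
        dz <- dh * (1 - fw$hs[, t]^2)
        gWxh[, ids[t]] <- gWxh[, ids[t]] + dz
        h_prev <- if (t > 1L) fw$hs[, t - 1L] else numeric(par$hidden)
        gWhh <- gWhh + dz %o% h_prev
        gbh <- gbh + dz
        dh_next <- as.numeric(crossprod(par$Whh, dz))
      }
      for (nm in c("Wxh", "Whh", "Why", "bh", "by")) {
        g <- clip(get(paste0("g", nm)) / fw$n_pred)
        acc[[nm]] <- acc[[nm]] + g^2
        par[[nm]] <- par[[nm]] - lr * g / sqrt(acc[[nm]])
      }
    }
    eval_nll <- function(ss) {
      tot <- 0; np <- 0
      for (ids in ss) { fw <- .rnn_forward(par, ids); tot <- tot + fw$nll; np <- np + fw$n_pred }
      tot / np
    }
    history[[ep]] <- tibble(
      epoch = ep,
      train_nll = eval_nll(seqs),
      holdout_nll = if (length(holdout) > 0L) eval_nll(holdout) else NA_real_
    )
  }
  list(par = par, history = dplyr::bind_rows(history))
}

#' Train the SMILES language-model prior
#'
#' Fits an autoregressive token model to a SMILES corpus. The model supplies
#' the selection prior of the tree search and the rollout sampler. Two
#' interchangeable implementations sit behind one contract (a conditional
#' next-token distribution plus a sampler): a single-layer recurrent network
#' over one-hot token embeddings (`method = "rnn"`, trained by
#' backpropagation through time with Adagrad), and a deterministic
#' interpolated n-gram model (`method = "ngram"`) that trains in one counting
#' pass and is the fast choice for testing — search correctness does not
#' depend on prior quality.
#'
#' @param corpus character vector of SMILES strings (all tokenizable).
#' @param method `"ngram"` or `"rnn"`.
#' @param vocab optional [smiles_vocabulary()]; built from the corpus if
#'   missing.
#' @param epochs training epochs (RNN only).
#' @param hidden hidden-state width (RNN only).
#' @param lr Adagrad learning rate (RNN only).
#' @param order maximal n-gram order (ngram only).
#' @param alpha additive-smoothing weight of the back-off interpolation
#'   (ngram only).
#' @param holdout optional character vector of held-out SMILES; per-epoch
#'   held-out NLL is recorded in `model$history`.
#' @param seed integer seed controlling initialization and epoch shuffling.
#' @return an object of class `ft_prior` with fields `method`, `vocab`,
#'   `fit`, `history` (per-epoch negative log-likelihoods), `nll_before`,
#'   `nll_after` and `meta`.
#' @export
train_prior <- function(corpus, method = c("ngram", "rnn"), vocab = NULL,
                        epochs = 5, hidden = 24, lr = 0.5,
                        order = 4, alpha = 0.2,
                        holdout = character(0), seed = 1) {
  method <- match.arg(method)
  if (length(corpus) == 0L) {
    abort("empty corpus", class = "fluortree_input_error")
  }
  if (is.null(vocab)) vocab <- smiles_vocabulary(corpus)
  seqs <- .encode_corpus(corpus, vocab)
  n_tokens <- length(vocab$tokens)
  n_pred <- sum(lengths(seqs) - 1L)
  nll_before <- log(n_tokens)                # untrained reference: uniform

  if (method == "ngram") {
    fit <- .ngram_fit(seqs, n_tokens, order, alpha)
    model <- structure(
      list(method = "ngram", vocab = vocab, fit = fit,
           history = tibble(epoch = 1L, train_nll = NA_real_,
                            holdout_nll = NA_real_),
           nll_before = nll_before,
           meta = list(corpus_size = length(corpus), seed = seed,
                       order = order, alpha = alpha)),
      class = "ft_prior")
    model$history$train_nll <- prior_nll(model, corpus)
    if (length(holdout) > 0L) model$history$holdout_nll <- prior_nll(model, holdout)
    model$nll_after <- model$history$train_nll
    return(model)
  }

  par <- .rnn_init(n_tokens, hidden, seed)
  ho_seqs <- if (length(holdout) > 0L) .encode_corpus(holdout, vocab) else list()
  tr <- .rnn_train(par, seqs, epochs = epochs, lr = lr, seed = seed,
                   holdout = ho_seqs)
  structure(
    list(method = "rnn", vocab = vocab, fit = tr$par, history = tr$history,
         nll_before = nll_before,
         nll_after = tr$history$train_nll[epochs],
         meta = list(corpus_size = length(corpus), epochs = epochs,
                     hidden = hidden, lr = lr, seed = seed)),
    class = "ft_prior")
}

#' @export
print.ft_prior <- function(x, ...) {
  cat("<ft_prior> ", x$method, " model, ", length(x$vocab$tokens),
      " tokens, corpus n = ", x$meta$corpus_size,
      ", per-token NLL = ", round(x$nll_after, 4), "\n", sep = "")
  invisible(x)
}

.prefix_ids <- function(model, prefix) {
  vocab <- model$vocab
  if (length(prefix) == 0L || prefix[1] != vocab$begin_token) {
    prefix <- c(vocab$begin_token, prefix)
  }
  ids <- match(prefix, vocab$tokens)
  if (anyNA(ids)) {
    abort(sprintf("token(s) not in vocabulary: %s",
                  paste(unique(prefix[is.na(ids)]), collapse = " ")),
          class = "fluortree_vocab_error")
  }
  ids
}

#' Conditional next-token distribution
#'
#' Deterministic probability vector over the vocabulary given a token
#' prefix. The begin sentinel is never emitted inside a sequence, so its
#' probability is clamped to zero and the vector renormalized.
#'
#' @param model an [train_prior()] model.
#' @param prefix character vector of tokens (the leading begin sentinel may
#'   be omitted).
#' @return named numeric vector over `model$vocab$tokens`, summing to 1.
#' @export
next_token_distribution <- function(model, prefix = character(0)) {
  stopifnot(inherits(model, "ft_prior"))
  ids <- .prefix_ids(model, prefix)
  p <- if (model$method == "ngram") {
    .ngram_dist(model$fit, ids)
  } else {
    par <- model$fit
    h <- numeric(par$hidden)
    for (t in seq_along(ids)) {
      h <- tanh(par$Wxh[, ids[t]] + par$Whh %*% h + par$bh)
    }
    as.numeric(.softmax(par$Why %*% h + par$by))
  }
  p[match(model$vocab$begin_token, model$vocab$tokens)] <- 0
  p <- p / sum(p)
  setNames(p, model$vocab$tokens)
}

#' Average per-token negative log-likelihood
#'
#' @param model an [train_prior()] model.
#' @param corpus character vector of SMILES strings.
#' @return mean negative log-likelihood per predicted token (nats).
#' @export
prior_nll <- function(model, corpus) {
  seqs <- .encode_corpus(corpus, model$vocab)
  tot <- 0; np <- 0
  for (ids in seqs) {
    for (t in seq_len(length(ids) - 1L)) {
      p <- next_token_distribution(model,
                                   model$vocab$tokens[ids[seq_len(t)]])
      tot <- tot - log(p[[ids[t + 1L]]] + 1e-300)
      np <- np + 1L
    }
  }
  tot / np
}

#' Sample a SMILES completion from the prior
#'
#' Autoregressively extends a token prefix until the end sentinel or
#' `max_len` tokens (sentinels included), then detokenizes. The returned
#' string may still fail chemical validation downstream; that is the
#' rollout's job to handle.
#'
#' @param model an [train_prior()] model.
#' @param prefix character vector of tokens (leading begin sentinel
#'   optional).
#' @param max_len maximum total token count, begin sentinel included.
#' @param seed optional integer; when given, sampling is reproducible and
#'   the caller's RNG state is untouched.
#' @return list with `smiles` (string), `tokens` (full token vector) and
#'   `terminated` (`FALSE` when `max_len` was hit before the end sentinel).
#' @export
sample_completion <- function(model, prefix = character(0), max_len = 82,
                              seed = NULL) {
  stopifnot(inherits(model, "ft_prior"))
  vocab <- model$vocab
  ids <- .prefix_ids(model, prefix)
  if (max_len < length(ids)) {
    abort("max_len shorter than the prefix", class = "fluortree_input_error")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  end_id <- match(vocab$end_token, vocab$tokens)
  terminated <- end_id %in% ids
  while (!terminated && length(ids) < max_len) {
    p <- next_token_distribution(model, vocab$tokens[ids])
    nxt <- sample.int(length(p), 1L, prob = p)
    ids <- c(ids, nxt)
    terminated <- nxt == end_id
  }
  tokens <- vocab$tokens[ids]
  list(smiles = detokenize(tokens, vocab), tokens = tokens,
       terminated = terminated)
}

#' Save / load a prior checkpoint
#'
#' The checkpoint is a self-describing serialized archive holding the
#' vocabulary, the fitted parameters and the training metadata.
#'
#' @param model an [train_prior()] model.
#' @param path checkpoint file path.
#' @return `read_prior` returns the `ft_prior`; `write_prior` returns
#'   `path` invisibly.
#' @export
write_prior <- function(model, path) {
  stopifnot(inherits(model, "ft_prior"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ft_prior")) {
    abort("not a prior checkpoint", class = "fluortree_input_error")
  }
  model
}
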