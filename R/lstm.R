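# Recurrent binary classifier for pseudo-sentences.
#
# Tokens are embedded, run through an LSTM (optionally stacked), and the
# hidden state at the last real token feeds a two-logit softmax head
# trained with cross-entropy and Adam.  Everything is implemented with
# plain matrix algebra; all randomness (initialization, shuffling) comes
# from one seeded generator so a run is reproducible bit-for-bit.

#' Build a token index from a corpus
#'
#' Ids are dense and assigned in first-occurrence order after the two
#' reserved ids (0 = padding, 1 = out-of-vocabulary).
#'
#' @param corpus List of `pseudo_sentence` objects.
#' @return A `vocab_index` object.
#' @export
build_vocab <- function(corpus) {
  tokens <- unique(unlist(lapply(corpus, function(s) s$tokens),
                          use.names = FALSE))
  if (is.null(tokens)) tokens <- character(0)
  ids <- stats::setNames(seq_along(tokens) + 1L, tokens)
  structure(list(ids = ids, pad_id = 0L, oov_id = 1L,
                 size = length(tokens) + 2L),
            class = "vocab_index")
}

#' Map tokens to integer ids
#'
#' @param vocab A `vocab_index`.
#' @param tokens Character vector; unseen tokens map to the OOV id.
#' @return Integer vector of ids.
#' @export
vocab_lookup <- function(vocab, tokens) {
  if (!length(tokens)) return(integer(0))
  out <- unname(vocab$ids[tokens])
  out[is.na(out)] <- vocab$oov_id
  out
}

# stable content hash (FNV-1a, 32 bit) for the vocab sidecar;
# 16-bit limbs keep every intermediate exactly representable
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  hi <- 2166136261 %/% 65536
  lo <- 2166136261 %% 65536
  for (b in bytes) {
    lo <- bitwXor(lo, b)
    tot <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
    hi <- tot %/% 65536
    lo <- tot %% 65536
  }
  sprintf("%04x%04x", hi, lo)
}

#' Classifier configuration
#'
#' @param embedding_dim,hidden_dim Embedding / LSTM hidden sizes
#'   (default 128).
#' @param layers Number of stacked LSTM layers (default 1).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param epochs Training epochs (default 200).
#' @param seed Integer seed for init, shuffling and any subsampling.
#' @param max_len Optional cap on sentence length (NULL = no
#'   truncation; sequences are padded per batch to the longest).
#' @return A `model_config` list.
#' @export
model_config <- function(embedding_dim = 128L, hidden_dim = 128L,
                         layers = 1L, learning_rate = 1e-3,
                         batch_size = 32L, epochs = 200L, seed = 1L,
                         max_len = NULL) {
  stopifnot(embedding_dim > 0, hidden_dim > 0, layers > 0,
            learning_rate > 0, batch_size > 0, epochs > 0)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim),
                 layers = as.integer(layers),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 max_len = max_len),
            class = "model_config")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.init_params <- function(V, cfg) {
  d <- cfg$embedding_dim; h <- cfg$hidden_dim
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -0.1, 0.1), nr, nc)
  p <- list(E = u(V, d))
  p$E[1L, ] <- 0  # padding row stays zero
  for (l in seq_len(cfg$layers)) {
    din <- if (l == 1L) d else h
    p[[paste0("W", l)]] <- u(din, 4L * h)
    p[[paste0("U", l)]] <- u(h, 4L * h)
    bias <- rep(0, 4L * h)
    bias[(h + 1L):(2L * h)] <- 1  # forget-gate bias
    p[[paste0("b", l)]] <- bias
  }
  p$Wo <- matrix(0, h, 2L)  # zero head: untrained logits are all equal
  p$bo <- rep(0, 2L)
  p
}

# forward pass over a padded id matrix; returns probabilities and, when
# wanted, the caches needed for backprop
.lstm_forward <- function(params, ids, len, cfg, keep_cache = FALSE) {
  B <- nrow(ids); T <- ncol(ids); h <- cfg$hidden_dim
  L <- cfg$layers
  hs <- lapply(seq_len(L), function(l) matrix(0, B, h))
  cs <- lapply(seq_len(L), function(l) matrix(0, B, h))
  H_last <- matrix(0, B, h)
  cache <- if (keep_cache) vector("list", T)
  for (t in seq_len(T)) {
    x <- params$E[ids[, t] + 1L, , drop = FALSE]
    step <- if (keep_cache) vector("list", L)
    for (l in seq_len(L)) {
      A <- x %*% params[[paste0("W", l)]] +
        hs[[l]] %*% params[[paste0("U", l)]]
      A <- sweep(A, 2L, params[[paste0("b", l)]], "+")
      i <- .sigmoid(A[, 1:h, drop = FALSE])
      f <- .sigmoid(A[, (h + 1):(2 * h), drop = FALSE])
      g <- tanh(A[, (2 * h + 1):(3 * h), drop = FALSE])
      o <- .sigmoid(A[, (3 * h + 1):(4 * h), drop = FALSE])
      c_new <- f * cs[[l]] + i * g
      tc <- tanh(c_new)
      h_new <- o * tc
      if (keep_cache) {
        step[[l]] <- list(x = x, h_prev = hs[[l]], c_prev = cs[[l]],
                          i = i, f = f, g = g, o = o, tc = tc)
      }
      cs[[l]] <- c_new
      hs[[l]] <- h_new
      x <- h_new
    }
    if (keep_cache) cache[[t]] <- step
    done <- which(len == t)
    if (length(done)) H_last[done, ] <- hs[[L]][done, , drop = FALSE]
  }
  logits <- sweep(H_last %*% params$Wo, 2L, params$bo, "+")
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m); e2 <- exp(logits[, 2] - m)
  probs <- e2 / (e1 + e2)  # P(label = 1)
  list(probs = probs, H_last = H_last, cache = cache, ids = ids,
       len = len)
}

.lstm_backward <- function(params, fwd, y, cfg) {
  B <- nrow(fwd$ids); T <- ncol(fwd$ids); h <- cfg$hidden_dim
  L <- cfg$layers
  probs2 <- cbind(1 - fwd$probs, fwd$probs)
  Y <- cbind(1 - y, y)
  dlogits <- (probs2 - Y) / B
  grads <- list(E = matrix(0, nrow(params$E), ncol(params$E)))
  for (l in seq_len(L)) {
    grads[[paste0("W", l)]] <- params[[paste0("W", l)]] * 0
    grads[[paste0("U", l)]] <- params[[paste0("U", l)]] * 0
    grads[[paste0("b", l)]] <- params[[paste0("b", l)]] * 0
  }
  grads$Wo <- t(fwd$H_last) %*% dlogits
  grads$bo <- colSums(dlogits)
  dHlast <- dlogits %*% t(params$Wo)
  dh_next <- lapply(seq_len(L), function(l) matrix(0, B, h))
  dc_next <- dh_next
  for (t in rev(seq_len(T))) {
    extra <- lapply(seq_len(L), function(l) NULL)
    at_end <- which(fwd$len == t)
    for (l in rev(seq_len(L))) {
      cc <- fwd$cache[[t]][[l]]
      dh <- dh_next[[l]]
      if (!is.null(extra[[l]])) dh <- dh + extra[[l]]
      if (l == L && length(at_end)) {
        dh[at_end, ] <- dh[at_end, , drop = FALSE] +
          dHlast[at_end, , drop = FALSE]
      }
      dc <- dc_next[[l]] + dh * cc$o * (1 - cc$tc^2)
      dai <- (dc * cc$g) * cc$i * (1 - cc$i)
      daf <- (dc * cc$c_prev) * cc$f * (1 - cc$f)
      dag <- (dc * cc$i) * (1 - cc$g^2)
      dao <- (dh * cc$tc) * cc$o * (1 - cc$o)
      dA <- cbind(dai, daf, dag, dao)
      grads[[paste0("W", l)]] <- grads[[paste0("W", l)]] +
        t(cc$x) %*% dA
      grads[[paste0("U", l)]] <- grads[[paste0("U", l)]] +
        t(cc$h_prev) %*% dA
      grads[[paste0("b", l)]] <- grads[[paste0("b", l)]] + colSums(dA)
      dx <- dA %*% t(params[[paste0("W", l)]])
      dh_next[[l]] <- dA %*% t(params[[paste0("U", l)]])
      dc_next[[l]] <- dc * cc$f
      if (l > 1L) {
        extra[[l - 1L]] <- dx
      } else {
        idv <- fwd$ids[, t]
        valid <- which(idv > 0L & fwd$len >= t)
        if (length(valid)) {
          agg <- rowsum(dx[valid, , drop = FALSE], group = idv[valid])
          rows <- as.integer(rownames(agg)) + 1L
          grads$E[rows, ] <- grads$E[rows, , drop = FALSE] + agg
        }
      }
    }
  }
  grads$E[1L, ] <- 0  # padding embedding frozen
  grads
}

.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params$E[1L, ] <- 0
  list(params = params, state = state)
}

.pad_batch <- function(seqs) {
  lens <- lengths(seqs)
  T <- max(lens, 1L)
  ids <- matrix(0L, length(seqs), T)
  for (b in seq_along(seqs)) {
    if (lens[b]) ids[b, seq_len(lens[b])] <- seqs[[b]]
  }
  list(ids = ids, len = lens)
}

.encode_samples <- function(samples, vocab, max_len = NULL) {
  lapply(samples, function(s) {
    ids <- vocab_lookup(vocab, s$tokens)
    if (!is.null(max_len) && length(ids) > max_len) {
      ids <- ids[seq_len(max_len)]
    }
    ids
  })
}

.eval_accuracy <- function(params, seqs, labels, cfg) {
  n <- length(seqs)
  preds <- integer(n)
  bs <- cfg$batch_size
  for (start in seq(1L, n, by = bs)) {
    idx <- start:min(start + bs - 1L, n)
    pb <- .pad_batch(seqs[idx])
    fw <- .lstm_forward(params, pb$ids, pb$len, cfg)
    preds[idx] <- as.integer(fw$probs >= 0.5)
  }
  pos <- labels == 1L
  c(acc_pos = if (any(pos)) mean(preds[pos] == 1L) else NaN,
    acc_neg = if (any(!pos)) mean(preds[!pos] == 0L) else NaN,
    acc_all = mean(preds == labels))
}

#' Train the LSTM pseudo-sentence classifier
#'
#' @param samples List of labeled `pseudo_sentence` objects (both
#'   classes must be present; empty sentences are allowed and padded).
#' @param cfg A [model_config()].
#' @param validation Optional held-out samples; the per-epoch accuracy
#'   history is computed on them (on the training samples otherwise).
#' @param vocab Optional pre-built [build_vocab()] index; built from
#'   `samples` when NULL.
#' @return A list with `model` (a `pcr_lstm` handle) and `history`
#'   (data.frame `epoch`, `acc_pos`, `acc_neg`, `acc_all`, `loss`).
#' @export
train_classifier <- function(samples, cfg = model_config(),
                             validation = NULL, vocab = NULL) {
  labels <- vapply(samples, function(s) s$label, integer(1))
  if (length(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(labels)) stop("all training samples must be labeled",
                          call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  if (is.null(vocab)) vocab <- build_vocab(samples)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  seqs <- .encode_samples(samples, vocab, cfg$max_len)
  eval_set <- if (is.null(validation)) {
    list(seqs = seqs, labels = labels)
  } else {
    list(seqs = .encode_samples(validation, vocab, cfg$max_len),
         labels = vapply(validation, function(s) s$label, integer(1)))
  }

  params <- .init_params(vocab$size, cfg)
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  n <- length(seqs)
  hist <- matrix(NA_real_, cfg$epochs, 4L)
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      pb <- .pad_batch(seqs[idx])
      fw <- .lstm_forward(params, pb$ids, pb$len, cfg, keep_cache = TRUE)
      y <- labels[idx]
      p1 <- pmin(pmax(fw$probs, 1e-12), 1 - 1e-12)
      ep_loss <- ep_loss - mean(ifelse(y == 1L, log(p1), log(1 - p1)))
      nb <- nb + 1L
      grads <- .lstm_backward(params, fw, y, cfg)
      step <- step + 1L
      upd <- .adam_step(params, grads, state, cfg$learning_rate, step)
      params <- upd$params
      state <- upd$state
    }
    acc <- .eval_accuracy(params, eval_set$seqs, eval_set$labels, cfg)
    hist[epoch, ] <- c(acc, ep_loss / nb)
  }
  history <- data.frame(epoch = seq_len(cfg$epochs),
                        acc_pos = hist[, 1], acc_neg = hist[, 2],
                        acc_all = hist[, 3], loss = hist[, 4])
  model <- structure(list(params = params, cfg = cfg, vocab = vocab,
                          vocab_hash = .fnv1a(names(vocab$ids))),
                     class = "pcr_lstm")
  list(model = model, history = history)
}

#' Predict PCR success for one pseudo-sentence
#'
#' @param model A trained `pcr_lstm` handle.
#' @param sentence A `pseudo_sentence` (the empty sentence is valid and
#'   scored from the padding-only input).
#' @return A list with `probability` (of PCR success) and `label`
#'   (1 iff probability >= 0.5).
#' @export
predict_sentence <- function(model, sentence) {
  res <- predict_samples(model, list(sentence))
  list(probability = res$probability[1], label = res$label[1])
}

#' Predict PCR success for a list of pseudo-sentences
#'
#' @param model A trained `pcr_lstm` handle.
#' @param samples List of `pseudo_sentence` objects.
#' @return A data.frame with columns `probability` and `label`.
#' @export
predict_samples <- function(model, samples) {
  if (!inherits(model, "pcr_lstm") || is.null(model$vocab)) {
    stop("model handle has no vocabulary", call. = FALSE)
  }
  seqs <- .encode_samples(samples, model$vocab, model$cfg$max_len)
  n <- length(seqs)
  probs <- numeric(n)
  bs <- model$cfg$batch_size
  for (start in seq(1L, n, by = bs)) {
    idx <- start:min(start + bs - 1L, n)
    pb <- .pad_batch(seqs[idx])
    fw <- .lstm_forward(model$params, pb$ids, pb$len, model$cfg)
    probs[idx] <- fw$probs
  }
  data.frame(probability = probs, label = as.integer(probs >= 0.5))
}

#' Save a trained classifier
#'
#' Writes the model handle as one opaque file plus a JSON sidecar
#' (`<path>.json`) with the configuration, vocabulary hash and seed.
#'
#' @param model A `pcr_lstm` handle.
#' @param path Checkpoint path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(config = unclass(model$cfg), vocab_hash = model$vocab_hash,
               seed = model$cfg$seed,
               package_version = as.character(utils::packageVersion("pcrlingo")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Load a classifier checkpoint
#'
#' @param path Checkpoint path written by [save_model()].
#' @return The `pcr_lstm` handle.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pcr_lstm")) stop("not a classifier checkpoint",
                                         call. = FALSE)
  model
}
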