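#' Configure the neural family-history classifier
#'
#' The model projects a note into a tokens x `encoder_dim` dense matrix
#' with a pluggable encoder, applies convolutions of several kernel
#' widths (ReLU, stride one), max-over-time pools each filter,
#' concatenates the pooled features in ascending width order, and maps
#' them through a fully connected layer with sigmoid outputs - one
#' probability per quintet category.  Training minimises mean per-label
#' binary cross-entropy with Adam.
#'
#' Encoders:
#' \describe{
#'   \item{`small_contextual`}{randomly initialised token embeddings
#'     followed by `context_layers` (default 2) window-3 convolutional
#'     mixing layers with ReLU and a residual connection, trained
#'     end-to-end.  The desk-scale default: a compact contextual encoder
#'     that needs no external weights.}
#'   \item{`static_vectors`}{plain trainable token embeddings (no
#'     context mixing); with the `cnn` head this is the word-vector-CNN
#'     comparator, with `fc` a bag-of-vectors baseline.}
#'   \item{`pretrained_contextual`}{an externally supplied, frozen
#'     per-token embedding table (`pretrained_embeddings`, a numeric
#'     matrix with token rownames) standing in for a large pretrained
#'     language model; optional plug-in, never required.}
#' }
#'
#' @param encoder one of `"small_contextual"`, `"static_vectors"`,
#'   `"pretrained_contextual"`.
#' @param encoder_dim embedding dimensionality.
#' @param context_layers context-mixing layers for `small_contextual`
#'   (<= 2 keeps the desk-scale budget).
#' @param kernel_widths convolution kernel widths (tokens).
#' @param filters_per_width filters per kernel width.
#' @param head `"cnn"` (multi-width convolutions) or `"fc"` (mean-pooled
#'   encoder output into the output layer).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param decision_threshold probability threshold for positive labels.
#' @param max_text_length token truncation length.
#' @param max_vocab vocabulary cap (most frequent training tokens).
#' @param split_fractions train/validation/test fractions (sum to 1).
#' @param group_by_patient keep all notes of a patient in one split
#'   (prevents cross-split leakage from repeated admissions).
#' @param lexicon_id lexicon used for tokenization.
#' @param pretrained_embeddings optional matrix for
#'   `pretrained_contextual`.
#' @param seed RNG seed (initialisation, shuffling, split).
#' @return List of class `fh_classifier_config`.
#' @export
classifier_config <- function(encoder = c("small_contextual",
                                          "static_vectors",
                                          "pretrained_contextual"),
                              encoder_dim = 32L,
                              context_layers = 2L,
                              kernel_widths = c(2L, 3L, 4L),
                              filters_per_width = 128L,
                              head = c("cnn", "fc"),
                              learning_rate = 1e-3,
                              batch_size = 16L,
                              epochs = 100L,
                              decision_threshold = 0.5,
                              max_text_length = 256L,
                              max_vocab = 5000L,
                              split_fractions = c(0.64, 0.16, 0.20),
                              group_by_patient = FALSE,
                              lexicon_id = "zh_default",
                              pretrained_embeddings = NULL,
                              seed = 1L) {
  encoder <- match.arg(encoder)
  head <- match.arg(head)
  kernel_widths <- sort(as.integer(kernel_widths))
  if (any(kernel_widths < 1L) || any(kernel_widths > max_text_length))
    stop("kernel widths must lie in [1, max_text_length]")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (decision_threshold <= 0 || decision_threshold >= 1)
    stop("decision_threshold must lie in (0, 1)")
  if (abs(sum(split_fractions) - 1) > 1e-9)
    stop("split_fractions must sum to 1")
  if (encoder == "pretrained_contextual" && is.null(pretrained_embeddings))
    stop("pretrained_contextual requires 'pretrained_embeddings'")
  structure(list(encoder = encoder, encoder_dim = as.integer(encoder_dim),
                 context_layers = as.integer(context_layers),
                 kernel_widths = kernel_widths,
                 filters_per_width = as.integer(filters_per_width),
                 head = head, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 decision_threshold = decision_threshold,
                 max_text_length = as.integer(max_text_length),
                 max_vocab = as.integer(max_vocab),
                 split_fractions = split_fractions,
                 group_by_patient = isTRUE(group_by_patient),
                 lexicon_id = lexicon_id,
                 pretrained_embeddings = pretrained_embeddings,
                 seed = as.integer(seed)),
            class = "fh_classifier_config")
}

# ---- parameter initialisation --------------------------------------------

#' Initialise convolution weights
#'
#' He-scaled Gaussian weights for the multi-width convolution bank, zero
#' biases.
#'
#' @param encoder_dim input row dimensionality.
#' @param kernel_widths integer widths.
#' @param filters_per_width filters per width.
#' @param seed RNG seed.
#' @return List (one element per width, ascending) of
#'   `list(width, W, b)` with `W` of shape `(width * encoder_dim) x
#'   filters_per_width`.
#' @export
init_conv_weights <- function(encoder_dim, kernel_widths, filters_per_width,
                              seed = 1L) {
  with_seed(seed, lapply(sort(as.integer(kernel_widths)), function(w) {
    fan_in <- w * encoder_dim
    list(width = w,
         W = matrix(stats::rnorm(fan_in * filters_per_width,
                                 sd = sqrt(2 / fan_in)),
                    fan_in, filters_per_width),
         b = numeric(filters_per_width))
  }))
}

init_params <- function(cfg, vocab_size) {
  d <- cfg$encoder_dim
  params <- list()
  if (cfg$encoder == "pretrained_contextual") {
    params$E <- cfg$pretrained_embeddings
    params$frozen_E <- TRUE
  } else {
    params$E <- matrix(stats::rnorm(vocab_size * d, sd = 0.1), vocab_size, d)
    params$frozen_E <- FALSE
  }
  if (cfg$encoder == "small_contextual") {
    params$ctx <- lapply(seq_len(cfg$context_layers), function(i)
      list(W = matrix(stats::rnorm(3 * d * d, sd = sqrt(2 / (3 * d)) * 0.5),
                      3 * d, d),
           b = numeric(d)))
  } else params$ctx <- list()
  if (cfg$head == "cnn") {
    params$conv <- lapply(cfg$kernel_widths, function(w) {
      fan_in <- w * d
      list(width = w,
           W = matrix(stats::rnorm(fan_in * cfg$filters_per_width,
                                   sd = sqrt(2 / fan_in)),
                      fan_in, cfg$filters_per_width),
           b = numeric(cfg$filters_per_width))
    })
    K <- length(cfg$kernel_widths) * cfg$filters_per_width
  } else {
    params$conv <- list()
    K <- d
  }
  params$U <- matrix(stats::rnorm(K * 5L, sd = sqrt(1 / K)), K, 5L)
  params$b_out <- numeric(5L)
  params
}

# ---- forward pieces -------------------------------------------------------

# stack sliding windows of `w` rows into one row each (row-major blocks)
window_rows <- function(X, w) {
  T <- nrow(X)
  do.call(cbind, lapply(0:(w - 1L), function(o)
    X[(1L + o):(T - w + 1L + o), , drop = FALSE]))
}

# window-3 with zero padding at both ends (same number of output rows)
window3_pad <- function(X) {
  d <- ncol(X); T <- nrow(X)
  Xp <- rbind(matrix(0, 1L, d), X, matrix(0, 1L, d))
  cbind(Xp[1:T, , drop = FALSE], Xp[2:(T + 1L), , drop = FALSE],
        Xp[3:(T + 2L), , drop = FALSE])
}

encode_ids <- function(params, ids, cache = FALSE) {
  X <- params$E[ids, , drop = FALSE]
  caches <- list()
  for (l in seq_along(params$ctx)) {
    lay <- params$ctx[[l]]
    Xw <- window3_pad(X)
    Z <- sweep(Xw %*% lay$W, 2L, lay$b, "+")
    H <- pmax(Z, 0)
    if (cache) caches[[l]] <- list(Xw = Xw, Z = Z)
    X <- X + H
  }
  if (cache) list(X = X, caches = caches) else X
}

#' Encode a note as a dense token matrix
#'
#' @param model a trained model from [train_classifier()] (or a list
#'   with `params`, `vocab`, `config`).
#' @param text one string.
#' @param note_id optional id used in the empty-input error message.
#' @return Numeric matrix, one row per (truncated) token.
#' @export
encode <- function(model, text, note_id = NULL) {
  lx <- read_lexicon(model$config$lexicon_id)
  ids <- text_to_ids(text, lx, model$vocab, model$config$max_text_length)
  if (!length(ids))
    stop("input error: empty text after tokenization",
         if (!is.null(note_id)) paste0(" (note ", note_id, ")") else "")
  encode_ids(model$params, ids)
}

#' Multi-width convolution + ReLU + max-over-time pooling
#'
#' Each filter produces `max over positions of ReLU(conv)`; per-width
#' feature blocks are concatenated in ascending width order.  A width
#' larger than the number of rows is skipped with a warning (its block
#' is omitted); alternatively pad the input to the largest width first
#' (`pad_to_min = TRUE`, the behaviour used during training).
#'
#' @param mat tokens x dim matrix.
#' @param weights conv weight bank from [init_conv_weights()].
#' @param pad_to_min pad `mat` with zero rows up to the largest width
#'   instead of skipping.
#' @return Numeric feature vector.
#' @export
conv_pool <- function(mat, weights, pad_to_min = FALSE) {
  widths <- vapply(weights, `[[`, 0L, "width")
  if (pad_to_min && nrow(mat) < max(widths))
    mat <- rbind(mat, matrix(0, max(widths) - nrow(mat), ncol(mat)))
  out <- lapply(weights, function(wt) {
    if (nrow(mat) < wt$width) {
      warning("input shorter than kernel width ", wt$width, "; width skipped")
      return(NULL)
    }
    A <- pmax(sweep(window_rows(mat, wt$width) %*% wt$W, 2L, wt$b, "+"), 0)
    apply(A, 2L, max)
  })
  unlist(out[!vapply(out, is.null, TRUE)], use.names = FALSE)
}

forward_note <- function(params, cfg, ids, cache = FALSE) {
  enc <- encode_ids(params, ids, cache = cache)
  X <- if (cache) enc$X else enc
  T_real <- nrow(X)
  conv_caches <- list()
  if (cfg$head == "cnn") {
    wmax <- max(cfg$kernel_widths)
    if (T_real < wmax)
      X <- rbind(X, matrix(0, wmax - T_real, ncol(X)))
    feats <- lapply(params$conv, function(wt) {
      Xw <- window_rows(X, wt$width)
      C <- sweep(Xw %*% wt$W, 2L, wt$b, "+")
      A <- pmax(C, 0)
      r <- max.col(t(A), ties.method = "first")
      f <- A[cbind(r, seq_along(r))]
      list(f = f, r = r, Xw = Xw)
    })
    h <- unlist(lapply(feats, `[[`, "f"), use.names = FALSE)
    if (cache) conv_caches <- feats
  } else {
    h <- colMeans(X)
  }
  logits <- drop(crossprod(params$U, h)) + params$b_out
  p <- 1 / (1 + exp(-logits))
  if (!cache) return(p)
  list(p = p, h = h, X = X, T_real = T_real, enc = enc,
       conv_caches = conv_caches)
}

# ---- gradients ------------------------------------------------------------

zero_like <- function(params) {
  g <- list(E = params$E * 0,
            ctx = lapply(params$ctx, function(l)
              list(W = l$W * 0, b = l$b * 0)),
            conv = lapply(params$conv, function(l)
              list(W = l$W * 0, b = l$b * 0)),
            U = params$U * 0, b_out = params$b_out * 0)
  g
}

backward_note <- function(params, cfg, ids, y, grads) {
  fw <- forward_note(params, cfg, ids, cache = TRUE)
  p <- fw$p
  dl <- (p - y) / 5                       # d(mean BCE)/d logits
  grads$U <- grads$U + outer(fw$h, dl)
  grads$b_out <- grads$b_out + dl
  dh <- drop(params$U %*% dl)
  Tp <- nrow(fw$X); d <- ncol(fw$X)
  dX <- matrix(0, Tp, d)
  if (cfg$head == "cnn") {
    off <- 0L
    for (k in seq_along(params$conv)) {
      wt <- params$conv[[k]]
      cc <- fw$conv_caches[[k]]
      nf <- length(cc$f)
      dhk <- dh[(off + 1L):(off + nf)]
      off <- off + nf
      act <- which(cc$f > 0 & dhk != 0)
      if (length(act)) {
        coef <- dhk[act]
        Xr <- cc$Xw[cc$r[act], , drop = FALSE]
        grads$conv[[k]]$W[, act] <- grads$conv[[k]]$W[, act] +
          t(Xr * coef)
        grads$conv[[k]]$b[act] <- grads$conv[[k]]$b[act] + coef
        w <- wt$width
        for (m in seq_along(act)) {
          j <- act[m]
          rows <- cc$r[j]:(cc$r[j] + w - 1L)
          dX[rows, ] <- dX[rows, ] +
            coef[m] * matrix(wt$W[, j], w, d, byrow = TRUE)
        }
      }
    }
  } else {
    dX <- dX + matrix(dh / Tp, Tp, d, byrow = TRUE)
  }
  # context layers (reverse order)
  if (length(params$ctx)) {
    dX_enc <- dX[seq_len(fw$T_real), , drop = FALSE]
    for (l in rev(seq_along(params$ctx))) {
      lay <- params$ctx[[l]]
      cc <- fw$enc$caches[[l]]
      dZ <- dX_enc * (cc$Z > 0)
      grads$ctx[[l]]$W <- grads$ctx[[l]]$W + crossprod(cc$Xw, dZ)
      grads$ctx[[l]]$b <- grads$ctx[[l]]$b + colSums(dZ)
      dXw <- dZ %*% t(lay$W)
      T <- nrow(dZ)
      dXp <- matrix(0, T + 2L, d)
      for (o in 0:2)
        dXp[(1L + o):(T + o), ] <- dXp[(1L + o):(T + o), ] +
          dXw[, (o * d + 1L):(o * d + d), drop = FALSE]
      dX_enc <- dX_enc + dXp[2:(T + 1L), , drop = FALSE]
    }
    dX_emb <- dX_enc
  } else {
    dX_emb <- dX[seq_len(fw$T_real), , drop = FALSE]
  }
  if (!params$frozen_E) {
    agg <- rowsum(dX_emb, group = ids)
    rid <- as.integer(rownames(agg))
    grads$E[rid, ] <- grads$E[rid, ] + agg
  }
  attr(grads, "loss") <- -mean(y * log(pmax(p, 1e-12)) +
                                 (1 - y) * log(pmax(1 - p, 1e-12)))
  grads
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_apply <- function(x, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
  list(x = x - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  upd <- function(path_get, path_set) {
    r <- adam_apply(path_get(params), path_get(grads),
                    path_get(state$m), path_get(state$v), lr, state$t)
    params <<- path_set(params, r$x)
    state$m <<- path_set(state$m, r$m)
    state$v <<- path_set(state$v, r$v)
  }
  if (!params$frozen_E)
    upd(function(p) p$E, function(p, v) { p$E <- v; p })
  for (l in seq_along(params$ctx)) {
    upd(function(p) p$ctx[[l]]$W, function(p, v) { p$ctx[[l]]$W <- v; p })
    upd(function(p) p$ctx[[l]]$b, function(p, v) { p$ctx[[l]]$b <- v; p })
  }
  for (k in seq_along(params$conv)) {
    upd(function(p) p$conv[[k]]$W, function(p, v) { p$conv[[k]]$W <- v; p })
    upd(function(p) p$conv[[k]]$b, function(p, v) { p$conv[[k]]$b <- v; p })
  }
  upd(function(p) p$U, function(p, v) { p$U <- v; p })
  upd(function(p) p$b_out, function(p, v) { p$b_out <- v; p })
  list(params = params, state = state)
}

# ---- vocabulary and tokenization -----------------------------------------

build_vocab <- function(texts, lexicon, max_vocab) {
  toks <- unlist(lapply(texts, function(t) segment(t, lexicon)$token))
  freq <- sort(table(toks), decreasing = TRUE)
  keep <- utils::head(names(freq), max_vocab - 1L)
  c("<unk>", keep)
}

text_to_ids <- function(text, lexicon, vocab, max_len) {
  toks <- segment(text, lexicon)$token
  if (length(toks) > max_len) toks <- toks[seq_len(max_len)]
  ids <- match(toks, vocab)
  ids[is.na(ids)] <- 1L
  ids
}

# ---- training -------------------------------------------------------------

#' Train the neural family-history classifier
#'
#' Splits the corpus into train/validation/test, builds the vocabulary
#' from the training texts, and optimises mean per-label binary
#' cross-entropy with Adam.  After every epoch the validation micro-F1
#' is recorded; the returned parameters are those of the best validation
#' epoch.  Fully reproducible for a fixed config seed.
#'
#' @param notes list of admission-note records with `gold` annotations.
#' @param config an `fh_classifier_config`.
#' @param split optional precomputed split (list of train/validation/
#'   test note-id vectors, as from [split_dataset()]); by default one is
#'   drawn from the config seed.
#' @return List of class `fh_model`: `config`, `params`, `vocab`,
#'   `label_order`, `training_log` (per-epoch loss and validation
#'   micro-F1), `best_epoch`, `split`.
#' @export
train_classifier <- function(notes, config, split = NULL) {
  if (!length(notes)) stop("input error: empty corpus")
  lx <- read_lexicon(config$lexicon_id)
  note_ids <- vapply(notes, `[[`, "", "note_id")
  y_all <- do.call(rbind, lapply(notes, function(n)
    unclass(as_fh_label(n$gold$label))))
  rownames(y_all) <- note_ids
  if (all(y_all == 0L))
    stop("input error: corpus has no positive note for any label")
  if (is.null(split))
    split <- split_dataset(notes, fractions = config$split_fractions,
                           seed = derive_seed(config$seed, "split"),
                           group_by_patient = config$group_by_patient)
  tr <- match(split$train, note_ids)
  va <- match(split$validation, note_ids)

  zero_pos <- colnames(y_all)[colSums(
    y_all[tr, , drop = FALSE]) == 0L]
  if (length(zero_pos))
    warning("label(s) with zero positives in training data: ",
            paste(zero_pos, collapse = ", "), "; still trained")

  texts <- vapply(notes, `[[`, "", "text")
  vocab <- build_vocab(texts[tr], lx, config$max_vocab)
  ids_all <- lapply(seq_along(notes), function(i) {
    ids <- text_to_ids(texts[i], lx, vocab, config$max_text_length)
    if (!length(ids))
      stop("input error: empty text after tokenization (note ",
           note_ids[i], ")")
    ids
  })

  with_seed(derive_seed(config$seed, "train"), {
    params <- init_params(config, length(vocab))
    state <- adam_init(params)
    best <- list(f1 = -1, epoch = 0L, params = params)
    log <- data.frame(epoch = integer(), mean_loss = numeric(),
                      val_micro_f1 = numeric())
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr)
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        grads <- zero_like(params)
        bl <- 0
        for (i in batch) {
          grads <- backward_note(params, config, ids_all[[i]],
                                 y_all[i, ], grads)
          bl <- bl + attr(grads, "loss")
        }
        grads <- rapply(grads, function(g) g / length(batch),
                        how = "replace")
        st <- adam_step(params, grads, state, config$learning_rate)
        params <- st$params; state <- st$state
        losses <- c(losses, bl / length(batch))
      }
      val_p <- do.call(rbind, lapply(va, function(i)
        forward_note(params, config, ids_all[[i]])))
      val_lab <- (val_p >= config$decision_threshold) + 0L
      vf1 <- aggregate_metrics(
        confusion(val_lab, y_all[va, , drop = FALSE]), "micro")["f1"]
      log <- rbind(log, data.frame(epoch = ep, mean_loss = mean(losses),
                                   val_micro_f1 = unname(vf1)))
      if (vf1 > best$f1) best <- list(f1 = vf1, epoch = ep, params = params)
    }
    structure(list(config = config, params = best$params, vocab = vocab,
                   label_order = FH_CODES, training_log = log,
                   best_epoch = best$epoch, split = split),
              class = "fh_model")
  })
}

#' Predict family-history probabilities for notes
#'
#' @param model an `fh_model` from [train_classifier()].
#' @param notes list of admission-note records (or a character vector of
#'   texts).
#' @return n x 5 matrix of probabilities in (0, 1), columns in
#'   [FH_CODES] order, rownames = note ids when available.
#' @export
predict_proba <- function(model, notes) {
  if (!inherits(model, "fh_model")) stop("state error: untrained model")
  lx <- read_lexicon(model$config$lexicon_id)
  if (is.character(notes))
    notes <- lapply(seq_along(notes), function(i)
      list(note_id = paste0("text_", i), text = notes[i]))
  p <- do.call(rbind, lapply(notes, function(n) {
    ids <- text_to_ids(n$text, lx, model$vocab,
                       model$config$max_text_length)
    if (!length(ids))
      stop("input error: empty text after tokenization (note ",
           n$note_id, ")")
    forward_note(model$params, model$config, ids)
  }))
  colnames(p) <- FH_CODES
  rownames(p) <- vapply(notes, `[[`, "", "note_id")
  p
}

#' Threshold probabilities into quintet labels
#'
#' @param proba matrix from [predict_proba()].
#' @param threshold decision threshold (default 0.5).
#' @return 0/1 integer matrix of the same shape.
#' @export
predict_labels <- function(proba, threshold = 0.5) {
  (proba >= threshold) + 0L
}

#' Grid search over training hyper-parameters
#'
#' Evaluates every configuration on the test split over `runs`
#' independent training runs with the same data split, summarises each
#' metric as mean and sd across runs, and ranks configurations by mean
#' test micro-F1 (ties broken by grid order).
#'
#' @param notes corpus with gold annotations.
#' @param base_config an `fh_classifier_config` providing everything the
#'   grid does not vary.
#' @param grid data.frame of hyper-parameter combinations (default the
#'   learning-rate x batch-size grid `{1e-4, 1e-5} x {16, 32}`).
#' @param runs independent runs per configuration (default 5).
#' @return List with `ranking` (data.frame: grid columns, mean/sd test
#'   micro-F1, rank), `reports` (per-config [aggregate_runs()] tables)
#'   and `models` (last run's model per config).
#' @export
grid_search <- function(notes, base_config,
                        grid = expand.grid(learning_rate = c(1e-4, 1e-5),
                                           batch_size = c(16L, 32L)),
                        runs = 5L) {
  if (!nrow(grid)) stop("grid must contain at least one configuration")
  split <- split_dataset(notes, fractions = base_config$split_fractions,
                         seed = derive_seed(base_config$seed, "split"),
                         group_by_patient = base_config$group_by_patient)
  note_ids <- vapply(notes, `[[`, "", "note_id")
  te <- match(split$test, note_ids)
  gold_te <- do.call(rbind, lapply(notes[te], function(n)
    unclass(as_fh_label(n$gold$label))))
  rownames(gold_te) <- split$test

  reports <- vector("list", nrow(grid))
  models <- vector("list", nrow(grid))
  mean_f1 <- numeric(nrow(grid))
  sd_f1 <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    cfg <- base_config
    for (nm in names(grid)) cfg[[nm]] <- grid[gi, nm]
    run_vecs <- vector("list", runs)
    for (r in seq_len(runs)) {
      cfg$seed <- derive_seed(base_config$seed, sprintf("grid%d_run%d", gi, r))
      model <- train_classifier(notes, cfg, split = split)
      proba <- predict_proba(model, notes[te])
      lab <- predict_labels(proba, cfg$decision_threshold)
      run_vecs[[r]] <- report_vector(
        metric_report(lab, gold_te, scores = proba))
      models[[gi]] <- model
    }
    agg <- aggregate_runs(do.call(rbind, run_vecs))
    reports[[gi]] <- agg
    mean_f1[gi] <- agg$mean[agg$metric == "micro_f1"]
    sd_f1[gi] <- agg$sd[agg$metric == "micro_f1"]
  }
  ranking <- cbind(grid,
                   mean_test_micro_f1 = mean_f1, sd_test_micro_f1 = sd_f1)
  ord <- order(-mean_f1, seq_len(nrow(grid)))   # stable tie-break
  ranking <- ranking[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  row.names(ranking) <- NULL
  list(ranking = ranking, reports = reports, models = models, split = split)
}

#' Combine model and rule labels (hybrid post-filter)
#'
#' Deterministic per-note, per-label combination of the thresholded
#' model output with the rule annotator's labels.  `rule_and` keeps a
#' positive only when model and rules agree (the precision-oriented
#' hybrid); `rule_or` takes the union; `model_only` is the identity on
#' the thresholded model labels.
#'
#' @param model_labels 0/1 matrix (or probabilities, thresholded at
#'   `threshold`).
#' @param rule_labels 0/1 matrix aligned with `model_labels`.
#' @param policy `"rule_and"`, `"rule_or"` or `"model_only"`.
#' @param threshold applied when `model_labels` is not already binary.
#' @return 0/1 integer matrix.
#' @export
hybrid_postfilter <- function(model_labels, rule_labels,
                              policy = c("model_only", "rule_and", "rule_or"),
                              threshold = 0.5) {
  if (is.character(policy) && length(policy) == 1L &&
      !policy %in% c("model_only", "rule_and", "rule_or"))
    stop("configuration error: unknown policy '", policy, "'")
  policy <- match.arg(policy)
  m <- if (all(model_labels %in% c(0, 1))) model_labels + 0L
       else predict_labels(model_labels, threshold)
  switch(policy,
         model_only = m,
         rule_and = (m == 1L & rule_labels == 1L) + 0L,
         rule_or = (m == 1L | rule_labels == 1L) + 0L)
}
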