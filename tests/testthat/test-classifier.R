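toy_corpus <- function() clean_corpus(80, seed = 5, lexicon_id = "debug_en",
                                      rate = 0.25, admissions_lambda = 0)

toy_config <- function(...) {
  args <- utils::modifyList(
    list(encoder = "static_vectors", encoder_dim = 16L,
         filters_per_width = 16L, epochs = 25L, learning_rate = 5e-3,
         batch_size = 8L, lexicon_id = "debug_en", seed = 2L),
    list(...))
  do.call(classifier_config, args)
}

test_that("config invariants are enforced", {
  expect_error(classifier_config(kernel_widths = c(0, 2)), "kernel widths")
  expect_error(classifier_config(learning_rate = 0), "learning_rate")
  expect_error(classifier_config(decision_threshold = 1), "decision_threshold")
  expect_error(classifier_config(encoder = "pretrained_contextual"),
               "pretrained_embeddings")
})

test_that("conv_pool obeys the shape contract", {
  wts <- init_conv_weights(8L, c(2, 3, 4), 128L, seed = 1)
  mat <- matrix(rnorm(10 * 8), 10, 8)
  expect_length(conv_pool(mat, wts), 3 * 128)
})

test_that("an all-zero matrix with zero biases pools to zero features", {
  wts <- init_conv_weights(8L, c(2, 3), 16L, seed = 1)
  expect_identical(conv_pool(matrix(0, 6, 8), wts), rep(0, 2 * 16))
})

test_that("a width-1 identity filter max-pools to the column maximum", {
  wts <- list(list(width = 1L, W = matrix(1, 1, 1), b = 0))
  expect_identical(conv_pool(matrix(c(3, -1, 2), 3, 1), wts), 3)
})

test_that("too-short inputs skip the width with a warning unless padded", {
  wts <- init_conv_weights(4L, c(2, 5), 8L, seed = 1)
  mat <- matrix(rnorm(3 * 4), 3, 4)
  expect_warning(out <- conv_pool(mat, wts), "width skipped")
  expect_length(out, 8)
  expect_length(conv_pool(mat, wts, pad_to_min = TRUE), 16)
})

test_that("zero-row padding never decreases a max-pooled feature", {
  set.seed(6)
  wts <- init_conv_weights(6L, c(2, 3), 12L, seed = 3)
  for (i in 1:20) {
    mat <- matrix(rnorm(8 * 6), 8, 6)
    base <- conv_pool(mat, wts)
    padded <- conv_pool(rbind(mat, matrix(0, 3, 6)), wts)
    expect_true(all(padded >= base - 1e-12))
  }
})

test_that("encoding is deterministic, truncating and OOV-safe", {
  co <- toy_corpus()
  cfg <- toy_config(epochs = 1L, max_text_length = 12L)
  m <- suppressWarnings(train_classifier(co$notes, cfg))
  tx <- co$notes[[1]]$text
  expect_identical(encode(m, tx), encode(m, tx))
  expect_identical(nrow(encode(m, tx)), 12L)
  # an out-of-vocabulary token maps to the unknown row
  oov <- encode(m, "zzzunseen")
  expect_equal(oov[1, ], m$params$E[1, ])
  expect_error(encode(m, "", note_id = "N9"), "N9")
})

test_that("zero output weights give probability one half everywhere", {
  co <- toy_corpus()
  cfg <- toy_config(epochs = 1L)
  m <- suppressWarnings(train_classifier(co$notes, cfg))
  m$params$U[] <- 0
  m$params$b_out[] <- 0
  p <- predict_proba(m, co$notes[1:3])
  expect_true(all(p == 0.5))
  expect_identical(unname(predict_labels(p, 0.5)),
                   matrix(1L, 3, 5))
  # thresholding contract on an explicit probability row
  q <- matrix(c(0.9, 0.2, 0.6, 0.1, 0.4), 1, 5,
              dimnames = list("n", FH_CODES))
  expect_identical(as.integer(predict_labels(q, 0.5)), c(1L, 0L, 1L, 0L, 0L))
})

test_that("training splits 100 notes into 64/16/20", {
  co <- clean_corpus(100, seed = 31, lexicon_id = "debug_en", rate = 0.3,
                     admissions_lambda = 0)
  cfg <- toy_config(epochs = 1L)
  m <- suppressWarnings(train_classifier(co$notes, cfg))
  expect_identical(lengths(m$split)[c("train", "validation", "test")],
                   c(train = 64L, validation = 16L, test = 20L))
})

test_that("a separable toy corpus is learned to training micro-F1 1", {
  co <- toy_corpus()
  m <- suppressWarnings(train_classifier(co$notes, toy_config(epochs = 60L)))
  ids <- vapply(co$notes, `[[`, "", "note_id")
  tr <- match(m$split$train, ids)
  lab <- predict_labels(predict_proba(m, co$notes[tr]))
  f1 <- aggregate_metrics(confusion(lab, gold_matrix(co$notes[tr])),
                          "micro")["f1"]
  expect_equal(unname(f1), 1)
  expect_lte(m$best_epoch, 100L)
})

test_that("training is reproducible for a fixed seed", {
  co <- toy_corpus()
  cfg <- toy_config(epochs = 5L)
  m1 <- suppressWarnings(train_classifier(co$notes, cfg))
  m2 <- suppressWarnings(train_classifier(co$notes, cfg))
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$params, m2$params)
})

test_that("labels without training positives are warned about", {
  co <- toy_corpus()
  # erase one category from all gold labels
  for (i in seq_along(co$notes)) {
    l <- unclass(co$notes[[i]]$gold$label); l["F29"] <- 0L
    co$notes[[i]]$gold$label <- as_fh_label(l)
  }
  expect_warning(train_classifier(co$notes, toy_config(epochs = 1L)),
                 "F29")
})

test_that("the hyper-parameter grid is evaluated and ranked stably", {
  co <- toy_corpus()
  base <- toy_config(epochs = 2L)
  gr <- grid_search(co$notes, base,
                    grid = expand.grid(learning_rate = c(5e-3, 1e-3),
                                       batch_size = 8L),
                    runs = 2L)
  expect_identical(nrow(gr$ranking), 2L)
  expect_identical(gr$ranking$rank, 1:2)
  expect_true(all(diff(gr$ranking$mean_test_micro_f1) <= 0))
  single <- grid_search(co$notes, base,
                        grid = data.frame(learning_rate = 5e-3), runs = 2L)
  expect_identical(nrow(single$ranking), 1L)
})

test_that("the paper-style grid has four cells", {
  grid <- expand.grid(learning_rate = c(1e-4, 1e-5), batch_size = c(16L, 32L))
  expect_identical(nrow(grid), 4L)
})

test_that("the hybrid post-filter combines model and rule labels", {
  m <- matrix(c(1, 0, 1, 0, 0), 1, 5, dimnames = list("n", FH_CODES))
  r0 <- m * 0L
  r1 <- matrix(c(0, 1, 1, 0, 0), 1, 5, dimnames = list("n", FH_CODES))
  expect_identical(unname(hybrid_postfilter(m, r0, "rule_and")[1, ]),
                   rep(0L, 5))
  expect_identical(hybrid_postfilter(m, r1, "model_only"), m + 0L)
  expect_identical(unname(hybrid_postfilter(m, r1, "rule_or")[1, ]),
                   c(1L, 1L, 1L, 0L, 0L))
  expect_error(hybrid_postfilter(m, r1, "nope"), "unknown policy")
})

test_that("prediction requires a trained model", {
  expect_error(predict_proba(list(), "text"), "untrained")
})
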