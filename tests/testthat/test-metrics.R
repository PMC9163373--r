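# 4-note hand-enumerated fixture: F20 has TP=2 FP=1 FN=0,
# F32 has TP=1 FP=0 FN=1, all other labels empty
fixture_pred <- rbind(c(1, 1, 0, 0, 0),
                      c(1, 0, 0, 0, 0),
                      c(1, 0, 0, 0, 0),
                      c(0, 0, 0, 0, 0))
fixture_gold <- rbind(c(1, 1, 0, 0, 0),
                      c(1, 0, 0, 0, 0),
                      c(0, 1, 0, 0, 0),
                      c(0, 0, 0, 0, 0))
dimnames(fixture_pred) <- dimnames(fixture_gold) <-
  list(sprintf("N%d", 1:4), FH_CODES)

test_that("confusion counts match the hand-enumerated fixture", {
  cc <- confusion(fixture_pred, fixture_gold)
  expect_identical(cc$TP, c(2L, 1L, 0L, 0L, 0L))
  expect_identical(cc$FP, c(1L, 0L, 0L, 0L, 0L))
  expect_identical(cc$FN, c(0L, 1L, 0L, 0L, 0L))
  expect_true(all(cc$TP + cc$FP + cc$FN + cc$TN == 4L))
})

test_that("perfect and all-negative predictions produce degenerate counts", {
  cc <- confusion(fixture_gold, fixture_gold)
  expect_true(all(cc$FP == 0L) && all(cc$FN == 0L))
  zero <- fixture_gold * 0L
  cc0 <- confusion(zero, zero)
  expect_true(all(cc0$TN == 4L))
})

test_that("id mismatches are reported with the offending ids", {
  bad <- fixture_pred
  rownames(bad)[1] <- "NX"
  expect_error(confusion(bad, fixture_gold), "NX")
})

test_that("micro aggregation pools counts before the ratio", {
  mi <- aggregate_metrics(confusion(fixture_pred, fixture_gold), "micro")
  expect_equal(unname(mi["precision"]), 0.75)
  expect_equal(unname(mi["recall"]), 0.75)
  expect_equal(unname(mi["f1"]), 0.75)
})

test_that("micro equals macro when labels carry identical counts", {
  cc <- data.frame(label = FH_CODES, TP = rep(3L, 5), FP = rep(1L, 5),
                   FN = rep(2L, 5), TN = rep(4L, 5))
  expect_equal(aggregate_metrics(cc, "micro"),
               aggregate_metrics(cc, "macro"))
})

test_that("perfect predictions score 1 everywhere", {
  cc <- confusion(fixture_gold, fixture_gold)
  expect_equal(unname(aggregate_metrics(cc, "micro")), c(1, 1, 1))
  expect_equal(accuracy(fixture_gold, fixture_gold, "per_decision"), 1)
  expect_equal(accuracy(fixture_gold, fixture_gold, "subset"), 1)
})

test_that("accuracy modes match hand counts and per-decision dominates subset", {
  pred <- rbind(c(1, 0, 0, 0, 0), c(0, 0, 0, 0, 0))
  gold <- rbind(c(0, 0, 0, 0, 0), c(0, 0, 0, 0, 0))
  expect_equal(accuracy(pred, gold, "per_decision"), 0.9)
  expect_equal(accuracy(pred, gold, "subset"), 0.5)
  set.seed(42)
  for (i in 1:50) {
    p <- random_label_matrix(8); g <- random_label_matrix(8)
    expect_gte(accuracy(p, g, "per_decision"), accuracy(p, g, "subset"))
  }
})

test_that("aggregate metrics reproduce a brute-force recount", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:15, 1)
    p <- random_label_matrix(n); g <- random_label_matrix(n)
    cc <- confusion(p, g)
    # naive per-label loop recount
    for (j in seq_len(5)) {
      expect_identical(cc$TP[j], sum(p[, j] == 1 & g[, j] == 1))
      expect_identical(cc$FP[j], sum(p[, j] == 1 & g[, j] == 0))
      expect_identical(cc$FN[j], sum(p[, j] == 0 & g[, j] == 1))
    }
    mi <- aggregate_metrics(cc, "micro")
    tp <- sum(cc$TP); fp <- sum(cc$FP); fn <- sum(cc$FN)
    if (tp + fp > 0)
      expect_equal(unname(mi["recall"]), tp / (tp + fn))
  }
})

test_that("ROC endpoints and degenerate labels behave as specified", {
  g <- c(1, 1, 0, 0, 1)
  r <- roc(as.numeric(g), g)
  expect_equal(r$auc, 1)
  expect_equal(roc(rep(0.3, 5), g)$auc, 0.5)
  expect_true(roc(runif(4), c(1, 1, 1, 1))$degenerate)
})

test_that("trapezoid AUC equals the pairwise concordance statistic", {
  set.seed(19)
  for (i in 1:20) {
    n <- 50
    g <- rbinom(n, 1, 0.4)
    if (sum(g) == 0 || sum(g) == n) next
    s <- round(runif(n), 2)          # rounded scores force ties
    a <- roc(s, g)$auc
    pos <- s[g == 1]; neg <- s[g == 0]
    conc <- outer(pos, neg, function(x, y)
      (x > y) + 0.5 * (x == y))
    expect_equal(a, mean(conc), tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  g <- rbinom(80, 1, 0.3); s <- runif(80)
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(g, s, quiet = TRUE, direction = "<"))))
  expect_equal(roc(s, g)$auc, ref, tolerance = 1e-9)
})

test_that("run aggregation gives the sample mean and n-1 sd", {
  runs <- matrix(c(0.97, 0.97, 0.97, 0.97, 0.98), ncol = 1,
                 dimnames = list(NULL, "micro_f1"))
  agg <- aggregate_runs(runs)
  expect_equal(agg$mean, 0.972)
  expect_equal(agg$sd, sd(c(0.97, 0.97, 0.97, 0.97, 0.98)))
  expect_equal(aggregate_runs(matrix(c(0.5, 0.5), ncol = 1))$sd, 0)
  two <- aggregate_runs(matrix(c(0, 1), ncol = 1))
  expect_equal(two$mean, 0.5)
  expect_equal(two$sd, sqrt(0.5))
  expect_error(aggregate_runs(matrix(1, 1, 1)), "at least 2")
})

test_that("the Welch test matches t.test and honours conventions", {
  expect_equal(compare_configs(c(0.7, 0.7, 0.7), c(0.7, 0.7, 0.7))$p_value, 1)
  expect_lt(compare_configs(c(0, 0, 0), c(1, 1, 1))$p_value, 0.01)
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(6, 0.7, 0.05); b <- rnorm(5, 0.72, 0.04)
    mine <- compare_configs(a, b)
    ref <- t.test(a, b)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
  }
})
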