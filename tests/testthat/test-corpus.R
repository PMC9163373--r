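test_that("configuration validation names the offending field", {
  expect_error(corpus_config(diagnosis_mix = c(F31 = 0.5, F32 = 0.4,
                                               F33 = 0.2)),
               "diagnosis_mix")
  expect_error(corpus_config(negation_rate = 1.5), "negation_rate")
  expect_error(corpus_config(length_model = list(mean = 50, sd = 10,
                                                 min = 60, max = 900)),
               "length_model")
})

test_that("zero family-history rates give all-negative gold quintets", {
  cfg <- corpus_config(n_patients = 40,
                       fh_category_rates = fh_rates_from_groups(
                         flat_rates(0), flat_rates(0)),
                       negation_rate = 0.5, seed = 4)
  co <- generate_cohort(cfg)
  labs <- vapply(co$notes, function(n) sum(n$gold$label), 0)
  expect_true(all(labs == 0))
  expect_true(all(co$patients$any_family_history == 0L))
})

test_that("the same config and seed reproduce the corpus byte for byte", {
  cfg <- corpus_config(n_patients = 30, seed = 17)
  f1 <- tempfile(); f2 <- tempfile()
  write_corpus(generate_cohort(cfg)$notes, f1)
  write_corpus(generate_cohort(cfg)$notes, f2)
  expect_identical(readLines(f1, encoding = "UTF-8"),
                   readLines(f2, encoding = "UTF-8"))
})

test_that("diagnosis-group counts follow the configured multinomial", {
  cfg <- corpus_config(n_patients = 12006, admissions_lambda = 0, seed = 23)
  truth <- generate_patient_truth(cfg)
  counts <- table(truth$patients$first_diagnosis)[c("F31", "F32", "F33")]
  expected <- 12006 * cfg$diagnosis_mix[c("F31", "F32", "F33")]
  sds <- sqrt(expected * (1 - cfg$diagnosis_mix[c("F31", "F32", "F33")]))
  expect_true(all(abs(counts - expected) <= 3 * sds))
})

test_that("note count equals total admissions and truth is the OR of notes", {
  co <- clean_corpus(150, seed = 9)
  per_patient <- split(co$notes,
                       vapply(co$notes, `[[`, "", "patient_id"))
  expect_identical(length(co$notes),
                   sum(vapply(per_patient, length, 0L)))
  for (pid in names(per_patient)) {
    merged <- merge_labels(lapply(per_patient[[pid]],
                                  function(n) n$gold$label))
    truth <- co$patients[co$patients$patient_id == pid,
                         paste0("fh_", FH_CODES)]
    expect_identical(as.integer(merged), as.integer(unlist(truth)))
  }
})

test_that("per-category prevalence tracks the configured rates", {
  rate <- 0.15
  cfg <- corpus_config(n_patients = 3000,
                       fh_category_rates = fh_rates_from_groups(
                         flat_rates(rate), flat_rates(rate)),
                       seed = 31)
  truth <- generate_patient_truth(cfg)
  for (code in FH_CODES) {
    p_hat <- mean(truth$patients[[paste0("fh_", code)]])
    band <- 3 * sqrt(rate * (1 - rate) / 3000)
    expect_lt(abs(p_hat - rate), band)
  }
})

test_that("note lengths respect the configured bounds", {
  co <- clean_corpus(80, seed = 2)
  len <- vapply(co$notes, function(n) nchar(n$text), 0)
  expect_true(all(len >= 60 & len <= 500))
})

test_that("rendered notes realize exactly the given events", {
  lx <- read_lexicon("debug_en")
  rn <- render_note(event_row("F32", "sister", "major depressive disorder"),
                    target_length = 180L, lexicon = lx)
  expect_identical(unclass(rn$label), unclass(fh_label(F32 = 1)))
  expect_identical(nrow(rn$events), 1L)
  got <- substr(rn$text, rn$events$start + 1L, rn$events$end)
  expect_identical(got, "major depressive disorder")
  expect_match(rn$text, "sister had been diagnosed with")
})

test_that("negation rendering produces the denial phrase with a zero quintet", {
  lx <- read_lexicon("debug_en")
  rn <- render_note(event_row("F32", "x", "y")[0, ],
                    negation = TRUE, target_length = 150L, lexicon = lx)
  expect_match(rn$text, "denies any family history", fixed = TRUE)
  expect_true(all(rn$label == 0L))
  expect_identical(nrow(rn$events), 0L)
})

test_that("a distractor term does not contaminate the gold label", {
  lx <- read_lexicon("debug_en")
  rn <- render_note(event_row("F32", "x", "y")[0, ], negation = FALSE,
                    distractor_code = "F20", target_length = 180L,
                    lexicon = lx)
  expect_match(rn$text, "schizophrenia", fixed = TRUE)
  expect_true(all(rn$label == 0L))
})

test_that("unknown disease category in events raises a lexicon error", {
  lx <- read_lexicon("debug_en")
  expect_error(render_note(event_row("F99", "sister", "whatever"),
                           target_length = 150L, lexicon = lx),
               "lexicon error")
  expect_error(render_note(event_row("F32", "x", "y")[0, ],
                           distractor_code = "F99",
                           target_length = 150L, lexicon = lx),
               "lexicon error")
})

test_that("corpus JSONL round-trips losslessly", {
  co <- clean_corpus(40, seed = 5)
  f <- tempfile()
  write_corpus(co$notes, f)
  expect_identical(read_corpus(f), co$notes)
})

test_that("empty corpus writes an empty file and reads back empty", {
  f <- tempfile()
  write_corpus(list(), f)
  expect_identical(file.size(f), 0)
  expect_identical(read_corpus(f), list())
})

test_that("a malformed corpus line is reported with its line number", {
  f <- tempfile()
  writeLines('{"note_id": "N1", "patient_id"', f)
  expect_error(read_corpus(f), "line 1")
  co <- clean_corpus(5, seed = 1)
  write_corpus(co$notes, f)
  lines <- readLines(f, encoding = "UTF-8")
  lines[3] <- substr(lines[3], 1, 25)
  writeLines(lines, f, useBytes = TRUE)
  expect_error(read_corpus(f), "line 3")
})

test_that("configured odds-ratio truths are recovered from the rate matrix", {
  bd <- flat_rates(0.2)
  or_target <- c(F20 = 0.464, F32 = 1.058, F31 = 0.137, F28 = 0.409,
                 F29 = 0.643)
  odds_mdd <- or_target * (bd / (1 - bd))
  mdd <- odds_mdd / (1 + odds_mdd)
  cfg <- corpus_config(fh_category_rates = fh_rates_from_groups(mdd, bd))
  expect_equal(true_odds_ratios(cfg), or_target, tolerance = 1e-12)
})
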