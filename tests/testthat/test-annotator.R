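lx_en <- read_lexicon("debug_en")
lx_zh <- read_lexicon("zh_default")

test_that("segmentation handles empty and single-term inputs", {
  expect_identical(nrow(segment("", lx_en)), 0L)
  toks <- segment("schizophrenia", lx_en)
  expect_identical(toks$token, "schizophrenia")
  expect_identical(toks$start, 0L)
  expect_identical(toks$end, nchar("schizophrenia"))
})

test_that("unknown tokenizer ids are rejected", {
  expect_error(segment("abc", lx_en, tokenizer_id = "nope"),
               "unknown tokenizer_id")
})

test_that("token offsets are sorted, disjoint and reconstruct the text", {
  set.seed(11)
  texts <- c(
    vapply(clean_corpus(10, seed = 3, lexicon_id = "zh_default")$notes,
           `[[`, "", "text"),
    vapply(clean_corpus(10, seed = 3, lexicon_id = "debug_en")$notes,
           `[[`, "", "text"))
  for (tx in texts) {
    lx <- if (grepl("FAMILY", tx)) lx_en else lx_zh
    toks <- segment(tx, lx)
    # brute-force scan: each token matches its span in the original text
    for (i in seq_len(nrow(toks)))
      expect_identical(substr(tx, toks$start[i] + 1L, toks$end[i]),
                       toks$token[i])
    expect_true(all(diff(toks$start) > 0))
    expect_true(all(utils::head(toks$end, -1L) <=
                      utils::tail(toks$start, -1L)))
    expect_lte(sum(nchar(toks$token)), nchar(tx))
    # concatenation ignoring separators reconstructs the input
    # (multi-word dictionary tokens keep their internal spaces)
    expect_identical(gsub("\\s", "", paste(toks$token, collapse = "")),
                     gsub("\\s", "", tx))
  }
})

test_that("the family-history span covers exactly the rendered sentence", {
  rn <- render_note(event_row("F20", "father", "schizophrenia"),
                    target_length = 220L, lexicon = lx_en)
  span <- locate_family_history(rn$text, lx_en)
  sect <- substr(rn$text, span["start"] + 1L, span["end"])
  expect_match(sect, "^FAMILY HISTORY:")
  expect_match(sect, "schizophrenia\\.$")
  # events recorded in the gold annotation sit inside the span
  expect_true(all(rn$events$start >= span["start"] &
                    rn$events$end <= span["end"]))
})

test_that("locate returns NULL without a cue and spans to EOF for a final cue", {
  expect_null(locate_family_history("No cue in this sentence.", lx_en))
  txt <- "Filler sentence. FAMILY HISTORY: mother had been diagnosed"
  span <- locate_family_history(txt, lx_en)
  expect_identical(unname(span["end"]), nchar(txt))
})

test_that("extraction reproduces the sister/depression worked example", {
  rn <- render_note(event_row("F32", "sister", "major depressive disorder"),
                    target_length = 200L, lexicon = lx_en)
  ev <- extract_events(rn$text, lx_en)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$disease_code, "F32")
  expect_identical(ev$relation_term, "sister")
  expect_identical(ev$kinship_degree, "first")
  expect_identical(unclass(events_to_label(ev)),
                   unclass(fh_label(F32 = 1)))
})

test_that("denial notes and section-scoped distractors yield no events", {
  rn_neg <- render_note(event_row("F32", "x", "y")[0, ], negation = TRUE,
                        target_length = 150L, lexicon = lx_en)
  expect_identical(nrow(extract_events(rn_neg$text, lx_en)), 0L)
  # distractor note with a denial section: the disease word occurs in the
  # text but outside the located family-history span
  rn_dis <- render_note(event_row("F32", "x", "y")[0, ], negation = TRUE,
                        distractor_code = "F20", target_length = 200L,
                        lexicon = lx_en)
  expect_match(rn_dis$text, "schizophrenia")
  expect_identical(nrow(extract_events(rn_dis$text, lx_en,
                                       scope = "section")), 0L)
})

test_that("full-text scope picks up out-of-section mentions as unknown-kin events", {
  rn <- render_note(event_row("F32", "sister", "major depressive disorder"),
                    distractor_code = "F20", target_length = 250L,
                    lexicon = lx_en)
  ev_full <- extract_events(rn$text, lx_en, scope = "full")
  expect_true("F20" %in% ev_full$disease_code)
  expect_identical(ev_full$kinship_degree[ev_full$disease_code == "F20"],
                   "unknown")
})

test_that("negated clauses suppress disease matches", {
  txt <- paste0("FAMILY HISTORY: denies schizophrenia in relatives, ",
                "the patient's mother had been diagnosed with a ",
                "bipolar disorder.")
  ev <- extract_events(txt, lx_en)
  expect_identical(ev$disease_code, "F31")
  expect_identical(ev$relation_term, "mother")
})

test_that("kinship degrees follow the consanguinity map", {
  expect_identical(kinship_degree("sister", lx_en), "first")
  expect_identical(kinship_degree("cousin", lx_en), "third")
  expect_identical(kinship_degree("aunt", lx_en), "second")
  expect_identical(kinship_degree("telephone", lx_en), "unknown")
  expect_identical(kinship_degree("表哥", lx_zh), "third")
})

test_that("events_to_label is order-invariant and duplication-idempotent", {
  ev <- data.frame(disease_code = c("F20", "F28"),
                   relation_term = c("father", "aunt"),
                   kinship_degree = c("first", "second"),
                   start = c(0L, 10L), end = c(5L, 15L),
                   stringsAsFactors = FALSE)
  lab <- events_to_label(ev)
  expect_identical(unclass(lab), unclass(fh_label(F20 = 1, F28 = 1)))
  expect_identical(events_to_label(ev[c(2, 1), ]), lab)
  expect_identical(events_to_label(rbind(ev, ev)), lab)
  expect_identical(unclass(events_to_label(empty_events())),
                   unclass(fh_label()))
})

test_that("identical text and lexicon give identical events", {
  co <- clean_corpus(20, seed = 13)
  for (n in co$notes[1:10])
    expect_identical(extract_events(n$text, lx_zh),
                     extract_events(n$text, lx_zh))
})

test_that("rule labels equal gold exactly on a noise-free corpus", {
  co <- clean_corpus(120, seed = 21)
  labs <- annotate_corpus(co$notes, lx_zh)
  cc <- confusion(labs, gold_records(co$notes))
  expect_identical(sum(cc$FP), 0L)
  expect_identical(sum(cc$FN), 0L)
})
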