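# shared fixture builders: everything generated in code, no stored data

flat_rates <- function(p) stats::setNames(rep(p, 5), FH_CODES)

# small clean corpus (no negation, no distractors) in either lexicon
clean_corpus <- function(n_patients, seed, lexicon_id = "zh_default",
                         rate = 0.12, admissions_lambda = 0.3) {
  cfg <- corpus_config(
    n_patients = n_patients,
    admissions_lambda = admissions_lambda,
    fh_category_rates = fh_rates_from_groups(flat_rates(rate),
                                             flat_rates(rate)),
    negation_rate = 0, distractor_rate = 0,
    length_model = list(mean = 160, sd = 40, min = 60, max = 500),
    lexicon_id = lexicon_id, seed = seed)
  generate_cohort(cfg)
}

gold_records <- function(notes) {
  lapply(notes, function(n) list(note_id = n$note_id, label = n$gold$label))
}

gold_matrix <- function(notes) {
  m <- do.call(rbind, lapply(notes, function(n) unclass(n$gold$label)))
  rownames(m) <- vapply(notes, `[[`, "", "note_id")
  m
}

# random 0/1 label matrix with note ids
random_label_matrix <- function(n, p = 0.3) {
  m <- matrix(rbinom(n * 5, 1, p), n, 5, dimnames = list(
    sprintf("N%03d", seq_len(n)), FH_CODES))
  m
}

# a one-event patient-events row for render_note()
event_row <- function(code, kin_term, disease_term, degree = "first") {
  data.frame(patient_id = "P1", disease_code = code,
             kinship_degree = degree, kin_term = kin_term,
             disease_term = disease_term, stringsAsFactors = FALSE)
}
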