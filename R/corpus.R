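#' Default per-diagnosis family-history category rates
#'
#' Probability that a patient in each first-diagnosis code (F31 bipolar,
#' F32 depressive episode, F33 recurrent depression) carries a family
#' history of each of the five categories.  Defaults are the observed
#' family-history event counts of the study cohort divided by the group
#' sizes (N = 2,123 / 5,353 / 4,530).
#'
#' @return 3 x 5 numeric matrix, rows `F31`,`F32`,`F33`, columns
#'   [FH_CODES].
#' @export
default_fh_rates <- function() {
  n <- c(F31 = 2123, F32 = 5353, F33 = 4530)
  counts <- rbind( #        F20  F32  F31  F28  F29
    F31 = c(145, 177, 35, 212, 26),
    F32 = c(151, 419, 12, 250, 58),
    F33 = c(169, 437, 12, 192, 37))
  colnames(counts) <- FH_CODES
  sweep(counts, 1, n, "/")
}

#' Build a rate matrix from MDD/BD group-level rates
#'
#' Convenience for simulation studies: family-history rates specified per
#' analysis group (MDD pools F32 and F33; BD is F31).  With equal F32 and
#' F33 rows the implied outcome-given-history logistic model is exact and
#' [true_odds_ratios()] returns the exact simulation truth.
#'
#' @param mdd,bd named numeric vectors over [FH_CODES], probabilities.
#' @return 3 x 5 rate matrix as in [default_fh_rates()].
#' @export
fh_rates_from_groups <- function(mdd, bd) {
  mdd <- mdd[FH_CODES]; bd <- bd[FH_CODES]
  m <- rbind(F31 = bd, F32 = mdd, F33 = mdd)
  colnames(m) <- FH_CODES
  m
}

#' Default demographic model of the synthetic cohort
#'
#' Marginals follow the study cohort: 7,850/12,006 female; age truncated
#' normal with mean 48.75 on [9, 94]; marital status
#' married/no-spouse/not-specified at 8,694/3,296/16; 19 profession
#' classes with the largest (retired) at 26.2\%; admission years
#' 2010-2019.
#'
#' @return List of demographic sampling parameters.
#' @export
default_demographics <- function() {
  list(
    female_rate = 7850 / 12006,
    age = list(mean = 48.75, sd = 17, min = 9, max = 94),
    marital_probs = c(married = 8694, no_spouse = 3296,
                      not_specified = 16) / 12006,
    professions = c(sprintf("profession_%02d", 1:18), "retired"),
    profession_probs = c(rep((1 - 0.262) / 18, 18), 0.262),
    years = 2010:2019)
}

#' Configure a synthetic admission-note cohort
#'
#' Defaults reproduce the statistical structure of the study cohort:
#' diagnosis mix 2,123 : 5,353 : 4,530 over F31/F32/F33; family-history
#' category rates per diagnosis code from the observed event counts;
#' kinship degree mix 1,593 : 342 : 63 over first/second/third; note
#' lengths with (truncated) mean 204.3, sd 65.66 on [60, 948] characters;
#' admissions per patient 1 + Poisson(0.3).
#'
#' @param n_patients number of patients.
#' @param admissions_lambda Poisson rate; admissions per patient is
#'   `1 + Poisson(admissions_lambda)`.
#' @param diagnosis_mix named proportions over `F31`,`F32`,`F33`
#'   (must sum to 1).
#' @param fh_category_rates 3 x 5 matrix as [default_fh_rates()].
#' @param kinship_mix named proportions over first/second/third.
#' @param negation_rate probability that a note of a patient without any
#'   family-history event states an explicit denial.
#' @param distractor_rate probability that a note carries a disease term
#'   in a non-family-history (past history) sentence.
#' @param event_note_rate probability each patient-level event is
#'   mentioned in any given note (always forced into at least one).
#' @param length_model list(mean, sd, min, max) of note character counts;
#'   mean/sd are the moments of the truncated distribution itself.
#' @param demographics list as [default_demographics()].
#' @param lexicon_id lexicon used for rendering (and shared with the rule
#'   annotator).
#' @param seed RNG seed.
#' @return List of class `fh_corpus_config`.
#' @export
corpus_config <- function(n_patients = 1000,
                          admissions_lambda = 0.3,
                          diagnosis_mix = c(F31 = 2123, F32 = 5353,
                                            F33 = 4530) / 12006,
                          fh_category_rates = default_fh_rates(),
                          kinship_mix = c(first = 1593, second = 342,
                                          third = 63) / 1998,
                          negation_rate = 0.5,
                          distractor_rate = 0.2,
                          event_note_rate = 0.8,
                          length_model = list(mean = 204.3, sd = 65.66,
                                              min = 60, max = 948),
                          demographics = default_demographics(),
                          lexicon_id = "zh_default",
                          seed = 1L) {
  cfg <- list(n_patients = n_patients, admissions_lambda = admissions_lambda,
              diagnosis_mix = diagnosis_mix,
              fh_category_rates = fh_category_rates,
              kinship_mix = kinship_mix, negation_rate = negation_rate,
              distractor_rate = distractor_rate,
              event_note_rate = event_note_rate, length_model = length_model,
              demographics = demographics, lexicon_id = lexicon_id,
              seed = as.integer(seed))
  validate_corpus_config(cfg)
}

check_probs <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("configuration error in '", field,
         "': proportions must lie in [0, 1]")
}

check_mix <- function(x, field) {
  check_probs(x, field)
  if (abs(sum(x) - 1) > 1e-9)
    stop("configuration error in '", field, "': proportions must sum to 1")
}

validate_corpus_config <- function(cfg) {
  if (cfg$n_patients < 1) stop("configuration error in 'n_patients'")
  if (cfg$admissions_lambda < 0)
    stop("configuration error in 'admissions_lambda'")
  check_mix(cfg$diagnosis_mix, "diagnosis_mix")
  if (!setequal(names(cfg$diagnosis_mix), c("F31", "F32", "F33")))
    stop("configuration error in 'diagnosis_mix': names must be F31/F32/F33")
  check_mix(cfg$kinship_mix, "kinship_mix")
  check_probs(cfg$fh_category_rates, "fh_category_rates")
  check_probs(cfg$negation_rate, "negation_rate")
  check_probs(cfg$distractor_rate, "distractor_rate")
  check_probs(cfg$event_note_rate, "event_note_rate")
  lm <- cfg$length_model
  if (lm$min < 1 || lm$min > lm$mean || lm$mean > lm$max)
    stop("configuration error in 'length_model': need 1 <= min <= mean <= max")
  class(cfg) <- "fh_corpus_config"
  cfg
}

#' Exact odds ratios implied by a cohort configuration
#'
#' Adjusted odds ratio of MDD (outcome 1) versus BD per family-history
#' category, implied by the configured per-diagnosis rates.  F32 and F33
#' rates are pooled with the diagnosis-mix weights; when they are equal
#' the value is the exact coefficient truth of the outcome-given-history
#' logistic model (categories are conditionally independent given
#' diagnosis, so log-odds are additive).
#'
#' @param config an `fh_corpus_config`.
#' @return Named numeric vector of odds ratios over [FH_CODES].
#' @export
true_odds_ratios <- function(config) {
  r <- config$fh_category_rates
  w <- config$diagnosis_mix[c("F32", "F33")]
  p_mdd <- (w["F32"] * r["F32", ] + w["F33"] * r["F33", ]) / sum(w)
  p_bd <- r["F31", ]
  ors <- (p_mdd / (1 - p_mdd)) / (p_bd / (1 - p_bd))
  stats::setNames(as.numeric(ors), FH_CODES)
}

# sample one set of patient demographics
sample_demographics <- function(n, dm) {
  data.frame(
    age_years = as.integer(round(rtrunc_norm(n, dm$age$mean, dm$age$sd,
                                             dm$age$min, dm$age$max))),
    gender = ifelse(stats::runif(n) < dm$female_rate, "female", "male"),
    marital_status = sample(names(dm$marital_probs), n, replace = TRUE,
                            prob = dm$marital_probs),
    profession = sample(dm$professions, n, replace = TRUE,
                        prob = dm$profession_probs),
    stringsAsFactors = FALSE)
}

#' Generate patient-level ground truth (no note text)
#'
#' The demographic and family-history truth underlying a cohort,
#' without rendering any text.  Used by [generate_cohort()] and directly
#' by association simulations where only the patient table matters.
#'
#' @param config an `fh_corpus_config`.
#' @return List with `patients` (one row per patient: demographics,
#'   `first_diagnosis`, `diagnosis_group`, the five `fh_*` indicators,
#'   `any_family_history`, `kinship_group`) and `events` (one row per
#'   patient-level family-history event with its fixed surface terms).
#' @export
generate_patient_truth <- function(config) {
  lx <- read_lexicon(config$lexicon_id)
  with_seed(config$seed, {
    n <- config$n_patients
    diag <- sample(c("F31", "F32", "F33"), n, replace = TRUE,
                   prob = config$diagnosis_mix[c("F31", "F32", "F33")])
    dem <- sample_demographics(n, config$demographics)
    ind <- matrix(0L, n, 5, dimnames = list(NULL, FH_CODES))
    for (code in FH_CODES)
      ind[, code] <- as.integer(
        stats::runif(n) < config$fh_category_rates[diag, code])
    pid <- sprintf("P%06d", seq_len(n))
    # one event per positive (patient, category): fixed kinship + surfaces
    pos <- which(ind == 1L, arr.ind = TRUE)
    events <- empty_patient_events()
    if (nrow(pos)) {
      pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
      degree <- sample(names(config$kinship_mix), nrow(pos), replace = TRUE,
                       prob = config$kinship_mix)
      kin <- vapply(degree, function(d) {
        terms <- kinship_terms_of_degree(lx, d)
        terms[sample.int(length(terms), 1L)]
      }, "")
      code <- FH_CODES[pos[, 2]]
      dis <- vapply(code, function(cc) {
        terms <- disease_terms_of(lx, cc)
        terms[sample.int(length(terms), 1L)]
      }, "")
      events <- data.frame(patient_id = pid[pos[, 1]], disease_code = code,
                           kinship_degree = degree, kin_term = kin,
                           disease_term = dis, stringsAsFactors = FALSE,
                           row.names = NULL)
    }
    patients <- data.frame(patient_id = pid, dem,
                           first_diagnosis = diag,
                           diagnosis_group = ifelse(diag == "F31",
                                                    "BD", "MDD"),
                           stringsAsFactors = FALSE)
    colnames(ind) <- paste0("fh_", FH_CODES)
    patients <- cbind(patients, as.data.frame(ind))
    patients$any_family_history <- as.integer(rowSums(ind) > 0)
    patients$kinship_group <- ifelse(patients$any_family_history == 1L,
                                     "any_degree", "not_mentioned")
    list(patients = patients, events = events)
  })
}

empty_patient_events <- function() {
  data.frame(patient_id = character(), disease_code = character(),
             kinship_degree = character(), kin_term = character(),
             disease_term = character(), stringsAsFactors = FALSE)
}

#' Generate a synthetic admission-note cohort with gold annotations
#'
#' Draws patient-level truth, assigns each patient `1 + Poisson(lambda)`
#' admissions, distributes the patient's family-history events over the
#' notes (each event appears in a note with probability
#' `event_note_rate`, and always in at least one), and renders each note
#' with [render_note()].  The per-patient truth equals the bitwise OR of
#' its notes' gold quintets by construction.
#'
#' @param config an `fh_corpus_config`.
#' @return List with `notes` (list of admission-note records, each with a
#'   nested `gold` annotation) and `patients` (the ground-truth patient
#'   table of [generate_patient_truth()]).
#' @export
generate_cohort <- function(config) {
  truth <- generate_patient_truth(config)
  lx <- read_lexicon(config$lexicon_id)
  cal <- calibrate_truncnorm(config$length_model$mean, config$length_model$sd,
                             config$length_model$min, config$length_model$max)
  with_seed(derive_seed(config$seed, "render"), {
    pts <- truth$patients
    n <- nrow(pts)
    n_adm <- 1L + stats::rpois(n, config$admissions_lambda)
    notes <- vector("list", sum(n_adm))
    k <- 0L
    for (i in seq_len(n)) {
      pid <- pts$patient_id[i]
      pev <- truth$events[truth$events$patient_id == pid, , drop = FALSE]
      m <- n_adm[i]
      # event -> note incidence, each event in >= 1 note
      inc <- matrix(stats::runif(nrow(pev) * m) < config$event_note_rate,
                    nrow = nrow(pev), ncol = m)
      if (nrow(pev))
        for (e in seq_len(nrow(pev)))
          if (!any(inc[e, ])) inc[e, sample.int(m, 1L)] <- TRUE
      years <- sort(sample(config$demographics$years, m, replace = TRUE))
      tlen <- as.integer(round(rtrunc_norm(m, cal$mu, cal$sigma,
                                           config$length_model$min,
                                           config$length_model$max)))
      for (j in seq_len(m)) {
        ev <- pev[inc[, j], , drop = FALSE]
        negate <- nrow(ev) == 0L &&
          stats::runif(1) < config$negation_rate
        distract <- stats::runif(1) < config$distractor_rate
        dcode <- if (distract) sample(FH_CODES, 1L) else NULL
        rn <- render_note(ev, negation = negate, distractor_code = dcode,
                          target_length = tlen[j], lexicon = lx)
        k <- k + 1L
        notes[[k]] <- list(
          note_id = sprintf("%s_A%02d", pid, j),
          patient_id = pid,
          admission_year = as.integer(years[j]),
          age_years = pts$age_years[i],
          gender = pts$gender[i],
          marital_status = pts$marital_status[i],
          profession = pts$profession[i],
          first_diagnosis = pts$first_diagnosis[i],
          text = rn$text,
          gold = list(label = rn$label, events = rn$events))
      }
    }
    list(notes = notes, patients = pts)
  })
}

# split a template like "a{kin}b{disease}c" around its two placeholders;
# {kin} must precede {disease}
split_event_template <- function(tpl) {
  pk <- regexpr("{kin}", tpl, fixed = TRUE)
  pd <- regexpr("{disease}", tpl, fixed = TRUE)
  if (pk < 0 || pd < 0 || pd < pk)
    stop("lexicon error: fh_event template must contain {kin} then {disease}")
  list(p1 = substr(tpl, 1L, pk - 1L),
       p2 = substr(tpl, pk + 5L, pd - 1L),
       p3 = substr(tpl, pd + 9L, nchar(tpl)))
}

#' Render one synthetic admission note
#'
#' Builds a paragraph of filler sentences (present illness, past history,
#' physical examination) around exactly one family-history sentence that
#' realizes the given events - or the lexicon's denial phrase when
#' `negation` is set and there are no events, or no family-history
#' sentence at all otherwise.  An optional distractor places a disease
#' term inside a past-history sentence without affecting the gold label.
#' The text is padded/trimmed to `target_length` characters (never
#' cutting into the family-history sentence).
#'
#' @param events data.frame with columns `disease_code`, `kinship_degree`,
#'   `kin_term`, `disease_term` (one row per event to realize).
#' @param negation logical; explicit denial (only used when `events` is
#'   empty).
#' @param distractor_code optional disease code to mention outside the
#'   family-history context.
#' @param target_length desired character count.
#' @param lexicon an `fh_lexicon`.
#' @return List with `text`, gold `label` (quintet) and gold `events`
#'   (data.frame with 0-based half-open spans of the disease terms).
#' @export
render_note <- function(events, negation = FALSE, distractor_code = NULL,
                        target_length = 200L, lexicon) {
  tp <- lexicon$templates
  if (nrow(events)) {
    bad <- setdiff(events$disease_code, FH_CODES)
    if (length(bad))
      stop("lexicon error: unknown disease category ",
           paste(bad, collapse = ", "))
  }
  parts <- split_event_template(tp$fh_event)

  # family-history sentence plus relative disease-term spans
  fh_sentence <- NULL
  rel <- NULL
  if (nrow(events)) {
    phr <- character(nrow(events))
    off <- integer(nrow(events))
    for (e in seq_len(nrow(events))) {
      phr[e] <- paste0(parts$p1, events$kin_term[e], parts$p2,
                       events$disease_term[e], parts$p3)
      off[e] <- nchar(parts$p1) + nchar(events$kin_term[e]) + nchar(parts$p2)
    }
    body <- paste(phr, collapse = tp$event_sep)
    fh_sentence <- paste0(tp$fh_intro, body, tp$sentence_end)
    prev <- c(0L, cumsum(nchar(phr) + nchar(tp$event_sep)))[seq_len(nrow(events))]
    rel <- nchar(tp$fh_intro) + prev + off
  } else if (isTRUE(negation)) {
    fh_sentence <- paste0(tp$fh_intro, tp$denial_body, tp$sentence_end)
  }

  fillers <- sample(unlist(tp$fillers))
  lead <- fillers[1L]
  distractor <- NULL
  if (!is.null(distractor_code)) {
    terms <- disease_terms_of(lexicon, distractor_code)
    if (!length(terms))
      stop("lexicon error: unknown disease category ", distractor_code)
    distractor <- sub("{disease}", terms[sample.int(length(terms), 1L)],
                      tp$distractor, fixed = TRUE)
  }

  pre <- paste0(c(lead, distractor), collapse = "")
  fh_start <- nchar(pre)
  core <- paste0(pre, fh_sentence %||% "")
  target_length <- max(target_length, nchar(core))
  tail_pool <- paste(c(fillers[-1L],
                       rep(tp$padding, ceiling(target_length /
                                               max(1L, nchar(tp$padding))))),
                     collapse = "")
  text <- substr(paste0(core, tail_pool), 1L, target_length)

  gold_events <- empty_events()
  if (nrow(events)) {
    gold_events <- data.frame(
      disease_code = events$disease_code,
      relation_term = events$kin_term,
      kinship_degree = events$kinship_degree,
      start = as.integer(fh_start + rel),
      end = as.integer(fh_start + rel + nchar(events$disease_term)),
      stringsAsFactors = FALSE)
    gold_events <- gold_events[order(gold_events$start), , drop = FALSE]
    row.names(gold_events) <- NULL
  }
  list(text = text,
       label = events_to_label(gold_events),
       events = gold_events)
}
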