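#' Split notes into train/validation/test sets
#'
#' Random disjoint, exhaustive partition with exact sizes by
#' largest-remainder rounding (the 0.64/0.16/0.20 default).  With
#' `group_by_patient` no patient spans two splits: patients are shuffled
#' and each patient's notes go to the split with the largest remaining
#' deficit (sizes then match the fractions only approximately).
#'
#' @param notes list of admission-note records (or a character vector of
#'   note ids when `group_by_patient = FALSE`).
#' @param fractions three positive fractions summing to 1.
#' @param seed RNG seed.
#' @param group_by_patient keep each patient's notes together.
#' @return List with `train`, `validation`, `test` character vectors of
#'   note ids (pairwise disjoint; union = all ids).
#' @export
split_dataset <- function(notes, fractions = c(0.64, 0.16, 0.20),
                          seed = 1L, group_by_patient = FALSE) {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be positive and sum to 1")
  if (is.character(notes)) {
    ids <- notes
    pids <- NULL
  } else {
    ids <- vapply(notes, `[[`, "", "note_id")
    pids <- vapply(notes, `[[`, "", "patient_id")
  }
  n <- length(ids)
  if (n < 3L) stop("input error: need at least 3 notes to split")
  sizes <- largest_remainder(n, fractions)
  with_seed(seed, {
    if (!group_by_patient || is.null(pids)) {
      ord <- sample(n)
      grp <- rep.int(1:3, times = sizes)
      split(ids[ord], grp)[c("1", "2", "3")] |>
        stats::setNames(c("train", "validation", "test"))
    } else {
      out <- list(character(), character(), character())
      deficit <- sizes
      for (p in sample(unique(pids))) {
        sel <- ids[pids == p]
        k <- which.max(deficit)
        out[[k]] <- c(out[[k]], sel)
        deficit[k] <- deficit[k] - length(sel)
      }
      stats::setNames(out, c("train", "validation", "test"))
    }
  })
}

largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(left)]
    sizes[extra] <- sizes[extra] + 1L
  }
  as.integer(sizes)
}

#' Configure an end-to-end pipeline run
#'
#' @param corpus_config an `fh_corpus_config` for synthetic input (or
#'   `NULL` with `corpus_path` pointing at an existing JSONL corpus).
#' @param corpus_path optional existing corpus to load instead of
#'   generating one.
#' @param engine labeling engine: `"annotator"` (rules),
#'   `"classifier"`, or `"hybrid"` (classifier + `rule_and`
#'   post-filter).
#' @param classifier_config an `fh_classifier_config` (engines other
#'   than `"annotator"`).
#' @param scope rule-annotator scope (`"section"`/`"full"`).
#' @param split_fractions train/validation/test fractions.
#' @param runs evaluation runs for the classifier engines.
#' @param seed global seed; per-stage seeds derive via [derive_seed()].
#' @param log_level `"info"` or `"quiet"`.
#' @return List of class `fh_pipeline_config`.
#' @export
pipeline_config <- function(corpus_config = NULL,
                            corpus_path = NULL,
                            engine = c("annotator", "classifier", "hybrid"),
                            classifier_config = NULL,
                            scope = "section",
                            split_fractions = c(0.64, 0.16, 0.20),
                            runs = 5L,
                            seed = 1L,
                            log_level = c("info", "quiet")) {
  engine <- match.arg(engine)
  if (any(split_fractions <= 0) || abs(sum(split_fractions) - 1) > 1e-9)
    stop("configuration error in 'split_fractions'")
  if (is.null(corpus_config) && is.null(corpus_path))
    corpus_config <- famhx::corpus_config()
  structure(list(corpus_config = corpus_config, corpus_path = corpus_path,
                 engine = engine, classifier_config = classifier_config,
                 scope = scope, split_fractions = split_fractions,
                 runs = as.integer(runs), seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "fh_pipeline_config")
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(
    rapply(unclass(config), function(x)
      if (is.numeric(x)) signif(x, 12) else x, how = "replace"),
    auto_unbox = TRUE, force = TRUE, digits = NA)
  fnv1a_hex(as.character(js))
}

plog <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message("[famhx] ", ...)
}

#' Run the full extraction-to-association pipeline
#'
#' Stages: corpus (synthesize or load), label (rule annotator,
#' classifier, or hybrid), merge (patient table), evaluate (metrics
#' against gold), associate (contingency + chi-squared + adjusted
#' logistic ORs).  Every artifact lands in `out_dir`; `manifest.json`
#' records the config hash, seed and a content hash per output so
#' [verify_run()] can detect tampering.  A failing stage aborts with the
#' stage named and leaves a `FAILED` marker next to the partial outputs.
#'
#' @param config an `fh_pipeline_config`.
#' @param out_dir run directory (created if needed).
#' @return Invisibly, a list with the main in-memory artifacts
#'   (`notes`, `labels`, `patients`, `metrics`, `association`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "fh_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "FAILED"))
  hash <- config_hash(config)
  stage <- "configure"
  result <- tryCatch({
    stage <- "corpus"
    if (!is.null(config$corpus_path)) {
      if (!file.exists(config$corpus_path))
        stop("corpus file not found: ", config$corpus_path)
      notes <- read_corpus(config$corpus_path)
      patients <- NULL
    } else {
      cc <- config$corpus_config
      cc$seed <- derive_seed(config$seed, "corpus")
      cohort <- generate_cohort(cc)
      notes <- cohort$notes
      patients <- cohort$patients
    }
    lx <- read_lexicon((config$corpus_config %||%
                          list(lexicon_id = "zh_default"))$lexicon_id)
    write_corpus(notes, file.path(out_dir, "corpus.jsonl"))
    plog(config, "corpus: ", length(notes), " notes")

    stage <- "label"
    rule_labels <- annotate_corpus(notes, lx, scope = config$scope)
    model <- NULL
    if (config$engine == "annotator") {
      labels <- rule_labels
    } else {
      ccfg <- config$classifier_config %||%
        classifier_config(lexicon_id = lx$id)
      ccfg$seed <- derive_seed(config$seed, "classifier")
      ccfg$split_fractions <- config$split_fractions
      model <- train_classifier(notes, ccfg)
      proba <- predict_proba(model, notes)
      lab <- predict_labels(proba, ccfg$decision_threshold)
      if (config$engine == "hybrid") {
        rl <- label_matrix(rule_labels)
        lab <- hybrid_postfilter(lab, rl[rownames(lab), , drop = FALSE],
                                 "rule_and")
      }
      labels <- lapply(seq_along(notes), function(i) {
        ev <- rule_labels[[i]]$events
        list(note_id = notes[[i]]$note_id,
             label = as_fh_label(lab[notes[[i]]$note_id, ]),
             proba = proba[notes[[i]]$note_id, ],
             events = ev)
      })
    }
    write_labels(labels, file.path(out_dir, "labels.jsonl"),
                 meta = list(stage = "label", engine = config$engine,
                             config_hash = hash))
    plog(config, "label: engine=", config$engine)

    stage <- "merge"
    patient_table <- build_patient_table(notes, labels)
    utils::write.csv(patient_table,
                     file.path(out_dir, "patients.csv"),
                     row.names = FALSE)

    stage <- "evaluate"
    gold <- lapply(notes, function(n)
      list(note_id = n$note_id, label = n$gold$label))
    rep <- metric_report(labels, gold)
    metrics <- list(stage = "evaluate", config_hash = hash,
                    per_label = rep$per_label,
                    micro = as.list(rep$micro), macro = as.list(rep$macro),
                    accuracy = rep$accuracy,
                    subset_accuracy = rep$subset_accuracy)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "associate"
    assoc <- NULL
    if (length(unique(patient_table$diagnosis_group)) == 2L) {
      ct <- build_contingency(patient_table, "any_family_history")
      chi <- chi_squared(ct)
      lr <- fit_logistic(patient_table)
      assoc <- list(stage = "associate", config_hash = hash,
                    contingency = list(table = ct$table,
                                       overlapping = ct$overlapping),
                    chi_squared = chi[c("statistic", "df", "p_value")],
                    logistic = list(terms = lr$terms, model = lr$model))
      jsonlite::write_json(assoc, file.path(out_dir, "association.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }

    stage <- "manifest"
    files <- c("corpus.jsonl", "labels.jsonl", "patients.csv",
               "metrics.json",
               if (!is.null(assoc)) "association.json")
    manifest <- list(
      package_version = as.character(utils::packageVersion("famhx")),
      config_hash = hash, seed = config$seed, engine = config$engine,
      stages = c("corpus", "label", "merge", "evaluate", "associate"),
      files = stats::setNames(
        lapply(files, function(f) fnv1a_hex(file.path(out_dir, f))), files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    list(notes = notes, labels = labels, patients = patient_table,
         truth = patients, metrics = metrics, association = assoc,
         model = model, manifest = manifest)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Verify a run directory against its manifest
#'
#' Re-derives the content hash of every file listed in `manifest.json`
#' and fails on any mismatch.
#'
#' @param out_dir run directory.
#' @return `TRUE` invisibly; error on tampering.
#' @export
verify_run <- function(out_dir) {
  mf <- jsonlite::fromJSON(file.path(out_dir, "manifest.json"))
  for (f in names(mf$files)) {
    h <- fnv1a_hex(file.path(out_dir, f))
    if (!identical(h, mf$files[[f]]))
      stop("hash mismatch for ", f, ": manifest ", mf$files[[f]],
           ", actual ", h)
  }
  invisible(TRUE)
}
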