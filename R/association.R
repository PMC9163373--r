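#' Build a contingency table from the patient table
#'
#' Cross-tabulates patient-level fields against the diagnosis group.
#' `row_spec` is either a single field name (e.g. `"any_family_history"`
#' or `"kinship_group"`) or a vector of 0/1 indicator fields (e.g. the
#' five `fh_*` columns), in which case one row is produced per indicator
#' and rows may overlap (a patient can carry several family-history
#' categories); overlap is flagged in the result.
#'
#' @param patients patient table from [build_patient_table()].
#' @param row_spec field name or vector of indicator field names.
#' @param col_spec field name for the columns (default
#'   `"diagnosis_group"`).
#' @return List of class `fh_contingency`: `table` (integer matrix),
#'   `margins`, `overlapping`.
#' @export
build_contingency <- function(patients, row_spec = "any_family_history",
                              col_spec = "diagnosis_group") {
  bad <- setdiff(c(row_spec, col_spec), names(patients))
  if (length(bad))
    stop("configuration error: unknown patient field(s): ",
         paste(bad, collapse = ", "))
  cols <- sort(unique(as.character(patients[[col_spec]])))
  overlapping <- length(row_spec) > 1L
  if (overlapping) {
    tab <- t(vapply(row_spec, function(f)
      vapply(cols, function(cl)
        sum(patients[[f]] == 1L & patients[[col_spec]] == cl, na.rm = TRUE),
        0), numeric(length(cols))))
  } else {
    v <- as.character(patients[[row_spec]])
    rows <- sort(unique(v))
    tab <- t(vapply(rows, function(r)
      vapply(cols, function(cl) sum(v == r & patients[[col_spec]] == cl), 0),
      numeric(length(cols))))
  }
  storage.mode(tab) <- "integer"
  if (length(dim(tab)) != 2L) tab <- matrix(tab, nrow = 1L,
                                            dimnames = list(row_spec, cols))
  structure(list(table = tab,
                 margins = list(
                   row = stats::setNames(as.integer(rowSums(tab)),
                                         rownames(tab)),
                   col = stats::setNames(as.integer(colSums(tab)),
                                         colnames(tab)),
                   total = as.integer(sum(tab))),
                 overlapping = overlapping),
            class = "fh_contingency")
}

#' Pearson chi-squared test of independence
#'
#' Statistic `sum((O - E)^2 / E)` with expected counts
#' `E = row * col / total`, `(r - 1)(c - 1)` degrees of freedom and no
#' continuity correction.
#'
#' @param table integer matrix of observed counts (or an
#'   `fh_contingency`).
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_squared <- function(table) {
  if (inherits(table, "fh_contingency")) table <- table$table
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0) || n == 0)
    stop("degenerate table: zero margin")
  E <- outer(rs, cs) / n
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = E)
}

#' Adjusted logistic regression of diagnosis on family history
#'
#' Multivariable binary logistic regression of the first-diagnosis
#' outcome (MDD = 1 vs BD = 0) with the five family-history indicators
#' always retained ("forced") and demographic covariates entering by
#' stepwise selection on an information criterion.  Categorical
#' covariates are coded against their most frequent level; age is
#' continuous.  Odds ratios are `exp(coef)` with Wald 95\% intervals
#' `exp(coef +/- 1.96 SE)`.
#'
#' @param patients patient table from [build_patient_table()] (or
#'   [generate_patient_truth()]).
#' @param outcome field holding the outcome; `"diagnosis_group"` is coded
#'   MDD = 1, BD = 0, any other binary 0/1 field is used as is.
#' @param forced_terms terms always in the model (default the five
#'   family-history indicators).
#' @param candidate_terms covariates subject to stepwise selection
#'   (default age, gender, marital status, profession; set to
#'   `character()` to skip adjustment).
#' @param stepwise direction of stepwise selection over the candidates:
#'   `"both"` (default), `"forward"`, `"backward"` or `"none"` (enter all
#'   candidates).
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @return List of class `fh_logistic`: `terms` (coefficient table with
#'   OR and CI), `model` (n, log-likelihood, included covariates,
#'   convergence flag), `reference_levels`, and the underlying `fit`.
#' @export
fit_logistic <- function(patients,
                         outcome = "diagnosis_group",
                         forced_terms = paste0("fh_", FH_CODES),
                         candidate_terms = c("age_years", "gender",
                                             "marital_status", "profession"),
                         stepwise = c("both", "forward", "backward", "none"),
                         criterion = c("AIC", "BIC")) {
  stepwise <- match.arg(stepwise)
  criterion <- match.arg(criterion)
  dat <- as.data.frame(patients)
  y <- if (outcome == "diagnosis_group")
    as.integer(dat$diagnosis_group == "MDD") else as.integer(dat[[outcome]])
  if (length(unique(y)) < 2L)
    stop("outcome must have both classes present")
  dat$.y <- y

  candidate_terms <- intersect(candidate_terms, names(dat))
  refs <- list()
  for (f in c(forced_terms, candidate_terms)) {
    if (is.character(dat[[f]])) {
      lv <- names(sort(table(dat[[f]]), decreasing = TRUE))
      # drop single-level factors: nothing to estimate
      if (length(lv) < 2L) {
        candidate_terms <- setdiff(candidate_terms, f)
        next
      }
      dat[[f]] <- factor(dat[[f]], levels = lv)
      refs[[f]] <- lv[1L]
    }
  }

  base_fml <- stats::reformulate(c("1", forced_terms), response = ".y")
  base <- stats::glm(base_fml, family = stats::binomial(), data = dat)
  fit <- base
  if (length(candidate_terms)) {
    if (stepwise == "none") {
      fit <- stats::glm(stats::reformulate(c(forced_terms, candidate_terms),
                                           response = ".y"),
                        family = stats::binomial(), data = dat)
    } else {
      k <- if (criterion == "AIC") 2 else log(nrow(dat))
      full_fml <- stats::reformulate(c(forced_terms, candidate_terms),
                                     response = ".y")
      start <- if (stepwise == "backward")
        stats::glm(full_fml, family = stats::binomial(), data = dat) else base
      dir <- if (stepwise == "forward") "forward"
             else if (stepwise == "backward") "backward" else "both"
      fit <- stats::step(start,
                         scope = list(lower = base_fml, upper = full_fml),
                         direction = dir, k = k, trace = 0)
    }
  }

  sm <- stats::summary.glm(fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  separated <- any(abs(est[-1L]) > 15) || any(se[-1L] > 100)
  converged <- isTRUE(fit$converged) && !separated
  terms_tab <- data.frame(term = rownames(sm), coef = est, se = se,
                          or = exp(est),
                          ci_low = exp(est - 1.96 * se),
                          ci_high = exp(est + 1.96 * se),
                          p_value = sm[, "Pr(>|z|)"],
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms_tab,
                 model = list(n = nrow(dat),
                              log_likelihood = as.numeric(stats::logLik(fit)),
                              included = attr(stats::terms(fit),
                                              "term.labels"),
                              converged = converged,
                              separation_flag = separated),
                 reference_levels = refs,
                 fit = fit),
            class = "fh_logistic")
}

#' Format adjusted odds ratios as a report table
#'
#' One row per exposure term with OR, 95\% CI and p value; categorical
#' reference levels are rendered as `"1.00 (ref.)"` rows.  Refuses to
#' format a non-converged fit.
#'
#' @param result an `fh_logistic`.
#' @param digits significant digits for OR/CI.
#' @return data.frame with columns `term`, `or`, `ci`, `p_value`
#'   (formatted strings).
#' @export
report_ors <- function(result, digits = 3) {
  stopifnot(inherits(result, "fh_logistic"))
  if (!result$model$converged)
    stop("refusing to report a non-converged fit",
         if (result$model$separation_flag)
           " (quasi-complete separation suspected)" else "")
  tt <- result$terms[result$terms$term != "(Intercept)", , drop = FALSE]
  fmt <- function(x) formatC(x, digits = digits, format = "fg", flag = "#")
  rows <- data.frame(term = tt$term, or = fmt(tt$or),
                     ci = paste0(fmt(tt$ci_low), "-", fmt(tt$ci_high)),
                     p_value = formatC(tt$p_value, digits = 3,
                                       format = "g"),
                     stringsAsFactors = FALSE)
  for (f in names(result$reference_levels)) {
    rows <- rbind(rows, data.frame(
      term = paste0(f, result$reference_levels[[f]], " (reference)"),
      or = "1.00 (ref.)", ci = "1.00 (ref.)", p_value = "",
      stringsAsFactors = FALSE))
  }
  row.names(rows) <- NULL
  rows
}
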