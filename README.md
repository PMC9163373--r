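# famhx

Extraction and impact analysis of **family history of psychiatric
disorder** in free-text psychiatric admission notes.

Admission notes bury family history inside a paragraph that also
describes the present illness, past history and physical examination.
`famhx` labels each note with a *quintet* of binary indicators over
five ICD-10 family-history categories —

> (F20 schizophrenia, F32 depressive episode, F31 bipolar disorder,
> F28 other non-organic mental disorders, F29 unspecified non-organic
> psychosis)

— merges note labels into patient labels by bitwise OR across
admissions, and quantifies the association between family history and
the first diagnosis at admission (MDD = 1 vs BD = 0) with a chi-squared
test and a multivariable stepwise logistic regression reporting
adjusted odds ratios exp(β) with Wald 95% intervals exp(β ± 1.96·SE).

Two interchangeable labeling engines are provided:

* a **rule-based annotator**: dictionary longest-match segmentation,
  family-history section location by cue phrase (家族史 in the default
  Chinese lexicon), nearest-preceding kinship attachment with
  first/second/third consanguinity degrees, and clause-level negation
  handling;
* a **neural multi-label classifier**: token embeddings with an
  optional compact contextual encoder, convolutions of widths {2,3,4}
  with ReLU and max-over-time pooling, and a fully connected sigmoid
  head — trained with Adam on mean per-label binary cross-entropy,
  implemented entirely in vectorised base R (forward and backward
  passes included), with grid search, five-run mean ± sd evaluation
  and a rule-hybrid post-filter.

Because clinical corpora cannot be redistributed, the package includes
a **seeded synthetic admission-note generator** with known ground truth
(diagnosis mix, per-diagnosis family-history rates, kinship mix, note
lengths calibrated to mean 204.3 / sd 65.66 characters) so the full
pipeline is testable end to end.  See the vignette
`vignettes/family-history-pipeline.Rmd` for the model and design
choices.

## Worked example

```r
library(famhx)
lx <- read_lexicon("debug_en")   # romanized lexicon; zh_default is the default
set.seed(1)

ev <- data.frame(patient_id = "P1", disease_code = "F32",
                 kinship_degree = "first", kin_term = "sister",
                 disease_term = "major depressive disorder")
note <- render_note(ev, target_length = 200L, lexicon = lx)
substr(note$text, 58, 146)
#> "FAMILY HISTORY: the patient's sister had been diagnosed with a major depressive disorder."

extract_events(note$text, lx)
#>   disease_code relation_term kinship_degree start end
#> 1          F32        sister          first   120 145
events_to_label(extract_events(note$text, lx))
#> F20 F32 F31 F28 F29
#>   0   1   0   0   0
```

The quintet reads: no family history of schizophrenia, a family history
of depressive episode (the sister), none of the other categories.  A
patient whose three admissions were labeled schizophrenia,
schizophrenia and depression merges to:

```r
merge_labels(list(fh_label(F20 = 1), fh_label(F20 = 1), fh_label(F32 = 1)))
#> F20 F32 F31 F28 F29
#>   1   1   0   0   0
```

An end-to-end run on a synthetic cohort (generate → annotate → merge →
evaluate → associate, with a tamper-evident manifest):

```r
cfg <- pipeline_config(corpus_config = corpus_config(n_patients = 400, seed = 2),
                       engine = "annotator", seed = 99)
res <- run_pipeline(cfg, "run1")
res$metrics$micro$f1        # note-level micro-F1 of the rule labels vs gold
res$association$logistic$terms   # adjusted ORs per family-history category
verify_run("run1")
```

A thin CLI over the same functions lives at `inst/cli/famhx.R`
(`synth`, `annotate`, `merge`, `evaluate`, `analyze`, `run`).

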