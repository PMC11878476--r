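# memotrace

Clinical NLP and trajectory analysis for prodromal dementia symptoms in
outpatient EHR data.

Dementia is frequently recognised long after the first complaints about
memory reach a clinician, and most of what those complaints looked like
lives in free-text notes, not in coded data. `memotrace` implements the
full path from notes to epidemiology:

* an ontology of nine entity types — memory-loss symptom (SX), dementia
  diagnosis (DX), temporal expression, duration, worsening status change,
  other symptom, cognitive test result, caregiver relation, and
  cognition-enhancing medication (RX) — and nine relations between them,
  persisted as BRAT-style standoff annotation;
* query expansion of a memory-loss seed lexicon via collocation bigrams and
  skip-gram embeddings, and rule-based note retrieval;
* a BiLSTM-CRF sequence tagger (word + character embeddings, BIO-constrained
  linear-chain CRF, Viterbi decoding) written in C++/RcppArmadillo, with the
  annotate-and-retrain loop `train_until()` that stops once validation
  micro-F1 = 2·P·R/(P+R) exceeds 0.8;
* rule-based relation linking (nearest compatible trigger in sentence) and
  exact-span evaluation (precision = TP/(TP+FP), recall = TP/(TP+FN));
* concept normalization of heterogeneous surfaces — "dtr" → daughter,
  "Aricept" → donepezil — from editable CSV lexicons;
* EHR cohort phenotyping (≥3 distinct dementia ICD-code dates + note
  documentation, annual visits, a pre-diagnosis visit, a documented
  memory-loss symptom; same-day complaint/diagnosis patients excluded from
  analysis);
* trajectory statistics: the interval in days between first complaint and
  first diagnosis, modelled linearly on care locations, age, insurance and
  caregiver group, and a logistic model of pre-diagnosis
  cognition-enhancing medication with odds ratios per additional complaint.

Because real clinical notes are protected, the package ships a synthetic
EHR generator (`generate_ehr()`) with gold annotations whose defaults
emulate published study-scale marginals: a 342-day median
complaint-to-diagnosis interval, a median of 3 complaints (range 1–18), a
25.1% pre-diagnosis medication rate with odds 1.148 per additional
complaint, geriatrics/primary-care/neurology location mixes, and a 20.4%
same-day rate. Every module is testable end-to-end against the generator's
planted ground truth.

## Worked example

Generate a 500-patient synthetic EHR, train the tagger with the iterative
loop, extract and normalize entities, phenotype the cohort, and analyze
trajectories:

```r
library(memotrace)

ds <- generate_ehr(generator_config(n_patients = 500, seed = 42))
#> <synthetic_ehr> 505 patients, 2318 visits, 2082 notes

batches <- split(ds$notes[1:400], ceiling(seq_along(ds$notes[1:400]) / 100))
model <- train_until(batches, tagger_config(seed = 1), f1_threshold = 0.8)
#> <trained_tagger> |V|=149, 19 tags, val F1 = 0.988

pred   <- annotate_notes(model, ds$notes)   # NER + rule linker
ext    <- normalize_extractions(pred)       # canonical concepts
cohort <- select_cohort(ds, ext)
#> <cohort_result> 482 included (93 same-day excluded, 389 analysis);
#>   exclusions: dementia_diagnosis=1, annual_visits=1,
#>   visit_before_diagnosis=4, memory_symptom=17

rec <- build_trajectories(cohort, ds, ext)
describe_intervals(rec)$interval_days
#>    min     q1 median     q3    max
#>      1    108    372    727   1460

res <- fit_medication_model(rec)$table
res[res$factor == "n_complaints", c("estimate", "ci_low", "ci_high", "p")]
#>    estimate ci_low ci_high         p
#> 16    1.291  1.115   1.496 0.0006356
```

Reading the output: the first training batch of 100 notes already clears
the 0.8 stopping criterion (validation micro-F1 0.988), so the loop stops
there. The cohort funnel removes one patient per violated criterion (the
generator plants one of each) plus 93 same-day patients; a further 17 are
lost because the single-batch tagger missed every symptom mention in their
notes — per-label scoring shows the rare RX label at recall 0 after one
batch, which is exactly the situation the annotate-and-retrain loop exists
for (a second batch lifts RX recall to 0.36 and micro-F1 to 0.97). The
median recovered interval (372 days on these 389 NER-derived analysis
patients) sits near the planted 342-day median, and the medication model
estimates an odds ratio of 1.29 (CI 1.12–1.50) per additional complaint
against a planted 1.148 at this small n.

A thin command-line dispatcher over the same functions is installed at
`inst/cli/memotrace.R` (`generate`, `expand-query`, `train`, `extract`,
`evaluate`, `phenotype`, `analyze`, `run`), and `run_pipeline()` wires all
stages into one seeded, manifest-logged run.

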