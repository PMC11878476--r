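---
title: "Models and methods: from memory-loss complaints to dementia diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from memory-loss complaints to dementia diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What the package does

`memotrace` implements an ontology-driven clinical NLP pipeline for the
prodromal phase of dementia, together with the downstream epidemiology it
feeds. Free-text outpatient notes are scanned for nine entity types — memory
loss symptoms (SX), dementia diagnoses (DX), temporal expressions, symptom
durations, worsening status changes, other symptoms, cognitive test results,
caregiver relations and cognition-enhancing medications (RX) — plus nine
semantic relations between them (has complaint date, has duration
information, has caregiver information, and so on). The extracted mentions
are normalized to canonical concepts, combined with coded EHR tables to
phenotype a dementia cohort, and summarised as per-patient trajectories:
the interval in days between the first memory-loss complaint and the first
dementia diagnosis, the number of complaints made before diagnosis, and
whether a cognition-enhancing medication was prescribed before diagnosis.

Because real clinical notes are protected health information, the package
ships a fully synthetic EHR generator with gold standoff annotations whose
defaults emulate the published marginals of a single-site outpatient
dementia cohort (n = 581). Every stage is testable end-to-end against the
generator's planted ground truth.

# The annotation model

Entities are character spans, 0-based and half-open over Unicode code
points, stored in a BRAT-dialect standoff format (`T` lines for entities,
`R` lines for relations) next to the raw `.txt` note. `parse_standoff()`
and `write_standoff()` are exact inverses on valid notes; the constructor
validates surface/offset agreement, id uniqueness, and relation
compatibility against the ontology schema (`ontology_schema()`).

Relation directions follow the relation names: the trigger (SX, DX or RX)
is the head and the satellite it qualifies is the tail, e.g.
`HAS_DURATION_INFO: SX -> DURATION` and `HAS_DIAGNOSIS_DATE: DX ->
TEMPORAL`. The map is overridable from YAML for sites whose annotation
guidelines differ.

Tokenisation is rule-based and offset-faithful: maximal alphanumeric runs
(apostrophes and underscores allowed inside) or single punctuation
characters. This means clinical shorthand such as `c/o` tokenises as three
tokens; entity spans are unaffected because they are character-addressed.
Entities whose boundaries fall inside a token are expanded to token
boundaries for BIO conversion; overlapping gold entities are resolved by
keeping the longer span (a linear-chain tagger needs non-overlapping
spans), with a warning.

# The BiLSTM-CRF tagger

The tagger follows the standard neural sequence-labelling design: per-token
inputs are the concatenation of a word embedding (lower-cased vocabulary,
trained `<unk>` vector for out-of-vocabulary tokens), a per-word character
BiLSTM summary (capturing abbreviations and casing-insensitive morphology),
and a capitalisation bit. Inputs pass through inverted dropout into a token
BiLSTM; a linear layer maps the concatenated hidden states to per-tag
emission scores; a linear-chain CRF with learned transitions and hard BIO
constraints (illegal transitions carry a -1e4 penalty and receive no
gradient) defines the sequence likelihood. Training minimises the CRF
negative log-likelihood with minibatch Adam. All forward/backward passes
are hand-written in C++ (RcppArmadillo) and verified against finite
differences in the test suite; Viterbi decoding and the log-partition are
verified against brute-force path enumeration.

Defaults (`tagger_config()`): word dimension 64, character dimension 16
with a 16-unit/direction character BiLSTM, 100 hidden units per direction,
dropout 0.5, Adam at 3e-3, at most 30 epochs with early stopping (patience
5 on validation span-F1, evaluated only after a 10-epoch floor), batch size
8. The learning rate and the floor were chosen for desk-scale corpora of
tens to hundreds of notes: with a smaller step size the exact-span
validation F1 can remain at zero for the first several epochs, which would
otherwise trigger the early stop before the model lifts off. Tie-breaking
in Viterbi is toward the lowest tag index, making decoding fully
deterministic; a fixed seed determines initialisation, the train/validation
split, shuffling and dropout, so training is reproducible single-threaded.

`train_until()` mirrors the annotate-and-retrain workflow used to build
clinical taggers: annotated notes arrive in batches; after each batch the
model is retrained from scratch on the accumulated pool (80/20 split) and
the loop stops once validation micro-F1 exceeds 0.8 (configurable). On the
synthetic corpus the threshold is typically reached with the first batch of
100 notes.

# Query expansion

A seed lexicon of memory-loss terms ("memory loss", "confusion",
"cognition impairment", "trouble remembering", "not recalling",
"forgetting", "blackout") is expanded in three steps: (1) collocation
bigrams are merged with the discounted score
`(count(ab) - delta) * |V| / (count(a) * count(b))` (defaults min_count 5,
delta 5, threshold 10); (2) skip-gram embeddings with negative sampling
(dimension 50, window 5, 5 negatives, 5 epochs, seed 13 — small because the
corpora are desk-scale) are trained single-threaded and deterministically;
(3) `expand_terms()` ranks vocabulary terms by cosine similarity to each
seed. Expansion is deliberately human-in-the-loop: the candidate file is
meant to be reviewed, and only accepted terms join the retrieval query.
`match_query()` retrieval is case-insensitive and word-boundary-anchored,
with multi-word terms matching across whitespace.

# Relation linking

The relation extractor is a deterministic rule: each satellite entity links
to the nearest compatible trigger in the same sentence within 20 tokens
(ties: SX preferred over DX for temporal satellites, then the leftmost
head), emitting the schema-implied relation label. A learned linker is out
of scope: the annotation geometry of the synthetic corpus — satellites
placed next to their triggers within one sentence — makes the rule exact,
and the corresponding invariant (recall 1.0 with gold entities as input)
holds by construction because the generator derives its gold relations by
running the same geometry.

# Concept normalization

Surface forms are folded (case, whitespace, underscores) and looked up in
editable CSV lexicons: symptom surfaces map to five canonical concepts
(memory_loss, forgetfulness, short_term_memory_deficit, confusion,
cognitive_impairment); caregiver surfaces (including abbreviations such as
"dtr") map to 13 canonical family relations; brand and generic drug names
map to the four cognition-enhancing generics (donepezil, memantine,
rivastigmine, galantamine — the shipped brand map Aricept/Namenda/Exelon/
Razadyne completes the generics with their standard US brands). Unmapped
surfaces return `UNMAPPED` rather than erroring, so they can be logged for
lexicon growth. For association analyses, canonical relations are grouped:
husband, wife and daughter stand alone; son, son-in-law, daughter-in-law,
grandson and granddaughter form "other adult children"; nephew, niece,
cousin, brother and sister form "other family support". A cognitive
test-name lexicon (MMSE, SLUMS, MoCA, Mini-Cog, clock drawing, trail
making, Boston naming, Wisconsin card sorting) supports entity
normalization but is excluded from trajectory analysis, where such
documentation is typically too sparse to model.

# Phenotyping

A patient enters the cohort when they (1) received a dementia diagnosis —
dementia ICD codes on at least three *distinct dates* (guarding against
duplicate-coding artifacts) plus dementia documentation (a DX entity) in a
note; (2) had at least one outpatient visit in every calendar year from
first visit through the diagnosis year; (3) had at least one visit strictly
before the diagnosis date; and (4) had at least one note with a memory-loss
symptom that normalizes to a canonical concept. The diagnosis index date is
the earlier of the first qualifying code date and the first DX-note date;
the complaint index date is the earliest memory-loss SX note date.
Patients whose two index dates coincide stay in the included set but are
excluded from analysis, so every analysis interval is at least one day.
Exclusions are attributed to the first failing criterion in the order
above. The shipped ICD set (F00–F03, F05.1, G30, G31.0, G31.83; 290,
294.1, 331.0; dot-insensitive prefix matching) is a standard dementia
phenotyping list assembled for this package and is configurable.

# Trajectory statistics

`build_trajectories()` derives one record per analysis patient. The
complaint count is the number of *distinct note dates* carrying a
memory-loss SX strictly before diagnosis (repeated mentions within one
visit are one complaint event); prior medication means any normalized
cognition-enhancing order or RX mention strictly before the diagnosis date
(an order on the diagnosis day does not count). Descriptives use Tukey
hinges (`fivenum`).

Two association models mirror the study design:

* a linear model of the interval in days on age group, primary insurance,
  complaint location, diagnosis location and caregiver group, with
  reference levels 85+, commercial, primary care (both locations) and
  husband. Per-coefficient Wald chi-square tests with 95% Wald CIs are
  reported — the only reading that reconciles per-level estimates, CIs and
  chi-square labels. The outcome is left untransformed (additive day
  estimates); a log-scale option exists behind a flag. One joint model is
  the default; missing caregiver groups are handled complete-case for that
  factor.
* a logistic model of prior medication on age group, both locations,
  caregiver group and the complaint count, reported as odds ratios with
  95% CIs. Perfect separation stops with an error when only one outcome
  class exists and otherwise falls back to a lightly ridge-penalized fit
  (lambda 1e-2 on non-intercept terms) with Wald CIs from the penalized
  Hessian.

# The synthetic EHR generator

The generator is first-class, tested code, not a fixture. Its defaults are
the study-scale conditions: demographic mixes (85+ 54.2%, female 65.6%,
White 87.6%, Medicare 60.9%...), complaint/diagnosis department mixes
(geriatrics 53%/60.2%, primary care 31.8%/28.1%, neurology 6.7%/10.5%), a
caregiver distribution with 49.9% missing, a 20.4% same-day
complaint/diagnosis rate, a truncated negative-binomial complaint count
with median 3 on 1..18 (size 1.5, mu 3.5), and a logistic medication model
with odds 1.148 per additional complaint and a marginal rate of 25.1%.
Intervals are drawn as `max(1, min(1460, round(shift + LogNormal(log m0,
0.8))))`, where the additive shifts per care location and caregiver group
default to the published day estimates and the reference median `m0` is
calibrated numerically (mixture-CDF root-finding) so the *marginal* median
over the covariate mixture is exactly 342 days; the lower clamp cannot move
mass across 342, so the calibration is exact. The medication intercept is
calibrated the same way against the truncated complaint-count
distribution. Medication effects other than the per-complaint odds are
planted at zero, reflecting a design in which complaint count is the only
real driver of prescribing.

Notes are rendered from roughly forty sentence templates across complaint,
caregiver, medication, test, duration, status-change and distractor
families; surfaces are drawn from the shipped lexicons with configurable
abbreviation ("dtr") and brand-name ("Aricept") rates, so the normalizer is
total on the generated vocabulary by construction. Gold offsets are exact
because notes are assembled from labelled segments. Five exclusion
archetypes are always present — one violating each selection criterion plus
a guaranteed same-day patient — so attrition logic is testable at any
cohort size. The seed fully determines the output, byte-for-byte.

What the generator does *not* emulate, and hence what passing tests do not
show about real notes: misspellings and OCR noise, negated or hypothetical
mentions ("no memory loss"), cross-sentence and coreferent relation
geometry, template-free language variety, coding errors in the structured
tables, and informative missingness of caregivers. NER performance on the
synthetic corpus is therefore an upper bound, and the rule linker's
exactness is a property of the template geometry, not of clinical prose.

## A known estimation limitation

Under the full default configuration the interval model's coefficient
estimates are attenuated toward zero: clamping intervals at one day
truncates the left tail precisely in the strongly negatively-shifted cells
(e.g. geriatrics complaint + geriatrics diagnosis + wife caregiver), so the
OLS contrast no longer equals the planted shift (roughly -92 observed
versus -141 planted for the geriatrics complaint effect at n = 20,000).
This is a property of the data-generating process, not of the estimator;
the test suite therefore checks coefficient recovery under a
single-planted-effect configuration where the model is well specified, and
checks the default configuration through the quantities that are exactly
calibrated (the marginal median interval and the medication odds ratio).
Real-world day-scale interval regressions share this boundary problem
whenever same-day events are excluded.

# Problem sizes used in the checks

The bundled checks run at deliberately desk-scale sizes chosen to make the
statistics informative while keeping a full run in minutes: tagger
development corpora of 100–400 notes, CRF oracle enumeration over 1000
random instances with up to 5 tokens and 4 tags, cohort recovery at 120
patients, marginal checks at 5000 patients, and association-model recovery
at 8000–20,000 patients. `scripts/acceptance.R` regenerates everything it
reports from scratch at these sizes.

# Numerical choices

Log-domain forward algorithm with log-sum-exp guarding; hard BIO mask as a
-1e4 additive penalty (kept finite so the partition stays well-defined;
masked transitions receive zero gradient); Glorot-style initialisation
with forget-gate biases at 1; Viterbi ties broken toward the lowest tag
index; zero-denominator precision/recall/F1 defined as 0 for stable
aggregation over sparse labels; greedy left-to-right 1:1 entity matching
(optimal under exact span matching with unique gold spans); dates are ISO
strings parsed to `Date`, with intervals in whole days.
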