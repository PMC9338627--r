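---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: what each stage
assumes, which parameters matter, what the synthetic generator does and
does not emulate, and where genuinely open design questions were settled.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The pipeline and its assumptions

Records arrive from three source types — genetic reports (genes +
variants, plus a report-level diagnosis), a structured warehouse
(diagnosis codes with dates and stages, medication orders), and clinical
note sentences (drug mentions). The pipeline assumes:

* a patient is identified by a clinic number, or failing that by
  case-folded first + last name **and** date of birth (both must match;
  the clinic number, when present, is the only key consulted);
* the genetic report is the diagnostic gold standard: on primary-cancer
  discordance the warehouse entry is kept but marked `superseded`;
* only cancer diagnoses (dictionary `is_cancer` flag) enter the graph;
* the earliest report receipt date is the patient's *index test date*.

## 2. Temporal validity rules

With `t` the index test date and `w = window_days` (default 365, the
operationalization of "one year"):

| Relation | Rule |
|---|---|
| `HasDisease`, `AssociatedWithGene` | diagnosis date in `[t − w, t]` (closed both ends) |
| `TreatedBy` | prescription date in `(t, t + w]` (half-open: treatment *initiated after* the report) |
| `MayTargetedBy` | same window, and the drug is a targeted therapy whose dictionary annotation lists a gene the patient carries |
| `MayTreatedBy` | prescription on/after the diagnosis date, no upper bound, any drug category, once per patient |

Boundary choices are explicit so they are testable: day `t − 365` and day
`t + 365` are inside, `t − 366` / `t + 366` are outside. `TreatedBy` is
*not* restricted to targeted therapies — a patient treated with an
immunotherapy is still `TreatedBy` it; the targeted-only restriction
applies to the gene–drug association `MayTargetedBy`, which is the edge a
treatment-recommendation query would follow. `HasContraindicationWith` is
schema-supported but never populated: no available source describes it.
Diagnoses dated after the test never yield `AssociatedWithGene` (the
window rule is one-sided by design) but still anchor `MayTreatedBy`; the
two rules are stated independently.

## 3. Concept normalization

Mapping is an exact, case-folded, punctuation-trimmed dictionary lookup
with score ∈ {0, 1}. Fuzzy candidate scoring was deliberately not
re-implemented: clinical mapping errors in this setting come from
abbreviation ambiguity and substring matching, which exact whole-word
lookup avoids by construction, and scores beyond exact/miss carry no
information the pipeline uses. No mapping-score acceptance threshold is
therefore needed.

Variant strings resolve in order: dictionary hit on the raw string →
dictionary hit on `"<gene> <raw>"` → single-letter protein-substitution
rewrite to three-letter HGVS (`L858R` → `p.Leu858Arg`, status
`hgvs_normalized`, no concept identifier) → unmapped verbatim. Deletions,
fusions, frameshifts and splice variants stay unmapped, which is what
drives realistic low variant coverage. In coverage statistics an
`hgvs_normalized` variant **without** a CUI counts as *not* identifiable
— it has no identifier to link on; this convention is the conservative
reading of "identifiable" and is exercised directly by the tests.

The bundled dictionary is a synthetic curated fixture (~34 genes, ~42
drugs with brand names, HemOnc-style categories and target-gene
annotations, ~20 diseases, hotspot variants for the simulated gene
universe). Only the EGFR gene identifiers are real published values;
everything else is a realistic-format placeholder. Two columns extend the
minimal dictionary contract because the pipeline's stated rules need
them: `is_cancer` (disease filter) and `target_genes` (the
`MayTargetedBy` annotation).

## 4. The synthetic cohort: a stated world

The generator's defaults are the published marginals of the cohort it
emulates; everything the source never printed is an explicit modelling
choice, fixed once:

* **Size and demographics.** 2,593 patients; 51.4% female, 88.7% white,
  3.5% Hispanic; mean age 62 at first test, 58 at initial diagnosis; ages
  clamped to ≥ 18 (adult research cohort). Report receipt dates uniform
  over January 2016 – June 2020.
* **Cancer mix.** Ten named types + unknown primary at 10%. Only some
  type names are documented for the emulated cohort; the remainder
  (breast, pancreatic, prostate, ovarian, cholangiocarcinoma, lymphoma)
  are placeholders chosen as common referral-center cancers. Per-type
  proportions beyond the 10% unknown-primary figure are not transcribed
  from any source and need not match it.
* **Mutations.** Independent Bernoulli draws per (cancer type, gene) with
  prevalences set to literature-plausible values (e.g. TP53 0.5 and EGFR
  0.17 in lung; KRAS 0.9 in pancreatic). Only marginal structure is
  modelled; co-mutation correlations are not.
* **Variant dialects.** Each finding's variant string is
  dictionary-covered nomenclature with probability
  `variant_mappable_frac = 0.195` (a hotspot protein substitution drawn
  from the dictionary), otherwise free-form (deletion / amplification /
  fusion / rearrangement / splice phrasing) that no exact lookup can map.
* **Treatment.** Two layers: a genotype-conditional *treatment affinity*
  (e.g. EGFR+lung → osimertinib 0.60, erlotinib 0.15, gefitinib 0.08,
  afatinib 0.06 within the post-test year) and a genotype-agnostic
  *background* per cancer type (e.g. lung: carboplatin 0.30,
  pembrolizumab 0.30, pemetrexed 0.25). The background layer is not in
  the minimal configuration contract but is required for the stated world
  to rank chemotherapy and immunotherapy below targeted agents rather
  than omit them entirely. Background drugs occasionally also occur
  pre-test (rate 0.25 × the post-test rate), exercising the window rules.
* **Survival.** Weibull from the diagnosis date, shape 1.1, per-stage
  scales (I: 2600, II: 2000, III: 1300, IV: 650 days), per-gene hazard
  multipliers applied as `scale × m^(−1/shape)` (default TP53 m = 2, i.e.
  a doubled hazard). The diagnosis-to-test gap is
  `min(Exp(mean 4 y), 0.9 × T)`: exponential to match the printed 4-year
  mean age difference, truncated by survival so that every patient is
  alive at testing. An earlier formulation (gap + independent residual)
  was discarded because the gap's variance diluted the planted hazard
  separation — the penalty is a property of survival from diagnosis, and
  the test date should not erode it. Consequence: the realized mean
  diagnosis-to-test gap is slightly below 4 years for short survivors.
* **Censoring.** Administrative cutoff at `study_end` (2021-06-30) plus
  random loss to follow-up with probability `censoring_rate = 0.25`,
  uniform between test and the administrative bound. The emulated study
  does not state its censoring mechanism; this is the standard
  registry-style choice.
* **Coverage and linkage.** 46% of patients carry warehouse diagnosis
  rows; 5% of those are discordant with the report (exercising the
  gold-standard rule) and half carry an extra non-cancer code. 92% of
  reports carry a clinic number; the rest link by name + date of birth.
  One report per patient by default; with several, the earliest receipt
  is the index date. Report-sourced diagnosis rows carry the diagnosis
  date (the clinical diagnosis is known at test time); the warehouse
  date/stage still wins when present.

**What a green test establishes — and what it does not.** The generator
reproduces marginal frequencies, planted conditional structure, and the
qualitative survival ordering. It does not emulate real clinical-note
prose (sentences are templated), panel-specific gene lists, co-mutation
correlation, informative censoring, or treatment switching; agreement
with it validates the pipeline's mechanics, not any clinical claim.

## 5. The RDF graph

Entities are deduplicated per concept; each contributes one class-typing
triple plus one triple per populated data property, and each distinct
(subject, predicate, object) relation contributes one object-property
triple, so `|triples| = Σ entities (1 + populated properties) + unique
relations` — a ledger the tests recount by brute force. IRIs are
deterministic: `namespace + Class + "/" + local`, where local is
`CUI-SanitizedName` when a CUI exists (so gene-centric retrieval can
filter on `regex(str(?Gene), "EGFR")` while remaining identifier-stable),
the sanitized name otherwise, and the verbatim `Patient_ID` for patients.
Dates are `xsd:date` typed literals; identifiers stay plain strings
(preserving leading zeros). `Stage_At_Diagnosis` is listed as a Disease
data property in the schema but left unpopulated: disease entities are
shared across patients, so a per-patient stage has no single value there
— stage lives on the resolved per-patient disease record instead.
Per-class triple counts use the subject-side convention: an
object-property triple counts toward its subject's class only.

Serializations are N-Triples (full IRIs) and a line-oriented Turtle
subset (`@prefix`, `a`, prefixed predicates); the parser accepts exactly
what the writer emits plus prefix redeclaration, and errors carry file
and line. The SPARQL engine supports SELECT/DISTINCT, basic graph
patterns with variables in any position, and `FILTER regex(str(?v), ...)`
— the subset the gene-centric retrieval contract requires; UPDATE,
federation and reasoning are out of scope.

## 6. Analytics

Transactions include **all** post-test drugs, not only targeted
therapies: the ranking's value is precisely that chemotherapy and
immunotherapy appear with lower confidence, and the targeted-only rule
belongs to relation emission, not to mining. Ties in confidence break
lexicographically for determinism. A rule whose antecedent has zero
support is an error (undefined), never 0 or NaN. No significance
machinery (confidence intervals, log-rank tests) is attached — the
outputs are the descriptive tables; a user wanting inference can take the
curves and transactions into `survival` or any rule-mining package.

The Kaplan–Meier implementation is the plain product-limit estimator;
censored times leave the risk set after their time, and the reported
median is the smallest time with `S(t) ≤ 0.5` (undefined if never
reached). The test suite checks it against hand computations, the
no-censoring closed form, and `survival::survfit`.

## 7. Numerical and degenerate-input choices

* Probabilities are validated to `[0, 1]`; cancer-type weights must sum
  to 1 within 1e-9; hazard multipliers must be positive. Configuration
  errors name the offending field.
* `confidence × support(antecedent) = support(union)` holds to 1e-12
  (plain double arithmetic on counts).
* Empty cohorts, empty graphs, empty relation sets and all-censored
  survival inputs all produce well-formed empty results, not errors;
  records with missing dates are skipped with a warning.
* Determinism: a single integer seed fixes the whole cohort; graph
  construction and query evaluation are deterministic given their inputs.

## 8. Known limitations

Exact-match normalization cannot map misspellings or novel synonyms;
the SPARQL subset excludes OPTIONAL/UNION/paths; record linkage is
deterministic (no probabilistic matching); `AssociatedWithGene` uses all
in-window cancer diagnoses, not only the primary (the emulated procedure
does not say which); and the association analysis is purely associative —
confidence rankings reflect prescription practice, not efficacy.
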