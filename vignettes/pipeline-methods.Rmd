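---
title: "Identifying access to germline genetic testing from clinical notes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying access to germline genetic testing from clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtaccess)
```

## The problem

Guidelines recommend germline genetic testing for patients with breast
cancer, but whether a given patient was actually offered testing is usually
recorded only in free-text clinical notes, scattered across dozens of
documents per patient. Auditing access at population scale therefore
requires reading charts — or a pipeline that reads them automatically.

`gtaccess` implements such a pipeline as a reusable, fully testable package:

1. **Snippet extraction.** A keyword lexicon (genes such as *BRCA1/2*,
   *PALB2*, *CHEK2*; services such as *genomic medicine service*; testing
   vocabulary such as *germline*, *gene panel*) is matched case-insensitively
   as whole words against every note. Each hit is expanded to a context
   window of 100 words on either side; overlapping windows within a note are
   merged. All of a patient's snippets are concatenated in care-timeline
   order (note date, then note id, then position) and cleaned into a single
   consolidated document.
2. **Triage.** Deterministic pre-classification rules: zero snippets is an
   automatic negative (nothing to read); at least 20 snippets, or a
   consolidated document exceeding 4,000 words, is an automatic positive
   (that concept burden was always associated with testing having been
   offered). Everyone else goes to the classifier.
3. **Classification.** A zero-shot prompt embeds the four category
   definitions and demands a fixed answer scaffold (`ANSWER: <category>`),
   rendered with the consolidated document and sent to a pluggable backend.
   Responses are parsed by regular expression; the four categories (Yes /
   No / Not applicable / Not sure) are consolidated to a binary outcome,
   with only *Yes* positive.
4. **Evaluation.** Confusion matrices; accuracy, precision, recall, and F1;
   percentile-bootstrap confidence intervals; development/testing splits
   stratified by label and reviewer disagreement; agreed-case subsets;
   per-reviewer accuracies; and chi-square comparisons.

Because the motivating data are protected health records, the package ships
a **synthetic corpus generator** whose defaults encode the published corpus
statistics, so the entire pipeline can be exercised, calibrated, and tested
end to end on a laptop.

## The classifier backend contract

A backend is any object providing `complete(prompt, settings, patient_id)`.
Default generation settings are temperature 0.75 and top-p 0.9. Two mock
backends make runs deterministic without model weights:

* `scripted_backend()` replays a fixed mapping (by patient id or exact
  prompt), the tool for constructing runs with a planned error set;
* `heuristic_backend()` scans the document for the generator's category
  marker phrases and answers in the scaffold, optionally flipping the
  category with a configured error rate from a private seeded RNG stream.

An adapter for an OpenAI-compatible HTTP endpoint (`http_backend()`) is
provided for real models but deliberately excluded from the test suite.

Unparseable responses map to *Not sure* with `parse_ok = FALSE` rather than
triggering a retry: retries belong in backend adapters, and a total,
deterministic parse keeps whole-pipeline runs reproducible.

## What the synthetic generator emulates

Defaults of `cohort_config()` are the stated world, not tuning knobs:

| quantity | target | source of the default |
|---|---|---|
| label prevalence | Yes .59, No .305, NA .055, NS .05 | published label table |
| zero-snippet patients | 21.5%, always binary-negative | 43 of 200 |
| high-burden patients | 13.5%, always Yes | 27 of 200 |
| notes/patient | log-normal, median 42, IQR 21–82 | published |
| snippets/patient | log-normal, median 4, IQR 1–10 | published |
| snippet words | log-normal, median 199, IQR 124–285 | published |
| reviewer disagreement | 14.5% | published |

All count distributions are log-normal, parameterised directly from the
printed median and IQR (`meanlog = log(median)`,
`sdlog = log(q75/q25) / (2 qnorm(.75))`): strictly positive, right-skewed,
and requiring no unpublished moments. The published summaries give only
median and IQR, so the family itself is a design choice, not a reported
fact.

### Strata as tails, not bolt-ons

The delicate design question was how the two automatic-triage strata relate
to the count distributions. Simply forcing high-burden patients to carry 20+
snippets (or inflating their documents) stacks 13.5% of extra mass onto the
top tail: the snippet-bearing medians then drift to roughly 6 snippets and
1,500 words, far from the published 4 and 800. In real data the high-burden
patients *are* the upper tail of the one empirical distribution, not a
separate population. The generator therefore draws each snippet-bearing
patient's profile (snippet count *k*, per-snippet word counts) from one
joint distribution and uses rejection sampling to match the configured
stratum: high-burden requires *k* ≥ 20 **or** total words > 4,000, normal
requires neither. The natural tail probability (≈ 0.20 of snippet-bearing
patients) is close to the configured 0.172, so the rejection step distorts
the marginals only mildly.

### Correlated snippet lengths

The published summaries are mutually consistent only if snippet count and
snippet length are negatively correlated within patients: a consolidated
document is the *sum* of its snippet lengths, and with independent draws
(log-normal, median 199, mean 241) the document median comes out near 890
with a very heavy upper tail (upper quartile ≈ 2,600 vs the published
1,554) — patients with 15 independent snippets would carry 3,000-word
documents that the published document IQR rules out. Clinically this
correlation is the signature of repetition: high-mention patients
accumulate many short, overlapping, templated mentions rather than many
long distinct discussions.

Snippet lengths therefore share a patient-level log-scale factor
anti-correlated with the snippet count's log deviation. The marginal
snippet-length distribution keeps its published median and IQR exactly (the
patient-level and within-patient variances sum to the published log-scale
variance); 95% of the log-length variance is assigned to the patient level,
the largest share that keeps within-patient variation non-degenerate, chosen
because it brings the emergent document median as close to the published 800
as the summation structure allows. Measured at n = 2,000: median snippets 4,
median consolidated document ≈ 840 words (upper quartile ≈ 1,700), median
notes/patient 45 — all within the 15% calibration band, stably across seeds.
One consequence is documented rather than hidden: corpus-wide, snippets
drawn for high-count patients run shorter than the marginal distribution, so
the note-weighted snippet-length median sits below 199 even though
`generate_note()`'s length draws follow the published distribution exactly.

Two measurement conventions follow from the arithmetic and are used
consistently: snippet-count and document-length medians are computed over
**snippet-bearing** patients (with 21.5% zero-snippet patients included, a
median of 4 is unattainable from any distribution with median 4), and the
snippet word-count distribution describes **evidence notes** (high-burden
documents necessarily occupy the top of any per-patient aggregate).

### Note construction

Each evidence note embeds one category-consistent evidence phrase from a
fixed, versioned phrase bank (orders/referrals/completed testing for *Yes*;
considered-but-not-meeting-criteria for *Not sure*; community-care-only
phrasing for *Not applicable*; testing-not-discussed distractors for *No*),
padded with filler drawn from a vocabulary disjoint from every lexicon word.
Notes longer than one context window carry additional bare keyword mentions
spaced < 200 words apart, so all windows chain-merge into a single snippet
whose word count equals the drawn target exactly — the generator's length
draws survive extraction, consolidation, and cleaning unchanged. Zero-snippet
patients' notes are filler only and can never match the lexicon. Filler-note
lengths (20–120 words) and the date (2021–2022) / specialty vocabularies are
plumbing choices that affect no calibrated quantity.

Simulated review gives every patient two reviewer labels and an adjudicated
consensus equal to the truth; with probability 0.145 exactly one reviewer is
perturbed to a semantically adjacent category (Yes↔Not sure,
No↔Not applicable, Not sure↔No/Yes). The adjacency structure is a modelling
choice; the source reports only the disagreement rate.

### What a green test does not establish

The generator reproduces the *statistical and lexical* structure the
pipeline consumes — counts, lengths, label mixes, keyword placement — not
clinical narrative. Real notes contain negation, templated questionnaires,
copy-forward text, and section structure that keyword windows handle only
approximately; a perfect score for the heuristic backend on synthetic data
says the plumbing is correct, not that any particular LLM will reach the
published performance on real charts.

## Numerical and procedural choices

* **Words** are maximal whitespace-delimited runs, punctuation attached —
  the simplest reproducible reading of "100 words"; all thresholds count
  words this way, measured on the cleaned consolidated text.
* **Cleaning** keeps ASCII letters, digits, space, and `. , ; : ? ! ( ) ' /
  -`, collapses whitespace, trims, and is idempotent.
* **Merged windows** count as one snippet (the published counting unit is
  ambiguous); merging avoids double-counting against the ≥ 20 triage rule.
* **Thresholds**: "at least 20" is inclusive, "exceeded 4,000" strict; both
  overridable; the zero-snippet rule runs first and can never conflict.
* **Bootstrap** is the percentile method, resampling patients n-out-of-n,
  5,000 iterations by default; replicates where a metric is undefined are
  skipped and counted. Undefined metrics use `NA` markers, never 0.
* **Splits** shuffle within stratum (label × disagreement) and allocate
  proportionally; odd strata alternate the extra case across strata in
  sorted order, so neither half accumulates remainders.
* **Chi-square** defaults to Pearson without continuity correction, with
  Yates available by flag; the published analysis did not state its variant.
  (The published reviewer-vs-pipeline P = .188 is not reproducible from
  96/100 vs 93/100 under either variant, which give ≈ .35 and ≈ .54; the
  package documents this rather than guessing the construction.)
* **Reviewer accuracy** is scored on the binary consolidation, matching how
  the pipeline itself is scored.
* **Determinism**: every stochastic operation seeds a local RNG and restores
  the caller's state; mock-backend pipelines and file outputs (no
  timestamps in manifests) are byte-identical under rerun.

## Known limitations

* Keyword windows, not clinical NLP: no negation or section awareness.
* The exact production prompt of the motivating study is unpublished; the
  shipped template embeds the category definitions and scaffold but is a
  reconstruction, exposed as an editable asset.
* Log-normality beyond the median/IQR is assumed, not published.
* The heuristic backend is an oracle for the generator's phrase bank only;
  it measures pipeline correctness, not language-model capability.
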