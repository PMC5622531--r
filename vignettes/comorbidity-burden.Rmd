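---
title: "Estimating comorbidity burden from literature and electronic health records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating comorbidity burden from literature and electronic health records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litcomorbid)
library(dplyr)
```

## The problem

Estimating how much comorbidity accompanies an index disease in routine-care
data requires three decisions that are usually left to experts: *which*
comorbidities to look for, *how* to recognise them in the record, and *how*
to turn detections into prevalence estimates. litcomorbid implements a
data-driven alternative, developed around the case of autoimmune
comorbidities in adult celiac disease:

1. **Candidate selection from the literature.** MEDLINE indexes every
   citation with MeSH descriptors; the co-occurrence file counts, for each
   descriptor pair, how many citations carry both. Restricting partners of
   the index descriptor to a hierarchy subtree (autoimmune diseases live
   under tree number `C20.111`) and keeping the K most co-cited partners
   yields a reproducible comorbidity panel without expert elicitation.
2. **Terminology mapping.** Each panel disease is expressed as machine-usable
   detectors: ICD-10 code patterns (with descendant and OR semantics as used
   in billing catalogs), ATC drug-code prefixes where a drug is specific to
   the disease (levothyroxine for autoimmune thyroiditis, insulin for type 1
   diabetes), and regular expressions over clinical text.
3. **Phenotyping.** A patient is a case for a disease if *any* source fires
   at least once — one matching ICD code, one matching prescription, or one
   reviewed text mention. The studied comorbidities are chronic, so
   detection is timeless by design: calls are invariant to event dates.
4. **Estimation.** Per-disease prevalence with a binomial confidence
   interval, an any-disease burden summary, two-reviewer agreement (Cohen's
   kappa), encounter-timing regularity (Sperrin's I), and rank concordance
   between literature attention and observed prevalence (Spearman's rho).

## The statistical toolkit

### Prevalence intervals and the Wilson trigger

The point estimate for $x$ cases among $n$ patients is $1000\,x/n$ per mille.
The default interval is the Wald approximation
$\hat p \pm z_{1-\alpha/2}\sqrt{\hat p(1-\hat p)/n}$ with
$z = 1.959964$. Near zero the Wald interval misbehaves — its lower bound
goes negative, and at $x = 0$ it collapses to a point. The selection rule is
therefore: **use the Wilson score interval whenever the Wald lower bound is
negative or the case count is zero.** On the reference cohort of 741
patients this rule selects Wilson for exactly the rows of the published
prevalence table printed with Wilson-style bounds, including the 3-case row
whose Wald lower bound is $-0.5$ per 1000. The Wilson lower bound at zero
successes is exactly 0, and Wilson bounds can never leave $[0, 1000]$ per
mille. Clopper–Pearson exact intervals are deliberately out of scope: the
toolkit mirrors the published analysis, which used the normal/Wilson pair.

Reported tables round per-1000 values to one decimal, half-up; internal
computation keeps full precision.

### Sperrin's regularity index

For a patient with $n \ge 2$ encounters spanning a positive follow-up, the
$n-1$ consecutive gaps $g_i$ are normalised by the total span (so they sum
to 1) and

$$I = \frac{2}{n} + \frac{n-2}{n}\left[1 - \sqrt{(n-1)\,\mathrm{Var}(g_i)}\right].$$

Two conventions are not fixed by the formula as usually stated, and we fix
them here once:

* **Gap normalisation.** Gaps are expressed as fractions of the follow-up
  span, making the variance dimensionless and the index invariant to
  shifting or scaling the date axis.
* **Variance estimator.** $\mathrm{Var}$ is the population variance (mean
  squared deviation) over the $n-1$ gaps.

With these choices $I = 1$ exactly at perfect regularity (equal gaps make
the variance vanish) and at $n = 2$ (the $(n-2)/n$ factor vanishes, leaving
$2/n = 1$), matching the index's meaning as a regularity score; the result
is clamped to $[0, 1]$ against floating-point excursions. Patients with
fewer than two distinct encounter dates, or a zero span, are excluded (the
index is undefined there, and `sperrin_index()` signals rather than
returning 0).

### Agreement and concordance

`cohens_kappa()` is the standard two-rater, two-category chance-corrected
agreement from the 2×2 vote table; it is symmetric in the raters and
signals when the expected agreement is 1 (degenerate marginals). A useful
robustness fact, verified by brute force in the tests: with 140 joint
approvals, 304 joint rejections and 22 disagreements, kappa rounds to 0.89
for *every* possible split of the disagreements between the two off-diagonal
cells, so the published agreement is insensitive to how disagreements were
oriented.

`spearman_rho()` assigns average ranks to ties in each vector and returns
the Pearson correlation of the rank vectors (delegated to
`stats::cor(method = "spearman")`; the test suite checks it against an
explicit rank-then-correlate oracle over exhaustive small permutations).
Panel diseases with no prevalence-table row enter the concordance
computation with zero cases.

### Source attribution

For each disease, cases partition into *text only*, *structured only* (ICD
and/or drug, no text) and *both*; the three counts always sum to the case
count, and proportions are undefined (reported as `NA`/null) when a disease
has no cases.

## Adjudication of text candidates

Text matching is deliberately simple — word-boundary-anchored regular
expressions over accent-folded, lower-cased text, with optional edit-
distance-1 token matching for terms flagged `fuzzy`. No negation or
context handling is implemented: the workflow this package models relies on
*human* review of highlighted candidates, and raw-match mode (used when no
votes are supplied) is over-sensitive by construction and should be treated
as such. When a vote table is supplied, text detections are gated through
per-(patient, disease) adjudication items. The default policy is
`consensus`: both reviewers must approve; joint rejection yields a
non-case; disagreement leaves the item `unresolved`, and unresolved items
are *excluded* from case counts and reported separately — how disagreements
were resolved in the original review is not documented, so both
`any_approve` and `single_reader` policies are provided for sensitivity
analyses.

Match spans are 0-based, half-open offsets into the accent-folded text, and
the stored snippet equals the folded substring at the span, so every match
is independently verifiable from its document.

## The synthetic EHR generator

No patient-level data can ship with the package, so `generate_bundle()`
produces an EHR bundle (patients, encounters, documents, coded diagnoses,
prescriptions) whose statistical structure matches what the workflow
assumes, with known ground truth. Defaults are fixed once, as the study
conditions of the reference cohort:

* `n_patients = 741`; every patient carries the index disease, either as a
  registry member (60%) or with the full warehouse criteria (index ICD
  code, index-department encounter, index-term document) so cohort
  selection recovers the whole bundle.
* Per-disease true prevalences are the reference case counts over 741 (the
  one panel disease with no published case counts as zero).
* Detection sensitivities given a case: text 0.95 for all diseases, ICD
  0.15, drug 0.08 for the two drug-marked diseases. These are not published
  quantities; they were chosen once to reproduce the text-dominant source
  mix of the reference study (roughly 79% of detected cases text-only, 5%
  structured-only, 15% both) and not revisited. A `source_correlation`
  knob makes the three detectors share a latent severity draw, because the
  published per-disease source overlaps are visibly not independent; the
  default is independence.
* Non-cases never fire a detector by default (`false_positive_rate = 0`);
  a knob exists for robustness experiments.
* Encounter counts are 1 + negative binomial (median ≈ 3, long tail);
  encounter timing defaults to `clustered` — admission-like bursts of
  close-by contacts — because burst structure is what depresses the
  regularity index to the ~0.76 mean observed in hospital data. `regular`
  and `jittered` schemes are available; `regular` yields $I = 1$ exactly.
* Documents mix French-like and English-like templates (15% English), so
  accent folding is exercised end to end. A text firing inserts the
  disease's trigger term into a generated report; the generator's triggers
  and the shipped mapping catalog are consistency-tested against each other
  in both directions (every firing is detectable; nothing else is).

What the generator does *not* emulate: realistic clinical language (no
negations, no rejected hypotheses, no section structure), disease
co-occurrence (case draws are independent across diseases, which slightly
inflates the any-disease burden relative to a real cohort where autoimmune
conditions cluster), temporal disease progression, and coding-practice
drift over calendar time. Passing tests on synthetic data therefore
demonstrate that the machinery is correct and calibrated under the stated
assumptions — not that raw-match text detection would be precise on real
clinical narratives, which is exactly why the workflow keeps a human
reviewer in the loop.

`generate_cooccurrence()` plants the reference (index, disease) citation
counts among decoy descriptors outside the autoimmune subtree, some with
pair counts *above* the top planted count, so the subtree restriction is
load-bearing in every test that uses it.

## Numerical and design choices

* **Tie at the ranking cut.** The published panel was formed by a count
  cutoff at rank 15 with no documented tie rule. If several partners tie
  exactly at the cut, the panel keeps all of them and warns, rather than
  truncating arbitrarily; display order breaks ties by descriptor ID. The
  tests enumerate small tied inputs to pin this behaviour.
* **Subtree matching respects dot boundaries.** `C20.111` covers
  `C20.111` and `C20.111.x`, never `C20.1119`: tree numbers are positional
  addresses, not strings.
* **ICD-10 normalisation.** Codes are dot-stripped and upper-cased before
  comparison, because billing extracts write `E10.1` and `E101`
  interchangeably; matching is exact-stem or prefix (descendant).
* **ATC matching** is prefix-based at any hierarchy level, so a short stem
  covers all formulations of a drug family; the mapping ships prefixes
  rather than an enumerated code list.
* **Duplicate co-occurrence pairs** (after unordered canonicalisation) are
  summed with a warning; self-pairs are rejected.
* **Study window** is the closed interval 2000-01-01 to 2014-12-31 by
  default (whether the published window bounds were inclusive is unstated;
  both endpoints are included here and the window is configurable).
* **Co-occurrence dialect.** Real MEDLINE co-occurrence distributions are
  release-specific; the package defines a minimal delimited dialect
  (`dui_a`, `dui_b`, `count`, optional ignored `year`) and leaves
  conversion from a native distribution to a one-off preprocessing step.
* **Mapping fixture.** The shipped catalog reproduces the published
  15-disease ICD-10 patterns; the text-term catalog is a synthetic
  reconstruction from disease names and common French/English synonyms
  (the original review catalog is not published) and is flagged as such in
  the file itself.

## Problem sizes used in the test suite

The suite exercises the generator at 50,000 patients for the
law-of-large-numbers calibration check (each disease's empirical prevalence
within a simultaneous 1% family-wise normal bound of its planted value),
and runs 200 seeded replicates at the study scale (741 patients) with
perfect detection sensitivities for the end-to-end recovery check: the
planted burden and per-disease prevalences must fall inside the pipeline's
own 95% intervals in at least 93% of replicates. Under imperfect
sensitivities the pipeline estimates the *detectable* prevalence (truth ×
combined sensitivity), which is the comparison the calibration tests use in
that regime; comparing a deliberately desensitised estimate against raw
truth would mix bias into a coverage statement.

## A worked example

```{r example}
descriptors <- read_mesh_descriptors(
  system.file("extdata", "mesh_descriptors.tsv", package = "litcomorbid"))
records <- read_cooccurrence(
  system.file("extdata", "cooccurrence.tsv", package = "litcomorbid"))
panel <- rank_comorbidities(records, "D002446",
                            mesh_subtree(descriptors, "C20.111"), 15)
glance(panel)

sim <- generate_bundle(synth_config(n_patients = 741, seed = 2026))
res <- run_pipeline(
  descriptors, records,
  system.file("extdata", "mappings.yaml", package = "litcomorbid"),
  sim$bundle)
tidy(res$prevalence) |> head(5)
res$summary[c("burden_per_1000", "mean_sperrin_I", "spearman_rho")]
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(res$prevalence)
plot_source_attribution(res$attribution, names = res$mappings[c("dui", "name")])
```

## Known limitations

* Raw-match text detection has no notion of negation, family history or
  temporality; it is a candidate generator for human review, not a
  classifier.
* The package validates and applies terminology mappings but does not build
  them: deriving ICD-10/ATC/term mappings from a terminology server is an
  upstream, licensed step, and the mapping config is the interface.
* Year-stratified ("as-of") literature ranking is not implemented.
* Confidence-interval endpoints reproduce published tables to about one
  unit in the last printed decimal (the published rounding convention for
  interval endpoints is not fully consistent); point estimates reproduce
  exactly.
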