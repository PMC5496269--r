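---
title: "Methods: ensemble pathogenicity scoring and phenotype prediction for MPS I"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble pathogenicity scoring and phenotype prediction for MPS I}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saamp)
```

## The problem

Mucopolysaccharidosis type I (MPS I) is an autosomal recessive lysosomal
disease caused by deficiency of α-L-iduronidase (IDUA). Clinical severity
spans a continuum conventionally divided into Hurler (severe),
Hurler-Scheie (intermediate) and Scheie (mild) phenotypes, and treatment
outcomes improve sharply with early intervention — which makes phenotype
prediction from genotype clinically valuable. No single in-silico
variant-effect predictor is reliable enough on its own, so this package
implements an ensemble approach: seven established predictors are reduced to
binary damaging/benign calls and aggregated, and for known mutations a
curated severity knowledge base feeds a small rule engine that maps a
diallelic genotype to a phenotype call.

## The ensemble and its thresholds

Each tool's published decision rule is applied to its native score
(`categorize_score()`); all thresholds are strict inequalities, so boundary
values fall in the non-extreme class:

| tool | score | damaging call when |
|---|---|---|
| SIFT | tolerance index, 0–1 | < 0.05 (`deleterious`) |
| PolyPhen | PSIC-based score, 0–1 | > 0.85 (`probably_damaging`) |
| I-Mutant | DDG, kcal/mol | < −0.5 (`large_decrease`) |
| PROVEAN | alignment score | < −2.5 (`deleterious`) |
| PANTHER | subPSEC (or disease probability) | < −3 (probability > 0.5) |
| SNPs&GO | disease probability, 0–1 | > 0.5 (`disease`) |
| PHD-SNP | disease probability, 0–1 | > 0.5 (`disease`) |

`is_damaging()` collapses each vocabulary onto one binary axis. Two
deliberate choices: PolyPhen's `possibly_damaging` counts as *not* damaging
(the screen retains only probably-damaging variants) and I-Mutant's
`large_increase` counts as *not* damaging (only large stability decreases
pass). Where a table supplies both a numeric score and a printed label and
the two disagree, the printed label wins and the conflict is recorded on the
profile object — never silently resolved. The packaged tables contain two
such conflicts: the PHD-SNP call for G265R (labelled disease at probability
0.12) and the SIFT call for F143L (labelled deleterious at tolerance index
0.05, which the strict threshold reads as tolerated).

## The pathogenic index

For a variant with `a` available tool calls of which `d` are damaging, the
pathogenic index is the exact fraction `PI = d / a`. Classification is an
integer count rule: with all seven tools, a variant is pathogenic at the
sensitive cutoff when `d >= 3` and at the specific cutoff when `d >= 4`. The
familiar spellings 0.43 and 0.57 are two-decimal half-up display roundings
of 3/7 and 4/7; comparing the rounded decimal against PI would misclassify
the boundary case (3/7 ≈ 0.4286 < 0.43), so the count rule is the
operational definition and the decimals are labels. With fewer than seven
tools the threshold generalizes to `k = ceiling(fraction × available)`
(integer arithmetic on the exact fraction), which reproduces the 7-tool
behaviour and errs on the sensitive side; a warning marks partial profiles.
Display rounding everywhere is half *up* (`round_half_up()`), matching the
94%/80% reporting style, not base R's round-half-even.

The sensitive cutoff is the recommended default: in a screening context a
false benign call (a missed patient) costs more than a false pathogenic one.

## The screening funnel

`run_funnel()` applies the predictors sequentially — SIFT, PolyPhen,
I-Mutant, PROVEAN, then a consensus stage requiring all three of PANTHER,
SNPs&GO and PHD-SNP to call disease — and reports entering/surviving counts
per stage. Each stage is an independent predicate, so the final survivor set
is invariant to the order of the first four stages (asserted by brute force
in the tests); the sequential presentation exists for its per-stage counts.
A profile lacking a stage's call is eliminated with the distinct reason
`not_evaluated` (the source study always had complete profiles; real inputs
will not), or raises an error under `strict = TRUE`. Running the packaged
score tables through the funnel in label mode yields the published
28-variant endpoint; re-thresholding the probabilities at 0.5 instead of
trusting printed labels yields 27, the difference being exactly the G265R
conflict. Both modes are first-class because the original analysis does not
state which was used.

## The severity knowledge base and the genotype rules

The knowledge base (`load_severity_kb()`) is a transcription of the curated
severity tables: mutation name (legacy nomenclature, whitespace-normalized),
mutation class by the tables' column placement, one or more severities per
entry, and a low-reliability flag. Severity may be set-valued
(`"mild,intermediate"`) — the curators' uncertainty is preserved, not
collapsed to a worst case.

Transcription fidelity takes precedence over the prose summary counts.
`kb_validation_report()` compares the two and currently flags real
conflicts: the prose total of 185 mutations (86 missense) against 183
transcribed entries (84 missense) — the printed missense/nonsense table is
two cells short of its own prose summary — and severity breakdowns that the
dual-labelled entries (e.g. `intermediate,severe`) make ambiguous. Three
class assignments follow column placement rather than name pattern:
`3308del12` and `c.1-2C>G` are filed under splicing and `D444/445` under
deletions/insertions, which is what makes the 32-splicing / 45-deletion
totals balance.

`combine_alleles()` encodes the four diallelic rules: both alleles severe →
Hurler; intermediate + severe → Hurler-Scheie; both intermediate →
Hurler-Scheie or Scheie; any mild allele → Scheie; any unknown → unknown.
Rule precedence is explicit: the any-mild rule fires before the
both-intermediate rule, so mild + intermediate is Scheie, not ambiguous.
Set-valued severities propagate by Cartesian closure — the result is the
union of the atomic results over all severity pairs — because collapsing
would fabricate certainty the curation does not claim. `predict_phenotype()`
wraps the workflow per allele (knowledge base → ensemble fallback → unknown)
and returns a trace; the ensemble fallback reports pathogenic/benign only,
since none of the seven tools grades severity, and the trace states that
computational evidence is supporting-level only.

## UTR variants

Two annotation rules, applied to records supplied by the user (the package
does not scan sequences for motifs): a UTR variant is flagged when the
functional element recognized before and after the substitution differs,
with "no pattern" as a first-class none state; and a polymorphic miRNA
target site is flagged when its class is C (creates a site) or D (disrupts a
conserved site), the two classes most likely to perturb repression.

## The synthetic benchmark generator

`generate_benchmark()` emulates the *structure* of the published evaluation
panel — labelled pathogenic and benign variants, each with seven binary tool
calls — so the scoring and evaluation machinery is testable offline.
Conditional on the true label, each tool calls damaging with probability
equal to its sensitivity (pathogenic variants) or 1 − specificity (benign
variants). Defaults are 0.85/0.85 per tool, a realistic middle of the
accuracy range reported for predictors of this class; label balance is
exact; mutation names are synthesized in legacy nomenclature for parser
fuzzing. Calls are independent given the label by default, which is what
makes the ensemble metrics analytically predictable: sensitivity at count
threshold `k` is the binomial tail `P(X ≥ k)` with `X ~ Binomial(7, 0.85)`,
the closed form the tests check against at 3 Monte-Carlo standard errors
with panels of 1,000 + 1,000 variants. Real predictors share training data
and conservation signals and therefore correlate; the `correlation` knob
(a per-variant latent difficulty shifting all tools' logits) exists for
sensitivity analyses but is an extension beyond the published design.
What passing these tests shows is that the aggregation and evaluation
machinery is correct — not that real-tool ensembles achieve the published
94%/80%, which would require the unpublished per-tool outputs for the 81 + 15
benchmark mutations.

## Numerical and design notes

* Name matching is case-sensitive after whitespace normalization; lookups
  fall back to a case-insensitive match with a warning.
* The parser never errors on a name: anything unrecognized is class
  `unknown` with the raw text preserved.
* `evaluate_benchmark()` reports an undefined metric as `NA` when a truth
  class is empty, never as 0.
* Degenerate inputs: an empty profile table gives an all-zero funnel report;
  a profile with zero available tools is an error (`"no predictions"`).
* Surface-accessibility records (native/mutant RSA, ASA, Z-fit) are packaged
  as printed and never recomputed.

## Limitations

The knowledge base is a static curation; it cannot grade novel mutations, and
its severities inherit the reliability limits of the underlying case
reports (hence the low-reliability flags). The ensemble treats the seven
tools as equally weighted and independent, which they are not in reality;
the pathogenic index is a vote share, not a calibrated probability. The
genotype rules assume both alleles' severities are known or confidently
predicted — any unknown propagates, by design.
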