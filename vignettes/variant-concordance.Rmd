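---
title: "Concordance of variant interpretations and ACMG-AMP re-classification: methods"
author: "varconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concordance of variant interpretations and ACMG-AMP re-classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varconcord)
```

This vignette documents the models, parameters and design choices behind
`varconcord`. The package compares interpretations of protein-variant
pathogenicity between an expert-curated protein resource, which labels a
variant × disease association as *disease*, *polymorphism* or
*unclassified*, and a submission-based clinical repository, which uses
the five-tier ACMG-AMP scale (*pathogenic*, *likely pathogenic*,
*uncertain significance*, *likely benign*, *benign*).

## Harmonization and the concordance statistic

The two vocabularies are compared through a fixed bucket equivalence:
pathogenic and likely pathogenic correspond to disease, benign and likely
benign to polymorphism, and uncertain significance to unclassified.
Agreement is therefore always judged at the bucket level — a likely
pathogenic repository call never counts as disagreement with a pathogenic
one. All agreement logic in the package (the contingency table, the
2-star concordance test among submitters, re-curation outcome labels)
uses this same equivalence, so the statistics are internally consistent.

For matched variant × condition pairs cross-classified into a 3×3 table
$T$, the per-category concordance of bucket $b$ is

$$ c_b \;=\; 100 \cdot \frac{T_{bb}}{\sum_j T_{bj} + \sum_i T_{ib} - T_{bb}}, $$

the interpretations common to both resources divided by the
interpretations present in either (a union denominator, analogous to a
Jaccard index on interpretation sets). Overall concordance is
$100\cdot\mathrm{tr}(T)/n$. Both are computed unrounded;
`round_half_up()` provides the display convention (nearest integer, half
away from zero), which matches how such percentages are conventionally
printed. When a bucket is empty in both resources its concordance is
undefined and `category_concordance()` refuses to invent a value.

No chance-corrected agreement (e.g. Cohen's kappa) is computed: the
package reports raw percent agreement by design, because the statistic of
interest here is the operational question "do the resources say the same
thing", not agreement in excess of chance.

### Projection after full re-curation

Re-curating a sample of concordant pairs yields a retention rate $r$ (the
fraction whose interpretation is confirmed); re-curating a sample of
discordant pairs yields a resolution rate $s$ (the fraction whose
conflict is solved). `project_concordance()` combines these with the
observed agreement rate $a = \mathrm{tr}(T)/n$ as

$$ 100\,[\,a\,r + (1-a)\,s\,]. $$

This is the natural rate-combination estimate of the agreement to be
expected once *all* shared variants have been re-curated; it assumes the
re-curated samples are representative of their strata, and the result is
labelled a projection, not a measurement. With the shipped fixtures
($a = 3771/4286$, $r = 96/100$ from the concordant-sample transition
table, $s = 78/100$ from the published outcome counts) it evaluates to
93.84, i.e. 94% after display rounding. The resolution rate cannot be
recomputed from the discordant transition table alone — deciding whether
a re-curated call *agrees with the repository* needs each variant's
repository label, which the package does not ship — so the published
outcome counts are provided as an input fixture instead.

## Review-status aggregation

Repository records are aggregated per variant × condition with the 0–4
star scale: 4 = practice guideline, 3 = expert panel, 2 = at least two
distinct submitters with assertion criteria whose classifications agree
at bucket level, 1 = at least one submitter with criteria, 0 = none.
The concordance analysis conditions on 2-star records: multiple agreeing
criteria-backed submitters, but no expert-panel validation — a deliberate
upper-bound stratum for measuring disagreement. Each variant × condition
pair is one record; the package does not collapse conditions, because the
clinically meaningful unit of interpretation is the variant–disease
association.

Bucket-concordant records also receive an aggregate five-tier label: the
modal label across submissions, ties broken toward the more severe tier
(a deterministic, conservative choice); bucket-discordant records get
`NA` and are excluded from contingency tables.

## Matching and study filters

Records are joined by normalized dbSNP rsid first, then transcript-level
HGVS (exact string after whitespace removal — a versioned transcript
mismatch is *not* forgiven, since curated names carry versions), then
accession plus protein-level HGVS. A record matched at a higher-precedence
key is withdrawn from lower stages. Duplicate identities are all paired
but flagged ambiguous rather than silently deduplicated.

The study filters retain missense, 2-star, Mendelian-disease pairs
(ACMG-AMP classification is only defined for Mendelian disorders, so
multifactorial-disease variants are excluded). Exclusions are attributed
to the *first* failing filter in the fixed order missense → stars →
Mendelian, which makes the exclusion table reproducible and guarantees
that retained + excluded = input.

## The ACMG-AMP engine

Evidence codes determine polarity and default strength from their prefix.
`adjust_strength()` implements curator re-weighting: it requires a
non-empty justification whenever the applied strength changes, records
the default alongside the applied strength for the report, and refuses to
flip polarity (stand-alone strength is additionally reserved for the
benign side, where the guideline defines it). Repeated codes are counted
once — the rules count distinct criteria, not citations.

The combining rules are shipped as a frozen minimum-count table
(`extdata/acmg_rules.tsv`, 18 rows) rather than hard-coded conditionals,
so the tests can pin the table bit-exactly and compare the generic
rule-matcher against an independent boolean encoding, exhaustively over
all strength-count vectors with counts ≤ 4. Strength strata outside the
rule vocabulary are counted at the nearest stratum the rules know: a
benign criterion raised to very strong counts as strong, a benign
criterion lowered to moderate counts as supporting, and a pathogenic
criterion raised to stand-alone counts as very strong.

**Conflict policy.** The five-tier outcome is pathogenic / likely
pathogenic when only pathogenic-side rules fire (pathogenic winning), and
mirrored on the benign side. Uncertain significance arises two ways:
no rule fires, or rules fire on *both* sides. The `conflicting` flag is
set when both sides fire, and also when no rule fires but evidence of
both polarities is present — the situation of a variant with moderate
pathogenic population/genetic evidence opposed by strong benign
functional evidence, which the field describes exactly as "conflicting
evidence" even though no combining rule resolves it. A conflicting result
is always uncertain significance, never a side's class.

## Frequency evidence and thresholds

`max_credible_af()` computes the maximum credible population allele
frequency, `prevalence × allelic heterogeneity × genotypic contribution /
penetrance`, with genotypic contribution defaulting to 1/2 for
autosomal-dominant disease (one allele of a heterozygote) and 1
otherwise. Both heterogeneity and contribution default to the
conservative value when unknown, and the derived BS1 justification
records the numbers used. Without a prevalence the threshold is
unavailable and BS1 is never fired from it.

`frequency_evidence()` uses the maximum observed frequency across
datasets and emits:

* **BA1** above the stand-alone cutoff, default 5% (the guideline's
  conventional value; configurable);
* **BS1** above the disease-specific threshold — for recessive disease
  with a known carrier frequency this is the carrier *allele* frequency,
  `carrier_frequency / 2` (carriers are heterozygotes, so the allele
  frequency is half the carrier frequency), used directly in preference
  to the prevalence-derived product; otherwise `max_credible_af()`;
* **BS2** when the variant was observed in a healthy adult in the
  genotype state relevant to the inheritance mode (the caller supplies
  this flag; penetrance-based down-weighting of BS2 is a curator decision
  made through `adjust_strength()`);
* **PM2** below the "extremely low" cutoff — the carrier-scale threshold
  for recessive disease with a known carrier frequency, else a
  configurable default of 1e-4 (a round value consistent with how
  "extremely low" is operationalized for dominant disease) — provided the
  frequency does not also exceed the BS1 threshold and, for recessive
  disease, no homozygote is reported.

BS1 and PM2 are mutually exclusive by construction. In-trans (PM3) and
segregation-type criteria are accepted as supplied assignments, not
derived: they come from literature reports, not from the data the package
sees. Computational consensus requires all three predictors (PolyPhen,
SIFT, MutationTaster) to agree: PP3 for unanimous deleterious, BP4 for
unanimous tolerated, nothing otherwise. Functional assays yield PS3/BS3
only when the assay reflects the biological environment of the disease;
equivocal or mechanistically unlinked assays are disregarded with a
logged message rather than down-weighted.

## The synthetic-data generator

`generator_config()` defaults describe the study conditions of the global
comparison: 4286 variants, curated-bucket mixture proportional to the
observed marginals (1533 / 2502 / 251), concordance target 0.88, and a
discordance kernel proportional to the observed off-diagonal structure,
so synthetic discordance "looks like" the real table. Star distribution
(0.15, 0.35, 0.40, 0.07, 0.03) and Mendelian fraction (0.9) are not
constrained by the comparison, which conditions on 2-star Mendelian
records; these values are chosen as plausible for a 2017-era repository
snapshot and chiefly serve to exercise every filter. A single integer
seed drives all randomness and the generator restores the caller's RNG
state, so fixed-seed output is byte-identical across platforms.

Submissions are fabricated to *realize* the drawn star level (two
bucket-concordant criteria-backed submitters for 2 stars, etc.), so the
review-status computation is exercised end-to-end, not bypassed. Evidence
templates per latent bucket are designed so the engine recovers the
bucket for template-pure profiles; the uncertain bucket's templates are
the empty profile and the conflicting PM2 + PM3 + BS3 triple.

What the generator does *not* emulate: real gene/protein identifiers
(identities are schematic, rs-numbers drawn from a disjoint high range),
correlated evidence within genes, non-missense variation, per-submitter
behavioral differences, and secular drift in classification practice.
Passing recovery tests therefore demonstrates the pipeline's statistical
correctness under the generative model, not robustness to the
idiosyncrasies of real release files.

## Numerical and testing choices

Problem sizes in the test suite are chosen to keep the full run around
two minutes on a single core: exhaustive rule-table equivalence over all
count vectors ≤ 4 (78 125 cases, vectorized), 1000 random tables against
brute-force tallies, and parameter recovery at n = 2000 with a binomial
99% confidence-interval criterion plus a 20-seed unbiasedness check
(mean error below one percentage point). Degenerate inputs are errors,
not guesses: empty contingency tables, empty-union categories, transition
sets with unmatched identities, and pipeline runs on empty inputs all
abort with named diagnostics before any output is written.

## Known limitations

* The engine implements the categorical 2015-style combining rules; it
  does not implement later Bayesian point-based refinements.
* Frequency filtering uses point estimates, not confidence-interval-based
  filtering allele frequencies.
* HGVS handling covers protein-level missense substitutions and exact
  transcript-level strings; there is no transcript-to-protein mapping,
  genomic liftover or VCF normalization.
* The resolution-rate input of the projection is a published count, not a
  quantity the package can recompute without per-variant repository
  labels for the discordant sample.
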