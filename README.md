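# varconcord

Clinical laboratories, locus-specific databases and expert-curated protein
resources often interpret the *same* protein-coding variant independently —
and do not always agree on whether it causes disease. `varconcord` is an R
toolkit for quantifying and improving that agreement. It compares
variant-pathogenicity interpretations between an expert-curated
protein-variant resource (humsavar-style tables with a three-class
*disease / polymorphism / unclassified* scheme) and a submission-based
clinical repository (ClinVar-style records with the five-tier ACMG-AMP
scheme), and re-classifies variants with an ACMG-AMP evidence-combination
engine informed by population allele-frequency logic.

It is aimed at biocurators and bioinformaticians who maintain or consume
variant-interpretation resources and want reproducible concordance
statistics and standardized re-classification.

## What it computes

**Concordance.** The two schemes are harmonized at the bucket level
(pathogenic/likely pathogenic ↔ disease, benign/likely benign ↔
polymorphism, uncertain significance ↔ unclassified). For matched variant
× condition pairs, a 3×3 contingency table is built; for a category *b*
with diagonal count *d*,

```
concordance(b) = 100 · d / (row_total(b) + col_total(b) − d)
overall        = 100 · trace / grand_total
```

i.e. interpretations common to both resources over interpretations present
in either. A post-re-curation projection combines the observed agreement
rate *a* with the confirmation rate of re-curated concordant variants
(*r*) and the conflict-resolution rate of re-curated discordant variants
(*s*): `100·[a·r + (1−a)·s]`.

**ACMG-AMP classification.** Evidence codes (PVS1, PS1–4, PM1–6, PP1–5,
BA1, BS1–4, BP1–7) carry a polarity and a default strength that expert
judgment may re-weight (with a mandatory justification, never flipping
polarity). The combining rules of the ACMG-AMP guideline are shipped as a
frozen rule table and resolved by `combine_evidence()`; frequency evidence
(BA1/BS1/BS2/PM2) is derived from population observations, a disease model
and the maximum credible population allele frequency
`prevalence × allelic heterogeneity × genotypic contribution / penetrance`
(carrier-allele scale for recessive disease with a known carrier
frequency). Predictor consensus (PP3/BP4) and functional assays (PS3/BS3)
round out the evidence model.

**Matching and filters.** Variants are matched by dbSNP rsid, then
transcript-level HGVS, then accession + protein-level HGVS; study filters
retain missense, 2-star, Mendelian-disease pairs with exact per-filter
exclusion accounting.

A synthetic-data generator (`generate_paired_tables()`) emulates paired
resource tables with known ground truth, and `run_pipeline()` orchestrates
match → filter → concordance → classification with a digest-carrying run
manifest. A thin CLI (`inst/exec/varconcord`) exposes `match`, `concord`,
`classify`, `simulate` and `run` subcommands.

## Worked example

The package ships a six-variant demo pair of tables
(`inst/extdata/humsavar_demo.tsv`, `clinvar_demo.tsv`; two rows carry the
identities of the GLI3 and ATP7B re-curation case studies, the GENEA–GENED
rows are synthetic):

```r
library(varconcord)
u  <- read_uniprot_table(system.file("extdata", "humsavar_demo.tsv",
                                     package = "varconcord"))
cv <- read_clinvar_table(system.file("extdata", "clinvar_demo.tsv",
                                     package = "varconcord"))
filt <- apply_study_filters(match_variants(u, cv))
filt
#> <filtered_pairs> retained 4 of 6 pair(s)
#>   excluded: missense=0, review_stars=1, mendelian=1
overall_concordance(build_contingency(filt))
#> <concordance_report> 3 of 4 interpretations agree (75%)
#>   disease       50%
#>   polymorphism  50%
#>   unclassified  100%
```

Six pairs match; one is excluded because its submitters disagree (1-star
record), one because its disease is multifactorial. Of the four analyzed
pairs three agree — the discordant one is GLI3 p.Ile808Met, curated as
disease-causing but benign/likely benign in the repository. Re-curating it
from its evidence profile resolves the conflict:

```r
gli3 <- read_evidence_table(system.file("extdata", "evidence_gli3.tsv",
                                        package = "varconcord"))
cat(render_report(combine_evidence(gli3)))
#> ACMG-AMP classification report
#> Classification: Likely benign
#> Conflicting evidence: no
#> Fired rules: LB1
#> Evidence items: 2
#>   BS1 [BENIGN] default=STRONG applied=STRONG | ...
#>   BS2 [BENIGN] default=STRONG applied=SUPPORTING | ... penetrance is not 100% | ...
```

One strong plus one supporting benign criterion fire the likely-benign
rule: the variant's population frequency is far above what the disorder's
prevalence can support, so the original pathogenic call is withdrawn. The
analogous ATP7B profile (`evidence_atp7b.tsv`: PM2 + PM3 + BS3) yields an
uncertain-significance call with the conflicting-evidence flag set.

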