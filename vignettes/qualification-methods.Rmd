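---
title: "Graded DNA-variant qualification: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graded DNA-variant qualification: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edsqual)
```

## The scoring model

`edsqual` grades the diagnostic value of exome results for complex
connective-tissue phenotypes in two layers.

**Per variant.** Molecular impact is an ordinal 0–2 grade of product
disruption. The grade is decided by the consequence class and, for
missense changes, by a physicochemical substitution table: residues are
grouped into aliphatic (ILVMA), aromatic (FWY), positively charged (KRH),
negatively charged (DE), polar (STNQC) and conformationally special (GP)
classes; a same-class substitution is conservative (grade 1), a
cross-class one disruptive (grade 2). Two domain rules override the
table: any truncating change (nonsense, frameshift, splice-disrupting) is
grade 2, and any glycine or proline substitution in a fibrillar collagen
gene is grade 2, because the Gly-X-Y triple-helical repeat tolerates
neither. Conservation and in-silico pathogenicity scores are consumed as
pre-computed annotations in `[0, 1]` — the package deliberately computes
neither, as both come from specialized external tools — and may promote a
conservative substitution to disruptive, never a silent change to
anything. This promotion is what separates, e.g., a benign Met→Val from a
deleterious one: both are within-class by the table, and only the
annotation evidence distinguishes them.

Gene–disease relevance is mechanism-based rather than symptom-based. Each
catalog gene carries disease associations tagged with the mechanisms they
act through (tissue laxity, neural, autonomic, immune/inflammatory,
clotting, viral response, developmental, renal/vascular, mitochondrial,
other), and each diagnostic context defines the tag set that makes a gene
relevant to it. A primary-association overlap makes the gene *relevant*;
an overlap running only through a secondary mechanism makes it a
*synergistic adjunct* (the profilaggrin pattern: its primary association
is ichthyosis, but skin-inflammation synergy links it to dysplasia
phenotypes); associations with no contextual overlap make it relevant to
an *other disease*; weak or absent associations yield no relevance. One
curation consequence deserves emphasis: a gene whose only association is
a multifactorial biochemical predisposition (the MTHFR pattern) is tagged
`other` even when its disease label mentions clotting, because it does
not act through the clotting-element tissue mechanism that the context
tag set means. The `clotting` tag is reserved for genes like VWF, F2 or
ADAMTS13 whose diseases are clotting-element dysfunctions.

Utility then combines the two: impact 0/1/2 maps to no/uncertain/moderate
diagnostic utility (`VNoDU`/`VUDU`/`VMDU`); a disruptive variant in an
established gene with clinical H or I evidence is strong (`VSDU`); an
exact match to a protein change with a long association history is
evidenced (`VEDU`). The population-frequency gate dominates everything:
at or above the common-variant threshold, utility is capped at `VUDU`
regardless of other evidence, because prevalence in unaffected
populations is the strongest single argument against individual
diagnostic value.

**Per patient.** The context score is the maximum impact over the
context-relevant variants plus one point each for abundant
disease-related history findings (H), inheritance of the primary variant
from a symptomatic relative (I), and a synergistic adjunct (S), capped at
4. `O`-suffixed variants generate separate impact-only scores for their
own diagnoses. Using the *maximum* impact rather than a sum prevents
double counting when several variants hit the same mechanism; the
synergy point is the single channel through which a second variant can
raise the score.

## Tunable parameters

All live in `qual_config()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `common_af_threshold` | 0.01 | allele fraction | conventional rare-variant cut-off; any reasonable value gates the 30%-frequency worked example |
| `h_threshold` | 20 | history findings (of 80) | midway between typical affected (~34) and unaffected (~7) cohort means, so it separates the two distributions by about 2.5 unaffected SDs |
| `conservation_cutoff` | 0.9 | fraction | promotion requires near-perfect cross-species conservation |
| `insilico_cutoff` | 0.8 | fraction | typical "likely deleterious" region of normalized predictor scores |
| `residue_classes` | 6-class table | — | standard physicochemical grouping |
| `collagen_genes` | 10 fibrillar collagens | — | genes with Gly-X-Y triple-helical repeats |
| `mdna_cap` | 4 | points | the scale's published ceiling |

The statistical helpers expose the unequal-variance (Welch) *t* by
default, with a `pooled` flag, because the cohorts being compared differ
in size and spread by an order of magnitude; significance flags use raw
p < 0.05 with no multiple-testing correction, matching how such
single-table comparisons are reported. The gene-set comparison takes an
explicit denominator argument because published class percentages have
used the full comparison set or the set minus virulence-related genes;
`compare_gene_sets(exclude_viral_b = TRUE)` implements the
host-mechanism-only convention.

## Numerical and formatting choices

- **Percentage rendering** uses round-half-up: integers at ≥ 10%, one
  decimal below 10%. This reproduces cohort-table renderings such as 66,
  51, 57, 3.5, 3.3, 4.5, 16 and 1.1. One published cell (566/568 printed
  as "99" where the convention gives 99.6 → 100) does not follow any
  standard rounding and is reproduced as a count, not a percentage.
- **N−1 chi-squared** is computed from the algebraically expanded 2×2
  Pearson statistic scaled by (N−1)/N, with p from the χ² distribution on
  1 df and no continuity correction. Zero-margin tables (no successes, no
  failures, or an empty group) raise an explicit error rather than
  returning 0/0.
- **Welch's t** from moments refuses n < 2 or sd ≤ 0, where the statistic
  is undefined.
- **Ties** in the per-patient primary-variant choice (several
  context-relevant variants at the same maximal impact) resolve to the
  first in input order; the score is unaffected because only the maximum
  impact and the evidence bits enter it.
- **Score ordering before the cap** is immaterial: adding the synergy
  point before or after capping yields the same result whenever the
  uncapped sum reaches the cap, which is the only case where the order
  could matter.
- **Family similarity** between gene symbols is curated-table-first: the
  packaged table carries the irregular families (complement C1R/C3,
  POLG/POLD4, IKBKAP/IKBKG, NDUFA11/NDUFAF7, WNT, SLC6, RBM, ZNF, PIK3,
  IRF) that no prefix rule recovers; a fallback rule pairs symbols
  sharing a leading alphabetic prefix of ≥ 4 letters with differing
  suffixes (ADAMTS2/ADAMTS13, TMPRSS6/TMPRSS2, FOXP2/FOXP4, NFKB2/NFKB1).
  Similarity is symbol-level only; no sequence homology is computed.
- **Symbol normalization** uppercases, strips non-alphanumerics and
  applies a curated alias map for published variant spellings (T1CAM1 →
  TICAM1, IF1H1 → IFIH1, IFR3 → IRF3).

## Design decisions that were genuinely open

- The strong-utility (`VSDU`) trigger — disruptive impact in an
  established gene plus H or I evidence — is inferred from the category
  ordering; no worked example of it is published. We additionally
  restrict the promotion to *context-relevant* variants: a patient's
  abundant EDS history is not evidence for an unrelated other-diagnosis
  variant.
- When context-relevant variants exist but all have zero impact, the
  context score is 0: clinical evidence points only augment a molecularly
  scored variant. The alternative (evidence points standing alone) would
  let a patient score without any usable variant, which the scale never
  does.
- Suffix assignment when a gene could serve both the context and another
  disease: context relevance wins; `O` applies only when no contextual
  overlap exists at all. If curation ever produced a gene satisfying
  both the synergy and other-disease conditions simultaneously, the
  engine raises an ambiguity error rather than choosing silently.

## The synthetic-cohort generator

`generate_cohort()` emulates the structure of a systematically evaluated
dysplasia cohort: 82% female; per-group/sex history-finding counts (of
80) with affected means 36 (female) and 26 (male), SD 10, versus
7.2 ± 1.3 for the group not meeting criteria; physical counts (of 40)
19/17 ± 4.7 versus 7.6 ± 1.3; Beighton hypermobility means 6.9/5.6
(SD 1.5, a chosen dispersion — none is published — and config-exposed)
versus a population-like 4.5; and the published DNA-testing outcome
rates (51% tested; 59% of those with a potentially significant variant;
3.5% / 32% / 99.6% company-condition / company-other / author relevance
among carriers; 16% mitochondrial and 3.4% nuclear-to-mitochondrial
variants). Age-interval bins (2.5-year bins under 10, 10-year above) are
generated but unused by the statistics.

Counts are realized by drawing a target from an exact (inverse-CDF)
truncated normal on the bounded scale and selecting which findings are
positive by prevalence-weighted sampling without replacement. This hits
the configured count moments directly, which is why a fixed-seed cohort
of n = 1261 recovers its configured mean within 3 standard errors. The
generator deliberately does **not** model inter-finding correlation
structure, real allele-frequency spectra, or any dependence of variant
content on phenotype: passing tests on synthetic cohorts therefore
demonstrate the correctness of the arithmetic and the plumbing, not
clinical validity on real patients. Truncation bias is negligible at the
default moments (the bounds sit ≥ 3.4 SD from the means).

`reference_cohort()` is the deterministic companion: it realizes the
published group-level testing-outcome counts exactly (flags only, no
checklists), for exercising the summary tables. `generate_worked_examples()`
returns the five fixture patients whose qualifications the engine
reproduces end to end.

## Problem sizes and runtime

The test suite qualifies a few hundred small synthetic patients,
generates cohorts of up to 1325, and property-tests the N−1 statistic on
1000 random tables; the whole suite runs in well under a minute. These
sizes were chosen as the smallest at which the parameter-recovery checks
(3 SE at n = 1261) and property suites are meaningful.

## Known limitations

- The gene catalog shipped with the package is a curated subset (the
  genes named in worked examples and comparisons), not the full
  several-hundred-gene study catalog, which is not published in
  machine-readable form; the classified-set builders labelled *synthetic*
  realize only stated class marginals.
- Steps D/E/F (conformational, conservation, in-silico analysis) are
  consumed as annotations, never computed.
- The engine implements this specific graded protocol, not a general
  ACMG/AMP criteria engine; no live queries to OMIM, ClinVar or
  population-frequency databases are made.
- Symptom-overlap analysis is label-level on a controlled vocabulary;
  frequency ranges are carried through but not statistically compared.
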