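---
title: "Somatic prioritization and two-hit integration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic prioritization and two-hit integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatichit)
```

## The problem

Tumors with low mutational burden — lung adenocarcinomas arising in
never-smokers are the motivating case — offer few somatic events from which
to separate selection from noise. Two consequences drive the design of this
package. First, somatic calling must be conservative: variants are accepted
only on multi-caller agreement and survive a cascade of read-support and
population filters, each of which is individually simple and auditable.
Second, single-dimension evidence is weak, so candidate tumor suppressors
are evaluated for *biallelic* ("two-hit") inactivation by integrating
mutation zygosity with gene-level copy number.

Everything downstream of raw caller output is in scope; running aligners
and variant callers, computing predictor scores, and array segmentation are
not — the pipeline consumes their standard outputs (VCF, a read-count
recount table, an annotation table, SEG).

## Variant identity and normalization

All cross-caller and cross-sample matching uses the normalized
`(chrom, pos, ref, alt)` tuple; genotype fields are ignored. Normalization
trims the shared allele suffix first, then the shared prefix (advancing
`pos`), and — when a reference-base accessor is supplied — left-aligns
indels to their 5'-most equivalent representation. The operation is
idempotent and multi-allelic rows are split before normalizing, so the key
set is independent of allele listing order. Internal coordinates are
1-based inclusive everywhere (VCF-native); BED input is converted at the
boundary. Chromosome names are compared verbatim: silently harmonizing
`chr6`/`6` dialects hides real input errors.

## The somatic filter cascade

Consensus: a tumor variant needs `min_callers_tumor = 2` of the three
callers, a matched-normal variant `min_callers_normal = 1`. Presence is the
only signal used; caller quality fields vary too much across tools to
compare meaningfully.

The panel of normals is the union of variant keys over *all* normal
consensus sets in the cohort, not only the matched pair. This is the
stronger and, in our reading, intended interpretation of removing variants
seen "in any matched-normal control"; it also catches recurrent artifacts.
The per-pair read-support rules then apply, in fixed order, with
`somatic_filter_config()` defaults:

| rule | fires when | default | boundary |
|---|---|---|---|
| NORMAL_VAF | normal VAF ≥ `max_normal_vaf` | 0.05 | inclusive |
| ZERO_ALT | tumor alt = 0 and tumor ref > `min_ref_reads_for_zero_alt` | 20 | strict |
| VAF_RATIO | tumor VAF < `tumor_to_normal_vaf_ratio` × normal VAF | 2.0 | strict |
| POPFREQ | `pop_freq_max` > `max_population_freq` | 0.01 | strict |

The inclusive/strict boundaries follow the rules' wording exactly ("5% or
more", "more than 20", "less than twice", "more than 1%"), and the first
firing rule names the trace. A zero-depth tissue has VAF 0 by definition,
which makes the ratio rule unsatisfiable there rather than dividing by
zero. Variants with no entry in the recount table are removed with a
dedicated `MISSING_COUNTS` trace instead of silently passing: the recount
step is expected to cover every candidate.

A variant failing any of the three read-support rules in one sample is
blacklisted and removed from every sample (two-pass semantics). The
population-frequency rule is *not* propagated: it depends only on the key
and fires identically everywhere anyway.

## The functional cascade

Four stages in fixed order, each traced: coding/splice region
(`EXONIC`, `SPLICING`, `EXONIC_SPLICING` retained); silent variants removed
unless spliceogenic (|ΔPSI z-score| ≥ `spidex_z_threshold = 2`, inclusive);
unexpressed genes removed (exact symbol match by default; an empty
expressed-gene list is refused as a misconfiguration); then the
tolerability vote. With `A` predictors returning a verdict and `T` of them
voting tolerated, the variant is removed when `T ≥ ⌈A/2⌉` — ties count
toward removal — unless it is an indel or spliceogenic. Predictors that
return no score are excluded from the denominator
(`vote_denominator = "available"`): most of the six tools do not score
indels or splice-region variants, and counting their silence as evidence of
tolerability would be backwards. The alternative fixed denominator of six
is available as `vote_denominator = "all"`. Variants with *no* verdicts at
all are retained — absence of evidence is not a tolerability call.
Truncating classes (nonsense, splice) are deliberately *not* exempt from
the vote by default; only indels and spliceogenic variants are, with an
`exempt_truncating` switch for the more permissive convention.

Stage order matters and is fixed: a spliceogenic silent variant in an
unexpressed gene is removed at the expression stage, not rescued.

## Recurrence, enrichment

Candidates are genes with functional mutations in ≥ `cohort_min = 2` cohort
samples (a sample counts once per gene) and ≥ `external_min = 3` samples of
an external reference cohort; genes absent from the external table count
zero. Known drivers are flagged by census-list membership; the remainder
are the novel candidates used for per-sample gene-set enrichment.

Enrichment is the upper-tail hypergeometric probability, computed by
summing the pmf on the log-binomial scale (`lchoose`), exact for the set
sizes involved; the test suite checks it against direct pmf enumeration
for every population size up to 60. Terms are called enriched at nominal
p ≤ 0.05 with no multiple-testing correction by default — a deliberate
fidelity choice, since the upstream procedure defines recurrence across
samples (a term must be enriched in ≥ 3 samples) as its guard; BH
adjustment is available via `p_adjust`. The default universe is the
expressed-gene set, which is also the population the candidates were drawn
from.

## Copy number and two-hit integration

A gene's log2 ratio is the base-length-weighted mean of its overlapping
SEG segments (the `min` convention — most-deleted overlapping segment — is
available); thresholds are amplification ≥ 0.8 and loss ≤ −0.6. Those two
bounds are the segmentation thresholds used with GISTIC-style processing;
the boundary between single-copy loss and *deep* (biallelic) deletion is
not standardized, so `deep_del = −1.3` is this package's own parameter:
−1.3 log2 corresponds to under one remaining copy against a diploid
background. A gene with no overlapping segment is NEUTRAL with a warning —
absent evidence is not a deletion call.

Mutation zygosity: homozygous when any functional variant reaches tumor
VAF ≥ `homozygous_vaf_min = 0.7`, a bound chosen to tolerate normal-cell
contamination while excluding balanced heterozygotes; the value is a
config knob and is echoed into the run report. Two or more distinct
functional variants in one gene default to homozygous (compound biallelic
assumption — phasing is unavailable, so this is explicitly an assumption,
with `compound_hom = FALSE` to disable).

The integration truth table: deep deletion, homozygous mutation, or
heterozygous mutation with copy call LOSS/DEEP_DEL ⇒ TWO_HIT; heterozygous
mutation on neutral/amplified copy, or loss without mutation ⇒ ONE_HIT;
otherwise WT. The test suite checks the implementation against the
enumerated 3 × 4 table.

## Summaries

TMB divides the somatic mutation count by a callable territory of 38 Mb by
default (a typical exome callable size; configurable) — reported TMB is
otherwise platform-dependent and ill-defined. FGA uses the cBioPortal
convention |log2| ≥ 0.2. The mutation spectrum collapses SNVs to the six
pyrimidine-reference classes (G>T ≡ C>A). Validation follows the capture
rule: a variant confirms when ≥ 5% of its capture reads support the
alternate allele, with only captured variants in the denominator and no
depth floor. The one-tailed Mann–Whitney test enumerates all group
assignments over pooled mid-ranks exactly up to pooled size 20 (the
standard exact algorithms decline ties; enumeration does not), switching to
a tie-corrected, continuity-corrected normal approximation above that.

## The synthetic cohort generator

`cohort_spec()` fixes the emulated study conditions; its defaults are the
conditions under which the package's end-to-end claims are tested:

* 15 tumor/normal pairs; ~150 somatic variants per tumor (negative
  binomial, dispersion 8) of which ~80% are coding — matching a reported
  mean of ~120 coding variants per tumor in the motivating setting — plus
  40 germline heterozygous sites per individual drawn from a shared pool,
  so germline sites recur across the cohort and exercise the cohort-wide
  panel.
* Somatic VAFs are Beta(2, 5) truncated below 0.10: subclonal skew with a
  detection floor, since callers configured with minimum depth/quality
  cannot emit the near-zero-VAF tail; germline hets sit at exactly 0.5
  before binomial sampling. Depths are Poisson, 100× tumor / 80× normal.
* Caller sensitivities (0.95, 0.90, 0.85) with 20 caller-private false
  positives per caller per sample; false keys are drawn from a 12 Mb
  position space, so two callers virtually never agree on one, and they die
  at consensus.
* Annotations are consistent with planted effects: indels have
  length-changing alleles and (realistically) no predictor scores; silent
  variants are spliceogenic at rate 0.10; predictor verdicts match planted
  deleteriousness with probability 0.9 per tool; 2% of somatic-appearing
  variants are common polymorphisms (`pop_freq_max` > 1%) to exercise the
  population filter — true germline never reaches that stage, because it
  dies at the panel first.
* Copy-number engineering: a 6q-like loss (−0.8) across samples 1–8, a deep
  deletion (−1.8) over one designated gene in samples 2–4, an amplification
  on chr1, and designated genes for homozygous-mutation (planted VAF 0.9),
  het-mutation-plus-loss, mutation-only and loss-only configurations.
  Engineered mutations are frameshift indels, so their retention exercises
  the indel override rather than predictor noise. Designated genes are
  excluded from random mutation placement, keeping the per-gene truth table
  exact.

A single global seed derives per-sample substreams, so adding a sample
does not perturb earlier samples' draws, and a fixed seed yields
byte-identical output trees.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: sequence-context mutational signatures (the
spectrum is uniform), mapping artifacts and strand bias, purity/ploidy
variation, allele-specific copy number, correlated caller errors, and
transcript-level consequence ambiguity. The generator validates the
*bookkeeping and decision rules* of the cascade, not the biology of any
particular cohort.

## Numerical and testing choices

Degenerate inputs are errors, not guesses: `ref == alt` keys, overlapping
SEG segments, duplicate count rows, negative counts, an empty gene
universe, zero segmented length. Allele columns are read with forced
character types (an all-`T` column must never become logical). Exact
enumeration bounds — hypergeometric populations ≤ 60, rank-sum pooled sizes
≤ 12 against the pairwise-counting oracle, the full 3^6 verdict sweep —
were chosen so each oracle suite completes in seconds on one CPU while
covering the full decision space of the rule it checks. End-to-end tests
use a 15-pair noise-free cohort (exact recovery), a 5-pair noisy cohort
(.95/.90/.85 sensitivities; consensus within 4 SD of the closed-form
expectation over ~1000 planted variants), and a 3-pair cohort for
round-trip and conservation properties.

## Known limitations

* Zygosity from VAF alone conflates purity, ploidy and LOH; the 0.7 bound
  is a heuristic, and compound heterozygosity is assumed biallelic.
* The deep-deletion bound (−1.3) is a convention, not an inference.
* Blacklist propagation is exactly cohort-wide; there is no frequency-based
  middle ground (e.g. "fails in ≥ k samples").
* Gene-level copy calls ignore intragenic breakpoints beyond length
  weighting.
* The enrichment default (nominal p, no correction) reproduces the upstream
  procedure; treat recurrent terms as descriptive, not inferential, unless
  BH adjustment is enabled.
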