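---
title: "Methods: rare CNV prioritization and burden analysis in trio cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare CNV prioritization and burden analysis in trio cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemicnv)
```

## The analysis problem

Chromosomal microarray studies of neurodevelopmental cohorts — here, the
motivating setting is hemiplegic cerebral palsy probands genotyped together
with both parents — produce hundreds of copy-number variant (CNV) calls per
genome, most of which are common polymorphisms with no plausible clinical
role. `hemicnv` implements the downstream prioritization chain that turns
raw trio CNV tables into a clinically interpretable report:

1. **rarity filtering** against a large population control panel,
2. restriction to **copy-number-stable** genome,
3. **trio inheritance** classification (de novo / maternal / paternal),
4. **annotation and tiering** against gene models, genomic-disorder loci
   and a disease-gene list, and
5. **burden statistics** — brain critical-exon carrier burden and pLI
   (loss-of-function intolerance) deletion burden — plus cohort
   stratification tables.

Upstream CNV calling from array intensities, ancestry analysis, exome
interpretation and wet-lab validation are out of scope: CNV calls arrive
as tab-separated tables and all reference tracks are inputs.

## Interval conventions

All coordinates are handled internally as 0-based, half-open intervals, so
`end - start` is the event length with no off-by-one ambiguity; readers
accept 1-based inclusive tables through an explicit `dialect` flag because
array-reporting pipelines commonly emit that convention. Chromosome names
are normalized by stripping an optional `chr` prefix; mitochondrial and
unplaced contig names pass through untouched. CNVs are strandless, and no
strand is modeled anywhere.

Two interval primitives drive every stage:

* **Reciprocal overlap (RO)** of intervals $a,b$:
  $\mathrm{RO}(a,b) = \min\!\left(\frac{|a \cap b|}{|a|},
  \frac{|a \cap b|}{|b|}\right)$ — the field's standard criterion for
  declaring two CNV events "the same". Matching uses RO $\ge$ 0.50,
  **inclusive** at the boundary. Published filter descriptions rarely say
  whether exactly-0.50 matches; we chose inclusive (a configurable
  `ro_threshold`) because "50% reciprocal overlap" reads most naturally
  as attained at 0.50.
* **Union coverage**: the fraction of a CNV covered by the union of a
  region set, double-covered bases counted once. The stable-genome rule
  requires coverage **strictly greater** than 0.75, mirroring the "more
  than 75%" phrasing it implements; coverage exactly at 0.75 fails.

The overlap index behind panel queries, gene impact and exon burden is
backed by `GenomicRanges::findOverlaps`; its contract (query result ==
brute-force all-pairs scan) is enforced by randomized oracle tests.

## The rarity filter

A proband CNV is kept when all of the following hold
(`rarity_config()` defaults):

* **size** $\ge$ 10 kb — the resolution floor of stringent array calls;
  there is deliberately *no maximum* size, since whole-chromosome events
  are legitimate findings;
* **frequency**: the number of *distinct control individuals* carrying a
  same-type CNV at RO $\ge$ 0.50 is at most 0.1% of the panel
  (inclusive: with a 10,851-individual panel, 10 carriers pass, 11 fail).
  Frequency counts carrier individuals rather than CNV events because a
  panel-sample frequency is what "0.1% among N control samples" denotes;
* **stability**: coverage of the CNV by copy-number-stable regions
  exceeds 0.75.

Same-type matching (deletions against deletions, duplications against
duplications) is the default; the underlying publications typically do
not state this, so it is exposed as `require_same_type`. Every input CNV
receives an audit row (carrier count, stable fraction, first failing
rule), so the rejected set is partitioned by reason.

## Trio inheritance

The child-parent matching criterion is the central modeling assumption of
the inheritance stage: published trio CNV studies typically report de novo
status without stating their matching rule, so we reuse the panel rule —
same type, RO $\ge$ 0.50. A CNV is `maternal`/`paternal` when exactly one
parent carries a match, `biparental` when both do (tiering treats it as
inherited), `de_novo` when neither does, and `unknown_incomplete_trio`
when a parent has no CNV data (an empty, genotyped parent is *not*
missing). Whole-chromosome events are flagged as aneuploid when the CNV
spans more than 90% of its chromosome (hg19 lengths are built in): this
separates an entire-X duplication from an 84.9 Mb Xq deletion (55% of X)
without requiring a karyotype model.

## Annotation and tiering

A gene is *impacted* only when the CNV intersects at least one **coding
exon**; intronic or UTR-only contact is reported separately as noncoding.
Genomic-disorder ("syndrome") locus hits require reciprocal congruence
(RO $\ge$ 0.50 again — a small CNV inside a 2.6 Mb disorder locus is not
a locus event). Tiering is a deterministic cascade:

| tier | rule |
|------|------|
| `T1_de_novo` | de novo status or aneuploidy flag |
| `T2_syndrome_locus` | else, any syndrome-locus hit |
| `T3_disease_gene_inherited` | else, any impacted gene on the disease-gene list |
| `T4_other` | otherwise |

The disease-gene list is a user-supplied track; the packaged list (DMD,
GRIK2, DIP2C, CNTNAP2, PMP22, contactins, ...) is a convenience fixture
and explicitly non-authoritative. The "hg19-mini" gene fixture uses
hg19-approximate gene spans with synthetic uniform exon tilings —
adequate for exercising coding-exon logic, not for clinical use.

Per-individual **pLI sums** are taken over the *set* of distinct genes
impacted by that individual's deletions (a gene hit by two deletions
counts once), deletions only by default, matching the
haploinsufficiency rationale of the score; genes missing from the pLI
table contribute zero and are listed in an audit attribute.

## Burden statistics

**Critical-exon carrier burden.** For each of 16 brain regions × 3
developmental timepoints (prenatal, 4 months-15 years, adult), an
individual is a *carrier* when any of their rare CNVs intersects any
critical exon labeled with that stratum. The original critical-exon
burden statistic is not restated in the motivating literature, so the
2×2 carrier-proportion formulation is this package's documented
construction. The test is one-sided for enrichment in cases (that is the
reported direction of interest), and the default is the
**hypergeometric mid-p** test: across the carrier rates this design
produces (0.05-0.2) it holds type-I error at 0.048-0.051 where the plain
exact test is conservative (~0.04) and the one-sided score z-test is
anti-conservative (~0.055-0.062). The score test remains available
(`test = "score"`). One caveat of mid-p: at exactly equal carrier
proportions the one-sided p sits just below 0.5 (≈0.47-0.50) rather than
at it. Benjamini-Hochberg adjustment is applied across the 16 regions
*within* each timepoint — the family a per-timepoint display panel
implies — with a `bh_scope = "global"` option for a single 48-test
family.

**A note on BH fixed points.** The step-up adjustment
$q_{(i)} = \min_{j \ge i} p_{(j)} m / j$ is *not* idempotent in general:
re-adjusting $(0.02, 0.4)$ gives $(0.04, 0.4)$. Only plateau-type
outputs (all values achieved at the top rank, e.g. the all-tied case)
are fixed points; re-adjustment can only increase values. Tests assert
exactly these properties.

**pLI burden** is an unpaired two-sample t-test on per-individual pLI
sums, pooled-variance by default with a Welch option. **Stratification
tables** compare CNV-positive and CNV-negative probands per covariate:
Pearson chi-square without continuity correction for categorical
variables (the convention under which published 2×2 statistics like 8.6
for a 23-vs-74 sex table reproduce; Yates available by flag), pooled t
for continuous ones, missing values excluded listwise per variable.
Degenerate stratifications (an empty group) are an error, not a silent
zero.

## The synthetic cohort generator

Because real genotypes are not redistributable, every stage is validated
on generated cohorts with full truth labels. `sim_config()` defaults are
fixed to the study conditions the package targets: 97 trios, a
10,851-individual control panel, ~3.5 background CNVs per individual
(≈340 stringent calls across 97 probands), sizes log-uniform between
10 kb and 5 Mb plus rare whole-chromosome events, a 65:35
deletion:duplication mix, planted de novo events in 7% of probands, 90%
of each chromosome copy-number stable (5 Mb tiles with random unstable
holes), and gene models whose critical exons carry per-gene
developmental timepoints (40% prenatal) and Bernoulli(0.6) region
labels. pLI values come from a near-0 / near-1 / uniform mixture with
17% high-constraint mass.

Design choices worth knowing:

* **Transmitted CNVs** are copied into the transmitting parent with
  boundary jitter capped so child-parent RO stays $\ge$ 0.9 — safely
  above the 0.5 matching threshold; an `adversarial` jitter mode pushes
  copies near the threshold for boundary testing.
* **Common CNVs** appear in controls by binomial sampling at each
  locus's configured frequency (1-5%). Probands carry each common locus
  with probability 0.15 — above the population frequency — so that a
  97-proband cohort reliably contains events the frequency rule must
  remove; the panel frequencies that drive removal are faithful.
* **Rare planted CNVs** are placed wholly inside stable regions, so
  truth labels are also pass/fail labels for the filter.
* **Burden cohorts** compare the 97 cases against a platform-matched
  panel of 2,000 controls (`n_matched_controls`) — exon burden against
  a platform-matched subset, not the full panel, mirrors how such
  comparisons are run; enrichment is planted by giving each case, with
  probability `burden_effect` (default 0.25), one CNV centered on a
  randomly chosen prenatal-labeled critical exon.

What the generator does *not* emulate: array probe-level noise and
call-boundary uncertainty beyond uniform jitter, linkage structure,
ancestry stratification, segmental-duplication-mediated recurrence, and
mosaicism. Passing recovery tests therefore demonstrate the correctness
of the filtering/classification logic under clean planted structure, not
robustness to real array artifacts.

## Problem sizes and numerical choices

The packaged validation studies use: one full-scale cohort (97 trios +
10,851 controls) for filter and de novo recovery; 200 seeded replicates
for prenatal-burden detection power (declared detected when all 16
prenatal strata reach BH-adjusted p < 0.05); and 1,000 null replicates
for type-I calibration, summarized as the fraction of strata with raw
p < 0.05 and compared with the nominal 0.05 using a binomial 95%
interval with n equal to the number of replicates — strata within a
replicate share individuals and are positively correlated, so treating
all 48,000 stratum tests as independent Bernoullis would overstate the
precision of the estimate. All generators take explicit integer seeds
and identical config+seed reproduce outputs exactly.

Ties and degenerate inputs: zero-length intervals are rejected at
validation (`end > start` everywhere); empty CNV tables, empty panels
and empty annotation tracks flow through every stage as empty results;
an all-positive or all-negative stratification errors out; odds ratios
with empty denominators report `Inf` (and `NA` for 0/0) while the mid-p
value remains defined.

## Limitations

* The child-parent matching rule (same-type, RO ≥ 0.5) is an assumption,
  not a published criterion; genotype-level confirmation of de novo
  status (and parent-of-origin) is out of scope.
* Mosaicism is not modeled; a mosaic flag supplied in input tables is
  passed through untouched.
* The carrier-based 2×2 burden statistic is a stand-in for the original
  critical-exon burden formulation, which is defined on data this
  package does not consume (brain expression profiles).
* Tier assignment is a triage cascade, not ACMG-style pathogenicity
  scoring; expert pathogenicity labels are pass-through columns.
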