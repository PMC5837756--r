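---
title: "Recurrent CNA discovery by interval-graph maximal cliques: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent CNA discovery by interval-graph maximal cliques: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnaclique)
```

## The model

Somatic copy-number alterations (CNAs) are gains (copy number > 2) or
losses (< 2) of DNA segments relative to the diploid state. Given
per-patient segment calls (as produced by circular binary segmentation
of SNP-array data), a *recurrent* CNA is a region altered in many
patients, and the biologically interesting coordinates are the **minimal
common region (MCR)** — the part shared by *every* carrier, the natural
place to look for driver genes.

The combinatorial core: for one chromosome, one age group and one
alteration type, treat each patient segment as an interval and build the
interval graph (vertices = segments, edges = intersecting pairs). Maximal
cliques of an interval graph are exactly the maximal sets of mutually
overlapping segments, and because pairwise-intersecting intervals on a
line always share a common point (the 1-D Helly property), every clique
has a nonempty intersection — its MCR. Cliques are enumerated by an
endpoint sweep over the vertices ordered by chromosomal end position:
maintain the set of intervals currently open; whenever an interval
closes after at least one interval has opened since the last emission,
the open set is a maximal clique. This is `sweep_maximal_cliques()`; an
independent Bron–Kerbosch enumeration over the explicit adjacency matrix
(`brute_force_maximal_cliques()`) is kept purely as a testing oracle and
the two are checked for set equality on hundreds of random instances.

Gains and losses are always analysed separately, and patient counts are
over *distinct* patients (a patient contributing two segments to one
clique counts once).

### Filters and cohort logic

In order:

1. segment-level: ≥ 10 probes and ≥ 1 kb (`filter_segments`); neutral
   segments are dropped here, not at load, so raw files can be
   inspected;
2. clique-level: clique size ≥ 2, ≥ 5 distinct patients, MCR ≥ 1 kb
   (`call_recurrent_regions`); the 1 kb recurrence rule is applied to
   the *inner* MCR, the quantity that is reported;
3. age specificity: a young-group region is kept when its MCR overlaps
   no same-type old-group MCR (`group_specific_regions`);
4. validation: a discovery region is validated when its MCR overlaps a
   same-type young-specific MCR in the validation cohort
   (`match_discovery_validation`); the validated record keeps the
   discovery coordinates and reports both cohorts' carrier counts
   (`size1`, `size2`).

The age cutoff is 45 years with the boundary assigned to the old group
(age ≥ 45 is old).

### Association analyses

For each gene overlapping a validated region's MCR, carrier status of a
patient is defined as *carrying ≥ 1 filtered same-type segment that
overlaps the MCR* — deliberately not clique membership, so that status
is recomputable in any cohort with the same rule. Discovery and
validation young patients are pooled.

* **eQTL**: logistic regression of binarized-by-mean expression
  (1 iff strictly above the per-gene mean) on carrier status. For a
  single binary predictor the MLE odds ratio equals the 2×2
  cross-product ratio; the tests exploit this identity at 1e-6. A zero
  cell is reported with the Haldane–Anscombe-corrected ratio and a
  `separation` flag rather than an unstable Wald interval. Raw p-values
  are reported alongside Benjamini–Hochberg-adjusted ones; default
  significance calls use raw p < 0.05.
* **Survival**: disease-specific survival via Kaplan–Meier curves and
  the log-rank test by carrier status, and a Cox proportional-hazards
  fit on the gene's expression, z-scored by default so the hazard ratio
  is per SD (array expression scales are platform-specific). Times are
  in years.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_probes` | 10 | probes | array reliability filter |
| `min_seg_size` | 1000 | bp | discard sub-kb calls |
| `min_clique` | 2 | segments | a recurrence needs ≥ 2 carriers |
| `min_patients` | 5 | patients | recurrence threshold |
| `min_mcr_size` | 1000 | bp | reportable MCR |
| `young_cutoff` | 45 | years | young-onset definition; boundary is old |
| `alpha` | 0.05 | — | significance threshold in reports |

## Numerical and convention choices

* **Coordinates** are 0-based half-open throughout; `size = end − start`.
  This is the only convention consistent with published region tables of
  this analysis style (every printed inner/outer size equals
  end − start), so the default SEG dialect takes file coordinates as
  already half-open; `seg_dialect(coords = "one_based")` converts
  1-based-inclusive array exports on load and back on write.
* **Overlap** is strict: `u.start < v.end && v.start < u.end`. Touching
  intervals do not overlap, and correspondingly the sweep processes end
  events before start events at equal coordinates. The source
  description of the algorithm does not discuss ties; this choice is
  forced by the half-open size convention.
* **Duplicate intervals** are distinct, mutually adjacent vertices.
* **Singleton cliques** are emitted by the core sweep and removed by the
  `min_clique` filter, keeping the enumerator honest and the policy in
  one place.
* **KM median** is the first time the curve reaches 0.5 or below (NA if
  it never does). This is *not* `survfit`'s convention, which averages
  the two adjacent event times when the curve sits exactly at 0.5; the
  first-crossing definition matches the empirical-survival oracle used
  in the tests.
* **Degenerate inputs**: empty interval sets yield empty clique lists;
  constant expression binarizes to all-zero with a warning; an
  all-carrier or no-carrier gene is a "no contrast" error; a Cox fit
  with no events or a constant covariate is an error, not an NA row.

## Open design choices

Several policies are not pinned down by the analysis description this
package implements; the defaults take the strictest reading and every
alternative is exposed as a configuration option:

* *"Uniquely found" in one age group* → default: any base-pair overlap
  between inner MCRs (same type) excludes a region;
  `policy = "reciprocal50"` requires the overlap to cover half of both
  MCRs before excluding.
* *Validation matching* → any same-type inner-MCR overlap; ties among
  candidate partners are broken by larger overlap, then leftmost start.
* *Gene assignment* → against the inner MCR (the region all carriers
  share, and the coordinate set that published tables report genes
  against); `assign_by = "outer"` is available.
* *Coding classification* → a region is "coding" when it overlaps a
  protein-coding gene span, refined to exon-level overlap when the gene
  model carries exons; the many fine-grained functional classes of
  region annotators are collapsed to coding/non-coding.

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_paired_experiment()` generate paired
discovery/validation cohorts shaped like the motivating study: 130/125
young and 867/870 old patients, young cutoff 45, and planted recurrent
regions of ~100–150 kb at penetrance 0.35 (the top published recurrence
frequency in young patients, ~37%, rounded) — five young-specific
regions (three gains, two losses) plus one planted in both age groups
as a specificity control. Carrier segments cover the planted region
with outward breakpoint jitter |N(0, 300 bp)|; probe counts are Poisson
at 0.5 probes/kb (SNP-array density); expression of the one gene model
emitted inside each planted region is baseline 8 + 1 SD × carrier +
N(0, 1); disease-specific survival is exponential with baseline median
12 years, log-hazard 0.7 per carried deleterious region, and
administrative censoring at 20 years. One master seed drives per-cohort
and per-patient derived streams, so runs are byte-reproducible and any
single patient can be regenerated alone.

**Background noise rate.** Noise segments (random chromosome ∝ length,
size log-uniform on [1 kb, 5 Mb], random gain/loss) default to a Poisson
mean of 2 per patient. This number is derived from a false-positive
budget, not from raw array segment counts: with a mean segment of
~0.6 Mb, 2 segments/patient keeps the expected fraction of the genome
randomly covered by ≥ 5 same-type patients below 1e-3 even in an
~870-patient group (per-type coverage ≈ 0.5×, and P(Poisson(0.5) ≥ 5) ≈
1.6e-4). Real cohorts show ~100 segments/patient, but most of that is
*biologically recurrent* structure which a uniform noise model cannot
represent — cranking uniform noise to that rate makes the "background"
itself recurrent (at 10/patient it blankets ~11% of the genome at
≥ 5-patient depth in the old group), which contradicts what background
noise is for. The rate is configurable for stress testing.

Consequently, a green planted-recovery test establishes that the caller,
specificity subtraction, matching, annotation and association stages are
wired correctly and recover known structure under jitter and sparse
noise. It does **not** establish performance on real tumor genomes:
no wave/GC artefacts, no correlated co-occurring alterations, no
subclonality or aneuploidy, no realistic breakpoint hotspots, no
expression networks — and the survival model is a plain exponential.

## Known limitations

* Recurrence is purely combinatorial (frequency filters); there is no
  significance model against a genome-wide background rate à la GISTIC,
  and no multiple-testing control over *regions* (only over genes in
  the association tables).
* Association models are unadjusted (no age, stage or subtype
  covariates) and proportional hazards is not formally diagnosed.
* Pathway enrichment, transcript-level consequence annotation and
  figure rendering are out of scope; matrices and tables are exported
  for external tooling.
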