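---
title: "Profiling detoxification gene families in metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling detoxification gene families in metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detoxprof)
```

## The problem

Shotgun metagenomes of marine surface waters let us ask whether toxicant
selection pressure is visible in the gene content of bacterial communities:
are detoxification systems (metal resistance, toxin transporters, oxidative
stress defense, antibiotic resistance) more or less abundant than we would
expect, and do coastal, estuarine or polluted sites carry more of them than
the open ocean? Raw read counts per protein family cannot answer this
directly, for two reasons:

1. **Sequencing depth and community size vary per site.** We therefore divide
   every family's read count at a site by the count of a *single-copy marker*
   — the Pfam domain `RNA_pol_Rpb2_6` of the RNA polymerase *rpoB* gene, which
   occurs almost exactly once per bacterial genome. The resulting
   *per-genome equivalent* reads as "average copies of this family per genome
   in the community".
2. **Some families are naturally large paralogous families.** A major
   facilitator transporter count of 20 per genome is unremarkable; a catalase
   count of 0.05 is not. We therefore additionally divide each per-genome
   value by the family's average copy number across a panel of sequenced
   bacterial genomes (*paralog normalization*). A value of 1 means "as
   abundant as expected from genomes"; below 1, underrepresented.

Upstream of all of this, family assignment itself must be trustworthy.
Profile-HMM searches are filtered twice: by each profile's *trusted cutoff*
(a score threshold at or above which every hit is a bona fide member; a score
exactly at the cutoff passes), and by *reciprocal* filtering — a sequence is
kept only if its best match over the entire profile database is the family
that initially found it. This removes cross-matches within Pfam clans (the
peroxiredoxin/thioredoxin/redoxin families lose 40–70% of their initial hits
this way), at the cost of discarding genuinely ambiguous sequences.

## Pipeline stages and their contracts

`run_pipeline()` composes the stages in a fixed order; each is also an
exported function.

* **screen** — `parse_hit_table()` (HMMER3 `tblout`/`domtblout`),
  `apply_trusted_cutoffs()`, `best_profile()` per sequence over the
  full-database scan, `reciprocal_filter()`, `retention_stats()`. Reciprocity
  operates on full-sequence bit scores; ties are broken by higher score, then
  lower E-value, then lexicographically smaller profile id, so results are
  independent of input order.
* **genome-stats** — `build_genome_matrix()` counts *distinct protein
  sequences* per genome and family (genes/genome, not domains);
  `family_stats()` reports mean, median, sample SD (n−1) and CV%;
  `validate_marker()` checks the marker is single copy (defaults: mean within
  1 ± 0.15, SD ≤ 0.2). CV is reported as missing, not 0 or ∞, when the mean
  is 0.
* **normalize** — `per_genome_normalize()` (sites with zero marker counts are
  excluded and reported, never silently imputed), `sparsity_filter()`,
  `paralog_normalize()`, `log2_with_floor()`.
* **analyze** — `site_cv()`, `hierarchical_cluster()` (Euclidean distance,
  complete linkage on both axes), `group_compare()` /
  `category_compare()` (habitat, geographic region, pollution), and
  `environment_pca()`.

### Numerical rules in the normalization

* **Zero replacement (0.01)** applies only to genome-content *expectations*
  that are exactly zero, never to observed counts. Observed zeros stay zero
  through the ratio stages.
* **Sparsity filter**: sites with strictly more than 3 families at zero, and
  families with strictly more than 3 sites at zero, are removed. Both
  criteria are evaluated simultaneously on the input matrix, in a single
  pass. We deliberately do not iterate to a fixpoint: a single simultaneous
  pass is order-independent and matches the one-shot description of the
  procedure; iterating could cascade removals that depend on evaluation
  order.
* **log2 floor (−10)**: zeros that survive filtering are set to −10 on the
  log2 scale. The floor is applied *after* sparsity filtering, and the stage
  machinery enforces this: `log2_with_floor()` refuses matrices that have not
  passed `sparsity_filter()`, and refuses already-logged matrices. The floor
  is applied before any clustering distance is computed.
* **Mean vs median expectation** is a configuration switch (default mean).
  Across genome panels the two are highly concordant
  (`median_mean_concordance()` reports the R²), so either is defensible.

### Statistical choices

* **Group comparisons** use the two-sided Mann–Whitney U test on per-site
  normalized abundances (default), with Welch's t on log2 values as the
  alternative. Site-level abundances are skewed and group sizes are small,
  which favors a rank test; the cost is the discreteness of its null
  distribution at small n (see calibration below). Relative abundances are
  reported as group mean / reference-group mean with the reference fixed at
  exactly 1; significance is reported in raw tiers (p < 0.01, p < 0.05), with
  Benjamini–Hochberg correction available but off by default, matching the
  convention of reporting uncorrected tiers for this kind of survey.
* **Category aggregation** sums family values per functional category per
  site before testing. Summing (rather than averaging normalized values)
  keeps the category value interpretable as "category genes per genome" and
  pools power across weak, same-direction effects.
* **Clustering** is agglomerative with Euclidean distance and complete
  linkage on both sites and families. Complete linkage is the default of the
  standard R clustering routine and is insensitive to row order (merge
  heights are permutation invariant, which the tests assert).
* **PCA** is run on unit-scaled variables because family abundances and
  environmental covariates (salinity ‰, temperature °C, depth m, oxygen
  utilization) live on incommensurate scales. Only complete-case sites enter;
  chemistry estimates typically exist for a minority of sites, so region and
  pollution analyses run on that subset only, while habitat comparisons use
  all sites.
* **Pollution partitioning** uses the pollution class (or a thresholded
  continuous score); shipping intensity is recorded but never used for the
  split, because high shipping does not reliably imply high pollution.

## The synthetic-data generator

No public per-site hit tables accompany the bundled pooled counts, so the
package carries a forward model that generates data with the statistical
structure the analysis assumes. It simulates *hits and counts*, not
nucleotide sequences: read errors, assembly and ORF calling are out of scope.

* **Genome copy numbers** are zero-inflated negative binomial per family.
  This is a stand-in — no generative law is implied by the real genome
  tables — but it is the simplest family that reproduces their signature:
  means below 1 with CVs of 100–350% and many complete absences, which a
  Poisson cannot produce (a Poisson with mean 0.2 caps the CV near 224% and
  cannot decouple zeros from the mean). Defaults: zero inflation 0.25,
  dispersion 0.5, component means scaled so that overall means equal the
  bundled per-genome averages. All parameters are arguments.
* **The marker** is fixed at exactly one copy per genome, and is exempt from
  confusion and habitat effects by default, because the normalization assumes
  an unbiased marker; `marker_perturb` lets a fraction of genomes carry a
  second copy to emulate real panels where the marker is *nearly* single
  copy (mean 1.0, SD 0.1).
* **Site counts** are Poisson draws around
  `depth × Σ_g w_g copy_g(f) × effect_f / Σ_g w_g copy_g(marker)`, where the
  community weights `w_g` are arbitrary (the fixture draws them from a
  symmetric Dirichlet via normalized Gamma(1) variables) and `depth` is the
  expected marker read count. Habitat effects are multiplicative on the
  expectation.
* **Clan confusion** is a row-stochastic matrix over families; observed
  counts are redistributed multinomially (conserving the per-site total
  exactly), and synthetic full-database scan tables encode the same confusion
  so that reciprocal retention converges to the diagonal.
* **Determinism**: every operation draws from an RNG stream derived from the
  master seed and the operation's name (`stream_seed()`), so outputs are
  identical across runs and independent of call order elsewhere in the
  pipeline.

What passing tests on this generator do *not* show: robustness to real-data
features it omits — fragmentary reads truncating domains (the package only
*diagnoses* length bias via `length_bias_check()`), non-Poisson
overdispersion from population structure, chimeric ORFs, or taxonomic
composition shifts correlated with covariates in ways the habitat-effect
model does not capture.

## Problem sizes and calibration choices

The packaged fixture is 6 detoxification families plus the marker, 12 sites,
50 genomes at an expected marker depth of 2,000 reads/site — small enough to
run the full pipeline in well under two minutes while leaving every stage
non-trivial (tens of thousands of synthetic hits). Parameter-recovery checks
use a depth of 10⁵, where per-genome estimates recover truth with a median
relative error under 5%.

For the type-I calibration of `group_compare()` (1,000 null replicates × 20
families, lognormal abundances at 30% CV) we use 30 sites per group. The
group size was chosen from the exact null distribution of the two-sided
Mann–Whitney test *before* running the simulation: the test's attained size
for "p < 0.05" is 0.0433 at n = 10 per group (the discreteness of the exact
test makes it conservative) and 0.0496 at n = 30, so at 30 sites per group
the empirical rejection rate is expected to sit within two binomial standard
errors of the nominal 5%. The power demonstration (a planted 2× habitat
effect, 20 sites/group, 30% CV, 200 replicates) detects the effect at
p < 0.01 in well over 80% of replicates.

## Known limitations

* The TehB row of the bundled pooled-count table is arithmetically
  inconsistent as published (its reciprocal count would exceed its initial
  count at the printed retention); its read counts are stored as `NA` and it
  is excluded from retention computations, while its genome statistics are
  retained.
* Whether the original full-database rescans applied trusted cutoffs or
  default thresholds is not documented; `screen_site()` applies cutoffs to
  the initial search only, and takes the best full-database hit as-is.
* Reciprocal filtering is sequence-level (full-sequence scores). Per-domain
  reciprocity would need domain coordinates that per-target tables do not
  carry; the per-domain parser dialect still reads full-sequence columns.
* The paralog normalization treats the genome panel as an unbiased prior for
  community genome content; if the panel over-represents cultivable clades,
  "expected" copy numbers inherit that bias. Using the marine-only subset
  (`subset: marine`) mitigates but does not remove it.
* Minimum read–ORF overlap for `count_reads_by_family()` defaults to 1 bp
  (any overlap counts), configurable via `min_overlap`.
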