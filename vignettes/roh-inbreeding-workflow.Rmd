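---
title: "Runs of homozygosity, genomic inbreeding and proband-unique variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Runs of homozygosity, genomic inbreeding and proband-unique variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
library(data.table)
```

## The problem

When a single affected individual (the proband) is whole-genome sequenced
together with a few unaffected relatives and breed-matched controls, two
questions dominate the analysis:

1. **Which variants are private to the proband?**  After standard hard
   filtering, the variants at which the proband carries an alternate
   allele that no other sequenced sample carries — not even
   heterozygously — are the candidates for de novo or private causal
   variation.
2. **How inbred is the proband, really?**  The genomic inbreeding
   coefficient F\_ROH — the fraction of the autosomal genome covered by
   runs of homozygosity (ROH) — can be compared against the expectation
   from a hypothesised pedigree.  For an offspring of two full siblings
   the expectation is F = 1/4 when the founders are themselves outbred,
   and

   $$F = \tfrac{1}{4}\,(1 + F_\mathrm{base})$$

   when the founding population already carries a baseline level of
   autozygosity \(F_\mathrm{base}\).  Estimating \(F_\mathrm{base}\) as
   the mean F\_ROH of the control genomes turns the genomic measurement
   into a test of the suspected mating structure.

`autozyg` implements this whole post-calling workflow — variant
filtering, ROH detection, inbreeding expectations, gene overlap and
keyword triage — together with a gene-dropping simulator that generates
pedigree-structured data with known truth, so that every stage can be
validated end to end without any external data.

## Variant retention

The filter chain mirrors the conventional short-variant hard-filter
recipe.  A record fails a named filter only when the annotation is
present and violates the *strict* inequality:

| filter | fails when | default |
|---|---|---|
| QD | QD < 2.0 | `qd_min = 2` |
| FS | FS > 60.0 | `fs_max = 60` |
| MQ | MQ < 56.0 | `mq_min = 56` |
| SOR | SOR > 3.0 | `sor_max = 3` |
| MQRankSum | < −12.5 | `mqranksum_min = -12.5` |
| ReadPosRankSum | < −8.0 | `readposranksum_min = -8` |
| DP | DP strictly below the 75th percentile of site DP | `dp_quantile = 0.75` |

Boundary values pass, and a missing annotation never fails its filter —
the same convention the upstream caller's `VariantFiltration` uses.  Two
points deserve emphasis:

* **The depth percentile is nearest-rank** (the sorted value at position
  `ceiling(q*n)`), because that definition is exact and reproducible
  across implementations; linear interpolation is available via
  `dp_method = "linear"`.
* **The depth rule as stated discards the lower 75% of sites.**  That is
  an aggressive cut — it keeps only the deepest quarter of the call set —
  and is unusual among depth filters, which normally remove extreme
  depths on both tails.  We implement the rule exactly as stated, and
  expose `dp_direction = "above"` for users who want the opposite
  reading.  The cutoff is always computed from the full table handed to
  `apply_hard_filters()`, so downstream subsetting cannot shift it.

SNP selection is record-level: a record with any non-SNV allele is
removed whole, matching record-level `--select-type-to-include SNP`
semantics.  Known-variant exclusion requires allele identity by default
(a novel allele at a known site survives); `match = "position"` switches
to site-level matching.  Proband-unique selection requires a call in
every sample, which is why missing genotypes are tracked explicitly.

## ROH detection

`detect_roh()` re-implements the sliding-window scanner of PLINK 1.9's
`--homozyg`.  Only two constraints are analysis-specific — segments must
contain at least 100 SNPs (`min_snps`) and span more than 1000 kb
(`min_kb`) — while the remaining knobs default to the published PLINK
defaults (50-SNP windows, at most 1 heterozygous and 5 missing calls per
homozygous window, a 5% window hit fraction, a 1000 kb maximum gap, and
at most 50 kb per SNP).  All of them are exposed in `roh_params()`.

The published scanner leaves some corners undocumented (behaviour at
chromosome ends, trimming order).  Here the semantics are pinned down by
a brute-force oracle — a naive implementation that materialises every
window and every candidate run — and the fast scanner is required, by
property-based tests over random genotype vectors, to agree with it
exactly.  Consequences of our definitions:

* a chromosome with fewer SNPs than `window_snps` contains no windows
  and therefore never yields a segment;
* candidate runs are trimmed so both endpoints are homozygous
  non-missing calls, preventing heterozygous or missing SNPs from
  padding segment length;
* segment length is `end − start + 1` bp (1-based inclusive);
* X and MT genotypes are never scanned: F\_ROH is an autosomal quantity.

Numerical identity with PLINK on real data is not claimed — the oracle,
not the external tool, defines this package's semantics.

## Inbreeding expectations

`kinship_matrix()` implements the recursive tabular method:
f(i,i) = (1 + F\_i)/2 with F\_i the kinship of i's parents, and
f(i,j) = (f(father\_i, j) + f(mother\_i, j))/2 processing individuals
parents-first.  Founders are unrelated but may carry per-founder
inbreeding, which is how the breed-level baseline enters the recursion.
The closed form `expected_sib_f(b) = 0.25 * (1 + b)` and the recursion
through `sib_mating_pedigree(b)` are required by tests to agree to
better than 10 decimal places, and both are checked against an
independent Wright path-counting oracle (exhaustive enumeration of
ancestral path pairs) on random multi-generation pedigrees.

Reported expectations are rounded **half-up** to two decimals
(`round_half_up()`), the convention used when such coefficients are
quoted; the raw values are retained in all returned tables.

The autosomal genome length defaults to 2,212,284 kb, the canine
autosomal assembly total, and is configurable for other genome builds.

## The simulator

`simulate_quartet()` generates the full study design: a proband whose
parents are full siblings, the father among the sequenced samples, and
two unrelated controls.

* **Meiosis** follows the Haldane model: crossover counts are Poisson
  with mean equal to the chromosome's genetic length in Morgans,
  positions uniform, no interference.  This is the simplest model with
  closed-form expectations, which the truth-tracking tests rely on.
* **Baseline autozygosity** is created by a finite founder-haplotype
  pool: each chromosome has `founder_pool_size` distinct haplotypes and
  every founder draws twice with replacement, so founder autozygosity is
  1/pool\_size in expectation.  This is far cheaper than simulating a
  deep ancestral pedigree, and — as in the intended analysis — the
  *measured* baseline, not the nominal pool size, is what feeds
  `expected_sib_f()`.
* **Truth labels**: every haplotype carries an origin label through the
  gene drop, so realized autozygosity is known exactly
  (`true_autozygosity()`), injected proband-only variants are recorded,
  and every annotation failure records which filter it violates.
* **Default scale**: 4 autosomes × 120 Mb at 1 marker / 3 kb (160k
  markers) and ~1 cM/Mb.  This keeps a full pipeline run in seconds
  while still allowing 100-SNP / >1000-kb ROH to arise.  The
  replication tests use 50 gene-dropping replicates on a 20-Morgan
  genome for the autozygosity recovery check and 20 full-pipeline
  replicates at the default scale for the proband-versus-controls
  F\_ROH comparison.
* **Injected uniques** default to 43 variants split 20/9/14 over
  autosomes, X and MT, with 8 of the X variants clustered within an
  800 bp span — the structure of a private-variant call set with a
  tight regulatory cluster.

Deliberate simplifications, hence what passing tests do *not* show about
real data: the X chromosome is gene-dropped as diploid for every
individual (no hemizygous male transmission) and exists only as a
variant compartment — ROH and F\_ROH ignore it by design; there is no
genotyping error beyond missingness and the annotation draws; marker
ascertainment, LD structure and allele-frequency spectra are idealised
(uniform MAF in `[maf_low, maf_high]`); and the mitochondrial compartment
is a single maternal lineage with no heteroplasmy.

## Worked run

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 2024)
report <- run_pipeline(sim = cfg)
report$roh_summary
report$inbreeding
```

With outbred founders (`founder_pool_size = Inf`) the controls show
F\_ROH near 0 and the proband recovers a large fraction of its true
~0.25 autozygosity; the detected F\_ROH underestimates the truth
slightly because the depth rule thins the marker backdrop and short
autozygous segments fall below the 100-SNP / 1000-kb emission
thresholds.  That bias direction is expected for ROH-based inbreeding
estimates at modest marker density.

The same orchestration accepts a real merged VCF
(`run_pipeline(vcf = "calls.vcf", proband_id = "...", known = "dbsnp.tsv",
genes = "genes.bed")`); the known-variant file must already be in the
analysis genome's coordinates — no liftover is performed.

## Clinical helpers

`mosaic_fraction(n_abnormal, n_total)` summarises karyotype mosaicism as
a whole-number percentage with an exact Clopper–Pearson interval, e.g.
18 abnormal spreads out of 82 give 22% (95% CI 13.6–32.5%).  The
interval is computed from beta quantiles and cross-checked in the tests
against a root-finding oracle on the binomial tail.

`keyword_triage()` filters an exported enrichment-term table by
case-insensitive substring match on term names only (gene names are not
searched), with "hermaphrodit" as the recommended stem covering both
"hermaphroditism" and "hermaphroditic".  `exclude_gene_patterns()`
reproduces the usual portal-side drop of miRNA- and olfactory-style
symbols with configurable patterns.

## Degenerate inputs and tie-breaks

* Empty record sets flow through every stage (header-only VCF out,
  all-zero summaries, empty overlap).
* A sample with zero ROH gets `kb_avg = 0` rather than NaN.
* `dp_quantile_threshold()` on a constant vector returns that constant;
  ties in the DP values are handled by the nearest-rank definition
  without interpolation.
* Multi-allelic records are retained in I/O and judged as whole records
  by the SNP and known-variant filters.
* Pedigree cycles are rejected at construction; an individual with an
  unknown parent has no defined expected inbreeding (NA with a warning).

## Interface note

The package is driven from R: `run_pipeline()` is the single
orchestrated entry point, every stage is also exported on its own, and
all thresholds carry the names used in the field
(`min_kb`/`min_snps` for the ROH constraints, the filter names for the
hard thresholds).  Intermediates are written as plain tab-separated
files plus a VCF of the unique variants, so runs are auditable and
diffable; identical configuration and seed reproduce outputs
byte-identically.
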