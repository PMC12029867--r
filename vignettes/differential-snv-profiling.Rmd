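---
title: "Differential SNV profiling of gut metagenomes under probiotic intervention"
author: "probiosnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential SNV profiling of gut metagenomes under probiotic intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A single oral dose of a probiotic transits the gut within days, yet while it
is present it competes with the resident microbiota for nutrients and
niches. That competition is a selective pressure, and its footprint can be
visible below the species level: as single-nucleotide variants (SNVs) that
accumulate in resident populations relative to their reference genomes.
`probiosnv` implements a reusable pipeline for detecting that footprint in a
controlled intervention design — two arms (treatment, control), two
intestinal segments (small, large), three sampling days (1, 3, 7), several
replicate animals per cell — and for separating intervention-induced
variants from two confounders that dominate naive comparisons:

* **reference-selection artifacts** — apparent SNVs caused by the chosen
  reference strain differing from the resident strain; these appear in
  control animals just as in treated ones;
* **natural temporal variation** — SNVs that arise over time regardless of
  the intervention; these appear in both arms on the same day.

## The calling model

The evidence unit is a per-sample *pileup*: for every reference position,
the counts of aligned A/C/G/T reads. A site is called an SNV iff

$$\mathrm{depth} \ge c \quad\text{and}\quad
  \frac{\max_{b \ne \mathrm{ref}} n_b}{\mathrm{depth}} \ge f,$$

with defaults $c = 100$ reads and $f = 0.49$. Both bounds are inclusive
(a site at exactly 100 reads and exactly 0.49 alternate fraction is
called); the near-threshold simulation preset
(`sim_config_near_threshold()`) plants variants at frequencies 0.45 and
0.49 so the boundary semantics stay pinned by tests. The reference base
comes from the reference genome, never from the pileup majority — with $f$
near 0.5 the caller deliberately targets near-consensus divergence from the
reference. Only the top non-reference allele is reported per site, with
ties broken by the fixed order A < C < G < T. An optional
`min_alt_count` (default 1) is exposed rather than guessing the internals
of upstream tools.

Raising either threshold can only remove calls, never add them; this
monotonicity (nested call sets across a $(c, f)$ grid) is asserted in the
test suite.

### Region and codon classification

Positions are classified against GFF3 gene models (1-based inclusive
coordinates, the convention used at every external interface of this
package): `coding` inside a CDS, `noncoding_genic` inside an RNA gene only,
`intergenic` otherwise. A record overlapping several CDSs is emitted once
per gene context so no annotation is silently lost.

For coding records the affected codon is extracted on the coding strand
(reverse complement for minus-strand genes; the reported ref/alt bases stay
in reference-strand orientation), the alternate base substituted at its
in-codon offset, and both codons translated with the bacterial genetic code
(NCBI table 11). Table 11 differs from the standard code only in
start-codon rules, which cannot affect single-substitution classification
of sense codons; initiator-specific translation is not modelled. A
substitution is synonymous iff the amino acids agree; an alternate allele
creating a stop codon is nonsynonymous with `aa_alt = "*"`. The classifier
is verified exhaustively against an independent whole-protein oracle: for
random CDSs on both strands, all 3L single-base substitutions are compared
with a mutate-translate-diff of the entire protein.

## The provenance filter

Variant identity is the key (species, contig, position, alternate base):
two alternate bases at one position are two variants; allele frequency and
day are not part of identity. Per-sample calls are first aggregated to
(group, segment, day) cells — by union over replicates by default, with
majority and intersection modes available, since the emulated workflow does
not state replicate handling. Union is the only mode that cannot miss a
control-observed artifact, which makes it the conservative choice for the
negative-control logic below.

Two set subtractions follow, per (species, segment, day):

1. **artifact removal** — treatment keys found in the union of control
   sets over *all* days of the segment are removed (a reference/resident
   strain discrepancy is visible in controls regardless of day; a
   day-matched scope is available by configuration);
2. **natural-variation removal** — remaining keys found in the
   *day-matched* control set are removed.

What survives is labelled `induced`. Because both stages subtract fixed
sets, their order cannot change the retained set — only the stage
attribution, which is fixed as artifact-first. One structural consequence
is worth stating plainly: under the default scope the day-matched control
set is a subset of the all-days union, so the natural-variation stage never
removes anything *additional* and the per-cell report attributes all
control-supported removals to the artifact stage. The two-stage structure
is retained because the scopes are independently configurable and the
bookkeeping (`n_input = n_artifact + n_natural + n_retained`, enforced as
an internal invariant) makes the attribution rule auditable.

## The taxon screen

Species quantitatively tied to the focal probiotic are found by Spearman
correlation against the focal taxon's relative abundance, with the strict
screen thresholds $p < 0.05$ and $|\rho| > 0.5$ (boundary values are
excluded on both gates). $\rho$ is the tie-aware rank correlation; the
two-sided $p$ is computed by full enumeration of all $n!$ permutations for
$n \le 8$ (which handles ties exactly) and by the $t$ approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ beyond. Which samples enter the
correlation is not dictated by the design, so the default pools all
treatment-arm samples within one segment ($n = 3\ \text{days} \times
\text{replicates} = 18$ at the default design) and the sample set is
configurable. No multiple-testing correction is applied by default,
matching the screening practice the pipeline mirrors; Benjamini–Hochberg
is available by flag. Species with constant abundance have undefined
$\rho$; they are excluded from the screen and reported separately rather
than erred on.

## Community statistics

Shannon ($-\sum p \ln p$, nats) and Simpson diversity are computed from
relative abundances; "Simpson" means the Gini–Simpson index $1 - \sum p^2$
by default (the convention of the ecology package family this field uses),
with the dominance form $\sum p^2$ available by flag. Group comparisons use
a gated `auto` mode: Shapiro–Wilk per group and Levene's test at
$\alpha = 0.05$ choose between one-way ANOVA + Tukey HSD and
Kruskal–Wallis (tie-corrected H) + Dunn pairwise $z$ tests; the degenerate
all-equal case returns $H = 0$, $p = 1$ rather than dividing by zero.
Between-sample structure uses Bray–Curtis dissimilarity, classical-scaling
PCoA (negative eigenvalues — Bray–Curtis is not Euclidean — are dropped
from the axis-proportion denominator and counted; no Cailliez correction),
and PERMANOVA. The ordination-attached group test is deliberately
PERMANOVA on Bray–Curtis with seed-controlled permutations and
$p = (1 + \#\{F^{perm} \ge F\})/(1 + n_{perm})$: the upstream literature
this mirrors does not name its test, so the package picks the common
practice and makes no claim of reproducing any particular printed value.

## The synthetic study generator

Every stage above is validated against a generator that emulates the full
design with planted, provenance-labelled truth:

* **genomes** — i.i.d. uniform A/C/G/T sequences (default 5 species of
  50 kb) with non-overlapping CDSs (lengths divisible by 3, mixed strands)
  and RNA genes;
* **variants** — positions drawn without collision; alternate bases drawn
  with a 2:1 transition:transversion bias so spectra are testably
  transition-heavy; provenance `induced` (treatment-only, all days of one
  segment), `artifact` (all samples of a segment), `natural` (both arms,
  one designated day);
* **pileups** — depth $\sim$ Poisson(150) per site; at a variant site
  present in a sample, alternate reads $\sim$ Binomial(depth, 0.6);
  miscalls at a configurable `error_rate` (default 0);
* **abundances** — built directly in relative-abundance space so the
  engineered relations survive compositional closure: the focal
  probiotic's share decays over days in treatment samples (0.05, 0.02,
  0.005) and is exactly 0 in controls (transient carriage after a single
  gavage); positive-design species get shares $b(1 + 25F)$ (exactly
  increasing in the focal share $F$); none-design species and bulk filler
  taxa get constant shares (exactly independent of the focal); the
  negative-design species absorb the remaining mass and are therefore
  exactly decreasing. Multiplicative log-normal noise (sd 0.3 by default)
  is applied on top and columns renormalized — a no-op at zero noise, so
  the zero-noise contracts ($\rho$ exactly $\pm 1$, null species flagged
  constant) are exact. Closure makes it impossible for *every* non-focal
  taxon to be independent of the focal — something must absorb its share —
  which is why the absorber role is explicit (negative-design species, or
  the fillers when none exist).

The defaults (6 replicates per cell, hence 72 samples; depth 150; planted
allele frequency 0.6; thresholds 100/0.49) are the study conditions the
package targets, not tuning knobs. One statistical subtlety is documented
rather than hidden: with binomial read sampling at frequency 0.6 and
Poisson depth 150, a single sample misses a planted variant with
probability $\approx 3\times10^{-3}$ (the alternate fraction falls below
0.49), so *per-sample* recovery is not exactly 1 over thousands of variant
observations. Recovery is therefore defined — and is exact for all
practical purposes, with per-cell miss probability $\approx 10^{-15}$ — at
the replicate-union level per (group, segment, day) cell, which is also
the filter's default aggregation. With `error_rate = 0` a non-variant site
cannot produce alternate reads, so precision is exactly 1.

What the generator does **not** emulate: indels, strand bias, mapping and
alignment artifacts, read-level error profiles, within-species strain
mixtures beyond a single planted allele frequency, and realistic genome
composition (GC skew, codon usage). Passing tests therefore demonstrate
the correctness of the pipeline's logic under its stated model, not
robustness to upstream alignment pathology.

## Determinism and numerics

Everything is deterministic given one master seed: each generator stage
and each sample derives a fixed sub-seed, so any sample's pileup can be
regenerated in isolation and two runs of `run_pipeline()` with the same
seed produce byte-identical TSVs (allele frequencies are serialized at a
fixed 6 decimals for this reason). Permutation tests take explicit seeds.
Degenerate inputs are contracts, not crashes: empty record sets write
header-only tables, all-equal groups return $p = 1$, constant screen
vectors are flagged, and the filter traps any violation of its counting
invariant as an internal error.

## Problem sizes used in validation

The shipped test-and-acceptance suite exercises: the full clean study
configuration (5 species × 50 kb × 72 samples) for exact recovery and
filter checks; 20 random 300-bp CDSs (both strands, all 900 substitutions
each) for the codon oracle; 2,000 simulated abundance tables for screen
null calibration; 2,000 replicates each for the type-I calibration of the
omnibus test, PERMANOVA (99 permutations, $n = 15$), and the regression
slope test; and a small 2-species demo configuration for end-to-end
byte-determinism. These sizes are the package's chosen validation budget:
large enough that the binomial bounds asserted in the tests are sharp,
small enough to run routinely.

## Known limitations

* The provenance filter is purely set-theoretic, by design; it performs no
  frequency-based differential testing, and a variant present but below
  the calling thresholds in controls will be retained as induced.
* Exact Spearman enumeration stops at $n = 8$ ($8! = 40{,}320$
  permutations); beyond that the $t$ approximation is used, which is
  slightly anticonservative at small $n$ with heavy ties.
* The pipeline computes the screen and the SNV analysis independently; the
  screen's edge table reports which taxa correlate with the focal
  probiotic, but a species is not dropped from SNV profiling for failing
  the screen, since under noisy abundances that gate would make downstream
  outputs fragile to the seed.
* Multi-allelic sites report only the top alternate allele; a genuinely
  tri-allelic population is summarized by its strongest minor allele.
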