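---
title: "Prophage landscapes: models, detector, and statistics"
author: "prophagr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prophage landscapes: models, detector, and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prophagr)
```

## The quantities

A lysogen is a bacterium whose chromosome carries at least one integrated
temperate phage (a prophage). `prophagr` is built around three connected
quantities:

* **Genomic prophage density** `rho = prophage bp / host bp`, with the
  host length *excluding* the prophage regions. The density is
  scale-free; a genome carrying 24 bp of phage DNA per 1,000 bp of host
  DNA has `rho = 0.024`. The package's statistics ask whether `rho` is
  uniform across genome sizes (it is, by construction, in the synthetic
  cohorts; `bin_by_genome_size()` measures it).
* **Prophage length distribution.** Pooled across diverse taxa,
  individual prophage lengths form a unimodal, right-tailed distribution
  peaking near 20 kbp, while single species can be multimodal.
  `kde()` reports the mode; `dip_test()` tests unimodality.
* **Energetic cost of carriage.** Treating cellular maintenance as
  dominated by DNA replication, the ATP spent on prophages is the
  maintenance budget times the density:
  `prophage_atp_per_hr = M * rho`, and per genome base pair
  `M * rho / G`. With the defaults `M = 0.2e9` ATP/hr, `rho = 0.024`,
  `G = 5.1e6` bp this is 0.94 ATP/bp/hr, and the fraction of maintenance
  energy spent on prophages equals `rho` identically — that equality is
  the model's proportionality assumption, not an empirical output.
  (Note the intermediate `0.2e9 * 0.024` is `4.8e6` ATP/hr; the final
  per-bp figure 0.94 follows from it.)

```{r energetics}
prophage_energy_cost(maintenance_atp_per_hr = 0.2e9, density = 0.024,
                     genome_bp = 5.1e6)
```

## The synthetic cohort generator

Real corpus-scale analyses need hundreds of thousands of assemblies; the
generator instead produces cohorts whose *statistical structure* matches
the landscape the analysis assumes, together with exact ground truth, so
every downstream claim is checkable.

Each genome is an iid nucleotide backbone at a target GC (default 0.5)
with host-like gene structure: gene lengths around 900 bp, ~120 bp
intergenic spacing, strand assigned in alternating blocks of 3–8 genes.
Genome lengths are log-normal with mode 2.3 Mbp (or uniform over a
requested range, convenient for spanning genome-size bins evenly).

Prophage cassettes are planted into intergenic gaps, at least 2,500 bp
from contig edges, never overlapping, until the planted total reaches
`target_density` (default 0.024) times the backbone length. Cassette
lengths are log-normal with mode 20 kbp and standard deviation 8 kbp —
a tailed decay after the peak — or a per-taxon mixture of such
components. Because a genome receives only a handful of cassettes, the
integer cassette count is chosen as the closer of the two bracketing
counts, and the final cassette is resized only when the achieved total
would otherwise leave the ±20% (relative) band around the target. This
keeps per-genome densities naturally dispersed while the cohort mean
converges on the target (the test suite checks `|mean − target| <
0.1 × target` at n = 200).

Cassettes carry the five signals the detector uses:

1. shorter genes (mode 600 bp vs 900 bp in the backbone);
2. ≥90% of genes on one strand (long same-strand runs);
3. marker k-mers (default 200 random 12-mers) substituted at one per
   150 bp — the stand-in for foreign phage k-mer content;
4. a skewed base composition (GC skew +0.25, AT skew +0.15 by default),
   so ORF-level GC/AT skews deviate from the host baseline;
5. an exact direct repeat of 12 bp copied to both ends (the attL/attR
   pair formed at integration).

Two constructional details matter for exactness. Markers are assigned by
cycling through a shuffled marker set, so a marker reused within one
cassette has its copies ~30 kbp apart — otherwise marker pairs sitting in
both boundary windows would masquerade as att repeats. And the backbone
bases adjacent to each cassette are forced to mismatch the cassette bases
adjacent to the inner att copies, making the planted att pair *maximal*:
seed-and-extend then recovers exactly the planted coordinates.

MAG (metagenome-assembled genome) records are emulated by
`mag_degrade()`: each planted prophage is lost with probability
`mag_loss_prob` (default 2/3, i.e. a 3-fold expected density reduction)
and the contig splits at the excision point — the mechanism by which
binning pipelines drop prophage reads whose composition and coverage do
not match the backbone.

Metadata mimic assembly-database fields: isolation dates rendered in
mixed formats (ISO, year-month, bare year, and a few "not collected"),
country labels, GTDB-style rank-prefixed lineages, and a MAG flag.

What the generator does **not** emulate: real codon usage and gene
content, transposon decay of prophages (which degrades the compositional
signal in real genomes), insertion-sequence churn, assembly errors other
than MAG prophage loss, and database sampling bias beyond what the
taxon pool encodes. Detector performance on these cohorts is therefore a
check of the machinery under its stated signal model, not an estimate of
sensitivity on real assemblies — on real data the compositional contrast
is weaker and decayed prophages blur region boundaries.

`generate_cohort(..., sequences = FALSE)` plants at the coordinate level
only (no nucleotide sequence or gene layout). The density, length, MAG
and binning statistics are functions of coordinates alone, so their
checks run on cohorts of hundreds of multi-Mbp genomes in seconds;
sequence-level cohorts are reserved for the detector itself.

## The detector

Per retained contig (contigs shorter than `min_contig_len = 5000` bp are
dropped; assemblies with 100+ contigs are excluded by
`filter_assembly()`), the pipeline is:

1. **ORFs**: CDS features when the record has them, else a six-frame
   maximal start-to-stop ORF caller (first in-frame ATG after the
   previous stop, minimum 90 bp).
2. **Raw per-ORF signals**: length; strand; marker k-mer score (the
   fraction of the ORF's k-mer windows found in the marker set, k = 12);
   GC and AT skew deviations from the whole-genome baseline, with
   zero-denominator spans scoring 0.
3. **Window features** over the up-to-30-ORF window centred on each ORF,
   truncated at contig ends: median ORF length; longest same-strand run
   divided by the window length; means of the marker score and the two
   skew deviations. The marker-score feature is a reconstruction of a
   "phage k-mer" signal from first principles: published descriptions
   name the signal but not its exact transform, so the package defines
   it as the smoothed coverage fraction above and tests that definition.
4. **Classification** by a 500-tree random forest over the five
   features, trained on simulator-labelled ORFs (an ORF is `phage` iff
   its midpoint lies in a planted region). The decision threshold
   defaults to 0.5; raising it can only shrink the kept prophage bp
   (a monotonicity property the suite checks).
5. **Region assembly**: maximal runs of phage-predicted ORFs, tolerating
   up to `gap_tolerance = 2` consecutive host-predicted ORFs inside a
   run (prophages carry non-viral cargo). Runs with fewer than
   `number = 5` phage-predicted genes are emitted as discarded
   (`too_few_genes`), never dropped.
6. **Boundary refinement**: within ±2,000 bp of each boundary, the
   longest exact direct-repeat pair of ≥10 bp with one copy per window
   (seed-and-extend, no mismatches); the region snaps to the outer edges
   of the two copies. Ties on length go to the pair minimising the total
   boundary displacement, then to the leftmost pair. Note that two
   random 4-kbp windows share ~one chance 12-mer in expectation, so on
   synthetic data the planted att pair wins exactly when it is the
   longest repeat present; an occasional chance repeat of equal or
   greater length can shift a boundary by up to 2 kbp without affecting
   recovery at 50% reciprocal overlap.
7. **Verification**: a region is kept iff it has ≥5 genes and either at
   least `phage_genes = 1` ORF whose annotation contains a phage token
   ({"phage", "prophage", "integrase", "capsid", "tail", "terminase",
   "portal"}, case-insensitive, configurable) or at least one hit from
   the pluggable `hit_provider`. The reference provider is the marker
   lookup (≥1 marker window in the ORF); an adapter for `hmmsearch`
   against a user-supplied profile-HMM file is included, with a default
   E-value threshold of 1e-5 (the conventional choice; the upstream
   threshold is not published). The verified fraction is hit-ORF bp over
   region bp.

All parameters live in `run_config()`; a `threads` option is honoured
for interface compatibility but the reference implementation is serial
and results are thread-count invariant by construction.

## The dip statistic and its Monte-Carlo test

The dip of a sample is the minimum over all unimodal distribution
functions `G` of `sup |F_n − G|`, where `F_n` is the empirical CDF. The
implementation works on the jump midpoints `c_i = (2i − 1)/(2n)`: a
continuous `G` with `sup |F_n − G| ≤ d` exists iff `G` passes within
`r = d − 1/(2n)` of every `(x_i, c_i)`, so `dip = 1/(2n) + r*` with `r*`
the least sup-distance from the midpoints to a convex-then-concave
curve. `r*` is found by the classic shrinking modal-interval iteration:
compute the greatest convex minorant (GCM) and least concave majorant
(LCM) of the midpoints on the current interval, find the largest
LCM−GCM gap, freeze the flanks (a convex or concave fit must absorb half
the bulge of the midpoints relative to the corresponding hull), and
recurse into the interval around the gap until the interior gap no
longer exceeds what the flanks already require. Consequences worth
knowing: the statistic lies in `[1/(2n), 0.25]`; a sample of equal
values attains the floor (`1/(2n)` is exactly the price of continuity at
a jump); two balanced point masses approach 0.25. The compiled
implementation is cross-checked in the test suite against an independent
pure-R implementation (different hull algorithm and evaluation code) to
1e-9 on random samples up to n = 200.

The p-value is Monte-Carlo: the proportion of dip statistics from
`n_boot = 2000` uniform(0,1) samples of the same size that reach the
observed dip, with the add-one convention `(1 + k)/(n_boot + 1)` so a
reported p is never exactly zero. The uniform is the asymptotically
least favourable unimodal null; a table-interpolation approach would be
faster but the Monte-Carlo version is self-contained and its error is
controlled by `n_boot`. Samples above 80,000 observations are randomly
subsampled first (`max_n`), mirroring standard practice for this test's
implementations. The suite calibrates the test end to end: type-I error
at nominal 0.05 within [0.03, 0.07] over 500 uniform replicates
(n = 100 each, fresh nulls), p < 0.001 power on a 6-sd-separated
balanced normal mixture of n = 1000, and a Kolmogorov–Smirnov check that
null p-values are uniform.

## Statistical conventions

* **Density denominator.** Genome length for the density is the sum of
  contigs that passed the contig filter — the same universe the
  detector saw — minus the kept prophage bp. Corpus descriptions do not
  pin this choice; using the detection universe keeps numerator and
  denominator commensurable.
* **Genome-size bins** default to [0, 1.2e7) bp in steps of 1.4e6,
  left-closed right-open; genomes at or beyond the maximum are excluded
  with a message. The range is not a whole multiple of the step, so the
  last bin is truncated. Binned means are over lysogens only by default.
* **KDE** uses a Gaussian kernel with the normal-reference (Scott-type)
  rule `bw.nrd` by default (the bandwidth rule is a free choice;
  configurable) on a grid padded by six bandwidths, and reports the
  argmax as the mode. A zero-variance sample is an error, with a
  pointer toward histograms. On right-skewed log-normal length samples
  the smoothed argmax sits slightly above the true mode at moderate n;
  the recovery tests use a ±10% band.
* **Dates** become decimal years: full dates as
  `year + (day_of_year − 1)/365`, bare years as mid-year (+0.5),
  year-months as the 15th — unbiased within the stated granularity.
  Parsing is total (junk maps to missing, never an error) and years
  outside [1800, next year] are treated as junk. Duplicate metadata rows
  per accession keep the first. MAG status is taken from the metadata
  column only, never inferred.
* **Dereplication** keeps one uniformly random genome per distinct
  species label under a caller-supplied seed; genomes without a species
  are excluded.
* **Coordinates** are 1-based inclusive everywhere in R structures
  (Bioconductor convention), which is also GFF3's convention; the
  GenBank reader/writer and GFF3 exporter therefore do no coordinate
  shifting.
* **Trend regression** is ordinary least squares with the usual
  two-sided slope t-test; the MAG/isolate comparison is a two-sided
  Mann–Whitney U (normal approximation; fully tied inputs report p = 1).

## Reproducibility machinery

Simulation functions take explicit seeds and restore the caller's RNG
state; `generate_cohort()` derives every per-genome seed from the spec's
single seed, so equal specs give bit-identical cohorts, metadata
included. `run_config()` validates every pipeline knob (unknown keys are
rejected), `write_config()`/`read_config()` round-trip it through YAML
exactly, and `write_run_log()` records the seed, versions, and md5
digests of inputs. The acceptance suite re-runs a full
simulate–train–detect pipeline from its configuration echo and asserts
bit-identical output.

## Problem sizes in the checks

The test suite and `scripts/acceptance.R` exercise: a 50-genome
sequence-level cohort at the default 2.3 Mbp mode (plus a 6-genome
training cohort and 10 prophage-free backbones) for detector recovery;
200-genome coordinate-level cohorts spanning 2–10 Mbp for density
uniformity, lengths, and MAG contrasts; 100-sample batches up to
n = 200 for dip cross-validation and 500 × 2000 Monte-Carlo replicates
for its calibration. These sizes were chosen as the smallest at which
the targeted properties are statistically stable.

## Known limitations

* The detector is trained and evaluated on the generator's signal
  model; real prophages are decayed, mosaic, and compositionally closer
  to their hosts. Treat the recovery rates as validation of the
  machinery, not field performance.
* Boundary snapping trusts the longest-repeat rule; genomes rich in
  repeats (IS elements, rRNA operons) will produce spurious att
  assignments within the ±2 kbp windows.
* The GenBank parser targets well-formed flat files with simple
  `a..b` / `complement(a..b)` CDS locations; compound (`join`) locations
  are skipped with a warning rather than resolved.
* The energetics model is deliberately minimal: maintenance strictly
  proportional to DNA content, no transcription/translation terms, so
  its energy fraction *is* the density by assumption.
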