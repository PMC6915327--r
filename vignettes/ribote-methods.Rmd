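---
title: "ribote: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribote: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribote)
```

# What the package computes

`ribote` analyses ribosome profiling experiments in transcript space: a
footprint (RPF) library and a matched total-mRNA library per sample, two
conditions, several replicates. The chain is

1. **QC** — footprint length distribution, P-site reading-frame
   periodicity, metagene profile around the CDS start, and replicate
   reproducibility;
2. **Quantification** — gene counts, RPKM, and translational efficiency
   (TE);
3. **Differential translation** — a population z-score test on log2 TE
   ratios with BH FDR and fold-change classification of differentially
   translated genes (DTGs);
4. **5' UTR features** — length, GC content, TOP and uORF motifs,
   compared between DTG groups.

A seeded synthetic-data generator produces inputs with known ground
truth, so every stage can be validated by recovery rather than by
eyeballing.

# Quantification model

**RPKM.** For gene $i$ in one library,

$$\mathrm{RPKM}_i = \frac{c_i}{\frac{L_i}{10^3}\cdot\frac{\sum_k c_k}{10^6}},$$

with $c_i$ the raw gene count, $L_i$ the transcript length in nt, and
the library size $\sum_k c_k$ the per-sample total of gene-assigned
counts, computed **before** any gene filtering. Two consequences are
asserted as invariants: RPKM is invariant to rescaling a sample's
counts, and $\sum_i \mathrm{RPKM}_i L_i/10^3 = 10^6$ exactly per sample.

**Counting region.** By default every read counts toward its
transcript's gene and $L_i$ is the transcript length ("per kilobase of
*transcript*"). A `region = "cds"` option restricts counting to reads
whose P-site falls inside the CDS, for users who prefer CDS-restricted
footprint quantification; the default keeps both assays on the same
footing.

**TE.** Per condition, TE is the ratio of replicate-mean RPKMs,
$\mathrm{TE} = \overline{\mathrm{RPKM}}_{\mathrm{RPF}} /
\overline{\mathrm{RPKM}}_{\mathrm{mRNA}}$ — one TE per condition (not a
mean of per-replicate ratios), undefined (and logged) when the mRNA mean
is zero.

**Low-count filter.** A gene is kept only if its summed raw counts reach
40 in *each* assay (strictly fewer than 40 discards). The rule is
deliberately interpreted per assay, summed over that assay's samples:
the TE definition consumes both assays, and a gene unreliable in either
is unreliable in the ratio. `min_reads` and the scope are exposed if a
different reading is wanted.

# Differential translation

For genes with TE defined in both conditions the statistic is the log2
TE ratio $x_g = \log_2(\mathrm{TE}_B/\mathrm{TE}_A)$. Significance comes
from a **population z-score**: $z_g = (x_g - c)/s$ with $c,s$ estimated
across genes, and $p_g = 2(1-\Phi(|z_g|))$. BH-adjusted FDR values are
reported alongside; classification uses the raw $p$, as is conventional
for this style of analysis.

A gene is called **up** iff $\mathrm{ratio} > 1.5$ and $p < 0.05$,
**down** iff $\mathrm{ratio} < 0.667$ and $p < 0.05$; both inequalities
are strict, so a ratio exactly at a threshold is `unchanged`. The
classification is exactly symmetric under swapping the two conditions.

**Standardization choice.** The z-score needs the spread of the
*unchanged* gene population, and the observed ratio distribution is a
mixture of that null with genuinely changed genes. The estimator
matters:

* `mean_sd` is heavily inflated by real effects (with a fraction $f$ of
  changed genes at $\pm\delta$, the sd picks up $f\delta^2$), which can
  push true effects below the significance threshold — at 20% planted
  2.5-fold effects it roughly halves sensitivity;
* `median_mad` is better, but *any* fixed-quantile estimator is still
  inflated by at least $1/(1-f)$ under distant contamination, because
  contamination rescales the central probability mass uniformly;
* `trimmed` (the default) takes the median as center and, for the
  scale, the RMS of points within $1.96\,s$ of the center, iterated to
  convergence and divided by the truncated-normal consistency factor
  $\sqrt{1 - 2\cdot 1.96\,\varphi(1.96)/(2\Phi(1.96)-1)} \approx 0.871$.
  Points beyond the cutoff — which is where real effects live — are
  excluded rather than down-weighted, so the estimate tracks the null
  spread itself. Under a pure null all three options agree
  asymptotically; the test suite checks calibration of each on 10^5
  standard-normal draws.

**Known limitation.** The z-score treats all genes as sharing one null
spread. Count noise varies with expression, so lowly-expressed genes are
noisier than the population scale and contribute slightly more than
$\alpha$ false positives (about 5-6% at $\alpha = 0.05$ under the
simulation's conditions, rather than exactly 5%). Replicate-aware
count models (negative-binomial regression with per-gene dispersion)
fix this but are a different method family and deliberately out of
scope here; the FDR column gives a conservative handle if the excess
matters downstream.

**Transcriptional concordance.** As a companion diagnostic,
`transcription_concordance()` reports the squared Pearson correlation of
per-condition mean log10 mRNA RPKM — near 1 when the contrast between
conditions is translational rather than transcriptional.

# QC metrics

* **Length histogram**: exact tally plus the fraction inside the
  canonical 28-32 nt window of intact mammalian ribosome footprints
  (pass threshold 0.8 by default).
* **Frame distribution**: the P-site is the read 5' end + 12 nt (the
  standard offset for 28-32 nt mammalian footprints; configurable).
  Fractions are over reads whose P-site lands inside the CDS; the
  excluded fraction is reported. The frame-0 share is the periodicity
  score (pass threshold 0.6: a uniform 1/3 fails, a dominant frame
  passes); a period-3 discrete Fourier amplitude of the metagene profile
  is reported secondarily.
* **Metagene profile**: P-site counts by position relative to the CDS
  start over a configurable window (default -50..+150 nt).
* **Replicate r²**: squared Pearson correlation of
  $\log_{10}(\mathrm{RPKM} + \mathrm{pc})$ per sample pair, restricted
  to genes with RPKM > 0 in both samples. The pseudocount is
  per-sample (half that sample's smallest retained RPKM), which makes
  the statistic exactly invariant to rescaling a sample. The pass
  threshold is 0.9 per assay. The transform is a documented choice —
  plotted RPKM reproducibility is conventionally assessed on the log
  scale, and the report header records the transform used. With a
  single replicate the flag is "not evaluable" (NA), never a silent
  pass.

# 5' UTR features

* **TOP motif**: position 1 is `C` and the run of pyrimidines (C/T)
  starting at position 2 has length ≥ 4 (`min_tract`, recorded in
  output headers). This cap-C + pyrimidine-tract definition is the
  classic operational form of the 5' terminal oligopyrimidine element;
  the tract length is reported up to `max_check`.
* **uORFs**: ATG with an in-frame stop, the whole ORF (stop included)
  inside the 5' UTR, and at least `min_codons = 2` codons before the
  stop (the ATG counts). Distinct starts sharing a stop each count.
  CDS-overlapping ORFs are not counted: the fully-contained rule keeps
  the feature UTR-internal and unambiguous.
* **Group comparison**: UTR length and GC% by one-way ANOVA with
  all-pairs t comparisons, Bonferroni-corrected; motif presence by
  per-pair two-sided Fisher exact tests. Degenerate (zero-variance)
  features are flagged and skipped rather than tested.

# The synthetic-data generator

The generator emulates the study design the pipeline expects: two
conditions (`WT`, `2D`) with 3 replicates each, paired RPF and mRNA
libraries, 2000 genes, one transcript per gene.

* **Transcripts**: 5' UTR (normal lengths, mean 150 sd 50 nt, min 25),
  CDS of 100-500 codons starting ATG, no internal in-frame stop, stop
  codon included in the CDS; 3' UTR mean 300 sd 100 nt. Coordinates are
  transcript-space, 0-based, half-open.
* **Planted motifs are exact**: TOP-planted UTRs start `C` + 4-8
  pyrimidines + a purine; non-TOP UTRs start with a purine. uORF-planted
  UTRs contain the planted number of ORFs built from a junction-safe
  codon set, and every accidental `ATG` in UTR background is removed at
  assembly (replacing its `T` with `C`, which can never create a new
  occurrence). Scanners therefore recover planted flags with zero
  mismatches, which the tests assert.
* **Expression**: abundance is log-normal (meanlog 3, sdlog 1 — a
  realistic several-orders-of-magnitude dynamic range), identical across
  conditions, so the simulated contrast is purely translational.
  Baseline TE is log-normal (sdlog 0.25); 10% of genes have TE
  multiplied and 10% divided by exactly 2.5 in the second condition,
  with deterministic rounding of class counts.
* **Counts**: expected mRNA count ∝ abundance × length, expected RPF
  count ∝ abundance × TE × length, each column scaled to an expected
  depth of 10^6 reads; counts are negative-binomial with
  `variance = mu + phi * mu^2` (`phi = 0` degrades to Poisson for limit
  tests). The default `phi = 0.02` is calibrated so that replicate
  RPKM r² comfortably exceeds the 0.9 reproducibility bar at the
  default depth; the differential-testing validation runs use
  `phi = 0.05` as a deliberately harder noise setting.
* **Reads**: each footprint's length is drawn from
  {28: .15, 29: .35, 30: .25, 31: .15, 32: .10} (mode 29 nt), its
  frame from (0.85, 0.10, 0.05), and its P-site uniformly over CDS
  codons compatible with the frame, the +12 offset and the transcript
  bounds. Per-gene read tallies equal the count matrix exactly
  (conservation is asserted).
* **Determinism**: every output is a pure function of the configuration
  (including the seed); per-stage substreams are derived from the master
  seed so stages are independently reproducible. The caller's RNG state
  is never disturbed.

What the generator does **not** emulate: sequencing errors, rRNA/tRNA
contamination, multi-isoform genes, positional biases along the CDS
(ramps, pause sites), or library-specific GC bias. Passing recovery
tests on this generator therefore demonstrates correctness of the
statistical machinery under the stated model, not robustness to every
artefact of real libraries.

# Numerical and edge-case policy

* Strict parsing: non-numeric, negative or fractional counts, unknown
  assay tokens, CDS violations and duplicate ids are errors carrying
  the file and line; nothing is silently coerced.
* TE with zero mRNA mean is NA and routed to a discard log, never Inf.
* `zscore_test` refuses fewer than 3 finite ratios or zero spread
  ("degenerate ratio distribution").
* Ratio ties at the fold thresholds are `unchanged` by the strict
  inequalities.
* Empty metagene windows warn; an empty read set is a QC error.
* All TSV output is UTF-8/LF with `#` header comments carrying the
  package version and a config hash, so outputs from different
  configurations are distinguishable.

# Problem sizes used in validation

The packaged checks run the full study design (2000 genes, 3 replicates
per condition, depth 10^6) for the count-level analyses, ~10^5 reads for
read-level QC, and 1000-instance sweeps for the oracle-equivalence
checks of frame assignment, BH step-up, Fisher exact and the motif
scanners — sizes at which all Monte-Carlo bands in the tests are
comfortably stable on a laptop-class machine.

# Reproducing the analysis

```{r, eval = FALSE}
cfg <- validate_config(system.file("extdata", "default_config.yaml",
                                   package = "ribote"))
report <- run_pipeline(cfg, "ribote_out")
```

`scripts/acceptance.R` (repository root) regenerates the headline
quantities — replicate r², in-frame fraction, null calibration,
planted-effect sensitivity and direction accuracy, transcriptional
concordance and DTG counts — from scratch for any seed.
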