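---
title: "Segmenting the genome by chromatin compactness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the genome by chromatin compactness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromseg)
```

## The measurement and its sign convention

General chromatin sensitivity to DNase I (GCSDI) probes chromatin
compactness genome-wide: accessible ("open") chromatin is preferentially
nicked by the nuclease, so after amplification and hybridisation to a
tiling array, open sequences are depleted in the treated sample.  The
per-probe quantity this package works with is the log2 fold difference
between the untreated control and the DNase I-treated sample, averaged
over replicates on the linear intensity scale before the log is taken
(`compute_differential_signal()`).  Positive values mean open chromatin,
negative values closed chromatin.  Array-level normalisation is assumed to
have happened upstream; the package starts from per-probe intensities or
precomputed signals.

Unlike DNase I hypersensitive site (DHS) mapping, which finds narrow peaks
of extreme accessibility, the goal here is to partition the genome into
*contiguous domains* of open and closed chromatin, kilobases to hundreds
of kilobases long.

## The two-configuration model (2CM)

`segment_2cm()` tiles each chromosome with alternating open/closed
domains:

1. **Filter and cap.** The mean and SD of the signal are computed over all
   probes genome-wide; probes within one SD of the mean are discarded as
   uninformative, and each retained probe is capped to +1 (positive
   signal) or −1 (negative).  Capping uses the sign of the raw signal, not
   of the deviation from the mean, because the open/closed semantics live
   on the raw log2 scale and the mean of a differential signal is close
   to 0.  The filter statistics are genome-wide rather than
   per-chromosome: there is one biological signal scale, and
   per-chromosome statistics would shift domain calls with no benefit.
2. **Transition statistic.** For each retained probe, *d* is the absolute
   difference between the mean capped values of the *n* retained probes up
   to and including it and the *n* retained probes after it.  Flanks are
   counted in retained-probe units — discarded probes carry no value to
   average.  *d* ranges from 0 (homogeneous neighbourhood) to 2 (perfect
   −1/+1 contrast).  Probes within *n* of a chromosome end get no
   statistic.
3. **Permutation calibration.** Capped values are shuffled uniformly
   across retained probe slots genome-wide (per-chromosome shuffling is
   available as an option) and the number of probes with *d* at or above
   the cutoff is compared between the real and `n_permutations` shuffled
   series.  A setting (*n*, *d*) is admissible when the empirical p —
   the fraction of permutations reaching the real count — is below
   `alpha`; among admissible settings the one maximising the ratio of real
   to mean permuted counts ("most discriminating") is selected.  The
   defaults, *n* = 48 probes, *d* = 0.8, 100 permutations, alpha = 0.05,
   are the model's standard operating point.
4. **Assembly.** Consecutive supra-cutoff probes are collapsed to the
   probe of maximal *d* (leftmost on ties, for reproducibility); segment
   boundaries fall midway between the transition probe and the next
   retained probe; each segment is called open when the mean raw signal of
   the probes inside is positive, closed otherwise; and adjacent same-state
   segments are merged.  The result partitions the probe-covered span of
   every chromosome.

How segment state is assigned between transitions is a genuinely open
design point; the bp-weighted mean-raw-signal sign used here is the
simplest reading consistent with the rest of the model.  *d* is computed
on capped values; a raw-signal variant would differ only in the scale of
*d*.

Two degenerate cases are worth knowing about.  A series whose values are
all identical has SD 0 and is rejected.  Less obviously, a *noiseless
balanced two-valued* series (e.g. exact ±1 blocks) is also degenerate:
every deviation sits at about one SD, so the filter discards everything.
Real signals — and the synthetic generator's — carry probe noise, which is
what gives the filter its intended tail behaviour.

## The three-configuration model (3CM)

The 2CM resolves large domains well but cannot leave anything
uncommitted, which blurs gene-dense regions with small genes.
`segment_3cm()` trades coverage for selectivity by allowing a third,
*neutral*, state:

1. **Peak calling.** A two-state Gaussian-emission hidden Markov model
   (background vs peak) is fitted by expectation–maximisation and applied
   twice: to the signal for positive (open) peaks and to its negation for
   negative (closed) peaks, mirroring the one-sign-per-run semantics of
   classic array peak callers.  A peak is a maximal run of probes whose
   peak-state posterior (forward–backward) exceeds 0.5; spans extend to
   inter-probe midpoints so that bp accounting is well defined.
   Initialisation is deterministic and scale-aware: background mean 0,
   peak mean the mean of the top decile of signals, both variances from
   the global SD, self-transition 0.99.  The forward–backward recursions
   are implemented in C++; EM stops when the relative log-likelihood
   change falls below `tol` (default 1e-4) and errors with its trace if
   `max_iter` is exhausted.  A three-state single-pass variant was
   considered and rejected: the two-pass design keeps the open and closed
   calls symmetric and each EM problem strictly two-state.
2. **FDR filtering.** The empirical false discovery rate at a peak-area
   threshold *t* is the mean number of peaks of area ≥ *t* called on
   value-shuffled signals (reusing the fitted HMM parameters) divided by
   the real count; peaks above the smallest *t* with FDR ≤ 0.1 are kept.
   The filter statistic is the peak *area* (absolute summed signal):
   a shuffled genome produces occasional short runs whose per-probe mean
   matches a real peak's, so a mean-based threshold has no power, while
   area separates the two regimes cleanly.  Shuffles reuse the fitted
   parameters rather than refitting: EM on a structureless series is
   unstable, and the fitted emission model is precisely the null being
   probed.
3. **Consolidation.** The gap threshold is the 95th percentile of pooled
   edge-to-edge inter-peak distances (linear interpolation between order
   statistics, quantile type 7 — pinned for reproducibility; 16721 bp was
   the corresponding value in the fly genome and is available as the
   `gap_threshold_fly` override).  Adjacent same-sign peaks closer than
   the threshold merge, together with the gap, into one open or closed
   domain; every other gap — opposite signs, or too far apart — becomes a
   neutral domain, as do the spans outside the outermost peaks.
   Consolidation is idempotent and monotone: raising the threshold never
   creates neutral domains.

## Overlap statistics

`cumulative_overlap()` measures, for every domain state and every
annotation label (chromatin states, lamina-associated domains,
histone-modification enriched/depleted regions), the total bp of
intersection between the merged unions of the two sides, genome-wide, for
chromosome subsets, or under arbitrary BED masks (e.g. heterochromatic
compartments).  Merging first means duplicated intervals in downloaded
tracks cannot double-count.  Both normalisations are provided — the
fraction of each state's bp inside each label
(`fraction_of_domains_in_track()`) and each label's contribution
(`contribution_to_state()`) — because published percentage figures are
ambiguous about which denominator excludes track-uncovered bp.
Coordinates are 0-based half-open BED throughout; inputs must already
share a genome build (no liftover is attempted).

## Expression analyses

Activity is classified from RPKM (`compute_rpkm()`: count / (length/1000)
/ (library/10^6)): a gene is *active* iff its RPKM is at least 1 in all
five samples.  Structural elements are derived from gene models
(`gene_elements()`); the promoter is the 500 bp upstream of the TSS,
strand-aware — the width is a required convention rather than an
established constant, so it is a visible, configurable argument.  Gene
size categories are <1 kb, 1–4 kb (inclusive), >4 kb; intron categories
≤80 bp, 81–200 bp, 201 bp–1 kb, 1–10 kb, >10 kb.  The printed forms of
the first two intron categories ("81 bp or less", "81–200 bp") both
contain 81; the package resolves the tie downward (≤80) so the categories
partition the integers while preserving the cut points.

`intron_profile()` divides introns into non-overlapping 100 bp windows
pooled by distance from the 5′ and 3′ intron ends and reports cumulative
open/closed bp, fractions, and the open:closed ratio per offset — the
positional profile that shows closed chromatin concentrating in the cores
of long introns.  Window offsets are genome-oriented; pooled over both
ends this matches transcript orientation on average.

`cluster_chromatin_class()` labels a gene cluster *open* or *closed* only
when its span lies entirely within domains of that state — under the 3CM
any neutral bp makes it *mixed*, reading "uninterrupted domain" literally
— and `compare_cluster_tau()` contrasts the tissue-specificity index
tau = Σ(1 − x_i/x_max)/(N − 1) between open- and closed-cluster genes
with a two-sided Welch t-test and Mann–Whitney U test.

## The synthetic genome generator

`simulate_probe_signals()` and companions generate the fixture every test
builds on: per chromosome, domains with exponential lengths (truncated at
the chromosome end), i.i.d. states by weight with adjacent same-state
domains merged (so boundary-recovery is well defined), point probes at
fixed spacing, and Gaussian probe noise.  The defaults are the study
conditions used throughout the package's own validation: a 5 Mb
chromosome tiled at 35 bp, open/closed weights 0.5/0.5, exponential mean
15 kb, signal means ±0.8, noise SD 0.8 (signal-to-noise ratio 1).  With
two equally weighted states the merge step roughly doubles the realized
mean domain length relative to the configured exponential mean; the
configured mean is kept as the interface because it is the natural
per-draw parameter.

`simulate_annotations()` plants a LAD track covering a configurable
fraction of closed-truth bp (plus a leak fraction of open bp), a
correlated chromatin-state track, and paired enriched/depleted
modification tracks.  `simulate_genes_and_expression()` places
non-overlapping genes wholly inside truth domains (so activity/chromatin
coupling can be made exact), with five expression samples, and plants
gene clusters with a configurable tau difference between closed- and
open-cluster genes.  All generator randomness flows through one seed,
with fixed per-stage offsets so stages are independently reproducible.

What the generator does *not* emulate: probe-sequence effects and
cross-hybridisation, amplification bias, replicate-level variance
structure, non-Gaussian noise tails, and the irregular probe spacing of a
real array.  Passing recovery tests on this fixture therefore shows the
algorithms are correct and well calibrated under their own model
assumptions, not that the biological conclusions transfer to any
particular real dataset.

## Problem sizes and numerical choices

The package's validation suite runs the full study-scale genome (5 Mb,
~143,000 probes) for both models, 100-seed null-calibration and tau-power
Monte Carlos, 100 randomised per-base oracle comparisons for the overlap
engine, and 50 brute-force equivalence checks for the sliding window;
smaller planted genomes (0.3–2 Mb) back the per-module tests.  Ties in
run collapse break leftmost; the gap percentile is quantile type 7; HMM
emission SDs are floored at 1e-3 of the global SD to keep EM away from
singular solutions; and a retained probe with signal exactly 0 caps
to −1 (it can only arise when the genome-wide mean exceeds one SD in
magnitude).

## Limitations

The 2CM forces every base into open or closed even where evidence is
thin; the 3CM's neutral state is the remedy but costs coverage.  The
permutation null treats probes as exchangeable genome-wide and ignores
autocorrelated noise, so its p-values are calibrated against an
i.i.d. null only.  The FDR filter's shuffles reuse the fitted HMM rather
than refitting, a deliberate conservative choice.  Multi-sample joint
segmentation and replicate-level variance modelling are out of scope.
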