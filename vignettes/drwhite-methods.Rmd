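---
title: "Models and methods behind drwhite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind drwhite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drwhite)
```

# The assay and what this package computes

The DR-*white* reporter places an I-SceI recognition site inside a broken
*white* gene, with an intact i*white* donor downstream. After I-SceI cuts,
the repair pathway leaves a sequence signature at the junction:

* **HR** (homologous recombination with the donor) restores the wild-type
  *white* sequence — read out as loss of the I-SceI site, a 23-nt deletion
  relative to the uncut reporter;
* **NHEJ** (non-homologous end joining) leaves small indels, mostly 1-bp
  deletions;
* **MMEJ** (microhomology-mediated end joining) leaves deletions whose two
  boundaries share ≥ 2 identical bases.

`drwhite` implements the full computational workflow around this readout:
a synthetic-data generator with known truth, a junction caller, a pathway
classifier, a trace-decomposition quantifier, focus-movement statistics
for live-imaging tracks, and ΔΔCt ChIP-qPCR quantification. Everything
stochastic is a pure function of its parameters and an explicit seed.

# Coordinates and the reference construct

All coordinates are 0-based, half-open; the cut site is an inter-base
index. `build_reference()` assembles

```
left_primer + arm + left_flank + right_flank + arm + revcomp(right_primer)
```

with the flank and primer sequences of the assay
(`TTGAGCTGTAGGGATAA` / `CAGGGTAATAGCTCTTTG`;
`GACTGGACTCATTTACCGCCC` / `TTGGTAGGACACTGGGCAC`). The two flanks meet at
the cut and jointly compose the 18-bp I-SceI recognition site.

The 23-nt HR-signature window is placed as `[cut − 9, cut + 14)`. Only its
length and the requirement that it contain the cut are dictated by the
assay; this particular placement is the one that keeps the complete 18-nt
recognition site inside the deleted window, which is the biologically
meaningful property (HR removes the cut site). The classifier matches HR
by shift-equivalence against this interval, so the placement choice is
self-consistent end to end.

Cleavage chemistry (the staggered 4-nt overhang) is deliberately not
modelled: the package simulates repair *products*, not cutting. Reads are
emitted single-end over the whole repaired amplicon, emulating merged
paired-end data; merging itself is out of scope.

# Junction calling

Reads are anchored on two 15-mers taken from the reference **outside** the
HR window (12 bp clear of each edge). This matters: the assay's printed
flank sequences compose the I-SceI site itself, which HR deletes —
anchoring on them would make every HR product unalignable. One mismatch is
tolerated per anchor; the rightmost left-anchor and leftmost right-anchor
occurrences are used.

The inter-anchor segment is compared with the reference segment through
its longest common prefix `p` and suffix `s`:

* length deficit with `p + s ≥ n_read` → pure **deletion**;
* length excess with `p + s ≥ n_ref` → pure **insertion**;
* anything else → **deletion-with-insert** (the minimal del + ins pair).

Deletions are left-aligned over the whole reference and reported with
their **microhomology length** `m`: the largest `m` with
`ref[s, s+m) == ref[e, e+m)` at the left-aligned placement `[s, e)`. This
equals the number of alternative placements producing the identical
repaired sequence (`m + 1` placements in total) — the standard junction
ambiguity convention for MMEJ, verified in the test suite against a
brute-force enumeration of all placements. Note that in periodic sequence
the ambiguity run can be longer than a naive flank comparison at the
original placement suggests; the placement-count definition is the one
used consistently.

Distance to the cut uses the **whole shift-equivalence region** (union of
all equivalent placements), not the left-aligned point, so a shiftable
junction near the cut is retained under any alignment convention. This is
the nearest-placement reading of the assay's "distance from expected cut
site" filter; the alternative (left-aligned-point) reading is not used.

# Classification

Defaults (`classifier_config()`), all taken from the assay's analysis
settings: retention within 10 bp of the cut; HR = 23-nt signature; NHEJ
indels ≤ 25 bp; MMEJ microhomology ≥ 2 bp. Precedence:

1. a pure 23-bp deletion whose equivalence class contains the HR interval
   is **HR**, even if its junction shows ≥ 2 bp microhomology — the −23
   product is the HR signature unconditionally. (A spontaneous NHEJ
   deletion identical to the HR product is indistinguishable by this
   assay; it is counted as HR, the assay's known ambiguity.)
2. any other pure deletion with `m ≥ 2` is **MMEJ**;
3. remaining indels ≤ 25 bp — insertions, deletions, and
   deletions-with-insert regardless of microhomology — are **NHEJ**;
4. larger indels are tallied as `other`, not silently dropped, so counts
   always reconcile: `n_hr + n_nhej + n_mmej + n_unmodified + n_other =
   n_retained`.

Summary percentages use the denominators the assay reports: repaired
reads for HR/NHEJ/MMEJ shares, pure-deletion products for the MMEJ-of-
deletions share.

# The synthetic-data generator

The generator's defaults are the study conditions, not free dials:

* mixture `hr = 0.20, nhej = 0.75, mmej = 0.05` (HR and NHEJ inside the
  reported 17–26% / 74–83% bands; MMEJ sized so that 3–9% of deletion
  products carry microhomology);
* within NHEJ, deletion-containing products at 99.3% (pure deletions
  99.1% + deletions-with-insert 0.2%), matching the reported 99.0–99.4%
  range; deletion sizes geometric with `P(1 bp) = 0.6` truncated at 25 bp
  (the study reports only "majority 1-bp deletions", so the tail shape is
  a modelling choice); insertions 1–3 bp;
* MMEJ deletions are rejection-sampled against the concrete reference
  until their left-aligned junction shows `m ≥ 2`; NHEJ deletions until
  `m ≤ 1`;
* sequencing noise: independent per-base substitutions (default 0),
  constant Q30 qualities.

What the generator does **not** emulate: PCR amplification bias, chimeras,
quality-dependent errors, cell-cycle structure, cutting kinetics. Passing
tests therefore demonstrate correctness of the analysis pipeline on reads
whose only distortions are the modelled ones — not robustness to every
artefact of real amplicon sequencing.

## Focus tracks

Each simulated track starts `inside` a polycomb body at appearance and is
sampled every 5 min (the imaging interval was 5–10 min). The state at the
10-min timepoint is drawn from the preset's categorical distribution —
`mu2_isceI_control` 60% outside, `atrip_control` 77%, `atrip_dUtx` 53%,
matching the reported percentages; outside-destined foci move at 5 min
with probability 1/2. Location then persists, and resolution follows a
geometric per-interval hazard calibrated so the median resolution time is
55 min (inside the reported 30–80 min range):
`hazard = 1 − 0.5^(interval / (median − 10))`.

The default observation horizon is 45 min, matching how individual tracks
were followed; at that horizon fewer than half the foci resolve, so
`median_resolution_time()` flags itself undefined — kinetics analyses in
the tests therefore simulate with a 120–150 min horizon, which is the
regime the resolution-time observations come from. The `pct_outside`
denominator includes not-detectable/resolved foci; the presets keep the
not-detectable fraction at 0, so the reported percentages are reproduced
without taking a side on the denominator ambiguity, and
`pct_outside_of_located` is also reported.

## qPCR plates and ROI intensities

`simulate_qpcr()` writes `Ct = base_ct − log2(quantity) + N(0, σ_Ct)` per
measurement, with IP rows scaled by the design's IP/input ratio. The ΔΔCt
chain (`2^(Ct_input − Ct_IP)`, target over control locus) is invariant to
uniform Ct shifts and to the unknown input dilution factor — only ratios
of ratios are reported, so no dilution correction is applied.

`simulate_roi_intensities()` draws lognormal domain intensities
(median 100, arbitrary units) and sets the DSB-proximal mean to
`ratio × domain × noise` with mean-one lognormal noise (σ_log = 0.10), so
the preset ratio (0.90 for `damaged_control`, i.e. the ~10% break-proximal
H3K27me3 drop; 1.00 under dUtx depletion) is exactly the expected per-cell
ratio.

# Trace decomposition

The aggregate trace downstream of the cut is modelled as a non-negative
mixture of indel-shifted reference indicator profiles over offsets
−25…+25 (the assay quantified indels up to 25 bp; the ±25 decomposition
window is an assumption, as the original window is not stated). Inserted
bases are unknown a priori and are modelled as ambiguity-averaged
channels (0.25 each). The solver is Lawson–Hanson non-negative least
squares; weights below 0.1% of the total are pruned and the rest
renormalized, and R² comes from the unpruned residual. No per-component
significance machinery is attempted — it is not described for the assay
and nothing downstream depends on it. Exact recovery of noise-free
mixtures to 1e-6 and agreement with an independent grid-search oracle are
enforced in the tests. A degenerate all-zero trace is an error rather
than a zero spectrum.

# Statistics

* **Ratio paired t-test**: paired t-test on natural-log per-replicate
  ratios — the standard reading of the assay's "ratio two-sided paired
  t-test"; symmetric under condition swap and reciprocation. Welch's
  t-test on logs is the unpaired variant.
* **Chi-square**: Pearson, 2 × k, no continuity correction; zero-margin
  categories are pooled with a warning.
* **Viability**: observed test/reference count ratio over the expected
  Mendelian ratio, in percent.
* One-way ANOVA + Tukey is deliberately not re-implemented (standard
  machinery, `aov`/`TukeyHSD`, nothing assay-specific).

A note on detection power: with σ_Ct = 0.2 and 13 paired replicates, a
28% enrichment loss gives an analytic noncentral-t power of 0.79 at
α = 0.05 — each paired log-ratio accumulates noise from 8 independent Ct
measurements, so the per-pair SD is `sqrt(8) × 0.2 × ln 2 ≈ 0.39`. The
test suite checks the simulated rejection rate against this analytic
value rather than against a round-number threshold.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use n = 2000–10000 reads or
events for frequency recovery (binomial 4-SD bands), 2000 tracks per
preset, 300 cells for ROI statistics, 200 simulation repetitions for
power estimates, and 1000 random cases for the microhomology oracle —
sizes at which the sampling bands are a few-fold tighter than the effects
being recovered, while a full run stays in the minutes range. Ties in
deletion placement are always broken by left-alignment; equality
comparisons on weights and percentages use explicit tolerances (1e-6 for
exact NNLS recovery, 4 SD for stochastic recovery).

# Known limitations

* The caller models a single contiguous indel between anchors; multiple
  separated mutations collapse into one deletion-with-insert (or fail
  anchoring). This mirrors what the junction assay can interpret.
* Anchors require `arm_length ≥ 30`; deletions so large that they invade
  the anchors become unalignable and are counted, not called.
* The trace module consumes simulated aggregate profiles, not real AB1
  chromatograms.
* Focus tracking, nucleus segmentation and ROI drawing are manual steps
  in the underlying experiments; this package starts from their tabular
  outputs.
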