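# drwhite

Simulation and analysis of **DR-*white* single double-strand-break (DSB)
reporter assays** in *Drosophila* facultative heterochromatin.

The DR-*white* reporter carries a *white* gene interrupted by an I-SceI
cut site plus a downstream i*white* homology donor. After a single DSB is
induced, the repair pathway is inferred from the junction sequence:

* **HR** — gene conversion with the donor removes the I-SceI site, seen
  as a 23-nt deletion relative to the uncut reporter;
* **NHEJ** — small indels (≤ 25 bp) at the cut, overwhelmingly 1-bp
  deletions;
* **MMEJ** — deletions whose two boundaries share a microhomology of
  ≥ 2 bp (the junction is ambiguous over *m* + 1 equivalent placements).

`drwhite` provides, for people analysing such reporters or benchmarking
junction-calling pipelines:

* a **synthetic-data generator** (reference amplicon, repair events with
  truth labels, FASTQ reads, aggregate trace profiles, focus-track
  tables, qPCR plates, ROI intensity tables);
* a **junction caller** — anchor-based, left-aligned indels,
  microhomology = placement-ambiguity length, distance to the cut over
  the whole shift-equivalence region;
* a **pathway classifier** with the assay's filters (≤ 10 bp from the
  cut, HR = −23 signature, NHEJ ≤ 25 bp, MMEJ microhomology ≥ 2 bp) and
  summary tables;
* **trace decomposition** — non-negative least squares over indel-shifted
  reference profiles (offsets −25…+25), reporting the −23 (HR) component
  and total editing;
* **focus-movement statistics** — fraction of DSB foci outside polycomb
  bodies at a query lag, resolution kinetics, accumulation, chi-square
  condition comparisons;
* **ΔΔCt quantification** — ChIP-qPCR enrichment normalized to an
  internal-control locus, spike-in antibody specificity, ratio paired
  t-tests, RT-qPCR knockdown levels, relative viability.

All coordinates are 0-based half-open with the cut as an inter-base
index; every stochastic function demands an explicit seed and is fully
reproducible.

## Worked example

```r
library(drwhite)

ref <- build_reference(arm_length = 50, seed = 1)
ref
#> DR-white reference construct
#>   amplicon length: 175 nt
#>   cut index (0-based, inter-base): 88
#>   HR deletion interval: [79, 102)

ev    <- sample_events(default_event_mixture(), ref, 5000, seed = 10)
sim   <- events_to_reads(ev, ref, substitution_rate = 0, seed = 11)
calls <- call_junctions(sim$reads, ref)
summarize_pathways(calls, classifier_config(), ref)
#> Repair pathway summary
#>   reads: 5000 total, 5000 retained, 0 unalignable, 0 off-target
#>   unmodified 0 | HR 1041 | NHEJ 3726 | MMEJ 233 | other 0
#>   % repaired: 100.0; of repaired: HR 20.8%, NHEJ 74.5%, MMEJ 4.7%
#>   % of pure deletions with >=2 bp microhomology: 5.9
```

The classifier recovers the generating mixture (20% HR, 75% NHEJ, 5%
MMEJ) within binomial sampling error; the HR and NHEJ shares sit inside
the 17–26% / 74–83% bands typical for this reporter, and 5.9% of pure
deletion products carry ≥ 2 bp microhomology (reported range 3–9%).

Focus movement and trace decomposition work the same way:

```r
tracks <- simulate_focus_tracks("mu2_isceI_control", 2000, seed = 101)
fraction_outside_at(tracks, lag = 10)$pct_outside
#> [1] 61.1        # preset: 60% of foci leave the polycomb body by 10 min

lib <- build_shift_library(ref, 25)
d <- decompose_trace(simulate_trace(c("0" = 0.45, "-23" = 0.11,
                                      "-1" = 0.40, "-2" = 0.04), ref), lib)
spectrum_report(d)
#> $pct_hr           [1] 20    # -23 component, % of total editing
#> $pct_nhej         [1] 80
#> $pct_total_edited [1] 55
```

See `vignettes/drwhite-methods.Rmd` for the models, default parameters
and their rationale, and known limitations.

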