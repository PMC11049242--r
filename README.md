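# gliaquant

Quantification pipeline for microglia morphology and seizure readouts in
larval zebrafish epilepsy models (e.g. `scn1lab` knockdown models of
Dravet syndrome). Microglia react to neuronal hyperactivity by retracting
their processes and rounding up — from "branched" surveillance cells to
"amoeboid" activated cells — while the brain produces more seizure-like
events and the larvae swim more. `gliaquant` implements the complete
measurement chain behind those observations, for anyone who needs the
same readouts without proprietary imaging software:

* **3D morphometrics** of segmented microglia: volume `V`, surface area
  `A`, Wadell sphericity `S = π^(1/3)·(6V)^(2/3)/A`, primary process
  count `NP`, total/mean process length `TL` (µm), ramification index
  `RI = terminals/NP`, and Sholl profiles — from a TEASAR-style
  shortest-path-tree skeleton traced on the voxel graph.
* **Activation-state classification**: a cell is *branched* with ≥3 of
  {`S < 0.5`, `NP > 7`, `TL > 140 µm`, `A > 2400 µm²`}, *amoeboid* with
  ≥3 of {`S > 0.7`, `NP < 3`, `TL < 60 µm`, `A < 1500 µm²`}, otherwise
  *transitional* (strict inequalities).
* **Cell-body motility**: mutual-nearest-neighbour centroid tracking,
  displacement / path length / mean speed per track.
* **Calcium events**: ΔF/F₀ = (F − F̄)/F̄ with running-percentile drift
  correction; an event is a maximal run of frames with ΔF/F₀ > 0.04.
* **LFP events**: zero-phase Butterworth 0.1 Hz–1 kHz band-pass; an event
  is a downward deflection below −0.3 mV lasting more than 100 ms.
* **Locomotor scoring**: total distance and time in
  immobile/low/medium/high speed states (4 and 8 mm/s thresholds,
  one-minute integration bins).
* **Statistics**: Shapiro-guided t/Welch/Mann–Whitney two-group
  comparisons and two-way ANOVA + Tukey for the factorial design.
* **Synthetic generators** for every input kind — branched/amoeboid 3D
  cells, calcium and LFP traces with injected events, larva trajectories
  — with known ground truth, so the whole chain is testable without any
  raw recordings.

## Worked example

Generate a synthetic microglia population with 30% amoeboid / 60%
transitional / 10% branched cells, measure every cell in 3D, and classify:

```r
library(gliaquant)

mix <- c(amoeboid = 0.3, transitional = 0.6, branched = 0.1)
pop <- gen_population(mix, n = 100, seed = 11)
tab <- morphology_table(pop)     # one row per cell: S, NP, TL, A, V, RI
cls <- classify_population(tab)
round(cls$proportions, 1)
#>     branched     amoeboid transitional
#>          3.0         21.0         76.0
```

(The seeded multinomial drew 3/21/76 — every cell was classified into its
intended class.) A single cell:

```r
set.seed(0)  # for the truth's process lengths
g <- gen_microglia(shape_truth(soma_radius = 6, runif(8, 18, 28)), seed = 7)
measure_cell(g$volume)
#> cell_morphology: S=0.360 NP=8 TL=199.1 um mean=24.9 um
#>   A=2774 um^2 V=2970 um^3 RI=1.00
```

`S = 0.36` (far from a sphere), 8 primary processes of ~25 µm — a typical
branched cell; its generator truth was 8 processes totalling 194.6 µm
(TL recovered within 2.3%).
Detect seizure-like events in a synthetic calcium trace:

```r
truth <- calcium_truth(event_onsets = c(100, 300, 500),
                       event_peak_dff = c(0.08, 0.10, 0.09),
                       noise_sigma = 0.5, drift_slope = 0.01)
tr <- gen_calcium_trace(600, truth, seed = 3)
detect_events(correct_drift(tr), threshold = 0.04)$onset_frame
#> [1] 100 300 500
```

The full synthetic experiment (two genotypes × microglia present/depleted,
every module, group statistics) runs with one call and writes CSV/JSON
tables:

```r
res <- run_synthetic_experiment(seed = 1, out_dir = "out")
res$comparisons$amoeboid_fraction$p_value   # wt vs kd, two-proportion test
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/gliaquant.R`
(`Rscript gliaquant.R run-all --seed 1 --out-dir out`, plus `calcium`,
`lfp`, `swim`, `classify` subcommands for CSV inputs).

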