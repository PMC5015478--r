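# mmnrubberband

Simulation and analysis of **mismatch negativity (MMN)** difference waves
from passive auditory oddball paradigms, built around one question about the
temporal control of the response: *does the MMN return to baseline by
passive decay, or is it actively pulled back within a fixed time window?*

If the return were an amplitude-independent decay, the descending slope of
the difference wave would be unrelated to its peak amplitude. If instead the
brain enforces a fixed return window T, the average descending slope is
`|amplitude| / T` — proportional to the amplitude. Across a cohort this
"rubberband" mechanism predicts a positive Spearman correlation between
|amplitude| and downslope, and none between |amplitude| and upslope.

The package provides, for R users working with ERP-style data or simulation
studies of ERP methodology:

* a **synthetic cohort generator**: constrained oddball stimulus sequences
  (exact deviant counts, minimum deviant separation, standard lead-in),
  subject-level MMN ground truth with a switchable coupling mode
  (`rubberband`: fixed 120 ms return window; `null`: descent rate drawn
  independently of amplitude), and trial-level epoched EEG
  (-400..798 ms at 500 Hz, 13-electrode fronto-central/temporal montage,
  four ISI conditions);
* the **processing chain**: per-epoch baseline correction (-200..0 ms),
  condition averaging, deviant-minus-standard subtraction, zero-phase
  4th-order Butterworth low-pass at 25 Hz (implemented in-package), and
  region-of-interest averaging;
* **nine-parameter extraction** per difference wave — amplitude, ampavg
  (±20 ms mean around the peak), onset, offset, peak latency, duration,
  area, upslope, downslope — guarded by a baseline-derived threshold
  `Th = mean(baseline) - SD(baseline)` that discards "fake MMNs" never
  dipping below `Th`;
* the **correlation stage**: Spearman correlations across subjects for all
  36 parameter pairs per electrode and ISI, an electrode-count summary
  (p < 0.1 combined / p < 0.05 strict), ROI amplitude-slope tables with
  significance stars, and a Lilliefors-type normality log;
* a **pipeline/CLI layer** (`run_pipeline()`, `exec/mmn-rubberband`) with
  JSON/YAML configs, deterministic seeding and CSV/markdown outputs.

## Worked example

```r
library(mmnrubberband)
cfg <- mmn_config(seed = 1, mode = "rubberband")   # 22 subjects, 13 electrodes, 4 ISIs
res <- run_pipeline(cfg, out_dir = "mmn_out")      # ~1.5 min (trial-level synthesis)
res$counts[pair == "amplitude-downslope"]
```

```
                  pair isi_s count_combined count_strict count_pos_combined ...
1: amplitude-downslope   1.5             13           13                 13
2: amplitude-downslope   3.0             10           10                 10
3: amplitude-downslope   4.5             10            8                 10
4: amplitude-downslope   6.0             10            8                 10
```

10-13 of the 13 electrodes show (marginally) significant positive
amplitude-downslope correlations in every ISI condition — the rubberband
signature (the corresponding real-data benchmark is "more than 8 of 13 on
average"). The frontal ROI shows the asymmetry directly:

```r
res$roi_table[region == "frontal"]
```

```
    region                pair isi_s    rho        p n_used stars
1: frontal   amplitude-upslope   1.5 0.2750 2.16e-01     22
2: frontal amplitude-downslope   1.5 0.9605 1.43e-12     22    **
3: frontal   amplitude-upslope   3.0 0.2332 2.96e-01     22
4: frontal amplitude-downslope   3.0 0.8250 2.32e-06     22    **
5: frontal   amplitude-upslope   4.5 0.3484 1.12e-01     22
6: frontal amplitude-downslope   4.5 0.8069 5.71e-06     22    **
7: frontal   amplitude-upslope   6.0 0.3156 1.52e-01     22
8: frontal amplitude-downslope   6.0 0.7572 4.51e-05     22    **
```

Downslope correlates strongly with amplitude at every ISI (rho 0.76-0.96,
all p < 0.01); upslope never reaches significance — because the generator
draws rise rates independently of amplitude. `out_dir` receives
`parameters.csv`, `correlations.csv`, `table2_counts.csv`, `table3_roi.csv`,
`ground_truth.csv`, `report.md` and `config.json`.

The same run from the shell:

```sh
exec/mmn-rubberband all --out mmn_out --seed 1
exec/mmn-rubberband all --out mmn_null --seed 1 --mode null   # coupling absent
```

## Scope and caveats

The generator emulates the oddball *design* and the coupling *mechanism*,
not real EEG (no volume conduction, artifacts, or subject-specific component
shapes). Two measurement effects matter when interpreting output — the
25 Hz filter shifts asymmetric peaks by a few ms and the max-derivative
slope estimator is length-biased, which couples measured slopes weakly to
amplitude even in null mode. See the methods vignette
(`vignettes/mmn-parameterization.Rmd`) for the full analysis.
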