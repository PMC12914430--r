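# prmflow

Design, schedule, and validate highly multiplex targeted **parallel
reaction monitoring (PRM)** assays from DIA chromatogram libraries — with a
synthetic-data generator that makes the whole workflow testable without any
instrument files.

Modern linear ion traps can monitor thousands of peptide precursors in a
single LC gradient, but getting there requires a chain of decisions that
are usually buried in vendor tools: which library precursors have peaks
good enough to target, how wide the acquisition windows can be before the
cycle-time budget is exceeded, how to keep windows on target when
chromatography drifts, and which targets survive matrix-matched
calibration. `prmflow` implements that chain end to end:

* **Library bookkeeping** — tryptic digestion (`digest`), monoisotopic
  precursor m/z (`precursor_mz`), cross-species shared-peptide removal
  (`shared_peptides`), and parsimony-based unique-peptide filtering
  (`filter_unique_peptides`), with a documented delimited table format for
  chromatogram libraries (`read_library` / `write_library`).
* **Refinement** — peak detection on summed transition traces
  (`detect_peak`), coelution/interference scoring (`transition_quality`),
  and threshold filtering (`filter_precursors`): a precursor is accepted
  when `area >= min_area`, `min_width <= width <= max_width`, and at least
  `min_clean_transitions` transitions are interference-free.
* **Scheduling** — the cycle-time budget `cycle = width / points_per_peak`
  (e.g. 12.9 s / 6 = 2.15 s), a per-scan duration model
  `span/scan_rate + injection + overhead`, concurrency capacity
  `floor(cycle / scan)`, window optimization with a minimum-width floor
  (`optimize_windows`), and greedy multi-injection splitting
  (`split_injections`).
* **Adaptive real-time alignment (emulated)** — a wide-window DIA run is
  compressed into a normalized time × m/z reference map
  (`compress_reference`); during a simulated acquisition the recent scans
  are compared against it to estimate the retention-time shift
  (`estimate_shift`), a monotone warp is maintained (`fit_warp`), and
  target windows are re-mapped on the fly (`simulate_acquisition`).
* **Figures of merit** — matrix-matched calibration curves are fit with a
  two-segment (flat noise + linear) changepoint model; LOD is the
  changepoint fraction and LOQ the smallest fraction whose bootstrap CV of
  the fitted prediction stays under a ceiling (`fit_fom`), with greedy
  transition-subset optimization (`optimize_transitions`), replicate CV
  tables and log2 ratio accuracy.
* **Sample statistics** — TIC normalization, Welch tests on log2 areas
  with Benjamini–Hochberg control (`differential_abundance`), and allele
  frequency summaries (`allele_frequency`).

## Worked example

```r
library(prmflow)

sim <- simulate_library(100, gradient_length = 30,
                        noise = noise_model(multiplicative_cv = 0.05,
                                            interference_rate = 0.1,
                                            seed = 7))
res  <- filter_precursors(sim$library, refine_config())
plan <- optimize_windows(res$accepted, schedule_config())
plan
#> schedule_plan: 91 targets, 1 injection(s), cycle 2.15 s, capacity 78

compute_cycle_time(12.9, 6)
#> [1] 2.15
allele_frequency(4, 19)
#> [1] 10.5
```

`91 targets` is the number of simulated precursors passing the default
area/width/interference thresholds; `cycle 2.15 s` is the acquisition
period needed for six points across a 12.9 s peak, and `capacity 78` the
number of 27.4 ms targeted scans that fit into one such cycle.

The same pipeline runs from a config file:

```sh
Rscript inst/cli/prmflow.R all --config inst/extdata/example_config.yaml \
  --seed 7 --out out/
```

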