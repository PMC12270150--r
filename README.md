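# efastress

Analysis of plate-based extracellular flux stress tests — the assays that
measure oxygen consumption rates (OCR) and extracellular acidification rates
(ECAR) in live cells across injections of metabolic drugs — with first-class
support for quantifying the **ATP synthase (complex V) inhibition confound**
in the mitochondrial stress test.

## The problem

The standard mitochondrial stress test inhibits ATP synthase with oligomycin
before uncoupling with FCCP. In intact cells that inhibition depresses the
measured *maximal respiration* (MR) and hence *spare respiratory capacity*
(SRC). Worse, test substances that shift cells toward glycolysis can change
the size of that bias, so a single-arm stress test can report substance
effects on MR/SRC that are qualitatively wrong. Running the test in paired
arms — with complex V inhibition and with a plain medium injection instead —
lets the bias be measured as the percent underestimation

```
U = 100 × (X_cv_free − X_cv_inhibited) / X_cv_free ,   X ∈ {MR, SRC}
```

`efastress` implements the full workflow for laboratories running this
paired design (and the companion glycolysis stress test) on 96-well flux
analyzers:

* canonical long-format CSV I/O for per-cycle OCR/ECAR plate runs, with
  protocol-aware validation (`read_plate_run()`, `write_plate_run()`,
  `default_protocol()`);
* blank correction, per-10⁴-cell normalization and phase-representative
  rate extraction (`blank_correct()`, `normalize_per_cell()`,
  `phase_rates()`);
* the six mitochondrial respiration parameters
  (basal, ATP-linked, proton leak, MR, SRC, non-mitochondrial OCR) and the
  paired-arm underestimation statistic (`mito_params()`,
  `percent_underestimation()`, `paired_underestimation()`);
* ECAR→proton-efflux-rate conversion (`PER = ECAR × BF × V × Kvol`,
  defaults BF = 2.4 mmol H⁺/L/pH, V = 2.28 µL, Kvol = 1.6), partition of
  mitochondrial CO₂ acidification via the CO₂ contribution factor
  (CCF = 0.61) and the four glycolytic parameters (`ecar_to_per()`,
  `partition_per()`, `glyco_params()`);
* mitochondrial (`ATP-linked OCR × 2 × P/O`, P/O = 2.75), glycolytic
  (1 ATP per extruded H⁺) and total ATP production budgets (`mito_atp()`,
  `glyco_atp()`, `atp_budget()`);
* Tukey's-fences outlier handling at the technical and experimental level,
  experiment-mean aggregation, one/two-way ANOVA with Dunnett and Tukey HSD
  post-hocs, Brown–Forsythe Levene, Cohen's *d* with 95% CI and
  dose-response slope F tests (`tukey_fences()`, `summarize_experiments()`,
  `anova_suite()`, `cohens_d()`, `slope_test()`);
* end-to-end pipelines and deterministic JSON/Markdown reports
  (`run_confound_analysis()`, `run_atp_analysis()`, `render_report()`);
* a seeded synthetic plate-run generator encoding dose-response ground
  truth (Ni²⁺ 0–72 ppm and LPS scenarios) for validating the whole pipeline
  by simulation recovery (`scenario_mito_confound()`,
  `scenario_atp_budget()`, `simulate_run()`).

## Worked example

Simulate the packaged Ni²⁺/LPS dose-sweep (4 experiments, sextuplicate
wells, both arms per plate) and run the confound analysis:

```r
library(efastress)
library(dplyr)

scenario <- scenario_mito_confound(seed = 1)
runs     <- simulate_runs(scenario, "MITO")
report   <- run_confound_analysis(runs)

filter(report$underestimation, substance != "NI" | dose == 72)
#>   substance dose parameter mean_percent   sem n
#> 1       LPS    1        MR        -1.95 0.827 4
#> 2       LPS    1       SRC         1.20 2.699 4
#> 3        NI   72        MR        20.04 1.181 4
#> 4        NI   72       SRC        34.05 1.464 4
#> 5      NONE    0        MR        56.64 1.425 4
#> 6      NONE    0       SRC        97.44 0.636 4

filter(report$dose_response, parameter == "MR")
#>   parameter slope     se    r2 statistic df1 df2        p
#> 1        MR -0.50 0.0190 0.969       697   1  22 3.78e-18
```

Reading the output: in the untreated control, complex V inhibition hides
56.6% of maximal respiration and 97.4% of spare respiratory capacity; at
72 ppm Ni²⁺ the MR underestimation has fallen to 20.0% (slope −0.50
percentage points per ppm, F(1, 22) = 697, p < 10⁻¹⁷), and LPS removes it
entirely (−2.0%). That dose-dependent shrinking of the bias is exactly what
makes the single-arm test misleading: the report's `tests` table shows the
same simulated data yielding a clear Ni²⁺ effect on MR in the CV-free arm
and Dunnett contrasts in the inhibited arm that tell a different story.
`render_report(report, "report/")` writes the tables as deterministic JSON
and Markdown.

The ATP side uses its own scenario (`scenario_atp_budget()`) and
`run_atp_analysis()`, which recovers a ~3.3-fold glycolytic ATP increase at
72 ppm Ni²⁺ with an approximately constant total ATP production rate, and a
1.3-fold total increase with LPS.

See `vignettes/stress-test-analysis.Rmd` for the model, parameter defaults,
the generator's noise hierarchy and the package's numerical conventions.

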