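# wmtransfer

Measurement and simulation tools for studying how visual **working memory
(WM)** constrains **long-term memory (LTM)** for objects and object–color
bindings across development.

The experimental paradigm is a single-probe change-detection task: on each
trial a participant studies a short sequence of unique objects (set size
S ∈ {2, 3, 4}), each drawn in one of six colors, and then judges a single
probe with one of three responses — *same object, same color* (SS),
*same object, different color* (SD), or *different object* (DO). After a
filled delay, memory for the studied objects is probed again in a surprise
LTM recognition test. The package provides:

* **Task designs** — a 120-trial WM phase (54/36/30 trials at S = 2/3/4,
  336 unique studied items, probe conditions split in thirds with
  re-paired / novel-color and array-color / novel-color halves) and a
  144-probe LTM test (48 new items + 32 per originating set size, with the
  8/8/8/8 sub-cell structure), seed-reproducible and fully validated.
* **A generative observer model** — a multinomial processing tree in which
  a probed object is available in WM with probability p = min(k/S, 1),
  its color binding survives with probability `b_wm`, novel probe colors
  are detected with probability `d_novel`, and unavailable objects elicit
  an "old" guess at rate `g_old` followed by a color guess with same-color
  bias `beta_same`. LTM availability is discounted by a transfer
  probability `tau_ltm` and a binding-survival probability `b_ltm`. The
  tree marginalizes exactly to the standard single-probe guessing model,
  `h = p + (1 − p) g`.
* **Estimators** — hit/false-alarm tallies, the guessing correction
  `p = (h − f)/(1 − f)`, Cowan's **k = p·S** with the one-item floor for
  implausible values (and p(LTM) floored at 0), the per-participant
  LTM/WM transfer ratio, contingent binding-error rates with all
  eligibility filters (object called old; novel-color probes excluded;
  WM-probed items excluded in LTM; sparse LTM cells flagged), and
  same-color guess-bias rates measured on false alarms to new objects.
* **Inference** — BIC-approximate Bayes factors for age, set-size and
  interaction effects on participant × set-size cell tables, and a
  default-prior (stretched-beta) correlation Bayes factor for the
  within-age-group standardized WM–LTM capacity correlation.
* **A pipeline and recovery experiment** — `run_pipeline()` chains
  design → simulate → score → analyze with full provenance, and
  `recovery_experiment()` validates the estimators against the generative
  model at the study's scale (43/39/42 participants).

## Worked example

```r
library(wmtransfer)

# one probe through the observer tree: k = 1.6, S = 2 (p = .8), g = .4,
# beta = .7, b_wm = .6
pp <- participant_params(k_true = 1.6, g_old = .4, beta_same = .7,
                         b_wm = .6, d_novel = .8, tau_ltm = .5,
                         b_ltm = .5, g_old_ltm = .3)
response_probabilities("SAME_SAME", "WM", 2, pp)
#>   SS   SD   DO
#> 0.76 0.12 0.12

# Cowan's k from a published group mean: adults, set size 4
capacity_k(0.90, 4)
#> [1] 3.6

# full synthetic study: three age cohorts, scored and analyzed
out <- tempfile()
run_pipeline(run_config(seed = 1), out)
read.csv(file.path(out, "table1_summary.csv"))[, c(
  "age_group", "set_size", "p_wm_mean", "p_ltm_mean", "k_mean")]
#>   age_group set_size p_wm_mean p_ltm_mean k_mean
#> 1     adult        2      1.00       0.52   2.00
#> 2     adult        3      0.98       0.52   2.94
#> 3     adult        4      0.87       0.45   3.48
#> 4  grade1-2        2      0.87       0.42   1.74
#> 5  grade1-2        3      0.63       0.29   1.88
#> 6  grade1-2        4      0.48       0.22   1.93
#> 7  grade5-7        2      1.00       0.53   2.00
#> 8  grade5-7        3      0.94       0.49   2.81
#> 9  grade5-7        4      0.77       0.42   3.06
```

The summary reproduces the canonical qualitative pattern: `p(WM)` falls
with set size and rises with age; estimated capacity `k_mean` rises with
age at every set size. The accompanying `report.json` contains the Bayes
factors — for this run, overwhelming evidence for set-size and age effects
on p(WM) (BF₁₀ ≈ 10⁶⁴ and 10²⁴), evidence *against* an age effect on the
contingent LTM binding-error rate (BF₀₁ ≈ 40), and a positive standardized
WM–LTM capacity correlation (r ≈ .30, BF₁₀ ≈ 34). These are outputs of the
synthetic cohorts, not reproductions of any human sample.

## Command line

```sh
Rscript inst/cli/wmtransfer.R design   --seed 1 --out out/
Rscript inst/cli/wmtransfer.R simulate --config inst/extdata/profiles_default.json --out out/
Rscript inst/cli/wmtransfer.R score    --in out/ --out out/ [--pool-wm-lures] [--binding-include-all]
Rscript inst/cli/wmtransfer.R analyze  --in out/ --out out/ [--prior-width W]
Rscript inst/cli/wmtransfer.R run      --seed 1 --out out/
Rscript inst/cli/wmtransfer.R recover  --seed 1 --replicates 20
```

## Documentation

See the methods vignette (`vignettes/wm-ltm-measurement.Rmd`) for the
model, the estimators, the calibration of the synthetic cohorts, numerical
choices, and known limitations.
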