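# probeval

Evaluation of transcriptome-scale RNA chemical probing data against
reference structure.

Chemical probing reagents (DMS, SHAPE) react with flexible, mostly
unpaired nucleotides. Sequencing reads the modifications out either as
reverse-transcription stops (SEQ) or as mutations (MaP), giving a
per-position event count and read depth for a probe-treated (plus) and
optionally a probe-free (minus) channel. `probeval` turns such count
tables into reactivity profiles and scores how well they reflect known
structure:

* **Reactivity**: raw per-base rates, `Mrate = Mnum / Mdepth` for
  mutation profiling and `STrate = STnum / STdepth` for stop profiling
  (with `STdepth` the reads informative at the position), optional
  background adjustment `rate(plus) − rate(minus)`, a strict coverage
  filter (depth > 500), the DMS A/C base restriction, and the ≥50
  covered-positions inclusion rule for mRNAs.
* **Secondary-structure concordance**: ROC/AUC with unpaired bases
  (dots in dot-bracket) as the positive class and reactivity as the
  score — the trapezoidal AUC equals the Mann-Whitney statistic
  `[#(unpaired > paired) + ½·#ties] / (n_u · n_p)` — plus the fraction
  of top-x% reactive bases that are unpaired, rate histograms, and
  class-conditional overlap summaries.
* **Ensemble pairing**: marginal pairing probabilities
  `m_i = Σ_j p_ij` from base-pair probability matrices, an
  exhaustive-enumeration toy ensemble (structures weighted `w^#pairs`)
  as internal oracle, and flagging of bases with `m_i ≥ 0.995` yet
  top-10% reactivity.
* **Solvent accessibility**: an in-package Shrake–Rupley implementation
  (3 Å probe, deterministic golden-spiral quadrature, rigid-motion
  invariant), per-residue relative accessibility, and Pearson
  correlations between reactivity and accessibility stratified by
  reactivity rank and pairing state.
* **Simulator**: a generative model of probing experiments (single-hit
  kinetics, 3'-initiated reverse transcription with detection
  censoring, background channels) with closed-form expected rates, so
  every statistic above can be validated on data with a known truth.

## Worked example

Simulate a probing experiment with overlapping paired/unpaired rate
distributions on a known 200-nt structure, compute reactivity, and
evaluate it:

```r
library(probeval)

sc      <- make_benchmark_scenario("overlap", seed = 1)
sim     <- simulate_experiment(sc$config)
profile <- pipeline_react(sim$plus, probe = "SHAPE")
report  <- pipeline_evaluate(profile, sc$structure)
report
#> <run_report> rna=benchmark mode=mutation probe=SHAPE background=FALSE
#>   AUC = 0.7133 over 200 valid bases; fraction rate >= 0.1: 0.0050
```

An AUC of 0.71 means a randomly chosen unpaired base out-scores a
randomly chosen paired base 71% of the time — informative but far from
perfect separation, because the class rate distributions overlap, as
they do in real probing data. Only 0.5% of bases exceed a rate of 0.1:
most reactivities sit near zero. The top-x% curve shows that the most
reactive bases are the trustworthy ones:

```r
report$top_x_curve[report$top_x_curve$x %in% c(5, 10, 20, 50, 100), ]
#> # A tibble: 5 × 2
#>       x fraction_unpaired
#>   <dbl>             <dbl>
#> 1     5              1
#> 2    10              1
#> 3    20              0.85
#> 4    50              0.59
#> 5   100              0.48
```

Every base in the top 10% of reactivity is truly unpaired; at x = 100
the value is just the overall unpaired fraction (48%). On the ensemble
side, the toy ensemble of `GAAAC` has two structures (open, and the
single G–C pair), so with equal weights the marginal pairing
probability of the outer bases is exactly 1/2:

```r
marginal_pairing_probability(ensemble_bpp("GAAAC", pair_weight = 1))
#> # A tibble: 5 × 2
#>   position pairing_probability
#>      <int>               <dbl>
#> 1        1                 0.5
#> 2        2                 0
#> 3        3                 0
#> 4        4                 0
#> 5        5                 0.5
```

`pipeline_simulate()`, `pipeline_react()`, `pipeline_evaluate()` and
`pipeline_sasa()` chain the same steps through TSV/JSON files for
scripted use; see the vignette (`vignettes/probing-evaluation.Rmd`) for
the models, conventions and parameter choices.

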