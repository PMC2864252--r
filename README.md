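# decaytiming

Tools for analysing how mRNA degradation rates shape the temporal order of
gene induction and suppression in time-course expression data.

## The scientific problem

After a stimulus, genes reach detectable induction at different times, and this
ordering is usually attributed to regulatory cascades. But there is a purely
kinetic alternative. Transcript abundance obeys first-order kinetics,

```
dX/dt = beta - alpha * X
```

with transcription rate `beta` and degradation rate `alpha`. The *fractional*
progress of any transition to a new steady state is `1 - exp(-alpha * t)` —
it depends only on the degradation rate. So even if every gene switches its
transcription rate at the same instant, unstable mRNAs (large `alpha`, short
half-life) respond quickly while stable mRNAs lag: degradation rate alone can
produce a temporal program. The time to observe a `k`-fold increase after an
`L`-fold transcriptional step is

```
T_k = -log2(1 - (k - 1)/(L - 1)) * T_half
```

linear in the half-life. Conversely, after a transcriptional shutoff a
transcript can fall at most as fast as pure decay, which bounds its half-life:
a gene dropping faster than its known half-life allows must have been actively
destabilised.

The package implements this model (closed-form kinetics, pulse simulation,
fold-induction timing, shutoff bound), the analysis pipeline that tests it on
time-course data (presence filtering, probe collapse, first-crossing response
times, kinetic clustering, early/late partition, core-set extraction), the
statistics (an exact tie-aware rank-sum test, hypergeometric 3'-UTR k-mer and
category enrichment with BH correction), and a fully labelled synthetic-data
generator used to validate every claim end to end.

## Worked example

Half-life sets the induction timescale — the time to 2-fold induction under a
10-fold transcriptional step, for half-lives of 0.5, 2 and 8 hours:

```r
library(decaytiming)
time_to_fold_induction(k = 2, L = 10, t_half = c(0.5, 2, 8))
#> [1] 0.08483682 0.33934729 1.35738916
```

Generate a synthetic experiment with known ground truth (5000 genes, 500
induced, atlas half-lives log-normal around 274 minutes, a planted AU-rich
7-mer), then recover the kinetic signature:

```r
cfg <- synthetic_config(seed = 7)
exp <- generate_experiment(cfg)

lfc <- log2_fold_change(exp$expression)
rt  <- assign_response_time(lfc, fold_threshold = 2, direction = "up")
table(rt$response_time)
#> 0.5   1   2   4   6   8  10
#> 216  96  85  69  36  19  18

parts <- partition_early_late(rt, cutoff = 2)
early_late_stability_test(parts$early, parts$late, exp$atlas)
#> Wilcoxon rank-sum test (normal-approximation)
#>   n_a = 397, n_b = 142, rank-sum W = 90761
#>   alternative: less, p-value = 3.02676e-25
```

Early responders are dramatically less stable than late responders, exactly as
the kinetic model predicts. The full pipeline wraps these steps:

```r
rep <- run_induction_analysis(cfg)
str(rep$summary)
#> List of 11
#>  $ seed                : num 7
#>  $ fold_threshold      : num 2
#>  $ early_cutoff_h      : num 2
#>  $ n_genes             : int 5000
#>  $ n_responders        : int 539
#>  $ n_early             : int 397
#>  $ n_late              : int 142
#>  $ early_late_p        : num 3.03e-25
#>  $ early_late_p_no_core: logi NA
#>  $ genomic_length_p    : num 9.96e-16
#>  $ mature_length_p     : num 0.0937
```

(Early genes are also genomically shorter — the planted length bias.) The
planted 3'-UTR motif is recovered as the top-ranked 7-mer:

```r
fg <- exp$utr[exp$truth$motif_foreground]
bg <- exp$utr[!exp$truth$motif_foreground]
head(scan_kmers(fg, bg, k = 7), 3)
#> # A tibble: 3 × 9
#>   kmer        x     n     K     N fg_fraction bg_fraction      p_value q_value
#>   <chr>   <int> <int> <int> <int>       <dbl>       <dbl>        <dbl>   <dbl>
#> 1 TATTTAT    26    52   887  5000       0.5        0.177  0.0000000955 0.00157
#> 2 CACTAGG    11    52   225  5000       0.212      0.045  0.0000142    0.116
#> 3 CCCTCCG     7    52   106  5000       0.135      0.0212 0.0000963    0.526
```

Results have `autoplot()` methods (`run_figure1_simulation()` trajectories,
kinetic cluster means) and the tests have `tidy()`/`glance()` methods. Real
data enters through `read_expression_tsv()`, `read_flags_tsv()`,
`read_atlas_tsv()`, `read_annotation_tsv()` and `read_utr_fasta()`; pass a
named list of paths to `run_induction_analysis()` instead of a config.

See `vignette("degradation-and-timing")` for the model, the generator's
design, the statistics, and the package's limitations.

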