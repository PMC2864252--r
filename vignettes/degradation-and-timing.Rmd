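---
title: "mRNA decay rates and the temporal order of gene induction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mRNA decay rates and the temporal order of gene induction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decaytiming)
```

## The scientific question

When a stimulus induces a transcriptional program, different genes reach
detectable induction at different times. A natural explanation is regulatory
cascades: late genes wait for early gene products. This package implements and
validates a complementary, purely kinetic explanation: even if all genes switch
their transcription rates at the same instant, the *degradation rate* of each
mRNA sets how quickly its abundance can move to the new steady state, so stable
transcripts are intrinsically late.

## The kinetic model

Transcript abundance $X(t)$ follows first-order kinetics,

$$\frac{dX}{dt} = \beta - \alpha X,$$

with constant transcription rate $\beta$ and degradation rate $\alpha$
(units $h^{-1}$). The model has a closed-form solution implemented in
`transition_level()`:

$$X(t) = \frac{\beta}{\alpha} + \Big(X_0 - \frac{\beta}{\alpha}\Big)e^{-\alpha t}.$$

Key consequences exposed as functions:

* `steady_state_level()`: the steady state is $\beta/\alpha$.
* `half_life_from_rate()` / `rate_from_half_life()`: $T_{1/2} = \ln 2/\alpha$.
* The *fractional* progress of any transition, $1 - e^{-\alpha t}$, depends on
  $\alpha$ alone — not on $\beta$, the fold change, or the direction of the
  transition. This is the core of the kinetic argument.
* `time_to_fold_induction()`: if transcription steps from $\beta$ to $L\beta$,
  the time to observe a $k$-fold increase in abundance is
  $$T_k = -\log_2\!\big(1 - f\big)\, T_{1/2}, \qquad f = \frac{k-1}{L-1},$$
  linear in the half-life at fixed $(k, L)$. `k = L` returns `Inf` (the
  asymptote is approached but never reached) and `k > L` is an error.
* `shutoff_max_half_life()`: after a complete transcriptional shutoff, pure
  decay gives $X(t) = X_0 e^{-\alpha t}$, so an observed `fold_down`-fold drop
  by time $t$ bounds the half-life: $T_{1/2} \le t\,\ln 2 / \ln(\text{fold\_down})$.
  A gene whose atlas half-life *exceeds* this bound cannot have fallen that
  fast by transcriptional shutoff alone and must have been actively
  destabilised.

`simulate_pulse()` composes the closed form piecewise across a transcription
pulse (on at `t_on`, off at `t_off`); it evaluates the exact solution at the
requested grid points plus the breakpoints, so there is no integration error.
`calibrate_beta_for_level()` inverts the transition for $\beta$ so that
trajectories with different $\alpha$ can be equalised at a chosen time — a
target below the decayed floor $X_0 e^{-\alpha t}$ is an error, because no
non-negative transcription rate can reach it.

```{r classic-panel}
tr <- run_figure1_simulation(alphas = c(2, 1, 0.5, 0.2), beta = 5,
                             t_on = 0, t_off = 5, grid = seq(0, 10, 0.25))
# fractional completion at 0.5 h orders strictly by alpha
at <- tr[tr$time_h == 0.5, ]
round(at$level / steady_state_level(5, at$alpha), 3)
```

## From time courses to response times

Expression time courses are tibbles with one id column and columns named
`t_<hours>h` (e.g. `t_0.5h`); `as_time_course()` builds them and
`read_expression_tsv()` reads them. Preprocessing mirrors standard microarray
practice:

* `filter_by_presence()` keeps probe sets called Present (`"P"`) in at least
  `min_present = 2` chips; Marginal (`"M"`) calls count as absent. The rule is
  applied per dataset.
* `collapse_probesets()` keeps, per gene, the probe set with the highest
  median expression; ties break to the lexicographically smallest probe id so
  the choice is deterministic.
* `select_longest()` keeps, per gene, the transcript with the longest genomic
  transcribed length (or longest 3'-UTR), with the same deterministic
  tie-break.

`assign_response_time()` defines a gene's response time as the **first sampled
time point** at which $|\log_2$ fold change$|$ crosses $\log_2$ of the fold
threshold (default 2-fold). No interpolation is attempted: with typical
sampling grids the interpolation error is smaller than the biological and
measurement noise, and first-crossing at sampled times is reproducible and
assumption-free. Genes crossing in both directions are reported by their
first crossing and flagged `dual_response`.

`kinetic_clusters()` groups responders by their crossing time and averages
max-normalised profiles (`normalize_to_max()`), giving one mean curve per
response-time cluster. `partition_early_late()` splits responders at a cutoff
(default 2 h, *inclusive*: a gene crossing exactly at 2 h is early).
`identify_core_set()` intersects early-responder tables across datasets,
keeping genes early in at least `min_datasets` of them.

## Statistics

The central association test asks whether early responders have shorter
half-lives than late responders. `rank_sum_test()` implements the
Wilcoxon–Mann–Whitney rank-sum test with an **exact, tie-aware** null: for
combined samples up to `exact_limit` (default 12) it enumerates the exact
distribution of the rank sum by dynamic programming over doubled midranks
(which are integers even with ties), and otherwise uses the tie-corrected
normal approximation with continuity correction. The exact path exists because
`stats::wilcox.test()` cannot compute exact p-values in the presence of ties;
the package's test suite cross-checks both paths against brute-force
enumeration of all splits. Two-sided p-values are `min(1, 2 * min(p_less,
p_greater))`. Tests default to the one-sided alternative `"less"` because the
kinetic model makes a directional prediction (early implies less stable);
`alternative` is an argument everywhere for users who prefer two-sided tests.

`hypergeometric_tail()` computes $P(\text{overlap} \ge x)$ via
`stats::phyper()`, with argument-consistency validation. `scan_kmers()` counts
*presence* (not occurrence counts) of each DNA $k$-mer in foreground and
background 3'-UTR sets and applies the hypergeometric tail per $k$-mer with
Benjamini–Hochberg correction (`q_value`). The foreground is included in the
background universe by default (`include_fg_in_bg = TRUE`), matching the
convention that the background is "all sequences analysed"; set it to `FALSE`
for disjoint sets. `category_enrichment()` applies the same tail test to gene
categories. RNA input (`U`) is canonicalised to DNA (`T`) throughout, so the
AU-rich element `UAUUUAU` is scanned as `TATTTAT`.

## The synthetic generator

`synthetic_config()` + `generate_experiment()` produce a complete, fully
labelled experiment: an expression time course, presence flags, a probe-to-gene
map, a half-life atlas, a transcript annotation, 3'-UTR sequences, and a
`truth` tibble. It exists so that every pipeline claim can be tested against
known ground truth. Defaults and their rationale:

* **Atlas**: half-lives are log-normal with median 274 min (a published
  genome-wide mammalian median) and `atlas_log_sd = 1` on the natural-log
  scale, giving a realistic right-skewed spread from minutes to days.
* **Roles**: `n_induced` genes step transcription up by a fold $L$ drawn
  log-uniformly from `induction_fold_range = c(3, 30)`; `n_suppressed` step
  down by a fold from the mirrored `suppression_fold_range`; the rest are
  unchanged. Latent abundances follow the closed form exactly.
* **Sampling**: `c(0, 0.5, 1, 2, 4, 6, 8, 10)` hours, a typical dense early /
  sparse late design.
* **Noise**: measurements are the latent level times $2^{\varepsilon}$,
  $\varepsilon \sim N(0, 0.25)$ — multiplicative noise of about ±19% (one
  sd), in the range of array replicate variability.
* **Baselines**: $\log_2$ baseline levels uniform on `c(5, 14)`, spanning the
  usable dynamic range of arrays.
* **Motif**: the 7-mer `TATTTAT` is planted into 52% of a 52-gene foreground
  (the fastest-decaying induced genes) and 18% of the background, with chance
  occurrences scrubbed first so presence is controlled exactly.
* **Lengths**: when `length_model$enabled`, genomic lengths are
  log10-normal with mean 4.6 (≈ 40 kb) for background genes and 3.98
  (≈ 9.5 kb) for genes whose theoretical response time is below
  `early_cutoff_h = 1`, sd 0.45 — early genes are shorter, reproducing the
  known length bias of immediate-early genes.
* **Destabilisation**: a fraction `frac_destabilized` of suppressed genes get
  their decay rate multiplied by `destab_alpha_factor = 5` *and* transcription
  divided by `destab_shutoff_fold = 20`, modelling active destabilisation on
  top of shutoff; the remainder are suppressed by transcription alone. This is
  the planted signal for `flag_destabilized()`.
* **Reproducibility**: every stochastic stage (atlas, roles, lengths, UTRs,
  noise, baselines) uses a child seed derived deterministically from
  `cfg$seed`, so a config fully determines the experiment.

`write_fixture_bundle()` serialises an experiment to the TSV/FASTA formats the
readers accept, so the file-based and in-memory pipelines can be compared.

## Pipelines

`run_induction_analysis()` chains presence filtering, probe collapse, fold
changes, response times, kinetic clusters, the early/late half-life test
(optionally repeated after removing a core set), pairwise cluster tests, and
the gene-length association, returning an `induction_report` and optionally
writing TSV/JSON outputs. `run_suppression_analysis()` does the analogous
down-regulation analysis ending in shutoff-bound flags.
`run_figure1_simulation()` reproduces the classic four-rate pulse panel,
optionally with rate calibration. Results have `autoplot()` methods, and the
test objects have `tidy()`/`glance()` methods.

## Interpreting the detector's error rates

`flag_destabilized()` flags a suppressed gene when its atlas half-life exceeds
`margin` times the shutoff bound implied by its observed drop. The package's
acceptance checks report **sensitivity** as flagged truly-destabilised genes
over *all* truly-destabilised genes, and the **false-flag rate** as flagged
non-destabilised genes over *all* non-destabilised genes analysed. The
symmetric denominators make the two rates comparable; note that conditioning
instead on genes that happen to cross the 2-fold-down threshold would give a
much higher apparent false-flag rate, because noise-driven crossers are
precisely the cases where an apparent fast drop meets a long atlas half-life.
The default `margin = 1` flags any nominal violation; `margin = 1.5` absorbs
measurement noise in the observed fold.

## Numerical and design choices

* All kinetics are evaluated by closed form, never by numeric integration;
  the test suite checks agreement with an independent Runge–Kutta integrator
  to relative error below $10^{-6}$.
* Induction analyses assume the pre-stimulus level is the $t = 0$ sample
  (fold changes are relative to the first column), i.e. the system starts at
  its old steady state.
* Response times are defined only at sampled time points; a gene whose true
  crossing falls between samples is assigned the next sampled time.
* The early/late boundary (2 h) is inclusive on the early side.
* Multiple testing across $k$-mers uses Benjamini–Hochberg; the scan returns
  both raw `p_value` and `q_value` and never hard-thresholds for you.
* Case-insensitive gene-id joins against the atlas, with a message reporting
  how many genes lacked atlas measurements.

## Limitations

* The model is single-compartment and first-order: no transcriptional delay,
  splicing/export dynamics, or regulated changes of $\alpha$ over time (except
  the explicit destabilisation scenario). Deviations from exponential decay
  (e.g. biphasic decay) violate the shutoff bound's assumptions.
* First-crossing response times are resolution-limited by the sampling grid
  and threshold-dependent; they are ordinal summaries, not estimates of the
  underlying $T_k$.
* The rank-sum association is correlational. The package's synthetic
  validation shows the *kinetic* mechanism suffices to produce the observed
  orderings; it cannot exclude regulatory contributions in real data.
* The exact rank-sum path is limited to small combined samples
  (`exact_limit`); large-sample p-values rely on the normal approximation,
  which is standard but approximate in the extreme tails.
* The motif scan tests presence, not position, spacing, or secondary
  structure, and assumes UTR sequences are correct and complete.
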