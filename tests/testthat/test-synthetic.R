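test_that("half-life atlas is log-normal with the requested median", {
  atlas <- generate_half_life_atlas(10000, median_minutes = 274, log_sd = 1, seed = 1)
  expect_equal(median(atlas$t_half_hours) * 60, 274, tolerance = 10 / 274)
  # degenerate dispersion collapses to the median exactly
  flat <- generate_half_life_atlas(50, 300, log_sd = 0, seed = 2)
  expect_equal(flat$t_half_hours, rep(5, 50))
  # determinism
  expect_identical(
    generate_half_life_atlas(100, seed = 9),
    generate_half_life_atlas(100, seed = 9)
  )
  expect_error(generate_half_life_atlas(0), "positive")
})

test_that("zero-noise time courses equal the closed-form transition exactly", {
  cfg <- small_cfg(seed = 3, noise_log2_sd = 0)
  exp <- generate_experiment(cfg)
  lfc <- log2_fold_change(exp$expression)
  m <- as.matrix(lfc[grep("^t_", names(lfc))])
  times <- time_course_times(lfc)
  tr <- exp$truth
  for (i in which(tr$role == "induced")[1:5]) {
    expected <- log2(1 + (tr$L[i] - 1) * (1 - exp(-tr$alpha[i] * times)))
    expect_equal(unname(m[i, ]), expected, tolerance = 1e-9)
  }
  # unchanged genes are exactly flat without noise
  flat <- which(tr$role == "unchanged")
  expect_true(all(abs(m[flat, ]) < 1e-9))
})

test_that("generator is deterministic and conserves gene roles", {
  cfg <- small_cfg(seed = 5)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$expression, e2$expression)
  expect_identical(e1$utr, e2$utr)
  expect_identical(e1$truth, e2$truth)
  counts <- table(e1$truth$role)
  expect_equal(unname(counts["induced"] + counts["suppressed"] + counts["unchanged"]),
               cfg$n_genes)
  expect_equal(unname(counts["induced"]), cfg$n_induced)
  expect_true(all(e1$truth$genomic_length_bp >= e1$truth$mature_length_bp))
  expect_true(all(e1$truth$alpha > 0 & e1$truth$alpha_post > 0))
})

test_that("motif presence matches the planting probabilities", {
  cfg <- synthetic_config(n_genes = 2000, n_induced = 400, n_suppressed = 0,
                          motif_fg_size = 200, seed = 11)
  exp <- generate_experiment(cfg)
  pres <- kmer_presence(exp$utr, cfg$motif)
  fg <- exp$truth$motif_foreground
  # presence equals the planting flag exactly: chance hits are scrubbed
  expect_identical(pres$present, exp$truth$motif_planted)
  # planted frequency within the binomial 99% CI of the target rate
  ci_fg <- qbinom(c(0.005, 0.995), sum(fg), cfg$plant_rate_fg) / sum(fg)
  expect_gte(mean(pres$present[fg]), ci_fg[1])
  expect_lte(mean(pres$present[fg]), ci_fg[2])
  ci_bg <- qbinom(c(0.005, 0.995), sum(!fg), cfg$plant_rate_bg) / sum(!fg)
  expect_gte(mean(pres$present[!fg]), ci_bg[1])
  expect_lte(mean(pres$present[!fg]), ci_bg[2])
})

test_that("without destabilisation every suppressed gene obeys the shutoff bound", {
  cfg <- small_cfg(seed = 13, noise_log2_sd = 0, frac_destabilized = 0)
  exp <- generate_experiment(cfg)
  lfc <- log2_fold_change(exp$expression)
  ev <- suppression_events(lfc, 2)
  expect_gt(nrow(ev), 0)
  fl <- flag_destabilized(ev, exp$atlas, margin = 1)
  expect_false(any(fl$flagged))
})

test_that("theoretical response times rise with half-life", {
  exp <- generate_experiment(synthetic_config(seed = 7))
  ind <- exp$truth[exp$truth$role == "induced", ]
  rho <- cor(ind$theoretical_response_time, ind$t_half_hours, method = "spearman")
  # linear in T_1/2 at fixed L; the log-uniform spread of L over [3, 30]
  # caps the rank correlation well below 1
  expect_gt(rho, 0.6)
})

test_that("fixture bundle round-trips through the readers", {
  cfg <- small_cfg(seed = 17)
  exp <- generate_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(exp, dir)
  expect_true(all(file.exists(paths)))

  x <- read_expression_tsv(paths[["expression"]])
  expect_equal(as.data.frame(x), as.data.frame(exp$expression), tolerance = 1e-9)
  expect_identical(time_course_times(x), cfg$sampling_times)

  atlas <- read_atlas_tsv(paths[["atlas"]])
  expect_equal(atlas$t_half_hours, exp$atlas$t_half_hours, tolerance = 1e-9)

  utr <- read_utr_fasta(paths[["utr"]])
  expect_identical(utr, exp$utr)
  # FASTA body is wrapped at 60 characters
  body <- readLines(paths[["utr"]])
  body <- body[!startsWith(body, ">")]
  expect_true(all(nchar(body) <= 60))

  truth <- readr::read_tsv(paths[["truth"]], show_col_types = FALSE)
  expect_equal(nrow(truth), cfg$n_genes)

  ann <- read_annotation_tsv(paths[["annotation"]])
  expect_equal(ann$genomic_length_bp, exp$annotation$genomic_length_bp)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(synthetic_config(n_genes = 10, n_induced = 8, n_suppressed = 8), "exceed")
  expect_error(synthetic_config(plant_rate_fg = 1.2), "0, 1")
  expect_error(synthetic_config(sampling_times = c(1, 2)), "start at 0")
  expect_error(synthetic_config(induction_fold_range = c(0.5, 2)), "exceed 1")
  expect_error(synthetic_config(response_fold = 10), "attainable")
})
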