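test_that("response time is the first sampled crossing", {
  lfc <- tc(rbind(c(0, 0.5, 1.2, 2.0),
                  c(0, 0.2, 0.4, 0.6),
                  c(0, -0.5, -1.5, -2)),
            c(0, 0.5, 1, 2), ids = c("up1", "flat", "down1"))
  rt <- assign_response_time(lfc, fold_threshold = 2, direction = "up")
  expect_equal(rt$response_time[rt$gene_id == "up1"], 1)
  expect_identical(rt$direction[rt$gene_id == "flat"], "none")
  expect_true(is.na(rt$response_time[rt$gene_id == "flat"]))
  expect_identical(rt$direction[rt$gene_id == "down1"], "none")
  rt_dn <- assign_response_time(lfc, 2, direction = "down")
  expect_equal(rt_dn$response_time[rt_dn$gene_id == "down1"], 1)
  expect_error(assign_response_time(lfc, fold_threshold = 1), "fold_threshold")
})

test_that("zero-noise synthetic crossings match the closed-form induction time", {
  cfg <- small_cfg(seed = 23, noise_log2_sd = 0)
  exp <- generate_experiment(cfg)
  lfc <- log2_fold_change(exp$expression)
  rt <- assign_response_time(lfc, 2, "up")
  tr <- exp$truth
  times <- cfg$sampling_times
  for (i in which(tr$role == "induced")) {
    theo <- tr$theoretical_response_time[i]
    expected <- if (any(times[-1] >= theo)) min(times[-1][times[-1] >= theo]) else NA_real_
    got <- rt$response_time[rt$gene_id == tr$gene_id[i]]
    expect_equal(got, expected, info = tr$gene_id[i])
  }
})

test_that("raising the fold threshold never makes a response earlier", {
  cfg <- small_cfg(seed = 29)
  lfc <- log2_fold_change(generate_experiment(cfg)$expression)
  rt2 <- assign_response_time(lfc, 2, "up")
  rt3 <- assign_response_time(lfc, 3, "up")
  both <- !is.na(rt2$response_time) & !is.na(rt3$response_time)
  expect_true(all(rt3$response_time[both] >= rt2$response_time[both]))
  # genes responding at 3-fold always respond at 2-fold
  expect_true(all(!is.na(rt2$response_time[!is.na(rt3$response_time)])))
})

test_that("max-normalisation is scale invariant and bounded", {
  lfc <- tc(rbind(c(0, 1, 2), c(0, -1, -4)), c(0, 1, 2))
  nrm <- normalize_to_max(lfc)
  expect_equal(unname(as.matrix(nrm[-1])), rbind(c(0, 0.5, 1), c(0, -0.25, -1)))
  scaled <- lfc
  scaled[-1] <- lfc[-1] * 3
  expect_equal(normalize_to_max(scaled)[-1], nrm[-1], tolerance = 1e-12)
  expect_error(normalize_to_max(tc(rbind(c(0, 0, 0)), c(0, 1, 2))), "all-zero")
})

test_that("kinetic clusters average normalised member profiles", {
  lfc <- tc(rbind(c(0, 1, 2, 2), c(0, 2, 4, 4), c(0, 0.2, 1.5, 3)),
            c(0, 0.5, 1, 2), ids = c("a", "b", "c"))
  rt <- assign_response_time(lfc, 2, "up")
  nrm <- normalize_to_max(lfc)
  cl <- kinetic_clusters(rt, nrm)
  # a and b cross at 0.5 h and share kinetics up to scale: identical
  # normalised profiles, so the cluster mean equals either of them
  c1 <- cl[cl$response_time == 0.5, ]
  expect_equal(c1$n_genes, rep(2, 4))
  expect_equal(c1$mean_profile, c(0, 0.5, 1, 1))
  c2 <- cl[cl$response_time == 1, ]
  expect_equal(c2$n_genes, rep(1, 4))
  # single-cluster degenerate case
  rt1 <- rt[rt$gene_id %in% c("a", "b"), ]
  cl1 <- kinetic_clusters(rt1, nrm)
  expect_equal(unique(cl1$response_time), 0.5)
})

test_that("cluster mean curves are temporally ordered on synthetic data", {
  rep <- suppressMessages(run_induction_analysis(synthetic_config(seed = 7)))
  cl <- rep$clusters
  half_max_time <- sapply(split(cl, cl$response_time), function(d) {
    d$time_h[which(d$mean_profile >= 0.5)[1]]
  })
  expect_true(all(diff(half_max_time) >= 0))
})

test_that("early/late partition is an inclusive-boundary bipartition", {
  rt <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    direction = c("up", "up", "up", "none"),
    response_time = c(2, 4, 0.5, NA)
  )
  parts <- partition_early_late(rt, cutoff = 2)
  expect_setequal(parts$early, c("a", "c"))  # 2 h is early: "before or at"
  expect_setequal(parts$late, "b")
  expect_length(intersect(parts$early, parts$late), 0)
  expect_setequal(c(parts$early, parts$late), c("a", "b", "c"))
  none <- partition_early_late(rt[rt$direction == "none", ], 2)
  expect_length(none$early, 0)
  expect_length(none$late, 0)
})

test_that("core set requires early induction in enough datasets", {
  mk <- function(genes, times) tibble::tibble(
    gene_id = genes, direction = "up", response_time = times
  )
  tables <- list(
    mk(c("g1", "g2", "g3"), c(1, 1, 4)),
    mk(c("g1", "g2"), c(2, 4)),
    mk(c("g1", "g2"), c(0.5, 1)),
    mk(c("g1"), 1),
    mk(c("g4"), 1),
    mk(c("g4"), 8)
  )
  core <- identify_core_set(tables, cutoff = 2, min_datasets = 3)
  # g1 early in 4 datasets; g2 early in only 2 (its 4 h response is late)
  expect_setequal(core$gene_id, "g1")
  expect_equal(core$support_count[core$gene_id == "g1"], 4)
  expect_false("g4" %in% core$gene_id)
  # boundary: exactly min_datasets early datasets puts a gene in the core
  expect_true("g2" %in% identify_core_set(tables, 2, 2)$gene_id)
  # the core set shrinks weakly as the support requirement grows
  sizes <- sapply(1:6, function(k) nrow(identify_core_set(tables, 2, k)))
  expect_true(all(diff(sizes) <= 0))
  expect_error(identify_core_set(tables, 2, 7), "between 1")
})
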