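#' Resolve pipeline inputs from files or a synthetic configuration
#'
#' @param input Either a [synthetic_config()] or a named list of file paths
#'   with elements `expression`, and optionally `flags`, `probe_map`,
#'   `atlas`, `annotation`, `utr`.
#' @param min_present Presence-filter threshold (`NULL` skips the filter).
#' @param log2_input Whether the expression file stores log2 values.
#' @return A list `expression` (gene-level, presence-filtered), `atlas`,
#'   `annotation`, `utr`, `truth` (synthetic only).
#' @keywords internal
resolve_inputs <- function(input, min_present = 2, log2_input = FALSE) {
  if (inherits(input, "synthetic_config")) {
    exp <- generate_experiment(input)
    x <- exp$expression
    if (!is.null(min_present)) x <- filter_by_presence(x, exp$flags, min_present)
    return(list(
      expression = x, atlas = exp$atlas, annotation = exp$annotation,
      utr = exp$utr, truth = exp$truth, seed = input$seed
    ))
  }
  if (!is.list(input) || is.null(input$expression)) {
    abort("`input` must be a synthetic_config() or a list of file paths with an `expression` entry.")
  }
  for (nm in intersect(names(input), c("expression", "flags", "probe_map", "atlas", "annotation", "utr"))) {
    if (!file.exists(input[[nm]])) {
      abort(sprintf("input file for '%s' not found: %s", nm, input[[nm]]))
    }
  }
  x <- read_expression_tsv(input$expression, log2_input = log2_input)
  if (!is.null(input$flags) && !is.null(min_present)) {
    x <- filter_by_presence(x, read_flags_tsv(input$flags), min_present)
  }
  if (!is.null(input$probe_map)) {
    x <- collapse_probesets(x, read_probe_map_tsv(input$probe_map))
  }
  list(
    expression = x,
    atlas = if (!is.null(input$atlas)) read_atlas_tsv(input$atlas),
    annotation = if (!is.null(input$annotation)) read_annotation_tsv(input$annotation),
    utr = if (!is.null(input$utr)) read_utr_fasta(input$utr),
    truth = NULL, seed = NA
  )
}

write_report_tsv <- function(x, outdir, name) {
  if (is.null(outdir) || is.null(x) || !nrow(x)) return(invisible(NULL))
  readr::write_tsv(as_tibble(x), file.path(outdir, name), progress = FALSE)
}

#' Run the induction analysis end to end
#'
#' Presence filtering and probe collapse, log2 fold changes, first-crossing
#' response times, max-normalised kinetic clusters, the early/late half-life
#' comparison, pairwise cluster half-life tests, and the genomic-length
#' association (with the mature-length negative control). With no responding
#' genes the report is empty but the run succeeds.
#'
#' @param input A [synthetic_config()] or a named list of file paths (see
#'   `resolve_inputs`).
#' @param outdir Optional directory: all tables are written as TSV plus a
#'   `summary.json`.
#' @param fold_threshold Linear induction threshold (default 2).
#' @param early_cutoff Early/late boundary in hours, inclusive (default 2).
#' @param min_present Presence-filter threshold (default 2).
#' @param alternative Sidedness of the directional tests (default `"less"`).
#' @param exact_limit Exact rank-sum limit.
#' @param exclude_core Optional gene ids removed before re-running the
#'   early/late test (core-set removal check).
#' @return A list of class `induction_report`: `response_times`, `clusters`,
#'   `early`, `late`, `early_late_test`, `early_late_test_no_core`,
#'   `pairwise_tests`, `length_genomic`, `length_mature`, `summary`.
#' @export
run_induction_analysis <- function(input, outdir = NULL, fold_threshold = 2,
                                   early_cutoff = 2, min_present = 2,
                                   alternative = "less", exact_limit = 12,
                                   exclude_core = NULL) {
  dat <- resolve_inputs(input, min_present)
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  lfc <- log2_fold_change(dat$expression)
  rt <- assign_response_time(lfc, fold_threshold, direction = "up")
  responders <- rt$gene_id[rt$direction != "none"]

  clusters <- NULL
  el_test <- el_test_nocore <- pairwise <- len_g <- len_m <- NULL
  parts <- list(early = character(0), late = character(0))
  if (length(responders) > 0) {
    norm <- normalize_to_max(lfc[match(responders, lfc[[1]]), , drop = FALSE])
    clusters <- kinetic_clusters(rt, norm)
    parts <- partition_early_late(rt, early_cutoff)
    if (!is.null(dat$atlas) && length(parts$early) && length(parts$late)) {
      el_test <- early_late_stability_test(parts$early, parts$late, dat$atlas,
                                           alternative, exact_limit = exact_limit)
      if (!is.null(exclude_core)) {
        el_test_nocore <- early_late_stability_test(
          parts$early, parts$late, dat$atlas, alternative,
          exclude = exclude_core, exact_limit = exact_limit
        )
      }
      if (length(unique(rt$response_time[rt$direction != "none"])) >= 2) {
        pairwise <- pairwise_cluster_tests(rt, dat$atlas, alternative, exact_limit)
      }
    }
    if (!is.null(dat$annotation) &&
        length(unique(rt$response_time[rt$direction != "none"])) >= 2) {
      len_g <- length_association(rt, dat$annotation, "genomic_length_bp",
                                  alternative, exact_limit)
      len_m <- length_association(rt, dat$annotation, "mature_length_bp",
                                  alternative, exact_limit)
    }
  }

  summary <- list(
    seed = dat$seed,
    fold_threshold = fold_threshold,
    early_cutoff_h = early_cutoff,
    n_genes = nrow(dat$expression),
    n_responders = length(responders),
    n_early = length(parts$early),
    n_late = length(parts$late),
    early_late_p = if (!is.null(el_test)) el_test$p_value else NA,
    early_late_p_no_core = if (!is.null(el_test_nocore)) el_test_nocore$p_value else NA,
    genomic_length_p = if (!is.null(len_g)) len_g$test$p_value else NA,
    mature_length_p = if (!is.null(len_m)) len_m$test$p_value else NA
  )

  if (!is.null(outdir)) {
    write_report_tsv(rt, outdir, "response_times.tsv")
    write_report_tsv(clusters, outdir, "cluster_means.tsv")
    write_report_tsv(pairwise, outdir, "pairwise_cluster_tests.tsv")
    if (!is.null(len_g)) write_report_tsv(len_g$distributions, outdir, "length_by_cluster.tsv")
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(
    list(
      response_times = rt, clusters = clusters,
      early = parts$early, late = parts$late,
      early_late_test = el_test, early_late_test_no_core = el_test_nocore,
      pairwise_tests = pairwise,
      length_genomic = len_g, length_mature = len_m,
      summary = summary
    ),
    class = "induction_report"
  )
}

#' Run the suppression analysis end to end
#'
#' Mirrors [run_induction_analysis()] with direction = down, and adds the
#' transcription-shutoff check: every down-crossing gene gets its implied
#' maximal half-life, and genes whose atlas half-life exceeds `margin` times
#' the bound are flagged as actively destabilised.
#'
#' @inheritParams run_induction_analysis
#' @param margin Tolerance factor on the shutoff bound (1 = strict model
#'   argument; ~1.5 recommended with noisy data).
#' @return A list of class `suppression_report`: `response_times`, `events`,
#'   `flags`, `early_late_test`, `summary`.
#' @export
run_suppression_analysis <- function(input, outdir = NULL, fold_threshold = 2,
                                     early_cutoff = 2, min_present = 2,
                                     alternative = "less", exact_limit = 12,
                                     margin = 1) {
  dat <- resolve_inputs(input, min_present)
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  lfc <- log2_fold_change(dat$expression)
  rt <- assign_response_time(lfc, fold_threshold, direction = "down")
  events <- suppression_events(lfc, fold_threshold)
  flags <- NULL
  el_test <- NULL
  parts <- partition_early_late(rt, early_cutoff)
  if (!is.null(dat$atlas)) {
    if (nrow(events) > 0) flags <- flag_destabilized(events, dat$atlas, margin)
    if (length(parts$early) && length(parts$late)) {
      el_test <- early_late_stability_test(parts$early, parts$late, dat$atlas,
                                           alternative, exact_limit = exact_limit)
    }
  }
  summary <- list(
    seed = dat$seed,
    fold_threshold = fold_threshold,
    margin = margin,
    n_genes = nrow(dat$expression),
    n_suppressed = nrow(events),
    n_flagged = if (!is.null(flags)) sum(flags$flagged) else NA,
    early_late_p = if (!is.null(el_test)) el_test$p_value else NA
  )
  if (!is.null(outdir)) {
    write_report_tsv(rt, outdir, "response_times_down.tsv")
    write_report_tsv(flags, outdir, "destabilization_flags.tsv")
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(
    list(
      response_times = rt, events = events, flags = flags,
      early_late_test = el_test, summary = summary
    ),
    class = "suppression_report"
  )
}

#' Simulate pulse-response trajectories for a panel of decay rates
#'
#' Reproduces the canonical illustration of the kinetic model: transcripts
#' with the same transcription rate but different decay rates respond to a
#' square transcription pulse. The most unstable transcript reaches the
#' lowest steady state but completes its transition fastest. With
#' `equalize_at` set, each transcript's rate is first calibrated so all
#' trajectories meet `target_level` at that time.
#'
#' @param alphas Decay rates, per hour (default `c(2, 1, 0.5, 0.2)`).
#' @param beta Common transcription rate during the pulse (default 5).
#' @param t_on,t_off Pulse window, hours (default 0 to 5).
#' @param grid Evaluation grid (default 0..10 h, step 0.05).
#' @param x0 Level at the start of the grid (default 0: silent before
#'   stimulation).
#' @param equalize_at Optional hour at which all trajectories must coincide.
#' @param target_level Level they must reach there (required with
#'   `equalize_at`).
#' @param outdir Optional directory for one trajectory TSV.
#' @return A tibble of class `kin_trajectories` (`alpha`, `time_h`,
#'   `level`); the per-alpha transcription rates are in `attr(, "betas")`.
#' @export
run_figure1_simulation <- function(alphas = c(2, 1, 0.5, 0.2), beta = 5,
                                   t_on = 0, t_off = 5,
                                   grid = seq(0, 10, by = 0.05), x0 = 0,
                                   equalize_at = NULL, target_level = NULL,
                                   outdir = NULL) {
  check_alpha(alphas)
  betas <- rep(beta, length(alphas))
  if (!is.null(equalize_at)) {
    if (is.null(target_level)) abort("`target_level` is required with `equalize_at`.")
    if (equalize_at <= t_on || equalize_at > t_off) {
      abort("`equalize_at` must fall inside the pulse window.")
    }
    betas <- vapply(alphas, function(a) {
      calibrate_beta_for_level(target_level, a, equalize_at - t_on, x0)
    }, numeric(1))
  }
  out <- purrr::map2_dfr(alphas, betas, function(a, b) {
    tr <- simulate_pulse(a, beta_on = b, beta_off = 0, x0 = x0,
                         t_on = t_on, t_off = t_off, grid = grid)
    dplyr::mutate(tr, alpha = a, .before = 1)
  })
  attr(out, "betas") <- stats::setNames(betas, alphas)
  class(out) <- c("kin_trajectories", class(out))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(out, file.path(outdir, "trajectories.tsv"), progress = FALSE)
  }
  out
}
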