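match_atlas <- function(gene_ids, atlas, what = "genes") {
  idx <- match(tolower(gene_ids), tolower(atlas$gene_id))
  dropped <- sum(is.na(idx))
  if (dropped > 0) {
    message(sprintf("dropping %d %s without an atlas half-life.", dropped, what))
  }
  atlas$t_half_hours[idx[!is.na(idx)]]
}

#' Pairwise half-life comparisons between kinetic clusters
#'
#' For every ordered pair of kinetic clusters (earlier, later), tests whether
#' the earlier cluster's transcripts have shorter half-lives, using the
#' rank-sum test on atlas half-lives. Atlas joins are case-insensitive on
#' gene id; genes missing from the atlas are dropped with a message.
#'
#' @param rt Response-time table from [assign_response_time()].
#' @param atlas Half-life atlas tibble (`gene_id`, `t_half_hours`).
#' @param alternative Passed to [rank_sum_test()]; the default `"less"`
#'   encodes "earlier cluster has lower half-life".
#' @param exact_limit Passed to [rank_sum_test()].
#' @return A tibble with one row per cluster pair: `cluster_a`, `cluster_b`
#'   (response times in hours, a earlier than b), sample sizes, statistic,
#'   `p_value` and method.
#' @export
pairwise_cluster_tests <- function(rt, atlas, alternative = "less", exact_limit = 12) {
  resp <- rt[rt$direction != "none", , drop = FALSE]
  halves <- split(resp$gene_id, resp$response_time)
  halves <- purrr::map(halves, match_atlas, atlas = atlas, what = "cluster genes")
  halves <- halves[lengths(halves) > 0]
  if (length(halves) < 2) abort("need at least two clusters with atlas-matched genes.")
  times <- as.numeric(names(halves))
  pairs <- utils::combn(order(times), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    res <- rank_sum_test(halves[[i1]], halves[[i2]],
                         alternative = alternative, exact_limit = exact_limit)
    tibble(
      cluster_a = times[i1], cluster_b = times[i2],
      n_a = res$n_a, n_b = res$n_b,
      statistic = res$statistic, p_value = res$p_value, method = res$method
    )
  })
}

#' Compare half-lives of early- versus late-responding genes
#'
#' Rank-sum test between the atlas half-lives of early and late responders,
#' optionally after removing a core set of recurrently early genes (to check
#' that an association is not carried by those genes alone).
#'
#' @param early,late Character vectors of gene ids.
#' @param atlas Half-life atlas tibble.
#' @param alternative Default `"less"`: early genes have shorter half-lives.
#' @param exclude Optional character vector of gene ids (e.g. a core set)
#'   removed from both sets before testing.
#' @param exact_limit Passed to [rank_sum_test()].
#' @return A [rank_sum_test()] object.
#' @export
early_late_stability_test <- function(early, late, atlas, alternative = "less",
                                      exclude = NULL, exact_limit = 12) {
  if (!is.null(exclude)) {
    early <- setdiff(early, exclude)
    late <- setdiff(late, exclude)
  }
  a <- match_atlas(early, atlas, "early genes")
  b <- match_atlas(late, atlas, "late genes")
  rank_sum_test(a, b, alternative = alternative, exact_limit = exact_limit)
}

#' Gene-length distributions across kinetic clusters
#'
#' Returns the length distribution of each kinetic cluster and a one-sided
#' test of whether the earliest cluster's genes are shorter than all other
#' responders. The same machinery applied to `mature_length_bp` serves as a
#' negative control: mature transcript length is not expected to constrain
#' response time, while genomic transcribed length (introns included) bounds
#' how soon a full transcript can appear.
#'
#' @param rt Response-time table.
#' @param annotation Annotation tibble with `gene_id` and the length column.
#' @param length_col `"genomic_length_bp"` (default) or `"mature_length_bp"`.
#' @param alternative Default `"less"` (earliest cluster shorter).
#' @param exact_limit Passed to [rank_sum_test()].
#' @return A list: `distributions` (tibble `gene_id`, `response_time`,
#'   `length_bp`), `earliest` (hours) and `test` (a [rank_sum_test()]
#'   object, earliest cluster vs all other responders).
#' @export
length_association <- function(rt, annotation, length_col = "genomic_length_bp",
                               alternative = "less", exact_limit = 12) {
  resp <- rt[rt$direction != "none", , drop = FALSE]
  idx <- match(resp$gene_id, annotation$gene_id)
  dropped <- sum(is.na(idx))
  if (dropped > 0) message(sprintf("dropping %d responders without annotation.", dropped))
  resp <- resp[!is.na(idx), , drop = FALSE]
  len <- annotation[[length_col]][idx[!is.na(idx)]]
  if (length(unique(resp$response_time)) < 2) {
    abort("need at least two kinetic clusters for a length comparison.")
  }
  earliest <- min(resp$response_time)
  a <- len[resp$response_time == earliest]
  b <- len[resp$response_time > earliest]
  list(
    distributions = tibble(
      gene_id = resp$gene_id,
      response_time = resp$response_time,
      length_bp = len
    ),
    earliest = earliest,
    test = rank_sum_test(a, b, alternative = alternative, exact_limit = exact_limit)
  )
}

#' Down-crossing events of suppressed genes
#'
#' For each gene whose log2 fold change drops below `-log2(fold_threshold)`,
#' records the first sampled crossing time and the observed fold-decrease at
#' that time — the inputs of the transcription-shutoff bound.
#'
#' @param lfc Log2 fold-change time-course tibble.
#' @param fold_threshold Linear fold threshold (> 1), default 2.
#' @return A tibble `gene_id`, `crossing_time_h`, `fold_down`.
#' @export
suppression_events <- function(lfc, fold_threshold = 2) {
  rt <- assign_response_time(lfc, fold_threshold, direction = "down")
  resp <- rt[rt$direction == "down", , drop = FALSE]
  m <- time_course_matrix(lfc)
  times <- time_course_times(lfc)
  col <- match(resp$response_time, times)
  row <- match(resp$gene_id, lfc[[1]])
  tibble(
    gene_id = resp$gene_id,
    crossing_time_h = resp$response_time,
    fold_down = 2^(-m[cbind(row, col)])
  )
}

#' Flag suppressed genes whose decay outruns a transcription shutoff
#'
#' A gene observed to drop `fold_down`-fold by `crossing_time_h` hours can be
#' explained by reduced transcription alone only if its half-life is at most
#' [shutoff_max_half_life()] of that drop. Genes whose atlas half-life
#' exceeds `margin` times the bound are flagged as actively destabilised.
#' `margin = 1` is the strict model argument; a margin around 1.5 absorbs
#' multiplicative measurement noise. Raising `margin` can only remove flags.
#'
#' @param events Suppression events from [suppression_events()].
#' @param atlas Half-life atlas tibble.
#' @param margin Multiplicative tolerance on the bound (default 1).
#' @return `events` joined with the atlas, plus `implied_max_half_life_h`
#'   and logical `flagged`; genes missing from the atlas are dropped with a
#'   message.
#' @export
flag_destabilized <- function(events, atlas, margin = 1) {
  if (margin <= 0) abort("`margin` must be > 0.")
  idx <- match(tolower(events$gene_id), tolower(atlas$gene_id))
  dropped <- sum(is.na(idx))
  if (dropped > 0) message(sprintf("dropping %d suppressed gene(s) without an atlas half-life.", dropped))
  out <- events[!is.na(idx), , drop = FALSE]
  out$t_half_hours <- atlas$t_half_hours[idx[!is.na(idx)]]
  out$implied_max_half_life_h <-
    shutoff_max_half_life(out$fold_down, out$crossing_time_h)
  out$flagged <- out$t_half_hours > margin * out$implied_max_half_life_h
  out
}
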