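#' First-crossing response times
#'
#' Assigns each gene the first sampled time (after t = 0) at which its log2
#' fold change crosses the induction (or suppression) threshold:
#' `|log2 FC| >= log2(fold_threshold)` in the requested direction. No
#' interpolation is done — response times are always sampled times, which is
#' what makes them usable as kinetic cluster labels. A gene that also
#' crosses the opposite threshold at some point is flagged `dual_response`
#' but keeps its first crossing in the requested direction.
#'
#' @param lfc Log2 fold-change time-course tibble (from
#'   [log2_fold_change()]).
#' @param fold_threshold Linear fold threshold (> 1); the default 2.0 means
#'   `|log2 FC| >= 1`.
#' @param direction `"up"` (induction) or `"down"` (suppression).
#' @return A tibble with columns `gene_id`, `direction` (`"up"`, `"down"` or
#'   `"none"`), `response_time` (hours, `NA` for non-responders),
#'   `max_abs_log2fc`, `cluster_label` (the response time as a factor) and
#'   `dual_response`.
#' @export
assign_response_time <- function(lfc, fold_threshold = 2, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (fold_threshold <= 1) abort("`fold_threshold` must be > 1.")
  times <- time_course_times(lfc)
  if (times[1] != 0) abort("the first sampling time must be 0.")
  m <- as.matrix(lfc[time_course_cols(lfc)])
  cut <- log2(fold_threshold)
  post <- m[, -1, drop = FALSE]
  t_post <- times[-1]

  first_cross <- function(mat, thr, sense) {
    hit <- if (sense == "up") mat >= thr else mat <= -thr
    idx <- apply(hit, 1, function(h) if (any(h)) which(h)[1] else NA_integer_)
    t_post[idx]
  }
  rt <- first_cross(post, cut, direction)
  other <- first_cross(post, cut, if (direction == "up") "down" else "up")

  responded <- !is.na(rt)
  levels_rt <- t_post
  tibble(
    gene_id = lfc[[1]],
    direction = ifelse(responded, direction, "none"),
    response_time = rt,
    max_abs_log2fc = apply(abs(m), 1, max),
    cluster_label = factor(rt, levels = levels_rt),
    dual_response = responded & !is.na(other)
  )
}

#' Scale each profile to its maximal fold of change
#'
#' Divides every gene's log2 fold-change profile by its maximal absolute
#' value, so genes with similar kinetics but different response magnitudes
#' become directly comparable (entries lie in [-1, 1]).
#'
#' @param lfc Log2 fold-change time-course tibble.
#' @return A time-course tibble of the same shape.
#' @export
normalize_to_max <- function(lfc) {
  m <- as.matrix(lfc[time_course_cols(lfc)])
  mx <- apply(abs(m), 1, max)
  if (any(mx == 0)) {
    abort("cannot normalise all-zero profiles (no change at any time point).")
  }
  as_time_course(m / mx, time_course_times(lfc), lfc[[1]], id_col = names(lfc)[1])
}

#' Kinetic clusters of responding genes
#'
#' Groups responders by their first-crossing time and summarises each
#' cluster by the mean normalised profile and its size.
#'
#' @param rt Response-time table from [assign_response_time()].
#' @param norm_lfc Normalised profiles from [normalize_to_max()] (same
#'   genes or a superset).
#' @return A tibble of class `kinetic_clusters`, long format: one row per
#'   cluster and time with `response_time`, `n_genes`, `time_h`,
#'   `mean_profile`.
#' @export
kinetic_clusters <- function(rt, norm_lfc) {
  resp <- rt[rt$direction != "none", , drop = FALSE]
  if (nrow(resp) == 0) abort("no responding genes to cluster.")
  idx <- match(resp$gene_id, norm_lfc[[1]])
  if (anyNA(idx)) abort("`norm_lfc` is missing profiles for some responders.")
  m <- as.matrix(norm_lfc[time_course_cols(norm_lfc)])[idx, , drop = FALSE]
  times <- time_course_times(norm_lfc)
  out <- tibble(
    response_time = rep(resp$response_time, each = length(times)),
    gene_id = rep(resp$gene_id, each = length(times)),
    time_h = rep(times, nrow(resp)),
    value = as.vector(t(m))
  ) %>%
    dplyr::group_by(.data$response_time, .data$time_h) %>%
    dplyr::summarise(
      mean_profile = mean(.data$value),
      n_genes = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$response_time, .data$time_h) %>%
    dplyr::select("response_time", "n_genes", "time_h", "mean_profile")
  class(out) <- c("kinetic_clusters", class(out))
  out
}

#' Partition responders into early and late sets
#'
#' Early genes respond at or before the cutoff ("before or at" — the
#' boundary is inclusive); late genes respond after it. Non-responders are
#' excluded.
#'
#' @param rt Response-time table.
#' @param cutoff Hours; default 2.
#' @return A list with character vectors `early` and `late`.
#' @export
partition_early_late <- function(rt, cutoff = 2) {
  resp <- rt[rt$direction != "none", , drop = FALSE]
  list(
    early = resp$gene_id[resp$response_time <= cutoff],
    late = resp$gene_id[resp$response_time > cutoff]
  )
}

#' Core set of recurrently early-induced genes
#'
#' Genes induced at or before `cutoff` hours in at least `min_datasets` of
#' the supplied datasets.
#'
#' @param tables List of response-time tables, one per dataset.
#' @param cutoff Early cutoff in hours (default 2).
#' @param min_datasets Minimum number of datasets with early induction
#'   (default 3).
#' @return A tibble with `gene_id` and `support_count`, sorted by
#'   decreasing support.
#' @export
identify_core_set <- function(tables, cutoff = 2, min_datasets = 3) {
  if (min_datasets < 1 || min_datasets > length(tables)) {
    abort("`min_datasets` must be between 1 and the number of datasets.")
  }
  early <- purrr::map(tables, function(t) partition_early_late(t, cutoff)$early)
  counts <- table(unlist(early))
  keep <- counts[counts >= min_datasets]
  tibble(
    gene_id = names(keep),
    support_count = as.integer(keep)
  ) %>%
    dplyr::arrange(dplyr::desc(.data$support_count), .data$gene_id)
}
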