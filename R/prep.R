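#' @importFrom dplyr %>%
#' @importFrom rlang .data
NULL

# Time-course tibbles carry one id column followed by columns named
# "t_<hours>h" ("t_0h", "t_0.5h", ...). These helpers parse and build them.

#' Sampling times of a time-course tibble
#'
#' @param x A time-course tibble whose measurement columns are named
#'   `t_<hours>h`.
#' @return Numeric vector of times in hours, in column order.
#' @export
time_course_times <- function(x) {
  cols <- time_course_cols(x)
  as.numeric(sub("^t_", "", sub("h$", "", cols)))
}

time_course_cols <- function(x) {
  cols <- grep("^t_[0-9.]+h$", names(x), value = TRUE)
  if (length(cols) == 0) abort("no time columns (named like 't_0.5h') found.")
  cols
}

time_col_names <- function(times) sprintf("t_%gh", times)

#' Assemble a time-course tibble from a matrix
#'
#' @param values Numeric matrix, genes (or probe-sets) in rows.
#' @param times Sampling times in hours, one per column, strictly increasing.
#' @param ids Row identifiers (unique).
#' @param id_col Name of the identifier column.
#' @return A tibble: `id_col`, then one `t_<hours>h` column per time.
#' @export
as_time_course <- function(values, times, ids, id_col = "gene_id") {
  if (ncol(values) != length(times)) abort("one time per value column required.")
  if (nrow(values) != length(ids)) abort("one id per row required.")
  if (anyDuplicated(ids)) abort("row ids must be unique.")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  out <- as_tibble(as.data.frame(values), .name_repair = "minimal")
  names(out) <- time_col_names(times)
  dplyr::bind_cols(tibble(!!id_col := ids), out)
}

time_course_matrix <- function(x) {
  m <- as.matrix(x[time_course_cols(x)])
  rownames(m) <- x[[1]]
  m
}

#' Read and write the package's tab-separated formats
#'
#' Plain TSV readers/writers for the standard inputs: an expression
#' time-course (id column + `t_<hours>h` columns, linear-scale intensities),
#' detection flags (id column + one P/A/M letter per chip), a probe-set to
#' gene mapping (`probe_id`, `gene_id`), a half-life atlas (`gene_id`,
#' `t_half_hours` or `t_half_minutes`), and transcript annotation
#' (`gene_id`, optionally `transcript_id`, `genomic_length_bp`,
#' `mature_length_bp`, optionally `utr3_sequence`).
#'
#' @param path File path.
#' @param log2_input If `TRUE` the stored expression values are log2 and are
#'   converted back to the linear scale on read.
#' @return A tibble (readers) or the path, invisibly (writers).
#' @name tsv_io
NULL

#' @rdname tsv_io
#' @export
read_expression_tsv <- function(path, log2_input = FALSE) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cols <- time_course_cols(x)
  if (log2_input) x[cols] <- lapply(x[cols], function(v) 2^v)
  m <- as.matrix(x[cols])
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort("expression intensities must be finite and strictly positive (linear scale).")
  }
  x
}

#' @rdname tsv_io
#' @export
write_expression_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_flags_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname tsv_io
#' @export
read_probe_map_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname tsv_io
#' @export
read_atlas_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("t_half_minutes" %in% names(x) && !"t_half_hours" %in% names(x)) {
    x$t_half_hours <- x$t_half_minutes / 60
    x$t_half_minutes <- NULL
  }
  if (!all(c("gene_id", "t_half_hours") %in% names(x))) {
    abort("atlas must have columns `gene_id` and `t_half_hours` (or `t_half_minutes`).")
  }
  if (any(x$t_half_hours <= 0)) abort("half-lives must be > 0.")
  if (anyDuplicated(x$gene_id)) abort("atlas gene ids must be unique.")
  x
}

#' @rdname tsv_io
#' @export
read_annotation_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "genomic_length_bp", "mature_length_bp") %in% names(x))) {
    abort("annotation needs `gene_id`, `genomic_length_bp`, `mature_length_bp`.")
  }
  if (any(x$genomic_length_bp < x$mature_length_bp)) {
    abort("genomic transcribed length must be >= mature transcript length.")
  }
  x
}

#' Read 3'-UTR sequences from FASTA
#'
#' Sequences are upper-cased and U is mapped to T, so RNA-form files are
#' accepted.
#'
#' @param path FASTA file.
#' @return Named character vector of DNA sequences.
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- canonicalize_dna(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA (60-character lines)
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_utr_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Retain probe-sets detected on enough chips
#'
#' MAS5-style presence filtering: keep rows flagged `'P'` (Present) on at
#' least `min_present` chips. `'M'` (Marginal) counts as not Present. Row
#' order is preserved.
#'
#' @param x Time-course tibble (probe-set or gene level).
#' @param flags Tibble with the same ids and one letter column per chip.
#' @param min_present Minimum number of Present calls (default 2).
#' @return The filtered time-course tibble.
#' @export
filter_by_presence <- function(x, flags, min_present = 2) {
  fcols <- setdiff(names(flags), names(flags)[1])
  xcols <- time_course_cols(x)
  if (length(fcols) != length(xcols)) {
    abort("flags must have one chip column per expression column.")
  }
  idx <- match(x[[1]], flags[[1]])
  if (anyNA(idx)) abort("flags are missing some row ids of `x`.")
  fm <- as.matrix(flags[idx, fcols])
  keep <- rowSums(fm == "P") >= min_present
  x[keep, , drop = FALSE]
}

#' Collapse probe-sets to genes by highest median intensity
#'
#' For genes measured by several probe-sets, the probe-set with the highest
#' median intensity across all chips represents the gene; its row is kept
#' verbatim. Ties go to the lexicographically smallest probe-set id.
#' Probe-sets absent from the mapping are dropped (a message reports how
#' many).
#'
#' @param x Probe-set level time-course tibble (first column: probe ids).
#' @param probe2gene Tibble with columns `probe_id` and `gene_id`.
#' @return Gene-level time-course tibble (first column `gene_id`), ordered
#'   by first appearance of each gene in `x`.
#' @export
collapse_probesets <- function(x, probe2gene) {
  if (nrow(probe2gene) == 0) abort("`probe2gene` mapping is empty.")
  xcols <- time_course_cols(x)
  idx <- match(x[[1]], probe2gene$probe_id)
  unmapped <- sum(is.na(idx))
  if (unmapped > 0) {
    message(sprintf("collapse_probesets: dropping %d unmapped probe-set(s).", unmapped))
  }
  mapped <- x[!is.na(idx), , drop = FALSE]
  gene <- probe2gene$gene_id[idx[!is.na(idx)]]
  med <- apply(as.matrix(mapped[xcols]), 1, stats::median)
  ord <- tibble(
    probe_id = mapped[[1]], gene_id = gene, med = med,
    .row = seq_len(nrow(mapped))
  ) %>%
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$med), .data$probe_id) %>%
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) %>%
    dplyr::arrange(.data$.row)
  out <- mapped[ord$.row, , drop = FALSE]
  names(out)[1] <- "gene_id"
  out$gene_id <- ord$gene_id
  out
}

#' Log2 fold change relative to the pre-stimulation time point
#'
#' @param x Time-course tibble whose first sampling time is 0 and whose
#'   intensities are linear-scale and strictly positive.
#' @return A tibble of the same shape holding `log2(x(t) / x(0))`; the t=0
#'   column is all zeros.
#' @export
log2_fold_change <- function(x) {
  times <- time_course_times(x)
  if (times[1] != 0) abort("the first sampling time must be 0 (pre-stimulation baseline).")
  m <- as.matrix(x[time_course_cols(x)])
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort("intensities must be finite and strictly positive.")
  }
  lfc <- log2(m / m[, 1])
  as_time_course(lfc, times, x[[1]], id_col = names(x)[1])
}

#' Pick one transcript per gene by maximal length
#'
#' Selects, per gene, the transcript of maximal genomic transcribed length
#' (or maximal 3'-UTR length, `key = "utr3"`). Ties go to the smallest
#' transcript id, so the choice is stable across runs.
#'
#' @param annotation Tibble with `gene_id`, `transcript_id`, and the length
#'   columns (plus `utr3_sequence` when `key = "utr3"`).
#' @param key `"genomic_length"` or `"utr3"`.
#' @return One row per gene.
#' @export
select_longest <- function(annotation, key = c("genomic_length", "utr3")) {
  key <- match.arg(key)
  if (!"transcript_id" %in% names(annotation)) {
    annotation$transcript_id <- annotation$gene_id
  }
  keyval <- switch(key,
    genomic_length = annotation$genomic_length_bp,
    utr3 = nchar(annotation$utr3_sequence)
  )
  annotation %>%
    dplyr::mutate(.key = keyval) %>%
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$.key), .data$transcript_id) %>%
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) %>%
    dplyr::select(-".key")
}
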