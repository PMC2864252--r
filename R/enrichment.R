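#' Canonicalise nucleotide sequences to DNA alphabet
#'
#' Upper-cases and maps U to T so RNA-form motifs and sequences behave
#' identically to their DNA form.
#' @param x Character vector of sequences or motifs.
#' @return Character vector over A/C/G/T/N.
#' @keywords internal
canonicalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Per-sequence presence of a k-mer
#'
#' Presence/absence of at least one exact occurrence of `kmer` in each
#' sequence (overlapping occurrences still count once: the statistic is
#' presence, not multiplicity). RNA-form input (U instead of T) is accepted
#' on both sides.
#'
#' @param seqs Named character vector of sequences (names are gene ids).
#' @param kmer The motif to look for, e.g. `"TATTTAT"` or `"UAUUUAU"`.
#' @return A tibble with columns `seq_id` and `present`; the containing
#'   fraction is attached as attribute `"fraction"`.
#' @examples
#' kmer_presence(c(g1 = "GGTATTTATGG", g2 = "GGGGGG"), "UAUUUAU")
#' @export
kmer_presence <- function(seqs, kmer) {
  if (length(seqs) == 0) abort("`seqs` must contain at least one sequence.")
  if (!nzchar(kmer)) abort("`kmer` must be non-empty.")
  seqs <- canonicalize_dna(seqs)
  kmer <- canonicalize_dna(kmer)
  present <- grepl(kmer, seqs, fixed = TRUE)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  out <- tibble(seq_id = ids, present = present)
  attr(out, "fraction") <- mean(present)
  out
}

#' Upper tail of the hypergeometric distribution
#'
#' `P[X >= x]` where `X` counts marked genes among `n` drawn without
#' replacement from a universe of `N` genes of which `K` are marked: the
#' standard enrichment p-value for gene-set and motif overlaps.
#'
#' @param x Observed overlap (0 <= x <= min(n, K)).
#' @param n Foreground (drawn) set size.
#' @param K Marked genes in the universe.
#' @param N Universe size.
#' @return The tail probability.
#' @examples
#' hypergeometric_tail(x = 2, n = 2, K = 2, N = 4) # 1/6
#' @export
hypergeometric_tail <- function(x, n, K, N) {
  bad <- x < 0 | n < 0 | K < 0 | N < 0 | x > n | n > N | K > N | x > K
  if (any(bad)) {
    abort("inconsistent counts: need 0 <= x <= min(n, K), n <= N and K <= N.")
  }
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

# Presence counts of every k-mer across a set of sequences, chunked so the
# count matrix never exceeds ~65 MB.
all_kmer_presence_counts <- function(seqs, k, chunk = 500L) {
  ss <- Biostrings::DNAStringSet(canonicalize_dna(seqs))
  acc <- NULL
  idx <- split(seq_along(ss), ceiling(seq_along(ss) / chunk))
  for (i in idx) {
    m <- Biostrings::oligonucleotideFrequency(ss[i], width = k)
    cnt <- colSums(m > 0)
    acc <- if (is.null(acc)) cnt else acc + cnt
  }
  acc
}

#' Exhaustive k-mer presence enrichment scan
#'
#' Scores every k-mer over {A,C,G,T} by the hypergeometric upper tail of its
#' presence count in the foreground sequences against the background
#' universe, with Benjamini-Hochberg q-values. By default the foreground
#' genes are part of the background universe (enrichment against *all*
#' 3'-UTRs, not the complement).
#'
#' @param fg_seqs Named character vector: foreground 3'-UTR sequences.
#' @param bg_seqs Named character vector: background 3'-UTR sequences.
#' @param k k-mer length (1..12).
#' @param include_fg_in_bg If `TRUE` (default) the universe is the union of
#'   background and foreground; if `FALSE` the background alone.
#' @return A tibble sorted by ascending p-value with columns `kmer`, `x`,
#'   `n`, `K`, `N`, `fg_fraction`, `bg_fraction`, `p_value`, `q_value`.
#' @export
scan_kmers <- function(fg_seqs, bg_seqs, k = 7, include_fg_in_bg = TRUE) {
  if (k < 1 || k > 12) abort("`k` must be between 1 and 12.")
  if (length(fg_seqs) == 0 || length(bg_seqs) == 0) {
    abort("foreground and background sequence sets must be non-empty.")
  }
  uni_seqs <- if (include_fg_in_bg) c(bg_seqs, fg_seqs) else bg_seqs
  x <- all_kmer_presence_counts(fg_seqs, k)
  K <- all_kmer_presence_counts(uni_seqs, k)
  n <- length(fg_seqs)
  N <- length(uni_seqs)
  p <- hypergeometric_tail(x, n, K, N)
  out <- tibble(
    kmer = names(x), x = as.integer(x), n = n, K = as.integer(K), N = N,
    fg_fraction = x / n, bg_fraction = K / N,
    p_value = p, q_value = stats::p.adjust(p, method = "BH")
  )
  dplyr::arrange(out, .data$p_value, .data$kmer)
}

#' Category (GO-style) enrichment of a gene set
#'
#' For each category, the hypergeometric upper tail of its overlap with
#' `gene_set` inside `universe`, BH-corrected across categories.
#'
#' @param gene_set Character vector of gene ids, a subset of `universe`.
#' @param categories Named list of character vectors (category members).
#' @param universe Character vector: all genes eligible for the test.
#' @return A tibble sorted by ascending p-value with one row per category
#'   and the same count/fraction columns as [scan_kmers()].
#' @export
category_enrichment <- function(gene_set, categories, universe) {
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  universe <- unique(universe)
  if (!all(gene_set %in% universe)) {
    abort("`gene_set` must be a subset of `universe`.")
  }
  if (length(categories) == 0) abort("`categories` must be a non-empty named list.")
  gene_set <- unique(gene_set)
  n <- length(gene_set)
  N <- length(universe)
  rows <- purrr::imap(categories, function(members, id) {
    members <- intersect(unique(members), universe)
    K <- length(members)
    x <- length(intersect(members, gene_set))
    tibble(
      category = id, x = x, n = n, K = K, N = N,
      fg_fraction = if (n > 0) x / n else NA_real_,
      bg_fraction = K / N,
      p_value = hypergeometric_tail(x, n, K, N)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value, .data$category)
}
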