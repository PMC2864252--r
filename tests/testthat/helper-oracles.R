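# Independent numerical oracles used across the suite. These deliberately
# avoid the package's closed-form code paths.

# 4th-order Runge-Kutta integration of dX/dt = beta - alpha * X
rk4_transition <- function(t_end, beta, alpha, x0, h = 1e-3) {
  if (t_end == 0) return(x0)
  f <- function(x) beta - alpha * x
  n <- ceiling(t_end / h)
  h <- t_end / n
  x <- x0
  for (i in seq_len(n)) {
    k1 <- f(x)
    k2 <- f(x + h / 2 * k1)
    k3 <- f(x + h / 2 * k2)
    k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# Full enumeration of the rank-sum null: every subset of size n_a of the
# combined midranks is equally likely.
bf_ranksum_p <- function(a, b, alternative) {
  r <- rank(c(a, b))
  n_a <- length(a)
  idx <- utils::combn(length(r), n_a)
  sums <- colSums(matrix(r[idx], nrow = n_a))
  w <- sum(r[seq_len(n_a)])
  p_less <- mean(sums <= w + 1e-9)
  p_greater <- mean(sums >= w - 1e-9)
  switch(alternative,
    less = p_less,
    greater = p_greater,
    two.sided = min(1, 2 * min(p_less, p_greater))
  )
}

# Exhaustive enumeration of hypergeometric draws: all subsets of size n from
# a universe of N items of which the first K are marked.
bf_hyper_tail <- function(x, n, K, N) {
  idx <- utils::combn(N, n)
  marked <- colSums(idx <= K)
  mean(marked >= x)
}

# A small, fast synthetic configuration for unit tests.
small_cfg <- function(seed = 1, ...) {
  args <- list(
    n_genes = 120, n_induced = 40, n_suppressed = 20,
    motif_fg_size = 10, utr_length_range = c(50, 200), seed = seed
  )
  args <- utils::modifyList(args, list(...))
  do.call(synthetic_config, args)
}

# Build a time-course tibble from a plain matrix quickly.
tc <- function(values, times, ids = sprintf("g%02d", seq_len(nrow(values)))) {
  as_time_course(values, times, ids)
}
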