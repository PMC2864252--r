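#' @importFrom rlang abort
#' @importFrom tibble tibble as_tibble
NULL

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0)) {
    abort("`alpha` (degradation rate constant, per hour) must be finite and > 0.")
  }
  invisible(alpha)
}

#' Steady-state mRNA level of the first-order kinetic model
#'
#' Under `dX/dt = beta - alpha * X`, synthesis balances decay at
#' `X_ss = beta / alpha`.
#'
#' @param beta Transcription rate (concentration per hour, >= 0). Vectorised.
#' @param alpha Degradation rate constant (per hour, > 0). Vectorised.
#' @return Steady-state concentration(s) `beta / alpha`.
#' @examples
#' steady_state_level(beta = 5, alpha = 2)
#' @export
steady_state_level <- function(beta, alpha) {
  check_alpha(alpha)
  if (any(beta < 0)) abort("`beta` must be >= 0.")
  beta / alpha
}

#' Convert between degradation rate and half-life
#'
#' In the first-order model any transition between steady states covers
#' half of its remaining distance every `T_1/2 = ln(2) / alpha` hours; the
#' same quantity is the decay half-life.
#'
#' @param alpha Degradation rate constant (per hour, > 0).
#' @param t_half Half-life in hours (> 0).
#' @return Half-life in hours, or rate in per hour for the inverse.
#' @examples
#' half_life_from_rate(log(2)) # 1 hour
#' rate_from_half_life(274 / 60) # the mouse atlas median
#' @export
half_life_from_rate <- function(alpha) {
  check_alpha(alpha)
  log(2) / alpha
}

#' @rdname half_life_from_rate
#' @export
rate_from_half_life <- function(t_half) {
  if (!is.numeric(t_half) || any(!is.finite(t_half)) || any(t_half <= 0)) {
    abort("`t_half` must be finite and > 0.")
  }
  log(2) / t_half
}

#' Closed-form transition between steady states
#'
#' Solution of `dX/dt = beta - alpha * X` from initial level `x0`:
#' `X(t) = x0 + (beta/alpha - x0) * (1 - exp(-alpha * t))`. The level moves
#' monotonically toward `beta/alpha`, covering half the remaining distance
#' every `ln(2)/alpha` hours.
#'
#' @param t Time(s) since the rate change, hours (>= 0).
#' @inheritParams steady_state_level
#' @param x0 Concentration at `t = 0` (>= 0).
#' @return Concentration(s) at time `t`.
#' @examples
#' transition_level(log(2) / 1, beta = 5, alpha = 1) # half of X_ss
#' @export
transition_level <- function(t, beta, alpha, x0 = 0) {
  check_alpha(alpha)
  if (any(t < 0)) abort("`t` must be >= 0 (hours after the rate change).")
  if (any(x0 < 0)) abort("`x0` must be >= 0.")
  x0 + (beta / alpha - x0) * (1 - exp(-alpha * t))
}

#' Time to reach a k-fold induction
#'
#' When the transcription rate of a gene at steady state rises by a factor
#' `L`, the time to observe a `k`-fold increase in abundance is
#' `T_k = -log2(1 - f) * t_half` with `f = (k - 1) / (L - 1)`: linear in the
#' transcript's half-life at fixed (`k`, `L`).
#'
#' @param k Fold of induction to reach (>= 1).
#' @param L Factor by which the transcription rate increased (> 1).
#' @param t_half Transcript half-life, hours (> 0).
#' @return Time in hours. `k == L` asks for the new steady state itself and
#'   returns `Inf`; `k > L` is unattainable and errors.
#' @examples
#' time_to_fold_induction(k = 2, L = 3, t_half = 1) # exactly one half-life
#' @export
time_to_fold_induction <- function(k, L, t_half) {
  if (any(L <= 1)) abort("`L` must be > 1 (an increase in transcription rate).")
  if (any(k < 1)) abort("`k` must be >= 1.")
  if (any(t_half <= 0)) abort("`t_half` must be > 0.")
  if (any(k > L)) {
    abort("`k` > `L`: a k-fold induction above the new steady state is unattainable.")
  }
  f <- (k - 1) / (L - 1)
  # f == 1 (k == L) gives the asymptote: +Inf, not an error
  -log2(1 - f) * t_half
}

#' Simulate a transcriptional pulse
#'
#' Evaluates the abundance trajectory for a square pulse of transcription:
#' rate `beta_on` on `[t_on, t_off)` and `beta_off` elsewhere, switching
#' instantaneously at the edges. Each constant-rate segment is evaluated with
#' the closed-form transition (no numerical integration).
#'
#' @inheritParams steady_state_level
#' @param beta_on,beta_off Transcription rates during / outside the pulse.
#' @param x0 Level at the first grid time.
#' @param t_on,t_off Pulse start and end, hours (`t_on < t_off`).
#' @param grid Strictly increasing sampling times, hours; must start at or
#'   before `t_on`.
#' @return A tibble with columns `time_h` and `level`.
#' @examples
#' simulate_pulse(alpha = 0.2, beta_on = 5, grid = seq(0, 10, 0.5))
#' @export
simulate_pulse <- function(alpha, beta_on, beta_off = 0, x0 = 0,
                           t_on = 0, t_off = 5, grid) {
  check_alpha(alpha)
  if (missing(grid) || length(grid) == 0) abort("`grid` must be a non-empty time grid.")
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing.")
  if (t_on >= t_off) abort("`t_on` must be earlier than `t_off`.")
  if (grid[1] > t_on) abort("`grid` must start at or before `t_on`.")
  if (any(c(beta_on, beta_off) < 0) || x0 < 0) abort("rates and `x0` must be >= 0.")

  beta_at <- function(t) if (t >= t_on && t < t_off) beta_on else beta_off
  events <- sort(unique(c(grid, t_on, t_off)))
  events <- events[events >= grid[1]]
  lev <- numeric(length(events))
  lev[1] <- x0
  for (i in seq_along(events)[-1]) {
    dt <- events[i] - events[i - 1]
    b <- beta_at(events[i - 1])
    lev[i] <- transition_level(dt, beta = b, alpha = alpha, x0 = lev[i - 1])
  }
  keep <- events %in% grid
  tibble(time_h = events[keep], level = lev[keep])
}

#' Transcription rate needed to hit a target level at a given time
#'
#' Inverts the closed-form transition for `beta`: the rate such that a
#' transcript with decay rate `alpha`, starting from `x0`, reaches
#' `target_level` exactly at `t_end`. Used to equalise trajectories of
#' transcripts with different stabilities at a common time point.
#'
#' @param target_level Level to reach (>= 0).
#' @inheritParams steady_state_level
#' @param t_end Time at which the target must be met, hours (> 0).
#' @param x0 Level at `t = 0`.
#' @return The calibrated transcription rate `beta`.
#' @examples
#' calibrate_beta_for_level(5, alpha = 1, t_end = 5)
#' @export
calibrate_beta_for_level <- function(target_level, alpha, t_end, x0 = 0) {
  check_alpha(alpha)
  if (t_end <= 0) abort("`t_end` must be > 0.")
  floor_level <- x0 * exp(-alpha * t_end)
  if (target_level < floor_level) {
    abort("`target_level` is unreachable: it lies below the level after pure decay from `x0`.")
  }
  alpha * (target_level - floor_level) / (1 - exp(-alpha * t_end))
}

#' Maximal half-life compatible with a fold-decrease under shutoff
#'
#' With transcription completely shut off (`beta = 0`) a transcript decays as
#' `X(t) = x0 * exp(-alpha * t)`. Observing a `fold_down`-fold decrease by
#' time `t` therefore requires `T_1/2 <= t * ln(2) / ln(fold_down)`. A
#' transcript whose measured half-life exceeds this bound must have been
#' actively destabilised.
#'
#' @param fold_down Observed fold-decrease (> 1), linear scale.
#' @param t Hours after stimulation at which the decrease was observed (> 0).
#' @return The maximal compatible half-life in hours.
#' @examples
#' shutoff_max_half_life(fold_down = 2, t = 1) # 1 hour
#' @export
shutoff_max_half_life <- function(fold_down, t) {
  if (any(fold_down <= 1)) abort("`fold_down` must be > 1 (a decrease).")
  if (any(t <= 0)) abort("`t` must be > 0.")
  t * log(2) / log(fold_down)
}
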