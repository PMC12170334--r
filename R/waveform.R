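# Mitral inflow velocity waveforms. A waveform object carries both uniform
# samples over one period and a continuous periodic evaluator, so that
# resampling at any density is exact and C1 statements can be checked
# directly.

#' Construct a velocity waveform
#'
#' @param times sample times in s, uniform, spanning `[0, T)`.
#' @param velocity velocities in m/s at `times`.
#' @param period period T in s.
#' @param fun optional vectorized continuous evaluator `f(t)` (periodic);
#'   when absent a periodic cubic spline through the samples is used.
#' @return object of class `velocity_waveform`.
#' @export
velocity_waveform <- function(times, velocity, period, fun = NULL) {
  stopifnot(length(times) == length(velocity), period > 0,
            all(diff(times) > 0), times[1] >= 0,
            times[length(times)] < period,
            all(is.finite(velocity)))
  if (is.null(fun)) {
    sf <- stats::splinefun(c(times, period), c(velocity, velocity[1]),
                           method = "periodic")
    fun <- function(t) sf(t %% period)
  }
  structure(list(times = as.numeric(times), velocity = as.numeric(velocity),
                 period = as.numeric(period), fun = fun),
            class = "velocity_waveform")
}

#' @exportS3Method base::print
print.velocity_waveform <- function(x, ...) {
  cat(sprintf(
    "velocity_waveform: T = %.3f s, %d samples, peak %.3f m/s, %d local max\n",
    x$period, length(x$times), max(x$velocity), length(local_maxima(x))))
  invisible(x)
}

# indices of strict local maxima of the sampled waveform, periodic
local_maxima <- function(wf) {
  v <- wf$velocity
  n <- length(v)
  prev <- v[c(n, 1:(n - 1))]
  nxt <- v[c(2:n, 1)]
  which(v > prev & v >= nxt & v > 1e-12)
}

# smooth non-negative periodic bump: raised cosine on support of half-width w
cos_bump <- function(t, centre, w, period) {
  d <- (t - centre) %% period
  d <- ifelse(d > period / 2, d - period, d)
  ifelse(abs(d) < w, 0.5 * (1 + cos(pi * d / w))^2 / 2, 0)
}

#' Generate a two-peaked (E/A) mitral inflow waveform
#'
#' Smooth periodic waveform with an early-diastolic E-wave and, when
#' `a_peak > 0`, a later atrial-contraction A-wave, emulating a
#' phase-contrast mitral inflow profile.
#'
#' @param e_peak E-wave peak velocity, m/s.
#' @param a_peak A-wave peak velocity, m/s (0 for a single-peaked profile).
#' @param period cycle period, s.
#' @param n_samples number of uniform samples over the period (>= 32).
#' @param seed unused placeholder for interface symmetry (the waveform is
#'   deterministic).
#' @return a [velocity_waveform()]. If `a_peak > e_peak` a warning flags the
#'   atypical profile.
#' @export
generate_mitral_waveform <- function(e_peak = 0.8, a_peak = 0.5,
                                     period = 1.0, n_samples = 128L,
                                     seed = NULL) {
  stopifnot(e_peak >= 0, a_peak >= 0, period > 0, n_samples >= 32)
  if (a_peak > e_peak) warning("a_peak > e_peak: atypical E/A reversal")
  t_e <- 0.18 * period; w_e <- 0.16 * period
  t_a <- 0.72 * period; w_a <- 0.13 * period
  f <- function(t)
    e_peak * cos_bump(t, t_e, w_e, period) +
    a_peak * cos_bump(t, t_a, w_a, period)
  times <- seq(0, period, length.out = n_samples + 1L)[1:n_samples]
  velocity_waveform(times, f(times), period, fun = f)
}

#' Remove the mitral A-wave to emulate atrial fibrillation inflow
#'
#' Locates diastasis (the minimum between the E- and A-peaks) and replaces
#' the waveform from diastasis to the end of the cycle with a cubic Hermite
#' branch that decays to the cycle-start value with matching end slopes, so
#' the result is C1-continuous and periodic, keeps the E-wave segment
#' exactly, and has a single local maximum. Single-peaked input is returned
#' unchanged (the operation is idempotent).
#'
#' @param waveform a [velocity_waveform()].
#' @return a [velocity_waveform()] with one local maximum.
#' @export
remove_a_wave <- function(waveform) {
  pk <- local_maxima(waveform)
  if (length(pk) <= 1L) return(waveform)
  pk <- pk[order(waveform$velocity[pk], decreasing = TRUE)[1:2]]
  pk <- sort(pk)
  v <- waveform$velocity
  seg <- pk[1]:pk[2]
  i_d <- seg[which.min(v[seg])]
  t_d <- waveform$times[i_d]
  T_ <- waveform$period
  f0 <- waveform$fun
  eps <- 1e-6 * T_
  v_d <- f0(t_d)
  s_d <- (f0(t_d + eps) - f0(t_d - eps)) / (2 * eps)
  v_0 <- f0(0)
  s_0 <- (f0(eps) - f0(T_ - eps)) / (2 * eps)  # periodic slope at 0
  h <- T_ - t_d
  hermite <- function(t) {
    u <- (t - t_d) / h
    h00 <- (1 + 2 * u) * (1 - u)^2
    h10 <- u * (1 - u)^2
    h01 <- u^2 * (3 - 2 * u)
    h11 <- u^2 * (u - 1)
    h00 * v_d + h10 * h * s_d + h01 * v_0 + h11 * h * s_0
  }
  f_new <- function(t) {
    tt <- t %% T_
    ifelse(tt < t_d, f0(tt), pmax(0, hermite(tt)))
  }
  velocity_waveform(waveform$times, f_new(waveform$times), T_, fun = f_new)
}
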