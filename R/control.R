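## Perception and kernel-based transition rates -------------------------------

#' Perceptual signal: normalised rate of change of concentration
#'
#' The larva's only sensory input is `phi = (1/C) dC/dt`, discretised as a
#' backward difference normalised by the current concentration with a small
#' floor on the denominator. Positive when moving up-gradient, negative when
#' moving down.
#'
#' @param c_now,c_prev concentrations at the head tip on the current and
#'   previous step (>= 0).
#' @param dt time step, s.
#' @param eps floor on the normalising concentration.
#' @return phi in 1/s (vectorised).
#' @export
perceive <- function(c_now, c_prev, dt = 0.1, eps = 1e-12) {
  stopifnot(dt > 0)
  (c_now - c_prev) / (pmax(c_now, eps) * dt)
}

#' Linear transition kernel
#'
#' A linear weight profile over the recent perceptual history: weight
#' `k_end` on the most recent sample (lag 0) rising/falling linearly to
#' `k_start` at lag `duration`. The run-termination kernel (duration 20 s,
#' start 2, end -2) responds to a worsening trend in phi; the
#' cast-termination kernel (0.5 s, start 0, end 150) fires on a sharp recent
#' increase.
#'
#' @param duration kernel duration, s.
#' @param k_start weight at the oldest covered sample (lag = duration).
#' @param k_end weight at the most recent sample (lag = 0).
#' @param scaling global multiplier; 0 disables the mechanism's modulation,
#'   negative values reverse it.
#' @return a `kernel_spec` object.
#' @export
kernel_linear <- function(duration, k_start, k_end, scaling = 1) {
  if (duration <= 0) stop("kernel duration must be positive")
  structure(list(form = "linear", duration = duration,
                 k_start = k_start, k_end = k_end, scaling = scaling),
            class = "kernel_spec")
}

#' Differenced-mean transition kernel
#'
#' Weights such that the dot product with the perceptual history equals
#' `k_mult * (mean of the last t_short seconds - mean of the last t_long
#' seconds)`. Applied to a constant history it is exactly zero; it responds
#' to short-term rises in phi relative to the longer-term average, which is
#' what the weathervaning mechanism needs during forward motion.
#'
#' @param t_short,t_long averaging windows, s (`t_long > t_short`).
#' @param k_mult multiplicative factor.
#' @param scaling global multiplier as in [kernel_linear()].
#' @return a `kernel_spec` object.
#' @export
kernel_differenced_mean <- function(t_short = 1, t_long = 10, k_mult = 30,
                                    scaling = 1) {
  if (t_short <= 0 || t_long <= 0) stop("kernel duration must be positive")
  stopifnot(t_long > t_short)
  structure(list(form = "differenced_mean", t_short = t_short, t_long = t_long,
                 k_mult = k_mult, scaling = scaling),
            class = "kernel_spec")
}

#' Rescale a kernel
#' @param spec a `kernel_spec`.
#' @param scaling multiplier applied on top of the existing scaling.
#' @return the rescaled `kernel_spec`.
#' @export
scale_kernel <- function(spec, scaling) {
  stopifnot(inherits(spec, "kernel_spec"))
  spec$scaling <- spec$scaling * scaling
  spec
}

#' Continuous kernel weight at a given lag
#' @param spec a `kernel_spec`.
#' @param lag lag into the past, s (0 = most recent).
#' @param dt sampling interval used for the differenced-mean windows, s.
#' @return kernel weight(s) at the requested lag(s).
#' @export
kernel_weight <- function(spec, lag, dt = 0.1) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$form == "linear") {
    w <- spec$k_end + (spec$k_start - spec$k_end) * lag / spec$duration
    w[lag < 0 | lag > spec$duration] <- 0
  } else {
    n_short <- round(spec$t_short / dt)
    n_long <- round(spec$t_long / dt)
    w <- ifelse(lag < spec$t_short, spec$k_mult * (1 / n_short - 1 / n_long),
                ifelse(lag < spec$t_long, -spec$k_mult / n_long, 0))
    w[lag < 0] <- 0
  }
  w * spec$scaling
}

#' Sample a kernel on the simulation time grid
#'
#' Returns the weight sequence ordered most-recent-first (element 1 = lag 0).
#' Linear kernels are sampled at lags `0, dt, ..., duration - dt`
#' (`duration/dt` samples), so the weight on the most recent sample equals
#' the kernel's end value exactly. With this grid the default run-termination
#' kernel sums to `-2`, not zero: a sustained negative perceptual signal
#' (steadily falling concentration) raises the run-termination rate even
#' when the signal has no trend, which is the klinokinetic response the
#' mechanism exists for. Differenced-mean kernels are sampled over the long
#' window and sum to exactly zero on constant histories.
#'
#' @param spec a `kernel_spec`.
#' @param dt sampling interval, s. The kernel magnitudes of the default
#'   parameter set are tied to dt = 0.1 s (the rate sums carry no extra dt
#'   factor); changing dt requires rescaling the kernels.
#' @return numeric vector of weights, most recent first.
#' @export
sample_kernel <- function(spec, dt = 0.1) {
  stopifnot(inherits(spec, "kernel_spec"), dt > 0)
  if (spec$form == "linear") {
    n <- round(spec$duration / dt)
    lags <- (seq_len(n) - 1) * dt
    spec$scaling * (spec$k_end + (spec$k_start - spec$k_end) * lags / spec$duration)
  } else {
    n_short <- round(spec$t_short / dt)
    n_long <- round(spec$t_long / dt)
    w <- rep(-spec$k_mult / n_long, n_long)
    w[seq_len(n_short)] <- spec$k_mult * (1 / n_short - 1 / n_long)
    spec$scaling * w
  }
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$form == "linear")
    cat(sprintf("<kernel> linear, %gs, start %g end %g, scaling %g\n",
                x$duration, x$k_start, x$k_end, x$scaling))
  else
    cat(sprintf("<kernel> differenced mean, %gs vs %gs, mult %g, scaling %g\n",
                x$t_short, x$t_long, x$k_mult, x$scaling))
  invisible(x)
}

#' Transition rate from a perceptual history
#'
#' `rate = max(0, base + sum_k kernel[k] * phi(t - k dt))`, the literal
#' per-sample dot product of the sampled kernel with the recent history (no
#' additional dt weighting). With an all-zero history the rate equals the
#' base rate exactly.
#'
#' @param kernel sampled kernel weights (most recent first), from
#'   [sample_kernel()].
#' @param history phi samples, most recent first; shorter histories are
#'   zero-padded.
#' @param base base transition rate, 1/s.
#' @return transition rate in 1/s (>= 0).
#' @export
transition_rate <- function(kernel, history, base) {
  stopifnot(base >= 0 || is.finite(base))
  rate_from_history_cpp(as.double(kernel), as.double(history), as.double(base))
}

#' Convert a rate to a per-step transition probability
#' @param rate transition rate, 1/s (>= 0).
#' @param dt time step, s.
#' @return `min(1, rate * dt)` (vectorised).
#' @export
rate_to_probability <- function(rate, dt = 0.1) {
  stopifnot(all(rate >= 0), dt > 0)
  pmin(1, rate * dt)
}
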