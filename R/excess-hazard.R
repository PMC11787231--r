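#' Excess-hazard shape after return-to-play
#'
#' Parametric shapes for the transient excess of injury hazard in the days
#' after return-to-play (RTP), used by the synthetic cohort generator as the
#' ground-truth hazard. Two families are available:
#'
#' * `exp_decay()` — the excess starts at its full amplitude on the RTP day
#'   and halves every `half_time` days:
#'   \eqn{h(t) = \lambda_0 (1 + e \, 2^{-t/\tau})}.
#' * `delayed_peak()` — the excess builds up first, peaks near `peak_delay`
#'   days, then decays:
#'   \eqn{h(t) = \lambda_0 (1 + e \,(t/d)\, e^{1 - t/d}\, 2^{-t/\tau})},
#'   with \eqn{h(0) = \lambda_0}.
#'
#' In both families the hazard tends to the baseline \eqn{\lambda_0} as
#' \eqn{t \to \infty}.
#'
#' @param amplitude Excess amplitude \eqn{e \ge 0}; `amplitude = 1` means a
#'   two-fold hazard at the peak of the excess.
#' @param half_time Half-time \eqn{\tau > 0} of the decay, in days.
#' @param peak_delay Delay \eqn{d > 0} of the peak, in days
#'   (`delayed_peak()` only).
#'
#' @return An object of class `excess_params`.
#' @seealso [excess_hazard()]
#' @export
#' @examples
#' exp_decay(amplitude = 1, half_time = 25)
#' delayed_peak(peak_delay = 10)
exp_decay <- function(amplitude = 1, half_time = 25) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1, amplitude >= 0,
            is.numeric(half_time), length(half_time) == 1, half_time > 0)
  structure(
    list(family = "exp_decay", amplitude = amplitude, half_time = half_time),
    class = "excess_params"
  )
}

#' @rdname exp_decay
#' @export
delayed_peak <- function(amplitude = 1, half_time = 25, peak_delay = 10) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1, amplitude >= 0,
            is.numeric(half_time), length(half_time) == 1, half_time > 0,
            is.numeric(peak_delay), length(peak_delay) == 1, peak_delay > 0)
  structure(
    list(family = "delayed_peak", amplitude = amplitude,
         half_time = half_time, peak_delay = peak_delay),
    class = "excess_params"
  )
}

#' @export
print.excess_params <- function(x, ...) {
  extra <- if (x$family == "delayed_peak") {
    sprintf(", peak delay %g d", x$peak_delay)
  } else ""
  cat(sprintf("<excess_params: %s, amplitude %g, half-time %g d%s>\n",
              x$family, x$amplitude, x$half_time, extra))
  invisible(x)
}

#' Per-day hazard at a given time since return-to-play
#'
#' Evaluates the ground-truth post-RTP hazard of the synthetic cohort:
#' the baseline per-day rate \eqn{\lambda_0} multiplied by the excess
#' shape described by `params` (see [exp_decay()] and [delayed_peak()]).
#'
#' @param t Days since RTP (vectorised, all values `>= 0`).
#' @param params An `excess_params` object.
#' @param baseline Baseline per-day hazard \eqn{\lambda_0 > 0}.
#'
#' @return Numeric vector of per-day hazards, same length as `t`.
#' @export
#' @examples
#' excess_hazard(c(0, 25), exp_decay(amplitude = 1, half_time = 25), 0.005)
excess_hazard <- function(t, params, baseline) {
  if (!inherits(params, "excess_params")) {
    stop("`params` must be an `excess_params` object (see exp_decay()).")
  }
  stopifnot(is.numeric(t), is.numeric(baseline), length(baseline) == 1)
  if (baseline <= 0) stop("`baseline` hazard must be positive.")
  if (any(t < 0)) stop("`t` must be non-negative (days since RTP).")
  e <- params$amplitude
  tau <- params$half_time
  decay <- 2^(-t / tau)
  factor <- switch(
    params$family,
    exp_decay = 1 + e * decay,
    delayed_peak = {
      d <- params$peak_delay
      1 + e * (t / d) * exp(1 - t / d) * decay
    },
    stop("unknown excess family: ", params$family)
  )
  baseline * factor
}
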