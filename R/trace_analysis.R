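# Trace-level statistics: baseline handling, alkaline-pool sizes,
# exponential time-constant fits and surface-pool reconstruction.

#' Subtract the pre-stimulus baseline from a trace
#'
#' @param trace A [fluorescence_trace()].
#' @param window `c(t0, t1)` in seconds; the mean over this window is
#'   subtracted. Idempotent (re-applying subtracts ~0).
#' @return The baseline-subtracted [fluorescence_trace()].
#' @export
baseline_subtract <- function(trace, window) {
  stopifnot(inherits(trace, "fluor_trace"), length(window) == 2)
  idx <- which(trace$time >= window[1] & trace$time <= window[2])
  if (length(idx) == 0) stop_param(FALSE, "baseline window is empty")
  out <- trace
  out$values <- trace$values - mean(trace$values[idx])
  out
}

# sliding-window slope (intensity per second) at each sample; windows of
# `width` seconds, forward-looking, NA-padded at the tail
window_slopes <- function(trace, width) {
  w <- max(2L, round(width * trace$frame_rate))
  n <- length(trace$values)
  slopes <- rep(NA_real_, n)
  if (n >= w) {
    i <- seq_len(n - w + 1L)
    slopes[i] <- (trace$values[i + w - 1L] - trace$values[i]) /
      (trace$time[i + w - 1L] - trace$time[i])
  }
  slopes
}

#' Static alkaline-pool size from a single acid-switch trace
#'
#' After the bath is switched to pH 5.5 at the end of the stimulus, the
#' fluorescence first drops steeply (surface quench) and then decays slowly
#' (reacidification of the alkaline population). The static pool size is
#' the fluorescence difference between the end of the quench and the final
#' stable baseline, relative to the total response amplitude:
#' `(F_end_of_quench - F_stable_baseline) / total_amplitude`.
#'
#' The end of quench is the first sample whose forward `slope_window`-second
#' slope falls below `slope_tol`; the stable baseline is the mean of the
#' last such window.
#'
#' @param trace A [fluorescence_trace()] covering the post-switch segment
#'   (quench plateau through final baseline).
#' @param total_amplitude Peak stimulus response (same intensity units).
#' @param slope_tol Stability tolerance, intensity per second. Default
#'   1% of `total_amplitude` per second.
#' @param slope_window Window for the slope estimate, seconds (default 5).
#' @return A fraction (of `total_amplitude`), with the located
#'   `quench_end_time` (seconds) and `baseline` level as attributes. Note
#'   that the quench end is found where the decay has slowed below the
#'   tolerance, i.e. a few seconds after the actual bath switch; the
#'   returned size refers to the alkaline population remaining at that
#'   relaxed time point.
#' @export
static_avp_size <- function(trace, total_amplitude, slope_tol = NULL,
                            slope_window = 5) {
  stopifnot(inherits(trace, "fluor_trace"))
  stop_param(is_pos_scalar(total_amplitude),
             "total_amplitude must be positive")
  if (is.null(slope_tol)) slope_tol <- 0.01 * total_amplitude
  slopes <- window_slopes(trace, slope_window)
  stable <- which(!is.na(slopes) & abs(slopes) < slope_tol)
  if (length(stable) == 0)
    stop_protocol("no stable plateau found after the acid switch")
  quench_end <- stable[1]
  w <- max(2L, round(slope_window * trace$frame_rate))
  last_start <- stable[length(stable)]
  if (trace$time[last_start] - trace$time[quench_end] < slope_window)
    stop_protocol("no stable final baseline within the trace")
  baseline <- mean(trace$values[last_start:min(length(trace$values),
                                               last_start + w - 1L)])
  structure((trace$values[quench_end] - baseline) / total_amplitude,
            quench_end_time = trace$time[quench_end],
            baseline = baseline)
}

#' Relative alkaline-pool size from phase-split traces
#'
#' Divides the maximal pH 5.5 amplitude by the maximal pH 7.5 amplitude,
#' both taken over a post-stimulus window on baseline-subtracted traces.
#'
#' @param trace_55,trace_75 Baseline-subtracted [fluorescence_trace()]s of
#'   the two phases.
#' @param window Optional `c(t0, t1)` seconds restricting where the maxima
#'   are taken (default: whole traces).
#' @return A list of class `avp_size_result`: `relative_size`, `amp_55`,
#'   `amp_75`.
#' @export
relative_avp_size <- function(trace_55, trace_75, window = NULL) {
  stopifnot(inherits(trace_55, "fluor_trace"),
            inherits(trace_75, "fluor_trace"))
  pick <- function(tr) {
    v <- tr$values
    if (!is.null(window))
      v <- v[tr$time >= window[1] & tr$time <= window[2]]
    if (length(v) == 0) stop_param(FALSE, "window contains no samples")
    max(v)
  }
  amp_55 <- pick(trace_55)
  amp_75 <- pick(trace_75)
  if (amp_75 <= 0)
    stop(errorCondition("relative pool size undefined: non-positive pH 7.5 amplitude",
                        class = c("avpdyn_undefined_ratio", "error")))
  structure(list(relative_size = amp_55 / amp_75,
                 amp_55 = amp_55, amp_75 = amp_75),
            class = "avp_size_result")
}

#' Fit a monoexponential decay
#'
#' Least-squares fit of `a * exp(-(t - t_start)/tau) + c` to the trace for
#' `t >= t_start`, by Levenberg-Marquardt with starting values from a
#' log-linear regression on the offset-subtracted data. A non-decaying
#' segment yields `converged = FALSE` rather than an error.
#'
#' @param trace A [fluorescence_trace()].
#' @param t_start Fit window start, seconds.
#' @param fit_offset Estimate the additive offset `c` (default `TRUE`;
#'   otherwise `c = 0`).
#' @return A list of class `exp_fit_result`: `tau` (seconds), `amplitude`,
#'   `offset`, `rss`, `converged`, `fitted` (values over the fit window),
#'   `time`.
#' @export
fit_exp_decay <- function(trace, t_start = NULL, fit_offset = TRUE) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (is.null(t_start)) t_start <- trace$time[1]
  idx <- which(trace$time >= t_start)
  if (length(idx) < 10)
    stop_param(FALSE, "need at least 10 samples after t_start")
  t <- trace$time[idx] - t_start
  y <- trace$values[idx]

  failed <- function() structure(
    list(tau = NA_real_, amplitude = NA_real_, offset = NA_real_,
         rss = NA_real_, converged = FALSE, fitted = NULL, time = t + t_start),
    class = "exp_fit_result")

  c0 <- if (fit_offset) min(y) - 1e-3 * abs(diff(range(y))) else 0
  pos <- y - c0
  if (all(pos <= 0) || diff(range(y)) == 0) return(failed())
  pos[pos <= 0] <- min(pos[pos > 0])
  ll <- stats::lm(log(pos) ~ t)
  slope <- unname(stats::coef(ll)[2])
  if (!is.finite(slope) || slope >= 0) return(failed())
  tau0 <- -1 / slope
  a0 <- unname(exp(stats::coef(ll)[1]))

  fit <- tryCatch({
    if (fit_offset)
      minpack.lm::nlsLM(y ~ a * exp(-t / tau) + cc,
                        start = list(a = a0, tau = tau0, cc = c0),
                        lower = c(-Inf, 1e-6, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ a * exp(-t / tau),
                        start = list(a = a0, tau = tau0),
                        lower = c(-Inf, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) return(failed())
  cf <- stats::coef(fit)
  structure(list(tau = unname(cf["tau"]),
                 amplitude = unname(cf["a"]),
                 offset = if (fit_offset) unname(cf["cc"]) else 0,
                 rss = sum(stats::resid(fit)^2),
                 converged = cf["tau"] > 0 && cf["a"] > 0,
                 fitted = stats::fitted(fit),
                 time = t + t_start),
            class = "exp_fit_result")
}

#' Reconstruct the surface-pool time course
#'
#' The pH 7.5 trace tracks `S + A` and the pH 5.5 trace tracks `A`, so
#' their pointwise difference is the surface pool `S(t)`. The two phase
#' traces sample disjoint times; both are linearly interpolated onto a
#' common grid before subtraction. The post-stimulus decay of the result,
#' fitted with [fit_exp_decay()], yields the endocytosis time constant.
#'
#' @param trace_75,trace_55 Phase [fluorescence_trace()]s (ideally
#'   baseline-subtracted per phase).
#' @param grid Optional time grid (seconds); default: uniform at the pH 7.5
#'   trace's frame rate across the overlap of the two traces.
#' @return A [fluorescence_trace()] of the difference on the common grid.
#' @export
surface_pool_trace <- function(trace_75, trace_55, grid = NULL) {
  stopifnot(inherits(trace_75, "fluor_trace"),
            inherits(trace_55, "fluor_trace"))
  lo <- max(min(trace_75$time), min(trace_55$time))
  hi <- min(max(trace_75$time), max(trace_55$time))
  if (lo >= hi) stop_param(FALSE, "trace time ranges do not overlap")
  if (is.null(grid)) grid <- seq(lo, hi, by = 1 / trace_75$frame_rate)
  v75 <- stats::approx(trace_75$time, trace_75$values, grid, rule = 2)$y
  v55 <- stats::approx(trace_55$time, trace_55$values, grid, rule = 2)$y
  fluorescence_trace(v75 - v55, trace_75$frame_rate, time = grid)
}
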