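# Endocytosis kinetics by FFT deconvolution.
#
# Under the assumption that endocytosis is the only input and
# reacidification the only output of the alkaline vesicle population, the
# alkaline time course A(t) is the convolution of the endocytosis rate
# course E(t) with the reacidification kernel R(t) = exp(-t/tau_reac).
# Dividing the Fourier transforms recovers E; because raw division is very
# noise-sensitive, the division carries a Tikhonov guard and is applied to
# an alpha-function smoothing of A rather than to raw data.

#' Fit an alpha function to the alkaline-population time course
#'
#' Least-squares fit of
#' `k * (t - stim_start - delay) * exp(-(t - stim_start - delay)/tau_alpha)`
#' for `t` beyond the delay (zero before), the unimodal smoothing used
#' before deconvolution. The fitted curve peaks at
#' `stim_start + delay + tau_alpha`.
#'
#' @param trace A baseline-subtracted [fluorescence_trace()] covering the
#'   rise and decay of the alkaline population.
#' @param stim_start Stimulus onset, seconds.
#' @return A list of class `alpha_fit_result`: `k`, `delay`, `tau_alpha`,
#'   `rss`, `converged`, `stim_start`, and `predict(t)` for sampling the
#'   fitted curve.
#' @export
fit_alpha <- function(trace, stim_start) {
  stopifnot(inherits(trace, "fluor_trace"))
  t <- trace$time
  y <- trace$values

  failed <- function() structure(
    list(k = NA_real_, delay = NA_real_, tau_alpha = NA_real_,
         rss = NA_real_, converged = FALSE, stim_start = stim_start,
         predict = function(tt) rep(NA_real_, length(tt))),
    class = "alpha_fit_result")

  peak_i <- which.max(y)
  if (y[peak_i] <= 0 || t[peak_i] <= stim_start) return(failed())
  rise <- t[peak_i] - stim_start
  tau0 <- max(rise / 2, 1e-2)
  delay0 <- max(rise - tau0, 0)
  k0 <- y[peak_i] / (tau0 * exp(-1))

  alpha_val <- function(tt, k, delay, tau) {
    u <- tt - stim_start - delay
    ifelse(u > 0, k * u * exp(-u / tau), 0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ alpha_val(t, k, delay, tau),
                      start = list(k = k0, delay = delay0, tau = tau0),
                      lower = c(-Inf, 0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  cf <- stats::coef(fit)
  structure(list(k = unname(cf["k"]), delay = unname(cf["delay"]),
                 tau_alpha = unname(cf["tau"]),
                 rss = sum(stats::resid(fit)^2),
                 converged = cf["tau"] > 0 && cf["k"] > 0,
                 stim_start = stim_start,
                 predict = function(tt)
                   alpha_val(tt, cf["k"], cf["delay"], cf["tau"])),
            class = "alpha_fit_result")
}

#' Deconvolve the endocytosis time course from the alkaline kinetics
#'
#' Divides the FFT of the (smoothed) alkaline-population time course by the
#' FFT of the reacidification kernel `R(t) = exp(-t/tau_reac) * dt` and
#' inverse-transforms, with a Tikhonov guard
#' `E = ifft( A * Conj(R) / (|R|^2 + eps * max|R|^2) )`. The input is
#' zero-padded to at least twice its length to avoid circular wrap-around.
#' The post-peak segment of the recovered course is fitted with
#' [fit_exp_decay()] to give the endocytosis time constant.
#'
#' @param input Either an `alpha_fit_result` (its fitted curve is sampled
#'   on the `dt` grid from the stimulus start over `duration` seconds), a
#'   [fluorescence_trace()] (resampled onto the `dt` grid), or a numeric
#'   vector already sampled at `dt`.
#' @param tau_reac Reacidification time constant, seconds (> 0).
#' @param dt Deconvolution grid step, seconds (default 0.1; finer than the
#'   effective phase sampling, which the smooth fitted input permits).
#' @param eps Tikhonov regularisation relative to the peak kernel power
#'   (default 1e-6; `0` reproduces the plain division, which is only safe
#'   for noiseless inputs).
#' @param duration Sampling duration when `input` is an alpha fit
#'   (default 120 s).
#' @return A list of class `deconv_result`: `endo_course` (data frame
#'   `time`, `rate`), `tau_endo` (seconds), `regularization_eps`, `fit`
#'   (the `exp_fit_result` of the post-peak decay).
#' @export
deconvolve_endocytosis <- function(input, tau_reac, dt = 0.1, eps = 1e-6,
                                   duration = 120) {
  stop_param(is_pos_scalar(tau_reac), "tau_reac must be positive seconds")
  stop_param(is_pos_scalar(dt), "dt must be positive seconds")
  stop_param(is.numeric(eps) && eps >= 0, "eps must be >= 0")

  if (inherits(input, "alpha_fit_result")) {
    if (!input$converged) stop_param(FALSE, "alpha fit did not converge")
    tt <- seq(0, duration, by = dt)
    a <- input$predict(tt + input$stim_start)
  } else if (inherits(input, "fluor_trace")) {
    tt <- seq(min(input$time), max(input$time), by = dt)
    a <- stats::approx(input$time, input$values, tt)$y
    tt <- tt - tt[1]
  } else {
    a <- as.numeric(input)
    tt <- (seq_along(a) - 1) * dt
  }
  n <- length(a)
  npad <- 2L * n
  apad <- c(a, rep(0, npad - n))
  kern <- exp(-(seq_len(npad) - 1) * dt / tau_reac) * dt

  ahat <- stats::fft(apad)
  rhat <- stats::fft(kern)
  pow <- Mod(rhat)^2
  denom <- pow + eps * max(pow)
  if (any(denom == 0))
    stop(errorCondition("kernel spectrum vanishes and eps = 0: division undefined",
                        class = c("avpdyn_numeric_error", "error")))
  ehat <- ahat * Conj(rhat) / denom
  e <- Re(stats::fft(ehat, inverse = TRUE)) / npad
  e <- e[seq_len(n)]

  peak_i <- which.max(e)
  fit <- fit_exp_decay(fluorescence_trace(e, 1 / dt, time = tt),
                       t_start = tt[peak_i])
  structure(list(endo_course = data.frame(time = tt, rate = e),
                 tau_endo = fit$tau,
                 regularization_eps = eps,
                 fit = fit),
            class = "deconv_result")
}
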