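# Two-pool first-order kinetics of synaptic vesicle recycling.
#
# State: S (surface pool, fused pHluorin awaiting retrieval), A (alkaline
# vesicle population: endocytosed, not yet reacidified), Q (reacidified
# vesicles). Exocytosis feeds S at a constant rate during the stimulus;
# endocytosis S -> A and reacidification A -> Q are first order. During
# acid (pH 5.5) bath phases endocytosed vesicles are already acidic, so
# retrieval routes S -> Q directly and A only drains.
#
# The system is piecewise linear-time-invariant, so each segment between
# breakpoints (stimulus edges, solution exchanges) is propagated exactly
# with a matrix exponential on the augmented state (S, A, Q, 1).

# generator matrix for one segment; `rate` is the exocytosis rate
avp_generator <- function(rate, tau_endo, tau_reac, acid) {
  M <- matrix(0, 4, 4)
  M[1, 1] <- -1 / tau_endo
  M[1, 4] <- rate
  if (acid) {
    M[2, 2] <- -1 / tau_reac
    M[3, 1] <- 1 / tau_endo
    M[3, 2] <- 1 / tau_reac
  } else {
    M[2, 1] <- 1 / tau_endo
    M[2, 2] <- -1 / tau_reac
    M[3, 2] <- 1 / tau_reac
  }
  M
}

avp_deriv <- function(x, rate, tau_endo, tau_reac, acid) {
  S <- x[1]; A <- x[2]
  if (acid) {
    c(rate - S / tau_endo, -A / tau_reac, S / tau_endo + A / tau_reac, 0)
  } else {
    c(rate - S / tau_endo, S / tau_endo - A / tau_reac, A / tau_reac, 0)
  }
}

# propagate the trajectory over a uniform grid, cutting each dt step at any
# interior breakpoint so segment propagation stays exact
simulate_cascade <- function(params, stim, dt, t_end, cycling = NULL,
                             method = c("exact", "rk4")) {
  method <- match.arg(method)
  stop_param(is_pos_scalar(dt), "dt must be a positive number of seconds")
  stop_param(is.numeric(t_end) && t_end > 0, "t_end must be positive")
  stopifnot(inherits(params, "kinetic_params"),
            inherits(stim, "stimulus_protocol"))
  if (t_end < stim$start_time + stim$duration)
    stop_protocol("simulation window does not cover the stimulus")

  time <- seq(0, t_end, by = dt)
  n <- length(time)
  stim_on <- stim$start_time
  stim_off <- stim$start_time + stim$duration
  rate_stim <- if (stim$duration > 0) params$total_release / stim$duration else 0

  bp <- c(stim_on, stim_off)
  if (!is.null(cycling)) {
    period <- cycling$acid_phase_len + cycling$alkaline_phase_len
    edges <- seq(cycling$cycling_start, t_end, by = period)
    bp <- c(bp, edges, edges + if (cycling$first_phase == "acid")
      cycling$acid_phase_len else cycling$alkaline_phase_len)
  }
  bp <- sort(unique(bp[bp > 0 & bp < t_end]))

  seg_rate <- function(t0) if (t0 >= stim_on - 1e-12 && t0 < stim_off - 1e-12)
    rate_stim else 0
  seg_acid <- function(t0) !is.null(cycling) &&
    phase_at(cycling, t0 + 1e-9) == "pH5.5"

  cache <- new.env(parent = emptyenv())
  prop_exact <- function(x, t0, h) {
    r <- seg_rate(t0); ac <- seg_acid(t0)
    key <- paste(r, ac, signif(h, 12))
    P <- cache[[key]]
    if (is.null(P)) {
      M <- avp_generator(r, params$tau_endo, params$tau_reac, ac)
      P <- as.matrix(Matrix::expm(Matrix::Matrix(M * h)))
      cache[[key]] <- P
    }
    drop(P %*% x)
  }
  prop_rk4 <- function(x, t0, h) {
    r <- seg_rate(t0); ac <- seg_acid(t0)
    nsub <- max(1L, ceiling(h / dt))
    hh <- h / nsub
    for (i in seq_len(nsub)) {
      k1 <- avp_deriv(x, r, params$tau_endo, params$tau_reac, ac)
      k2 <- avp_deriv(x + hh / 2 * k1, r, params$tau_endo, params$tau_reac, ac)
      k3 <- avp_deriv(x + hh / 2 * k2, r, params$tau_endo, params$tau_reac, ac)
      k4 <- avp_deriv(x + hh * k3, r, params$tau_endo, params$tau_reac, ac)
      x <- x + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    x
  }
  prop <- if (method == "exact") prop_exact else prop_rk4

  out <- matrix(0, n, 3)
  x <- c(0, 0, 0, 1)
  for (i in seq_len(n - 1L)) {
    t0 <- time[i]; t1 <- time[i + 1L]
    cuts <- bp[bp > t0 + 1e-12 & bp < t1 - 1e-12]
    tt <- c(t0, cuts, t1)
    for (j in seq_len(length(tt) - 1L))
      x <- prop(x, tt[j], tt[j + 1L] - tt[j])
    out[i + 1L, ] <- x[1:3]
  }

  cum <- pmin(pmax(time - stim_on, 0) * rate_stim, params$total_release)
  traj <- data.frame(time = time,
                     surface = out[, 1],
                     alkaline = out[, 2],
                     acidified = out[, 3],
                     cumulative_exo = cum,
                     ph_label = phase_at(cycling, time),
                     stringsAsFactors = FALSE)
  structure(traj,
            class = c("avp_trajectory", "data.frame"),
            params = params, stimulus = stim, cycling = cycling,
            dt = dt, method = method)
}

#' Simulate vesicle-pool dynamics without pH-cycling ("ideal" model)
#'
#' Integrates the linear cascade
#' \deqn{dS/dt = r(t) - S/\tau_{endo},\quad
#'       dA/dt = S/\tau_{endo} - A/\tau_{reac},\quad
#'       dQ/dt = A/\tau_{reac}}
#' where the exocytosis rate \eqn{r(t)} is constant during the stimulus
#' (total release divided by stimulus duration) and zero otherwise. The
#' integrator propagates the state exactly with matrix exponentials per
#' linear segment; `method = "rk4"` is a classical Runge-Kutta fallback.
#'
#' @param params A [kinetic_params()].
#' @param stim A [stimulus_protocol()].
#' @param dt Sampling step in seconds (default 0.05).
#' @param t_end End of the simulation, seconds; must cover the stimulus.
#' @param method `"exact"` (matrix exponential) or `"rk4"`.
#' @return A data frame of class `avp_trajectory` with columns `time`,
#'   `surface`, `alkaline`, `acidified`, `cumulative_exo`, `ph_label`.
#' @examples
#' traj <- simulate_ideal(kinetic_params(), stimulus_protocol(100, 20), t_end = 120)
#' max(traj$alkaline) / max(traj$surface + traj$alkaline)
#' @export
simulate_ideal <- function(params, stim, dt = 0.05, t_end = 242,
                           method = c("exact", "rk4")) {
  simulate_cascade(params, stim, dt, t_end, cycling = NULL,
                   method = match.arg(method))
}

#' Simulate vesicle-pool dynamics under pH-cycling ("realistic" model)
#'
#' Identical to [simulate_ideal()] during pH 7.5 phases. During pH 5.5
#' phases endocytosed vesicles are already acidic and bypass the alkaline
#' pool: \eqn{dA/dt = -A/\tau_{reac}},
#' \eqn{dQ/dt = A/\tau_{reac} + S/\tau_{endo}}. Before `cycling_start` the
#' model behaves as the ideal one.
#'
#' @inheritParams simulate_ideal
#' @param cycling A [cycling_protocol()]; its `total_duration` sets the
#'   simulation length and must cover the stimulus window.
#' @return An `avp_trajectory` whose `ph_label` column tags each sample with
#'   the bath phase.
#' @export
simulate_realistic <- function(params, stim, cycling, dt = 0.05,
                               method = c("exact", "rk4")) {
  stopifnot(inherits(cycling, "cycling_protocol"))
  if (cycling$total_duration < stim$start_time + stim$duration)
    stop_protocol("cycling protocol does not cover the stimulus window")
  simulate_cascade(params, stim, dt, cycling$total_duration,
                   cycling = cycling, method = match.arg(method))
}

#' Relative alkaline-pool size of a simulated trajectory
#'
#' Ratio of the peak detectable alkaline-population signal to the peak
#' detectable total (pH 7.5) signal, mirroring the experimental measure in
#' which the maximal pH 5.5 and pH 7.5 fluorescence amplitudes are divided
#' by each other. The pH 7.5 signal is \eqn{S + A} (internal alkaline
#' vesicles fluoresce regardless of bath pH); the pH 5.5 signal is \eqn{A}.
#'
#' @param traj An `avp_trajectory`.
#' @param detected_only For pH-cycling trajectories, take each maximum only
#'   over samples in the matching bath phase (what the optical measurement
#'   can see). Ignored for ideal runs. Default `TRUE`.
#' @param normalize `"total"` (denominator `max(S + A)`, default) or
#'   `"surface"` (`max(S)`).
#' @param deadtime Seconds excluded at the start of each bath phase when
#'   `detected_only` (emulates the frames an image analysis discards around
#'   each solution exchange; default 0).
#' @return A fraction in \[0, 1\].
#' @export
relative_avp_size_model <- function(traj, detected_only = TRUE,
                                    normalize = c("total", "surface"),
                                    deadtime = 0) {
  stopifnot(inherits(traj, "avp_trajectory"))
  normalize <- match.arg(normalize)
  if (max(traj$cumulative_exo) <= 0)
    stop_param(FALSE, "trajectory has no exocytosis; ratio undefined")
  f75 <- if (normalize == "total") traj$surface + traj$alkaline else
    traj$surface
  cyc <- attr(traj, "cycling")
  if (!is.null(cyc) && detected_only) {
    acid <- traj$ph_label == "pH5.5"
    if (!any(acid) || !any(!acid))
      stop_protocol("cycling protocol leaves one phase unsampled")
    keep <- rep(TRUE, nrow(traj))
    if (deadtime > 0) {
      period <- cyc$acid_phase_len + cyc$alkaline_phase_len
      u <- (traj$time - cyc$cycling_start) %% period
      into_phase <- ifelse(u < cyc$acid_phase_len, u,
                           u - cyc$acid_phase_len)
      if (cyc$first_phase == "alkaline")
        into_phase <- ifelse(u < cyc$alkaline_phase_len, u,
                             u - cyc$alkaline_phase_len)
      keep <- traj$time < cyc$cycling_start | into_phase >= deadtime
    }
    num <- max(traj$alkaline[acid & keep])
    den <- max(f75[!acid & keep])
  } else {
    num <- max(traj$alkaline)
    den <- max(f75)
  }
  if (den <= 0)
    stop(errorCondition("relative alkaline-pool size undefined: zero denominator",
                        class = c("avpdyn_undefined_ratio", "error")))
  num / den
}

#' Underestimation of the relative alkaline-pool size caused by pH-cycling
#'
#' Acid-phase endocytosis bypasses the alkaline state, so the relative pool
#' size measured under cycling is smaller than the true (ideal) one. This
#' returns `1 - rel_realistic / rel_ideal`, with the realistic relative size
#' taken over in-phase samples only.
#'
#' @inheritParams simulate_realistic
#' @return A fraction in \[0, 1).
#' @export
underestimation <- function(params, stim, cycling, dt = 0.05) {
  ideal <- simulate_ideal(params, stim, dt = dt,
                          t_end = cycling$total_duration)
  real <- simulate_realistic(params, stim, cycling, dt = dt)
  1 - relative_avp_size_model(real, detected_only = TRUE) /
    relative_avp_size_model(ideal)
}

#' Fraction of measured fluorescence contributed by the surface pool
#'
#' At rest, a fraction `s` of the marker sits on the plasma membrane
#' (unquenched at pH 7.5) while the remaining `1 - s` is inside acidic
#' vesicles, quenched `q`-fold. The surface pool then contributes
#' \deqn{s / (s + (1 - s)/q)} of the total measured marker fluorescence.
#' With `s = 0.24, q = 20` (synapto-pHluorin) this is about 0.86; with
#' `s = 0.03` (VGLUT1-pHluorin) about 0.38.
#'
#' @param surface_fraction Resting surface fraction of the marker, in
#'   \[0, 1\].
#' @param quench_factor Fold-quenching between pH 7.5 and pH 5.5 (>= 1).
#' @return A fraction in \[0, 1\].
#' @export
surface_fluorescence_fraction <- function(surface_fraction,
                                          quench_factor = 20) {
  stop_param(is.numeric(surface_fraction) && length(surface_fraction) == 1 &&
               surface_fraction >= 0 && surface_fraction <= 1,
             "surface_fraction must be in [0, 1]")
  stop_param(is.numeric(quench_factor) && length(quench_factor) == 1 &&
               quench_factor >= 1, "quench_factor must be >= 1")
  s <- surface_fraction
  s / (s + (1 - s) / quench_factor)
}
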