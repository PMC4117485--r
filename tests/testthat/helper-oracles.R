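# Independent closed-form solution of the ideal two-compartment cascade
# driven by a boxcar exocytosis rate. Derived by hand from the variation-of-
# constants formula; deliberately does not share any code with the
# package's matrix-exponential integrator.
#
#   dS/dt = r(t) - S/te,  dA/dt = S/te - A/tr,
#   r(t) = R/D on [t0, t0 + D), else 0.
#
# Requires te != tr (all oracle test cases satisfy this).
cascade_oracle <- function(tau_e, tau_r, total_release, n_ap, freq,
                           stim_start, t) {
  D <- n_ap / freq
  r <- if (D > 0) total_release / D else 0
  beta <- (tau_e - tau_r) / (tau_e * tau_r)   # 1/tr - 1/te

  S_stim <- function(u) r * tau_e * (1 - exp(-u / tau_e))
  A_stim <- function(u) r * tau_r * (1 - exp(-u / tau_r)) -
    (r / beta) * (exp(-u / tau_e) - exp(-u / tau_r))

  S1 <- S_stim(D)
  A1 <- A_stim(D)
  S_free <- function(v) S1 * exp(-v / tau_e)
  A_free <- function(v) A1 * exp(-v / tau_r) +
    (S1 / (tau_e * beta)) * (exp(-v / tau_e) - exp(-v / tau_r))

  u <- t - stim_start
  S <- ifelse(u <= 0, 0, ifelse(u <= D, S_stim(pmax(u, 0)),
                                S_free(pmax(u - D, 0))))
  A <- ifelse(u <= 0, 0, ifelse(u <= D, A_stim(pmax(u, 0)),
                                A_free(pmax(u - D, 0))))
  cum <- pmin(pmax(u, 0) * r, total_release)
  data.frame(time = t, surface = S, alkaline = A, cumulative_exo = cum)
}
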