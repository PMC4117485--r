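# Shared fixtures: the standard recording protocol and a few canned
# synthetic experiments, built in code at test time.

std_params <- function(...) kinetic_params(tau_endo = 17, tau_reac = 4, ...)
std_cycling <- function(...) cycling_protocol(2, 2, 28, 242, "acid", ...)

# the stimulus grid used throughout: AP-number series at 20 Hz plus
# frequency series at 200 AP
std_grid <- function() rbind(
  data.frame(n_ap = c(50, 100, 200, 400), freq = 20),
  data.frame(n_ap = 200, freq = c(10, 40, 80)))

# single-switch protocol: pH 7.5 until the stimulus ends, then pH 5.5 for
# the rest of the recording (the static-measurement protocol)
single_switch <- function(switch_time = 50, total = 242)
  cycling_protocol(acid_phase_len = 2 * total,
                   alkaline_phase_len = switch_time,
                   cycling_start = 0, total_duration = total,
                   first_phase = "alkaline")

# standard cycling synthetic trace (200 AP @ 20 Hz unless overridden)
std_synth <- function(noise_sd = 0, n_ap = 200, freq = 20, seed = 1, ...) {
  cyc <- std_cycling()
  traj <- simulate_realistic(std_params(), stimulus_protocol(n_ap, freq),
                             cyc)
  synth_trace(traj, cyc, fluor_model(noise_sd = noise_sd, ...),
              frame_rate = 10, seed = seed)
}
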