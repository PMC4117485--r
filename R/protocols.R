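#' Kinetic parameters of the vesicle-recycling cascade
#'
#' Bundles the first-order time constants of compensatory endocytosis and
#' vesicle reacidification together with the cumulative amount of exocytosis
#' evoked by one stimulus. Units are seconds for the time constants and
#' dimensionless "vesicle units" for the release; all downstream ratios
#' (relative alkaline-pool size, underestimation) are invariant to the
#' release scale because the kinetics are linear.
#'
#' @param tau_endo Endocytosis time constant in seconds (> 0). Default 17 s,
#'   a literature value for moderate stimuli at hippocampal boutons.
#' @param tau_reac Reacidification time constant in seconds (> 0). Default
#'   4 s.
#' @param total_release Cumulative exocytosis per stimulus, in vesicle units
#'   (> 0). Default 1.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(tau_endo = 17, tau_reac = 4, total_release = 1) {
  stop_param(is_pos_scalar(tau_endo), "tau_endo must be a positive number")
  stop_param(is_pos_scalar(tau_reac), "tau_reac must be a positive number")
  stop_param(is_pos_scalar(total_release),
             "total_release must be a positive number")
  structure(list(tau_endo = tau_endo, tau_reac = tau_reac,
                 total_release = total_release),
            class = "kinetic_params")
}

#' Electrical stimulation protocol
#'
#' @param n_ap Number of action potentials (>= 0).
#' @param frequency Stimulation frequency in Hz (> 0).
#' @param start_time Stimulus onset in seconds from recording start.
#' @return An object of class `stimulus_protocol` with a derived `duration`
#'   field (`n_ap / frequency` seconds).
#' @export
stimulus_protocol <- function(n_ap, frequency, start_time = 40) {
  stop_param(is.numeric(n_ap) && length(n_ap) == 1 && n_ap >= 0,
             "n_ap must be a non-negative count")
  stop_param(is_pos_scalar(frequency), "frequency must be positive (Hz)")
  stop_param(is.numeric(start_time) && length(start_time) == 1 &&
               start_time >= 0, "start_time must be non-negative seconds")
  structure(list(n_ap = n_ap, frequency = frequency,
                 start_time = start_time, duration = n_ap / frequency),
            class = "stimulus_protocol")
}

#' Extracellular pH-cycling protocol
#'
#' Describes alternating perfusion with pH 5.5 (acid) and pH 7.5 (alkaline)
#' solutions. Before `cycling_start` the bath is held at pH 7.5; from
#' `cycling_start` onward acid and alkaline phases alternate, beginning with
#' `first_phase`. The default protocol mirrors a 242 s recording with 2 s
#' solution exchange, cycling from 28 s.
#'
#' @param acid_phase_len,alkaline_phase_len Phase lengths in seconds (> 0).
#' @param cycling_start Time at which cycling begins, seconds.
#' @param total_duration Total protocol length, seconds
#'   (>= `cycling_start`).
#' @param first_phase `"acid"` or `"alkaline"`: which phase starts the
#'   cycling.
#' @return An object of class `cycling_protocol`.
#' @export
cycling_protocol <- function(acid_phase_len = 2, alkaline_phase_len = 2,
                             cycling_start = 28, total_duration = 242,
                             first_phase = c("acid", "alkaline")) {
  first_phase <- match.arg(first_phase)
  stop_param(is_pos_scalar(acid_phase_len) && is_pos_scalar(alkaline_phase_len),
             "phase lengths must be positive seconds")
  stop_param(is.numeric(cycling_start) && cycling_start >= 0,
             "cycling_start must be non-negative seconds")
  stop_param(total_duration >= cycling_start,
             "total_duration must be >= cycling_start")
  structure(list(acid_phase_len = acid_phase_len,
                 alkaline_phase_len = alkaline_phase_len,
                 cycling_start = cycling_start,
                 total_duration = total_duration,
                 first_phase = first_phase),
            class = "cycling_protocol")
}

#' pH phase at given times
#'
#' Vectorised lookup of the bath pH implied by a cycling protocol. Times
#' before `cycling_start` are pH 7.5 (the pre-cycling baseline). A sample
#' falling exactly on a solution exchange takes the new phase's label.
#'
#' @param cycling A [cycling_protocol()], or `NULL` (constant pH 7.5).
#' @param t Numeric vector of times in seconds.
#' @return Character vector, `"pH5.5"` or `"pH7.5"`.
#' @export
phase_at <- function(cycling, t) {
  if (is.null(cycling)) return(rep("pH7.5", length(t)))
  stopifnot(inherits(cycling, "cycling_protocol"))
  period <- cycling$acid_phase_len + cycling$alkaline_phase_len
  u <- (t - cycling$cycling_start) %% period
  # guard against 239.9999999 %% 4 style round-off at exchange times
  u <- ifelse(abs(u - period) < 1e-9, 0, u)
  if (cycling$first_phase == "acid") {
    acid <- u < cycling$acid_phase_len - 1e-9
  } else {
    acid <- u >= cycling$alkaline_phase_len - 1e-9
  }
  acid <- acid & (t >= cycling$cycling_start - 1e-9)
  ifelse(acid, "pH5.5", "pH7.5")
}

# internal validation helpers ------------------------------------------------

is_pos_scalar <- function(x) is.numeric(x) && length(x) == 1 &&
  is.finite(x) && x > 0

stop_param <- function(ok, msg) {
  if (!ok) stop(errorCondition(msg, class = c("avpdyn_param_error", "error")))
  invisible(TRUE)
}

stop_protocol <- function(msg) {
  stop(errorCondition(msg, class = c("avpdyn_protocol_error", "error")))
}
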