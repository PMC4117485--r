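# End-to-end orchestration: the simulation sweeps and the synthetic /
# recorded analysis chain, with YAML configuration and a reproducibility
# manifest.

default_run_config <- function() {
  list(
    kinetics = list(tau_endo_s = 17, tau_reac_s = 4),
    stimulus = list(start_s = 40),
    sweeps = list(n_ap = c(50, 100, 200, 400), n_ap_freq_hz = 20,
                  freq_hz = c(10, 20, 40, 80), freq_n_ap = 200),
    cycling = list(acid_s = 2, alkaline_s = 2, start_s = 28,
                   total_s = 242, first_phase = "acid"),
    sim = list(dt_s = 0.05),
    seed = 0
  )
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration (or accepts a list) and validates it against
#' the known schema; unknown top-level keys are rejected with their paths.
#' Missing blocks fall back to the defaults, which encode the standard
#' recording protocol (242 s, 2 s exchanges from 28 s, stimulus at 40 s,
#' tau_endo 17 s, tau_reac 4 s).
#'
#' @param config A file path to a YAML file, or a (possibly partial) list.
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_param(FALSE,
      paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  def <- default_run_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0)
    stop_param(FALSE, paste("unknown config keys:",
                            paste(unknown, collapse = ", ")))
  for (blk in names(config)) {
    if (is.list(def[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(def[[blk]]))
      if (length(bad) > 0)
        stop_param(FALSE, paste0("unknown config keys: ",
                                 paste(paste0(blk, ".", bad), collapse = ", ")))
      def[[blk]][names(config[[blk]])] <- config[[blk]]
    } else {
      def[[blk]] <- config[[blk]]
    }
  }
  structure(def, class = c("run_config", "list"))
}

#' Run the ideal-versus-realistic simulation sweeps
#'
#' Reproduces the two standard stimulus sweeps (action-potential number at
#' fixed frequency; frequency at fixed pulse count) for the ideal and
#' pH-cycling models, reporting the relative alkaline-pool size of each and
#' the resulting underestimation. Cumulative release is scaled with the
#' number of action potentials (all reported ratios are invariant to this
#' scale).
#'
#' @param config A configuration accepted by [read_run_config()].
#' @param out_dir Optional directory; when given, writes
#'   `simulation_sweeps.csv` and a `manifest.json`.
#' @return A data frame with one row per protocol: `sweep`, `n_ap`,
#'   `frequency_hz`, `rel_ideal`, `rel_realistic`, `underestimation`.
#' @export
run_simulation_suite <- function(config = list(), out_dir = NULL) {
  cfg <- read_run_config(config)
  params_for <- function(n_ap) kinetic_params(
    tau_endo = cfg$kinetics$tau_endo_s,
    tau_reac = cfg$kinetics$tau_reac_s,
    total_release = max(n_ap, 1) / 200)
  cyc <- cycling_protocol(cfg$cycling$acid_s, cfg$cycling$alkaline_s,
                          cfg$cycling$start_s, cfg$cycling$total_s,
                          cfg$cycling$first_phase)
  grid <- rbind(
    if (length(cfg$sweeps$n_ap) > 0)
      data.frame(sweep = "n_ap", n_ap = cfg$sweeps$n_ap,
                 frequency_hz = cfg$sweeps$n_ap_freq_hz),
    if (length(cfg$sweeps$freq_hz) > 0)
      data.frame(sweep = "frequency", n_ap = cfg$sweeps$freq_n_ap,
                 frequency_hz = cfg$sweeps$freq_hz))
  if (is.null(grid) || nrow(grid) == 0)
    return(data.frame(sweep = character(), n_ap = numeric(),
                      frequency_hz = numeric(), rel_ideal = numeric(),
                      rel_realistic = numeric(), underestimation = numeric()))
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    stim <- stimulus_protocol(grid$n_ap[i], grid$frequency_hz[i],
                              cfg$stimulus$start_s)
    par <- params_for(grid$n_ap[i])
    ideal <- simulate_ideal(par, stim, dt = cfg$sim$dt_s,
                            t_end = cfg$cycling$total_s)
    real <- simulate_realistic(par, stim, cyc, dt = cfg$sim$dt_s)
    ri <- relative_avp_size_model(ideal)
    rr <- relative_avp_size_model(real, detected_only = TRUE)
    data.frame(sweep = grid$sweep[i], n_ap = grid$n_ap[i],
               frequency_hz = grid$frequency_hz[i],
               rel_ideal = ri, rel_realistic = rr,
               underestimation = 1 - rr / ri)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, "simulation_sweeps.csv"),
                     row.names = FALSE)
    write_manifest(cfg, out_dir)
  }
  res
}

#' Analyze a pH-cycling recording end to end
#'
#' Chains the analysis stages on a trace or an image stack: phase
#' separation by derivative extrema, (for stacks) bouton detection on the
#' stimulation difference image and ROI trace extraction, per-phase
#' baseline subtraction, relative alkaline-pool size, reacidification
#' time-constant fit on the post-stimulus pH 5.5 decay, endocytosis
#' time-constant fit on the reconstructed surface pool, and (optionally)
#' FFT deconvolution of the alkaline kinetics.
#'
#' @param input A [fluorescence_trace()], an `image_stack`, or a path to a
#'   trace CSV (columns `time_s`, `value`) or multi-frame TIFF.
#' @param stim_start Stimulus onset, seconds.
#' @param stim_duration Stimulus duration, seconds (sets the fit windows).
#' @param frame_rate Frame rate in Hz (used when reading files).
#' @param first_phase Phase label before the first detected marker.
#' @param deconvolve Also run the alpha-fit + deconvolution branch
#'   (default `TRUE`).
#' @param detection A [detection_config()] for stack inputs.
#' @param tau_reac_for_deconv Reacidification constant for the
#'   deconvolution kernel; default: the value fitted from the pH 5.5 decay.
#' @param out_dir Optional results directory (CSV/JSON outputs plus
#'   manifest).
#' @return A list of class `avp_analysis`: `split`, `relative_size`
#'   (`avp_size_result`), `tau_reac_fit`, `surface_trace`,
#'   `tau_endo_surface_fit`, and (if requested) `alpha_fit`, `deconv`.
#'   Stack inputs add `rois` and the analyzed mean trace.
#' @export
run_analysis <- function(input, stim_start = 40, stim_duration = 10,
                         frame_rate = 10, first_phase = "pH7.5",
                         deconvolve = TRUE,
                         detection = detection_config(),
                         tau_reac_for_deconv = NULL, out_dir = NULL) {
  rois <- NULL
  if (is.character(input)) {
    if (!file.exists(input))
      stop_param(FALSE, paste("input file not found:", input))
    input <- if (grepl("\\.tiff?$", input, ignore.case = TRUE))
      read_stack_tiff(input)
    else {
      df <- utils::read.csv(input)
      fluorescence_trace(df$value, frame_rate, time = df$time_s)
    }
  }
  if (inherits(input, "image_stack") ||
      (is.array(input) && length(dim(input)) == 3)) {
    mean_trace <- fluorescence_trace(apply(input, 3, mean), frame_rate)
    split0 <- split_by_derivative(mean_trace, first_phase = first_phase)
    stim_frame <- floor(stim_start * frame_rate) + 1L
    diff_img <- difference_image(input, stim_frame = stim_frame, n = 3,
                                 labels = split0$labels, phase = "pH7.5",
                                 post_offset = round(stim_duration *
                                                       frame_rate))
    rois <- detect_boutons(diff_img, detection)
    if (nrow(rois) == 0) stop_protocol("no boutons detected")
    roi_traces <- extract_roi_traces(input, rois, frame_rate)
    vals <- rowMeans(sapply(roi_traces, function(tr) tr$values))
    trace <- fluorescence_trace(vals, frame_rate)
  } else {
    stopifnot(inherits(input, "fluor_trace"))
    trace <- input
  }

  split <- split_by_derivative(trace, first_phase = first_phase)
  bl_window <- c(0, max(min(trace$time) + 1, stim_start - 2))
  t75 <- baseline_subtract(split$trace_75, bl_window)
  t55 <- baseline_subtract(split$trace_55, bl_window)

  size <- relative_avp_size(t55, t75, window = c(stim_start,
                                                 max(trace$time)))
  # reacidification: pH 5.5 decay after the response peak
  peak55_t <- t55$time[t55$time >= stim_start][
    which.max(t55$values[t55$time >= stim_start])]
  tau_reac_fit <- fit_exp_decay(t55, t_start = peak55_t)

  surf <- surface_pool_trace(t75, t55)
  peak_s_t <- surf$time[which.max(surf$values)]
  tau_endo_surface <- fit_exp_decay(surf, t_start = max(peak_s_t,
                                                        stim_start))

  out <- list(split = split, relative_size = size,
              tau_reac_fit = tau_reac_fit, surface_trace = surf,
              tau_endo_surface_fit = tau_endo_surface, rois = rois,
              trace = trace)
  if (deconvolve) {
    out$alpha_fit <- fit_alpha(t55, stim_start)
    tr_deconv <- if (!is.null(tau_reac_for_deconv)) tau_reac_for_deconv
      else if (isTRUE(tau_reac_fit$converged)) tau_reac_fit$tau else NULL
    if (!is.null(tr_deconv) && isTRUE(out$alpha_fit$converged))
      out$deconv <- deconvolve_endocytosis(out$alpha_fit, tr_deconv,
                                           duration = max(trace$time) -
                                             stim_start)
  }
  class(out) <- "avp_analysis"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      data.frame(time_s = trace$time, value = trace$values,
                 label = split$labels),
      file.path(out_dir, "labelled_trace.csv"), row.names = FALSE)
    summary <- list(
      relative_size = size$relative_size,
      amp_55 = size$amp_55, amp_75 = size$amp_75,
      tau_reac_s = tau_reac_fit$tau,
      tau_endo_surface_s = tau_endo_surface$tau,
      tau_endo_deconv_s = if (!is.null(out$deconv)) out$deconv$tau_endo
        else NA,
      n_rois = if (!is.null(rois)) nrow(rois) else NA)
    jsonlite::write_json(summary, file.path(out_dir, "analysis.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(rois))
      utils::write.csv(as.data.frame(rois),
                       file.path(out_dir, "rois.csv"), row.names = FALSE)
  }
  out
}

write_manifest <- function(cfg, out_dir) {
  manifest <- list(
    config = unclass(cfg),
    seed = cfg$seed,
    package = "avpdyn",
    package_version = as.character(utils::packageVersion("avpdyn")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a simulated trajectory to CSV
#'
#' @param traj An `avp_trajectory`.
#' @param path Output CSV path (columns `time_s`, `surface`, `alkaline`,
#'   `acidified`, `ph_label`).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "avp_trajectory"))
  utils::write.csv(
    data.frame(time_s = traj$time, surface = traj$surface,
               alkaline = traj$alkaline, acidified = traj$acidified,
               ph_label = traj$ph_label),
    path, row.names = FALSE)
  invisible(path)
}
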