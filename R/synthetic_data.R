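# Ground-truthed synthetic pH-cycling recordings.
#
# Fluorescence physics: the marker pool (total_pool vesicle units) splits
# into a resting surface pool, the stimulus-driven surface pool S(t), the
# alkaline population A(t) and a quenched interior remainder. pHluorin in
# contact with pH 5.5 (bath or vesicle lumen) is quench_factor-fold dimmer.

#' Fluorescence model for synthetic pHluorin recordings
#'
#' @param quench_factor Fold quenching of pHluorin between pH 7.5 and 5.5
#'   (default 20).
#' @param resting_surface_fraction Fraction of the marker resting on the
#'   plasma membrane: ~0.24 for synapto-pHluorin, ~0.03 for
#'   VGLUT1-pHluorin.
#' @param total_pool Total marker pool, in the same vesicle units as the
#'   kinetic model (default 4: the labelled pool is four times one
#'   stimulus's release).
#' @param background Constant non-pHluorin background, intensity counts.
#' @param bleach_tau Monoexponential photobleaching time constant in
#'   seconds, applied to all pHluorin-derived fluorescence; `NULL` disables
#'   bleaching.
#' @param noise_sd Additive Gaussian noise s.d. per frame, intensity counts.
#' @param scale Intensity counts per vesicle unit of visible marker.
#' @return An object of class `fluor_model`.
#' @export
fluor_model <- function(quench_factor = 20, resting_surface_fraction = 0.24,
                        total_pool = 4, background = 100, bleach_tau = NULL,
                        noise_sd = 100, scale = 1000) {
  stop_param(quench_factor >= 1, "quench_factor must be >= 1")
  stop_param(resting_surface_fraction >= 0 && resting_surface_fraction <= 1,
             "resting_surface_fraction must be in [0, 1]")
  stop_param(is_pos_scalar(total_pool), "total_pool must be positive")
  stop_param(noise_sd >= 0, "noise_sd must be >= 0")
  stop_param(is_pos_scalar(scale), "scale must be positive")
  if (!is.null(bleach_tau))
    stop_param(is_pos_scalar(bleach_tau), "bleach_tau must be positive or NULL")
  structure(list(quench_factor = quench_factor,
                 resting_surface_fraction = resting_surface_fraction,
                 total_pool = total_pool, background = background,
                 bleach_tau = bleach_tau, noise_sd = noise_sd,
                 scale = scale),
            class = "fluor_model")
}

# run `code` under a fixed RNG seed without disturbing the global stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# noiseless per-frame visible marker (vesicle units) for given pools/phase
visible_marker <- function(S, A, phase, fluor) {
  q <- fluor$quench_factor
  s_pool <- fluor$resting_surface_fraction * fluor$total_pool
  rest <- fluor$total_pool - s_pool - S - A
  ifelse(phase == "pH7.5",
         s_pool + S + A + rest / q,
         (s_pool + S) / q + A + rest / q)
}

#' Generate a synthetic pH-cycling fluorescence trace
#'
#' Samples a simulated trajectory at the camera frame rate and converts the
#' vesicle pools into fluorescence counts. In pH 7.5 frames the visible
#' marker is `resting_surface + S + A + rest/q`; in pH 5.5 frames it is
#' `(resting_surface + S)/q + A + rest/q`, where `rest` is the quenched
#' interior remainder of the marker pool and `q` the quench factor.
#' Optional monoexponential bleaching multiplies the pHluorin-derived part;
#' Gaussian noise is added last. To emulate the finite speed of solution
#' exchange, the first `ramp_frames` frames after each exchange take
#' intermediate values between the two phase levels.
#'
#' @param traj An `avp_trajectory` (from [simulate_ideal()] or
#'   [simulate_realistic()]).
#' @param cycling The [cycling_protocol()] that defines the bath phases, or
#'   `NULL` for constant pH 7.5.
#' @param fluor A [fluor_model()].
#' @param frame_rate Camera frame rate in Hz (default 10).
#' @param seed RNG seed for the noise; `NULL` uses the current RNG state.
#' @param ramp_frames Number of intermediate-valued frames per exchange
#'   (default 1; 0 gives an instantaneous square wave).
#' @return A list of class `avp_synth_trace` with elements `trace`
#'   (a [fluorescence_trace()]) and `truth` (phase labels per frame, the
#'   noiseless trace, ramp frame indices, and the generating objects).
#' @export
synth_trace <- function(traj, cycling, fluor = fluor_model(),
                        frame_rate = 10, seed = NULL, ramp_frames = 1) {
  stopifnot(inherits(traj, "avp_trajectory"), inherits(fluor, "fluor_model"))
  stop_param(is_pos_scalar(frame_rate), "frame_rate must be positive (Hz)")
  t_frames <- seq(0, max(traj$time), by = 1 / frame_rate)
  S <- stats::approx(traj$time, traj$surface, t_frames, rule = 2)$y
  A <- stats::approx(traj$time, traj$alkaline, t_frames, rule = 2)$y
  phase <- phase_at(cycling, t_frames)
  vis <- visible_marker(S, A, phase, fluor)
  bleach <- if (is.null(fluor$bleach_tau)) 1 else
    exp(-t_frames / fluor$bleach_tau)
  clean <- fluor$scale * bleach * vis + fluor$background

  ramp_idx <- integer(0)
  if (ramp_frames > 0 && length(clean) > 1) {
    switches <- which(phase[-1] != phase[-length(phase)]) + 1L
    for (sw in switches) {
      ks <- seq_len(min(ramp_frames, length(clean) - sw + 1L))
      prev <- clean[sw - 1L]
      clean[sw + ks - 1L] <- prev +
        (clean[sw + ks - 1L] - prev) * ks / (ramp_frames + 1)
      ramp_idx <- c(ramp_idx, sw + ks - 1L)
    }
  }

  values <- with_seed(seed,
    clean + stats::rnorm(length(clean), 0, fluor$noise_sd))
  structure(list(
    trace = fluorescence_trace(values, frame_rate, time = t_frames),
    truth = list(phase = phase, clean = clean, ramp_idx = ramp_idx,
                 trajectory = traj, cycling = cycling, fluor = fluor)),
    class = "avp_synth_trace")
}

#' Map of synthetic boutons in the field of view
#'
#' @param frame_size `c(rows, cols)` of the image frame, pixels.
#' @param n Number of boutons to place at random (ignored when `positions`
#'   is given).
#' @param positions Optional two-column matrix of (row, col) centres,
#'   0-based pixel coordinates.
#' @param psf_sigma Gaussian spot sigma in pixels (default 1.5,
#'   diffraction-limited boutons).
#' @param amplitudes Per-bouton brightness factors (recycled to `n`).
#' @param responding Logical per bouton: does it respond to the stimulus
#'   (recycled).
#' @param min_sep Minimum centre separation in pixels for random placement.
#' @param margin Margin in pixels kept free at the frame border.
#' @param seed RNG seed for random placement.
#' @return An object of class `bouton_map`.
#' @export
bouton_map <- function(frame_size, n = NULL, positions = NULL,
                       psf_sigma = 1.5, amplitudes = 1, responding = TRUE,
                       min_sep = 6, margin = 4, seed = NULL) {
  stopifnot(length(frame_size) == 2)
  if (is.null(positions)) {
    stop_param(is_pos_scalar(n), "n boutons must be positive")
    positions <- with_seed(seed, {
      pos <- matrix(NA_real_, 0, 2)
      tries <- 0
      while (nrow(pos) < n && tries < 20000) {
        cand <- c(stats::runif(1, margin, frame_size[1] - 1 - margin),
                  stats::runif(1, margin, frame_size[2] - 1 - margin))
        if (nrow(pos) == 0 ||
            min(sqrt(rowSums((pos - rep(cand, each = nrow(pos)))^2))) >= min_sep)
          pos <- rbind(pos, cand)
        tries <- tries + 1
      }
      if (nrow(pos) < n)
        stop_protocol("could not place boutons with requested min_sep")
      pos
    })
  } else {
    positions <- as.matrix(positions)
  }
  n <- nrow(positions)
  if (any(positions[, 1] < 0 | positions[, 1] > frame_size[1] - 1 |
          positions[, 2] < 0 | positions[, 2] > frame_size[2] - 1))
    stop_param(FALSE, "bouton positions outside the frame")
  amplitudes <- rep_len(amplitudes, n)
  stop_param(all(amplitudes > 0), "amplitudes must be positive")
  structure(list(positions = positions, amplitudes = amplitudes,
                 responding = rep_len(responding, n),
                 psf_sigma = psf_sigma, frame_size = frame_size),
            class = "bouton_map")
}

#' Render a synthetic image stack from per-bouton traces
#'
#' Each frame is `background` plus, for every bouton, a peak-normalised 2-D
#' Gaussian spot scaled by that bouton's trace value at the frame, plus
#' Gaussian pixel noise. Values are rounded and clamped to the 16-bit range.
#'
#' @param map A [bouton_map()].
#' @param traces Matrix of spot peak intensities above background,
#'   frames x boutons.
#' @param background Constant background level, counts.
#' @param noise_sd Pixel noise s.d., counts.
#' @param seed RNG seed for the pixel noise.
#' @return A 3-D array (rows x cols x frames) of class `image_stack`.
#' @export
synth_stack <- function(map, traces, background = 100, noise_sd = 10,
                        seed = NULL) {
  stopifnot(inherits(map, "bouton_map"))
  traces <- as.matrix(traces)
  if (ncol(traces) != nrow(map$positions))
    stop_param(FALSE, "one trace per bouton required")
  h <- map$frame_size[1]; w <- map$frame_size[2]
  n_frames <- nrow(traces)

  # precompute each bouton's local footprint (pixel indices + weights)
  half <- ceiling(4 * map$psf_sigma)
  feet <- lapply(seq_len(nrow(map$positions)), function(b) {
    r0 <- map$positions[b, 1]; c0 <- map$positions[b, 2]
    rows <- max(0, floor(r0) - half):min(h - 1, ceiling(r0) + half)
    cols <- max(0, floor(c0) - half):min(w - 1, ceiling(c0) + half)
    g <- outer(rows, cols, function(r, c)
      exp(-((r - r0)^2 + (c - c0)^2) / (2 * map$psf_sigma^2)))
    idx <- as.vector(outer(rows + 1L, (cols) * h, `+`))
    list(idx = idx, w = as.vector(g) * map$amplitudes[b])
  })

  stack <- array(0, dim = c(h, w, n_frames))
  base <- rep(background, h * w)
  for (f in seq_len(n_frames)) {
    px <- base
    for (b in seq_along(feet))
      px[feet[[b]]$idx] <- px[feet[[b]]$idx] + feet[[b]]$w * traces[f, b]
    stack[, , f] <- px
  }
  if (noise_sd > 0)
    stack <- stack + with_seed(seed,
      array(stats::rnorm(length(stack), 0, noise_sd), dim = dim(stack)))
  stack <- round(pmin(pmax(stack, 0), 65535))
  structure(stack, class = c("image_stack", "array"))
}

#' Generate a complete synthetic pH-cycling imaging experiment
#'
#' Convenience wrapper: simulates the realistic trajectory, builds noiseless
#' per-bouton traces (responding boutons follow the stimulus-driven pools,
#' non-responding boutons show only resting fluorescence), and renders the
#' image stack. All noise lives in the stack pixels so the per-bouton
#' ground-truth traces stay exact.
#'
#' @inheritParams synth_trace
#' @param params,stim,cycling Kinetics and protocols for the underlying
#'   simulation.
#' @param map A [bouton_map()]; its `responding` flags select which boutons
#'   follow the stimulus.
#' @param background,noise_sd Stack rendering parameters, see
#'   [synth_stack()].
#' @param seed RNG seed (pixel noise).
#' @return List of class `avp_synth_experiment`: `stack`, `truth`
#'   (map, phase labels, per-bouton clean traces, trajectory), `frame_rate`.
#' @export
synth_experiment <- function(params, stim, cycling, map,
                             fluor = fluor_model(noise_sd = 0),
                             frame_rate = 10, background = 100,
                             noise_sd = 10, seed = NULL) {
  traj <- simulate_realistic(params, stim, cycling)
  resp <- synth_trace(traj, cycling, fluor, frame_rate, seed = NULL,
                      ramp_frames = 1)
  quiet_stim <- stimulus_protocol(0, stim$frequency, stim$start_time)
  traj0 <- simulate_realistic(params, quiet_stim, cycling)
  rest <- synth_trace(traj0, cycling, fluor, frame_rate, seed = NULL,
                      ramp_frames = 1)
  n_b <- nrow(map$positions)
  traces <- sapply(seq_len(n_b), function(b)
    if (map$responding[b]) resp$truth$clean - fluor$background
    else rest$truth$clean - fluor$background)
  stack <- synth_stack(map, traces, background = background,
                       noise_sd = noise_sd, seed = seed)
  structure(list(stack = stack,
                 truth = list(map = map, phase = resp$truth$phase,
                              traces = traces, trajectory = traj,
                              cycling = cycling, fluor = fluor),
                 frame_rate = frame_rate),
            class = "avp_synth_experiment")
}

#' Write / read a multi-frame 16-bit grayscale TIFF
#'
#' @param stack An `image_stack` (rows x cols x frames) with values in
#'   \[0, 65535\].
#' @param path Output file path.
#' @return `read_stack_tiff` returns the `image_stack`; `write_stack_tiff`
#'   returns `path` invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                            length(frames)))
  for (f in seq_along(frames)) stack[, , f] <- round(frames[[f]] * 65535)
  structure(stack, class = c("image_stack", "array"))
}
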