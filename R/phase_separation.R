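# Splitting a pH-cycling recording into pH 7.5 and pH 5.5 sub-traces.
#
# The bath pH cannot be read from the absolute fluorescence level (the
# stimulus response is superimposed), but each solution exchange produces a
# steep flank whose point of inflection is an extremum of the first
# derivative. Alternating maxima (rise, 5.5 -> 7.5) and minima (fall,
# 7.5 -> 5.5) of f' mark the exchanges; quiet frames between markers are
# labelled by the direction of the most recent marker.

#' Uniformly sampled fluorescence trace
#'
#' @param values Intensity values, one per frame; must be finite.
#' @param frame_rate Sampling rate in Hz.
#' @param time Optional time vector (seconds); defaults to
#'   `(0, 1, 2, ...) / frame_rate`.
#' @return An object of class `fluor_trace` with fields `time`, `values`,
#'   `frame_rate`.
#' @export
fluorescence_trace <- function(values, frame_rate, time = NULL) {
  stop_param(is_pos_scalar(frame_rate), "frame_rate must be positive (Hz)")
  stop_param(all(is.finite(values)), "trace values must be finite")
  if (is.null(time)) time <- (seq_along(values) - 1) / frame_rate
  stopifnot(length(time) == length(values))
  structure(list(time = as.numeric(time), values = as.numeric(values),
                 frame_rate = frame_rate),
            class = "fluor_trace")
}

# centred 3-point first difference, optionally after boxcar(3) smoothing;
# per-frame units (intensity per frame)
trace_derivative <- function(values, smooth = TRUE) {
  v <- values
  if (smooth && length(v) >= 3) {
    sm <- stats::filter(v, rep(1 / 3, 3), sides = 2)
    sm[1] <- v[1]; sm[length(v)] <- v[length(v)]
    v <- as.numeric(sm)
  }
  n <- length(v)
  d <- rep(0, n)
  if (n >= 3) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
  d
}

phase_detection_error <- function(msg) {
  stop(errorCondition(msg,
       class = c("avpdyn_phase_detection_error", "error")))
}

#' Split a pH-cycling trace into phases by first-derivative extrema
#'
#' Computes the first finite difference of the (lightly smoothed) trace,
#' finds alternating maxima and minima exceeding `deriv_threshold` and
#' separated by at least `min_cycle_gap`, and labels the quiet frames
#' between markers: after a maximum the bath is pH 7.5, after a minimum
#' pH 5.5. Frames adjacent to a marker, or with `|f'|` above the threshold,
#' are labelled `transition`. Frames before the first marker take
#' `first_phase` when supplied, otherwise `transition`.
#'
#' This is the step that fails for markers with a small surface pool
#' (VGLUT1-pHluorin-like): the pH flanks are then too shallow relative to
#' the noise for the extrema to be detected reliably.
#'
#' @param trace A [fluorescence_trace()].
#' @param deriv_threshold Threshold on `|f'|` (intensity per frame) above
#'   which a frame counts as moving. Default: 3 x MAD of `f'` over the
#'   pre-cycling baseline window.
#' @param min_cycle_gap Minimum marker separation, seconds (default 1).
#' @param first_phase Optional `"pH7.5"` / `"pH5.5"` label for frames
#'   before the first marker.
#' @param baseline_window Seconds of trace used for the default threshold
#'   (default: first 20 s or the first fifth, whichever is shorter).
#' @param smooth Boxcar(3)-smooth the trace before differentiating
#'   (default `TRUE`).
#' @return A list of class `phase_split`: `labels` (per frame:
#'   `"pH7.5"`, `"pH5.5"` or `"transition"`), `markers` (data frame of
#'   marker time, frame and sign), `trace_75` / `trace_55`
#'   ([fluorescence_trace()]s over stable frames, original indices in
#'   `$frames`), and the `threshold` used.
#' @export
split_by_derivative <- function(trace, deriv_threshold = NULL,
                                min_cycle_gap = 1, first_phase = NULL,
                                baseline_window = NULL, smooth = TRUE) {
  stopifnot(inherits(trace, "fluor_trace"))
  n <- length(trace$values)
  if (n < 5) phase_detection_error("trace too short for phase detection")
  d <- trace_derivative(trace$values, smooth = smooth)

  if (is.null(deriv_threshold)) {
    if (is.null(baseline_window))
      baseline_window <- min(20, (n / trace$frame_rate) / 5)
    base_idx <- which(trace$time <= trace$time[1] + baseline_window)
    # noise floor from the quiet baseline, with a floor of 5% of the
    # largest flank so that noiseless traces keep a usable threshold
    deriv_threshold <- max(3 * stats::mad(d[base_idx]),
                           0.05 * max(abs(d)))
  }
  if (!is.finite(deriv_threshold) || deriv_threshold <= 0)
    phase_detection_error("no usable derivative threshold (flat trace?)")

  # candidate extrema of f' above threshold
  is_max <- c(FALSE, d[2:(n - 1)] >= d[1:(n - 2)] &
                d[2:(n - 1)] >= d[3:n], FALSE) & d > deriv_threshold
  is_min <- c(FALSE, d[2:(n - 1)] <= d[1:(n - 2)] &
                d[2:(n - 1)] <= d[3:n], FALSE) & d < -deriv_threshold
  cand <- data.frame(frame = c(which(is_max), which(is_min)),
                     sign = rep(c(1, -1), c(sum(is_max), sum(is_min))))
  cand <- cand[order(cand$frame), , drop = FALSE]
  if (nrow(cand) > 0) cand$mag <- abs(d[cand$frame])

  # same-sign extrema closer than min_cycle_gap, and same-sign runs, are
  # repaired by keeping the larger-|f'| one
  gap_frames <- max(1, round(min_cycle_gap * trace$frame_rate))
  repaired <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    m <- nrow(repaired)
    if (m > 0 && (repaired$sign[m] == cand$sign[i] ||
                  cand$frame[i] - repaired$frame[m] < gap_frames)) {
      # same-sign run, or opposite sign but too close: keep the stronger
      if (cand$mag[i] > repaired$mag[m]) repaired[m, ] <- cand[i, ]
    } else {
      repaired <- rbind(repaired, cand[i, ])
    }
  }
  # final alternation enforcement (replacements above can re-create runs)
  repeat {
    runs <- which(diff(repaired$sign) == 0)
    if (length(runs) == 0) break
    i <- runs[1]
    drop <- if (repaired$mag[i] >= repaired$mag[i + 1]) i + 1 else i
    repaired <- repaired[-drop, , drop = FALSE]
  }
  markers <- repaired
  if (nrow(markers) < 2)
    phase_detection_error(
      "fewer than 2 alternating derivative extrema: pH phases cannot be determined from this trace")

  labels <- rep("transition", n)
  marker_frames <- markers$frame
  last_before <- findInterval(seq_len(n), marker_frames)
  stable <- abs(d) < deriv_threshold
  # frames within 1 frame of a marker are transitions (exposure straddles
  # the exchange)
  near_marker <- rep(FALSE, n)
  near_marker[pmax(1, marker_frames - 1)] <- TRUE
  near_marker[marker_frames] <- TRUE
  near_marker[pmin(n, marker_frames + 1)] <- TRUE

  lab_after <- ifelse(markers$sign > 0, "pH7.5", "pH5.5")
  ok <- stable & !near_marker & last_before > 0
  labels[ok] <- lab_after[last_before[ok]]
  if (!is.null(first_phase)) {
    pre <- stable & !near_marker & last_before == 0
    labels[pre] <- first_phase
  }

  idx75 <- which(labels == "pH7.5")
  idx55 <- which(labels == "pH5.5")
  sub_trace <- function(idx) {
    tr <- fluorescence_trace(trace$values[idx], trace$frame_rate,
                             time = trace$time[idx])
    tr$frames <- idx
    tr
  }
  structure(list(labels = labels,
                 markers = data.frame(time = trace$time[marker_frames],
                                      frame = marker_frames,
                                      sign = markers$sign),
                 trace_75 = sub_trace(idx75),
                 trace_55 = sub_trace(idx55),
                 threshold = deriv_threshold),
            class = "phase_split")
}

#' Per-phase mean traces and average images of a stack
#'
#' For each bath phase, averages the labelled frames into one image and
#' collapses each frame to its mean pixel value, yielding the two mean
#' fluorescence traces.
#'
#' @param stack An `image_stack` (rows x cols x frames).
#' @param labels Per-frame labels (`"pH7.5"`, `"pH5.5"`, anything else is
#'   ignored), length equal to the frame count.
#' @param frame_rate Frame rate in Hz used to timestamp the sub-traces.
#' @param phases Phases to compute (default both); requesting a phase with
#'   no labelled frames is an error.
#' @return List with `trace_75`, `trace_55` ([fluorescence_trace()]s with
#'   original frame indices) and `avg_75`, `avg_55` (matrices); entries for
#'   phases not requested are `NULL`.
#' @export
mean_phase_traces <- function(stack, labels, frame_rate = 10,
                              phases = c("pH7.5", "pH5.5")) {
  stopifnot(length(dim(stack)) == 3)
  if (length(labels) != dim(stack)[3])
    stop_param(FALSE, "one label per frame required")
  per_frame_mean <- apply(stack, 3, mean)
  time <- (seq_len(dim(stack)[3]) - 1) / frame_rate
  one_phase <- function(ph) {
    idx <- which(labels == ph)
    if (length(idx) == 0)
      stop_protocol(paste("no frames labelled", ph))
    tr <- fluorescence_trace(per_frame_mean[idx], frame_rate,
                             time = time[idx])
    tr$frames <- idx
    list(trace = tr,
         avg = apply(stack[, , idx, drop = FALSE], c(1, 2), mean))
  }
  out <- list(trace_75 = NULL, trace_55 = NULL, avg_75 = NULL, avg_55 = NULL)
  if ("pH7.5" %in% phases) {
    p <- one_phase("pH7.5"); out$trace_75 <- p$trace; out$avg_75 <- p$avg
  }
  if ("pH5.5" %in% phases) {
    p <- one_phase("pH5.5"); out$trace_55 <- p$trace; out$avg_55 <- p$avg
  }
  out
}
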