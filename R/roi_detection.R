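# Bouton detection on stimulation difference images and colocalization.
#
# Responding boutons appear as diffraction-limited bright blobs in the
# post-minus-pre stimulation difference image. Candidates are local maxima
# of a scale-normalised Laplacian-of-Gaussian response; each candidate must
# sit in a connected above-threshold region of plausible size and receives
# a fixed-dimension square ROI. Pixel coordinates are 0-based (row, col).

#' Bouton detection configuration
#'
#' @param intensity_threshold Minimum difference-image intensity at a peak
#'   and for the connected-region size filter; `NULL` selects an Otsu
#'   threshold on the image.
#' @param min_region_px,max_region_px Admissible connected-region pixel
#'   counts (min < max).
#' @param log_sigma Sigma of the Laplacian-of-Gaussian filter, pixels;
#'   match to the PSF (default 1.5).
#' @param roi_halfwidth ROI half-width in pixels; ROIs are
#'   `(2 * roi_halfwidth + 1)^2` squares (default 2, i.e. 5x5).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(intensity_threshold = NULL, min_region_px = 3,
                             max_region_px = 200, log_sigma = 1.5,
                             roi_halfwidth = 2) {
  stop_param(min_region_px < max_region_px,
             "min_region_px must be < max_region_px")
  stop_param(roi_halfwidth >= 1, "roi_halfwidth must be >= 1")
  stop_param(is_pos_scalar(log_sigma), "log_sigma must be positive")
  structure(list(intensity_threshold = intensity_threshold,
                 min_region_px = min_region_px,
                 max_region_px = max_region_px,
                 log_sigma = log_sigma, roi_halfwidth = roi_halfwidth),
            class = "detection_config")
}

#' Stimulation difference image
#'
#' Averages `n` frames immediately before the stimulus and `n` frames from
#' a post-stimulus window (same bath phase) and returns their difference
#' (post minus pre) as a float image. Frames can be selected explicitly via
#' `pre_idx` / `post_idx`, or implicitly from `stim_frame` and optional
#' phase `labels` (only frames labelled `phase` are used).
#'
#' @param stack An `image_stack` (rows x cols x frames).
#' @param stim_frame Frame index of stimulus onset (1-based).
#' @param n Number of frames averaged on each side (default 3).
#' @param labels Optional per-frame phase labels; when given, only frames
#'   labelled `phase` are eligible.
#' @param phase Phase to restrict to (default `"pH7.5"`).
#' @param post_offset Frames skipped after `stim_frame` before collecting
#'   post frames (default 0: take the first eligible frames at/after
#'   stimulus onset; use e.g. the stimulus duration to sample the response
#'   peak).
#' @param pre_idx,post_idx Explicit frame indices (override the implicit
#'   selection).
#' @return A numeric matrix (rows x cols).
#' @export
difference_image <- function(stack, stim_frame = NULL, n = 3,
                             labels = NULL, phase = "pH7.5",
                             post_offset = 0,
                             pre_idx = NULL, post_idx = NULL) {
  stopifnot(length(dim(stack)) == 3)
  n_frames <- dim(stack)[3]
  if (is.null(pre_idx) || is.null(post_idx)) {
    stop_param(!is.null(stim_frame), "stim_frame (or explicit indices) required")
    eligible <- if (is.null(labels)) rep(TRUE, n_frames) else labels == phase
    pre_pool <- which(eligible & seq_len(n_frames) < stim_frame)
    post_pool <- which(eligible & seq_len(n_frames) >= stim_frame + post_offset)
    if (length(pre_pool) < n || length(post_pool) < n)
      stop_param(FALSE, "not enough eligible frames around the stimulus")
    pre_idx <- utils::tail(pre_pool, n)
    post_idx <- utils::head(post_pool, n)
  }
  if (length(intersect(pre_idx, post_idx)) > 0)
    stop_param(FALSE, "pre and post frame windows overlap")
  post <- apply(stack[, , post_idx, drop = FALSE], c(1, 2), mean)
  pre <- apply(stack[, , pre_idx, drop = FALSE], c(1, 2), mean)
  post - pre
}

# scale-normalised negative LoG response (positive at bright blobs)
log_response <- function(img, sigma) {
  half <- ceiling(3 * sigma)
  ax <- -half:half
  g <- outer(ax, ax, function(x, y)
    (x^2 + y^2 - 2 * sigma^2) / (2 * pi * sigma^6) *
      exp(-(x^2 + y^2) / (2 * sigma^2)))
  g <- g - mean(g)  # zero-sum kernel: flat regions respond zero
  -sigma^2 * EBImage::filter2(img, g, boundary = "replicate")
}

otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) <= 0) return(rng[1])
  EBImage::otsu(EBImage::Image(img), range = rng)
}

#' Detect responding boutons on a difference image
#'
#' Laplacian-of-Gaussian blob detection: local maxima of the
#' scale-normalised LoG response whose difference-image intensity exceeds
#' the threshold, whose connected above-threshold region has a pixel count
#' within the configured limits, and whose fixed square ROI fits inside the
#' frame.
#'
#' @param diff_img Float image (matrix), e.g. from [difference_image()].
#' @param cfg A [detection_config()].
#' @return An object of class `roi_set`: data frame with columns `id`,
#'   `row`, `col` (0-based centroids) and `score` (LoG response), with the
#'   ROI half-width and frame size as attributes. May be empty.
#' @export
detect_boutons <- function(diff_img, cfg = detection_config()) {
  stopifnot(is.matrix(diff_img), inherits(cfg, "detection_config"))
  thr <- cfg$intensity_threshold
  if (is.null(thr)) thr <- otsu_threshold(diff_img)
  resp <- log_response(diff_img, cfg$log_sigma)

  h <- nrow(diff_img); w <- ncol(diff_img)
  # 3x3 local maxima of the LoG response, away from the 1 px border
  peaks <- matrix(FALSE, h, w)
  if (h > 2 && w > 2) {
    ri <- 2:(h - 1); ci <- 2:(w - 1)
    core <- resp[ri, ci]
    is_peak <- core > 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      is_peak <- is_peak & core >= resp[ri + dr, ci + dc]
    }
    peaks[ri, ci] <- is_peak
  }
  peaks <- peaks & diff_img > thr

  cand <- which(peaks, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  if (nrow(cand) > 0) {
    mask <- EBImage::bwlabel(diff_img > thr)
    sizes <- tabulate(as.integer(mask))
    for (i in seq_len(nrow(cand))) {
      lab <- mask[cand[i, 1], cand[i, 2]]
      if (lab == 0) next
      sz <- sizes[lab]
      if (sz < cfg$min_region_px || sz > cfg$max_region_px) next
      r0 <- cand[i, 1] - 1; c0 <- cand[i, 2] - 1
      hwd <- cfg$roi_halfwidth
      if (r0 - hwd < 0 || r0 + hwd > h - 1 ||
          c0 - hwd < 0 || c0 + hwd > w - 1) next
      keep[i] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  rois <- data.frame(id = seq_len(nrow(cand)),
                     row = cand[, 1] - 1, col = cand[, 2] - 1,
                     score = resp[cand])
  rois <- rois[!duplicated(rois[c("row", "col")]), , drop = FALSE]
  rois$id <- seq_len(nrow(rois))
  structure(rois, class = c("roi_set", "data.frame"),
            roi_halfwidth = cfg$roi_halfwidth, frame_size = c(h, w),
            intensity_threshold = thr)
}

roi_pixel_index <- function(rois, frame_size) {
  hwd <- attr(rois, "roi_halfwidth")
  lapply(seq_len(nrow(rois)), function(i) {
    rr <- rois$row[i] + (-hwd:hwd) + 1
    cc <- rois$col[i] + (-hwd:hwd) + 1
    if (any(rr < 1 | rr > frame_size[1] | cc < 1 | cc > frame_size[2]))
      stop_param(FALSE, "ROI extends outside the frame")
    as.vector(outer(rr, (cc - 1) * frame_size[1], `+`))
  })
}

#' Extract per-ROI mean fluorescence traces
#'
#' @param stack An `image_stack`.
#' @param rois A `roi_set` from [detect_boutons()].
#' @param frame_rate Frame rate in Hz for the returned traces.
#' @return A list of [fluorescence_trace()]s, one per ROI (mean pixel value
#'   inside the square mask, per frame).
#' @export
extract_roi_traces <- function(stack, rois, frame_rate = 10) {
  stopifnot(length(dim(stack)) == 3, inherits(rois, "roi_set"))
  fs <- dim(stack)[1:2]
  idx <- roi_pixel_index(rois, fs)
  n_frames <- dim(stack)[3]
  flat <- matrix(stack, nrow = prod(fs), ncol = n_frames)
  lapply(idx, function(px)
    fluorescence_trace(colMeans(flat[px, , drop = FALSE]), frame_rate))
}

#' Manders and Pearson colocalization between two images
#'
#' Pixel-based colocalization: `M1` is the fraction of channel-A intensity
#' over pixels where channel B exceeds its threshold; `M2` symmetrically
#' for channel B over channel A; Pearson's r is computed over all pixels.
#' Thresholds default to Otsu per image.
#'
#' @param img_a,img_b Numeric matrices of equal size.
#' @param thr_a,thr_b Intensity thresholds; `NULL` selects Otsu.
#' @return An object of class `coloc_result`: list with `M1`, `M2`,
#'   `pearson_r`, `n_pixels`, `thr_a`, `thr_b`.
#' @export
manders_pearson <- function(img_a, img_b, thr_a = NULL, thr_b = NULL) {
  stopifnot(all(dim(img_a) == dim(img_b)))
  if (is.null(thr_a)) thr_a <- otsu_threshold(img_a)
  if (is.null(thr_b)) thr_b <- otsu_threshold(img_b)
  sum_a <- sum(img_a); sum_b <- sum(img_b)
  if (sum_a <= 0 || sum_b <= 0)
    stop(errorCondition("Manders coefficients undefined: zero total intensity",
                        class = c("avpdyn_undefined_ratio", "error")))
  structure(list(M1 = sum(img_a[img_b > thr_b]) / sum_a,
                 M2 = sum(img_b[img_a > thr_a]) / sum_b,
                 pearson_r = stats::cor(as.vector(img_a), as.vector(img_b)),
                 n_pixels = length(img_a),
                 thr_a = thr_a, thr_b = thr_b),
            class = "coloc_result")
}

#' Object-level overlap between two ROI sets
#'
#' Fraction of set-A centroids that fall inside any set-B square mask.
#'
#' @param rois_a,rois_b `roi_set` objects.
#' @return A fraction in \[0, 1\] (`NaN` for an empty set A).
#' @export
roi_overlap <- function(rois_a, rois_b) {
  stopifnot(inherits(rois_a, "roi_set"), inherits(rois_b, "roi_set"))
  if (nrow(rois_a) == 0) return(NaN)
  if (nrow(rois_b) == 0) return(0)
  hwd <- attr(rois_b, "roi_halfwidth")
  hit <- vapply(seq_len(nrow(rois_a)), function(i)
    any(abs(rois_b$row - rois_a$row[i]) <= hwd &
          abs(rois_b$col - rois_a$col[i]) <= hwd), logical(1))
  mean(hit)
}
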