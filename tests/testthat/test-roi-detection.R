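# short stacks for difference-image work: 3 flat pre frames and 3 flat
# post frames where only responding boutons brighten
make_diff_stack <- function(map, rest = 50, resp = 400, noise_sd = 0,
                            seed = NULL) {
  n_b <- nrow(map$positions)
  pre <- matrix(rest, 3, n_b)
  post <- matrix(ifelse(map$responding, resp, rest), 3, n_b, byrow = TRUE)
  synth_stack(map, rbind(pre, post), background = 100,
              noise_sd = noise_sd, seed = seed)
}

test_that("difference image is zero for identical windows and linear in the stack", {
  map <- bouton_map(c(48, 48), n = 6, seed = 13)
  stk <- make_diff_stack(map)
  same <- difference_image(stk, pre_idx = 1:3, post_idx = 4:6)
  flat <- difference_image(stk, pre_idx = 1:2, post_idx = 3)
  expect_true(all(flat == 0))
  stk2 <- stk * 3
  class(stk2) <- class(stk)
  expect_equal(difference_image(stk2, pre_idx = 1:3, post_idx = 4:6),
               3 * same, tolerance = 1e-12)
  expect_error(difference_image(stk, pre_idx = 1:3, post_idx = 3:5),
               class = "avpdyn_param_error")
  # response shows up only at responding boutons (noise off)
  resp_map <- bouton_map(c(48, 48), n = 6, responding = c(TRUE, TRUE, TRUE,
                                                          FALSE, FALSE, FALSE),
                         seed = 13)
  d <- difference_image(make_diff_stack(resp_map), pre_idx = 1:3,
                        post_idx = 4:6)
  for (b in 1:6) {
    px <- d[round(resp_map$positions[b, 1]) + 1,
            round(resp_map$positions[b, 2]) + 1]
    if (resp_map$responding[b]) expect_gt(px, 100) else
      expect_lt(abs(px), 1e-9)
  }
})

test_that("LoG detection recovers responding boutons with high recall and precision", {
  map <- bouton_map(c(96, 96), n = 30,
                    responding = rep(c(TRUE, FALSE), c(24, 6)),
                    amplitudes = runif(30, 0.7, 1.3), seed = 17)
  d <- difference_image(make_diff_stack(map), pre_idx = 1:3, post_idx = 4:6)
  rois <- detect_boutons(d, detection_config())
  truth <- map$positions[map$responding, , drop = FALSE]
  recall <- mean(sapply(seq_len(nrow(truth)), function(i)
    any(abs(rois$row - truth[i, 1]) <= 2 & abs(rois$col - truth[i, 2]) <= 2)))
  precision <- mean(sapply(seq_len(nrow(rois)), function(i)
    any(abs(truth[, 1] - rois$row[i]) <= 2 & abs(truth[, 2] - rois$col[i]) <= 2)))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("detection is empty on blank images and translation-equivariant", {
  expect_equal(nrow(detect_boutons(matrix(0, 64, 64))), 0)
  base_pos <- rbind(c(20, 20), c(35, 42))
  shift <- c(7, 5)
  for (off in list(c(0, 0), shift)) {
    map <- bouton_map(c(64, 64), positions = sweep(base_pos, 2, off, `+`))
    d <- difference_image(make_diff_stack(map), pre_idx = 1:3,
                          post_idx = 4:6)
    rois <- detect_boutons(d, detection_config(intensity_threshold = 50))
    if (all(off == 0)) first <- rois else second <- rois
  }
  expect_equal(second$row, first$row + shift[1])
  expect_equal(second$col, first$col + shift[2])
})

test_that("the region-size filter rejects oversized blobs", {
  img <- matrix(0, 64, 64)
  img[20:45, 20:45] <- 200  # 676-pixel plateau, far beyond max_region_px
  cfg <- detection_config(intensity_threshold = 50, max_region_px = 200)
  expect_equal(nrow(detect_boutons(img, cfg)), 0)
  # same intensity in a compact blob is kept
  map <- bouton_map(c(64, 64), positions = rbind(c(30, 30)))
  d <- difference_image(make_diff_stack(map), pre_idx = 1:3, post_idx = 4:6)
  expect_equal(nrow(detect_boutons(d, cfg)), 1)
})

test_that("ROI traces reproduce the underlying pixel data", {
  map <- bouton_map(c(48, 48), positions = rbind(c(12, 12), c(34, 30)))
  tr <- cbind(seq(0, 500, length.out = 12), seq(500, 0, length.out = 12))
  stk <- synth_stack(map, tr, background = 100, noise_sd = 0)
  # single-pixel ROI equals that pixel's series
  one_px <- structure(data.frame(id = 1, row = 12, col = 12, score = 1),
                      class = c("roi_set", "data.frame"),
                      roi_halfwidth = 0, frame_size = c(48, 48))
  expect_equal(extract_roi_traces(stk, one_px)[[1]]$values, stk[13, 13, ])
  # detected bouton ROI trace tracks its ground-truth trace
  d <- difference_image(stk, pre_idx = 1:2, post_idx = 11:12)
  rois <- detect_boutons(abs(d), detection_config(intensity_threshold = 50))
  traces <- extract_roi_traces(stk, rois)
  for (i in seq_along(traces)) {
    b <- which.min((map$positions[, 1] - rois$row[i])^2 +
                     (map$positions[, 2] - rois$col[i])^2)
    expect_gt(cor(traces[[i]]$values, tr[, b]), 0.99)
  }
  # ROIs outside the frame are refused
  bad <- one_px; bad$row <- 47; bad$col <- 47
  attr(bad, "roi_halfwidth") <- 2
  expect_error(extract_roi_traces(stk, bad), class = "avpdyn_param_error")
})

test_that("Manders and Pearson coefficients match direct arithmetic", {
  a <- matrix(c(1, 2, 3, 4), 2)
  b <- matrix(c(0, 0, 5, 5), 2)
  res <- manders_pearson(a, b, thr_a = 0, thr_b = 0)
  expect_equal(res$M1, (3 + 4) / 10)      # A-intensity where B > 0
  expect_equal(res$M2, 1)                 # all of B lies where A > 0
  expect_equal(res$pearson_r, 2 / sqrt(5)) # hand-computed covariance ratio
  # identical images: complete colocalization
  same <- manders_pearson(a, a, thr_a = 0, thr_b = 0)
  expect_equal(c(same$M1, same$M2, same$pearson_r), c(1, 1, 1))
  # disjoint supports: none
  x <- matrix(c(1, 1, 0, 0), 2); y <- matrix(c(0, 0, 1, 1), 2)
  disj <- manders_pearson(x, y, thr_a = 0, thr_b = 0)
  expect_equal(c(disj$M1, disj$M2), c(0, 0))
  # M1/M2 invariant to positive rescaling; Pearson to affine maps
  sc <- manders_pearson(5 * a, 3 * b, thr_a = 0, thr_b = 0)
  expect_equal(c(sc$M1, sc$M2), c(res$M1, res$M2))
  af <- manders_pearson(2 * a + 7, 0.5 * b + 1, thr_a = 7, thr_b = 1)
  expect_equal(af$pearson_r, res$pearson_r)
  expect_error(manders_pearson(a * 0, b, thr_a = 0, thr_b = 0),
               class = "avpdyn_undefined_ratio")
})

test_that("object-level overlap counts centroids inside the partner masks", {
  mk <- function(rows, cols, hw) structure(
    data.frame(id = seq_along(rows), row = rows, col = cols,
               score = rep(1, length(rows))),
    class = c("roi_set", "data.frame"), roi_halfwidth = hw,
    frame_size = c(64, 64))
  a <- mk(c(10, 20, 30), c(10, 20, 30), 2)
  b <- mk(c(11, 50), c(9, 50), 2)
  expect_equal(roi_overlap(a, b), 1 / 3)
  expect_equal(roi_overlap(b, a), 1 / 2)
  expect_equal(roi_overlap(a, mk(numeric(0), numeric(0), 2)), 0)
})
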