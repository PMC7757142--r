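# ROI quantification and the 2-SD closure classifier.

test_that("roi_mean averages the 3x3 neighbourhood with edge clipping", {
  expect_equal(roi_mean(matrix(7, 10, 10), c(5, 5)), 7)
  img <- matrix(0, 5, 5)
  img[1:3, 1:3] <- matrix(1:9, 3, 3, byrow = TRUE)
  expect_equal(roi_mean(img, c(2, 2)), 5)
  corner <- matrix(1:16, 4, 4)
  expect_equal(roi_mean(corner, c(1, 1)), mean(corner[1:2, 1:2]))
  expect_error(roi_mean(corner, c(0, 1)), "outside")
  expect_error(roi_mean(corner, c(5, 1)), "outside")
  # 3D input: ROI stays 3x3 in-plane on the focus's slice
  vol <- array(0, c(5, 5, 3))
  vol[, , 2] <- img
  expect_equal(roi_mean(vol, c(2, 2, 2)), 5)
})

test_that("contralateral statistics use the sample SD of the unenhanced side", {
  img <- matrix(10, 6, 6)
  mask <- col(img) <= 3
  cs <- contralateral_stats(img, mask)
  expect_equal(cs$mean, 10)
  expect_equal(cs$sd, 0)

  # sample (n-1) SD convention: nine voxels of {8, 10, 12} repeated
  img2 <- matrix(c(8, 10, 12), 3, 6)
  img2[, 4:6] <- 99  # sonicated side, ignored
  mask2 <- col(img2) >= 4
  cs2 <- contralateral_stats(img2, mask2)
  expect_equal(cs2$mean, 10)
  expect_equal(cs2$sd, sqrt(3))  # 24/8, not the population 24/9
  expect_error(contralateral_stats(matrix(1, 2, 2), matrix(TRUE, 2, 2)), "9 voxels")
})

test_that("2-SD classifier uses a permeable boundary and is monotone", {
  expect_false(classify_closure(10, 10, 2))      # zero excess -> closed
  expect_true(classify_closure(15, 10, 2))       # 2.5 SD excess
  expect_true(classify_closure(14, 10, 2))       # exactly 2 SD -> permeable
  expect_error(classify_closure(10, 10, -1), "contra_sd")
  # monotonicity: raising roi_mean never flips permeable -> closed
  rois <- seq(0, 30, by = 0.5)
  flags <- classify_closure(rois, 10, 2)
  expect_true(all(diff(as.integer(flags)) >= 0))
})

test_that("peak localisation recovers generator centres and rejects flat images", {
  spec <- image_gen_spec(noise_sd = 5)
  s <- generate_image_series(spec, seed = 7)
  found <- locate_peak_enhancement(s$images[["0"]], s$hemisphere_mask, 4)
  # each generator centre matched within 2 voxels, any order
  for (i in 1:4) {
    d <- sqrt((found[, 1] - spec$centers[i, 1])^2 +
              (found[, 2] - spec$centers[i, 2])^2)
    expect_lte(min(d), 2)
  }
  expect_error(locate_peak_enhancement(matrix(1, 20, 20),
                                       matrix(TRUE, 20, 20), 1),
               "0 distinct local maxima")
  one_bump <- matrix(0, 40, 40)
  one_bump[20, 30] <- 5
  expect_equal(unname(locate_peak_enhancement(one_bump, matrix(TRUE, 40, 40), 1)[1, ]),
               c(20, 30))
})

test_that("enhancement ratio relates ROI to the contralateral mean", {
  img <- matrix(100, 20, 20)
  mask <- col(img) <= 10
  img[5, 5] <- 200 * 9 - 100 * 8  # makes the 3x3 ROI mean exactly 200
  expect_equal(enhancement_ratio(img, rbind(c(5, 5)), mask), 2.0)
  expect_equal(enhancement_ratio(matrix(100, 20, 20), rbind(c(5, 5)), mask), 1.0)
  spec <- suppressWarnings(image_gen_spec(amplitude = 0, noise_sd = 5))
  s <- generate_image_series(spec, seed = 1)
  r <- enhancement_ratio(s$images[["0"]], s$focus_coords, s$hemisphere_mask)
  expect_true(all(abs(r - 1) < 0.1))
  expect_error(enhancement_ratio(matrix(-1, 20, 20), rbind(c(5, 5)), mask),
               "positive")
})

test_that("quantify_series reuses time-0 coordinates at follow-up", {
  # bump drifts by 10 voxels at 6 h; a re-localising pipeline would follow it
  spec <- image_gen_spec(centers = rbind(c(30, 20)), closure_times = Inf,
                         noise_sd = 1)
  s <- generate_image_series(spec, seed = 1)
  drifted <- generate_image_series(
    image_gen_spec(centers = rbind(c(40, 20)), closure_times = Inf,
                   noise_sd = 1), seed = 1)
  s$images[["6"]] <- drifted$images[["6"]]
  recs <- quantify_series(s)
  r6 <- recs[recs$timepoint_h == 6, ]
  # ROI still measured at (30, 20), where the drifted bump has no signal
  expect_false(r6$permeable)
  expect_lt(r6$roi_mean, 110)
})

test_that("full-chain quantification recovers fixture closure patterns", {
  spec <- image_gen_spec(closure_times = c(3, 9, 15, Inf))
  s <- generate_image_series(spec, seed = 5)
  recs <- quantify_series(s, coords = spec$centers)
  got <- tapply(recs$permeable, list(recs$focus, recs$timepoint_h), identity)
  expect_equal(unname(got["1", c("0", "6", "12", "20")]), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(got["2", c("0", "6", "12", "20")]), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(got["3", c("0", "6", "12", "20")]), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(got["4", c("0", "6", "12", "20")]), c(TRUE, TRUE, TRUE, TRUE))
})

test_that("full-chain permeable counts match the fixture at default noise", {
  fx <- generate_group_fixture("TgCRND8-VT")
  series <- simulate_group_images(fx, seed = 11)
  recs <- quantify_group(series)
  counts <- tapply(recs$permeable, recs$timepoint_h, sum)
  expect_equal(as.vector(counts[c("0", "6", "12", "20")]), c(23, 6, 4, 3))
})

test_that("classification decisions are stable across seeds at 10:1 amplitude:noise", {
  fx <- generate_group_fixture("nonTg-VT")
  expected <- c(23, 14, 6, 6)
  n_decisions <- 0L
  n_correct <- 0L
  for (seed in 1:40) {
    recs <- quantify_group(simulate_group_images(fx, seed = seed))
    counts <- unname(tapply(recs$permeable, recs$timepoint_h, sum)[
      c("0", "6", "12", "20")])
    n_decisions <- n_decisions + 4L * fx$n_foci
    n_correct <- n_correct + 4L * fx$n_foci - sum(abs(counts - expected))
  }
  expect_gte(n_correct / n_decisions, 0.99)
})

test_that("mirrored-ROI mode compares against the reflected neighbourhood", {
  spec <- image_gen_spec(closure_times = c(3, 9, 15, Inf))
  s <- generate_image_series(spec, seed = 9)
  recs <- quantify_series(s, coords = spec$centers, contra = "mirrored")
  counts <- tapply(recs$permeable, recs$timepoint_h, sum)
  expect_equal(as.vector(counts[c("0", "6", "12", "20")]), c(4, 3, 2, 1))
})
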