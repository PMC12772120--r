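# 8-bit conversion, multi-Otsu thresholding, ROI extraction and core QC.

test_that("8-bit conversion applies the stated affine map and rounding", {
  img8 <- matrix(as.integer(c(3, 200, 255, 0)), 2)
  expect_identical(convert_to_8bit(img8, 8L), img8)
  expect_true(all(convert_to_8bit(matrix(7000L, 4, 4), 16L) == 0L))
  ramp <- matrix(c(0, 32768, 65535), 1)
  expect_equal(as.vector(convert_to_8bit(ramp, 16L)), c(0L, 128L, 255L))
  expect_error(convert_to_8bit(matrix(numeric(0), 0, 0)), "empty")
  expect_error(convert_to_8bit(matrix(-1, 2, 2)), "negative")
})

test_that("discard_channels keeps the five markers plus candidate", {
  d <- study_design(profiles = make_profiles(1))
  s <- generate_core(d, "bronchus", 1, 1, d$profiles[[1]],
                     noise_model(sigma = 0))
  out <- discard_channels(s)
  expect_setequal(names(out$channels),
                  c("CL", "TZ", "RL", "CYTO", "NUC", "CANDIDATE"))
  expect_length(out$channels, 6L)
  s$manifest <- s$manifest[names(s$manifest) != "AF"]
  expect_error(discard_channels(s), "AF")
})

test_that("multi-Otsu separates three delta masses and matches brute force", {
  h <- integer(256)
  h[c(10, 100, 200) + 1L] <- c(50L, 30L, 20L)
  thr <- multi_otsu_thresholds(h)
  expect_true(thr$t1 > 10 && thr$t1 <= 100)
  expect_true(thr$t2 > 100 && thr$t2 <= 200)
  orc <- otsu_oracle(h)
  expect_identical(c(thr$t1, thr$t2), c(orc$t1, orc$t2))
  expect_equal(thr$sigma_b, orc$sigma_b, tolerance = 1e-12)

  h2 <- integer(256); h2[c(5, 250)] <- c(10L, 10L)
  expect_error(multi_otsu_thresholds(h2), "fewer than 3")
  expect_error(multi_otsu_thresholds(integer(256)), "empty")
  expect_error(multi_otsu_thresholds(integer(10)), "256")
})

test_that("multi-Otsu equals exhaustive search on random histograms", {
  set.seed(42)
  for (i in 1:60) {
    h <- random_histogram()
    thr <- multi_otsu_thresholds(h)
    orc <- otsu_oracle(h)
    expect_identical(c(thr$t1, thr$t2), c(orc$t1, orc$t2))
    expect_lt(abs(thr$sigma_b - orc$sigma_b), 1e-9)
  }
})

test_that("segment_marker mask is exactly the brightest threshold class", {
  set.seed(7)
  img <- matrix(as.integer(sample(0:255, 64 * 64, replace = TRUE)), 64)
  roi <- segment_marker(img, "CL")
  t2 <- roi$thresholds$t2
  expect_true(all(img[roi$mask] >= t2))
  expect_true(all(img[!roi$mask] < t2))
  expect_equal(roi$area, sum(roi$mask))
  expect_error(segment_marker(matrix(9L, 8, 8)),
               class = "cilia_seg_failure")
})

test_that("noiseless marker segmentation recovers the ground-truth mask", {
  d <- study_design(profiles = make_profiles(1))
  s <- generate_core(d, "fallopian_tube", 2, 2, d$profiles[[1]],
                     noise_model(sigma = 0))
  res <- process_core(s, keep_rois = TRUE)
  for (cmp in compartment_labels())
    expect_identical(res$rois[[cmp]]$mask, unclass(s$geometry[[cmp]]))
})

test_that("ROI statistics are plain masked summaries", {
  img <- matrix(40L, 6, 6)
  mask <- matrix(FALSE, 6, 6); mask[1:3, 1:4] <- TRUE
  roi <- structure(list(compartment = "TZ", mask = mask, area = sum(mask)),
                   class = "compartment_roi")
  core_id <- list(tissue = "cervix", patient = "1", core = "2")
  m <- extract_roi_stats(img, roi, "P", core_id)
  expect_equal(m[, c("mean", "max", "min", "area")],
               data.frame(mean = 40, max = 40L, min = 40L, area = 12L))

  img2 <- matrix(0L, 4, 4)
  mask2 <- matrix(FALSE, 4, 4); mask2[1, 1:4] <- TRUE
  img2[1, ] <- c(10L, 20L, 30L, 100L)
  roi2 <- structure(list(compartment = "CL", mask = mask2, area = 4L),
                    class = "compartment_roi")
  m2 <- extract_roi_stats(img2, roi2, "P", core_id)
  expect_equal(m2$mean, 40)
  expect_equal(m2$max, 100L)
  expect_equal(m2$min, 10L)
  expect_equal(m2$area, 4L)
  expect_error(extract_roi_stats(matrix(0L, 3, 3), roi2, "P", core_id),
               "dimensions")
})

test_that("process_core yields 5 measurements or a named QC failure", {
  d <- study_design(profiles = make_profiles(1))
  s <- generate_core(d, "bronchus", 1, 1, d$profiles[[1]], noise_model())
  res <- process_core(s)
  expect_true(res$qc$passed)
  expect_equal(nrow(res$measurements), 5L)
  expect_setequal(res$measurements$compartment, compartment_labels())
  expect_true(all(res$measurements$min <= res$measurements$mean &
                    res$measurements$mean <= res$measurements$max))

  s$channels$RL[] <- 5000L   # constant marker: degenerate histogram
  res2 <- process_core(s)
  expect_false(res2$qc$passed)
  expect_match(res2$qc$reason, "RL")
  expect_null(res2$measurements)
})

test_that("measurement rows scale as 5 x passing cores with injected failures", {
  d <- study_design(profiles = make_profiles(2))
  st <- generate_study(d, seed = 21, failed_fraction = 0.1)
  seg <- process_study(st$stacks)
  n_failed <- sum(st$cores$failed)
  expect_gt(n_failed, 0)
  expect_equal(sum(!seg$qc$passed), n_failed)
  expect_equal(nrow(seg$measurements), 5L * (length(st$stacks) - n_failed))
  # injected failures are exactly the excluded cores
  key <- function(d) paste(d$protein, d$tissue, d$patient, d$core)
  expect_setequal(key(seg$qc[!seg$qc$passed, ]),
                  key(st$cores[st$cores$failed, ]))
})
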