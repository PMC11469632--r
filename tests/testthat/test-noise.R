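test_that("outlier statistics match direct z-score arithmetic", {
  # nine areas of 1 and one of 20: mean 2.9, population sd ~5.70, z = 3.0
  areas <- c(rep(1, 9), 20)
  st <- outlier_stats(areas)
  expect_equal(st$mean_area, 2.9)
  expect_equal(st$std_area, sqrt(mean((areas - 2.9)^2)))
  expect_equal(st$std_area, 5.7, tolerance = 0.01)
  expect_equal(st$zscores[10], (20 - 2.9) / st$std_area)
  expect_equal(st$zscores[10], 3.0, tolerance = 1e-12)
  expect_equal(st$outlier_idx, 10L)

  # z = 2.0 is under the 2.75 cutoff: nothing flagged
  st2 <- outlier_stats(c(1, 1, 1, 1, 2))
  expect_equal(max(st2$zscores), 2.0)
  expect_equal(length(st2$outlier_idx), 0)

  # equal areas: sd 0, no outliers
  st3 <- outlier_stats(rep(3.3, 7))
  expect_equal(st3$std_area, 0)
  expect_equal(length(st3$outlier_idx), 0)

  expect_error(outlier_stats(numeric(0)), "at least one")
})

test_that("outlier statistics equal the brute-force oracle on 1,000 random vectors", {
  set.seed(123)
  for (i in 1:1000) {
    areas <- rexp(sample(1:40, 1), rate = runif(1, 0.1, 10))
    st <- outlier_stats(areas)
    or <- oracle_outlier(areas)
    expect_equal(st$mean_area, or$mean, tolerance = 1e-12)
    expect_equal(st$std_area, or$sd, tolerance = 1e-12)
    expect_equal(st$zscores, or$z, tolerance = 1e-12)
    expect_identical(st$outlier_idx, or$outliers)
  }
})

test_that("raising the cutoff never flags more lobes", {
  set.seed(8)
  for (i in 1:50) {
    areas <- rlnorm(sample(3:30, 1), sdlog = runif(1, 0.5, 2))
    counts <- vapply(c(1, 1.5, 2, 2.75, 3.5, 5),
                     function(ct) length(outlier_stats(areas, ct)$outlier_idx),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("cropping removes outlier lobes with margins and drops slivers", {
  rec <- pcg_recording(rnorm(40000), 4000)  # 10 s
  # twelve ordinary lobes and one huge one mid-recording; note the z-score
  # of a single extreme among M lobes is bounded by (M-1)/sqrt(M), so the
  # cutoff of 2.75 needs roughly ten lobes before anything can be flagged
  on <- c(seq(0.5, 3.5, by = 0.75), 4.0, seq(5.6, 9.4, by = 0.75))
  lobes <- make_lobes(on, on + c(rep(0.1, 5), 1.0, rep(0.1, 6)),
                      area = c(rep(1, 5), 50, rep(1, 6)))
  st <- outlier_stats(lobes$area)
  expect_equal(st$outlier_idx, 6L)

  iv <- crop_noise(rec, lobes, st)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$start_s, c(0, 5.05))
  expect_equal(iv$end_s, c(3.95, 10))

  # no outliers: the full recording is one clean interval
  st0 <- outlier_stats(rep(1, 12))
  iv0 <- crop_noise(rec, lobes, st0)
  expect_equal(nrow(iv0), 1)
  expect_equal(c(iv0$start_s, iv0$end_s), c(0, 10))

  # an outlier at the very start leaves one clean interval after it
  on2 <- c(0, seq(2, 9.5, by = 0.75))
  lb2 <- make_lobes(on2, on2 + c(1.0, rep(0.1, 11)),
                    area = c(80, rep(1, 11)))
  st2 <- outlier_stats(lb2$area)
  expect_equal(st2$outlier_idx, 1L)
  iv2 <- crop_noise(rec, lb2, st2)
  expect_equal(nrow(iv2), 1)
  expect_equal(iv2$start_s, 1.05)

  # clean intervals shorter than min_clean_s are dropped
  lb3 <- make_lobes(1.0, 1.2, area = 1)
  stx <- outlier_stats(1)
  stx$outlier_idx <- 1L
  expect_equal(nrow(crop_noise(rec, lb3, stx, min_clean_s = 9.5)), 0)
})

test_that("a loud burst at the start is cropped and segmentation succeeds", {
  s <- synth_pcg(synth_config(duration_s = 10, bpm = 85, seed = 17,
                              bursts = list(c(0, 1, 10))))
  seg <- segment_noise_robust(s$recording)
  expect_true(seg$success)
  iv <- tidy(seg)
  # cropped region at the start carries state 0
  expect_equal(iv$label[1], "NOISE")
  expect_lte(iv$start_s[1], 1e-9)
  # truth sounds clear of the burst are recovered
  clean_truth <- s$truth[s$truth$onset > 1.3, ]
  ev <- sensitivity_eval(seg, clean_truth)
  expect_gte(ev$sensitivity, 0.95)
})

test_that("a mid-recording burst leaves both sides segmented", {
  s <- synth_pcg(synth_config(duration_s = 10, bpm = 95, seed = 29,
                              bursts = list(c(4.5, 5.5, 10))))
  seg <- segment_noise_robust(s$recording)
  expect_true(seg$success)
  clean_truth <- s$truth[s$truth$offset < 4.3 | s$truth$onset > 5.7, ]
  ev <- sensitivity_eval(seg, clean_truth)
  expect_gte(ev$sensitivity, 0.95)
  # sounds on both sides of the crop were labeled
  s1 <- tidy(seg)
  s1 <- s1[s1$label == "S1", ]
  expect_true(any(s1$end_s < 4.5) && any(s1$start_s > 5.5))
})

test_that("with no flagged lobe the noise-robust result is bit-identical to base", {
  set.seed(4)
  suite <- synth_suite(5, synth_config(duration_s = 8), seed = 12)
  n_equal <- 0
  for (s in suite) {
    pre <- preprocess(s$recording)
    env <- compute_nase(compute_ase(pre))
    st <- outlier_stats(detect_lobes(env, pre)$area)
    if (length(st$outlier_idx) == 0) {
      expect_identical(tidy(segment_noise_robust(s$recording)),
                       tidy(segment_base(s$recording)))
      n_equal <- n_equal + 1
    }
  }
  expect_gte(n_equal, 1)  # clean defaults should rarely flag anything
})

test_that("pure noise yields a failure result, not an exception", {
  set.seed(6)
  noise <- pcg_recording(rnorm(40000), 4000)
  seg <- segment_noise_robust(noise)
  expect_s3_class(seg, "pcg_segmentation")
  expect_false(seg$success)
  expect_false(segment_base(noise)$success)
})

test_that("noise-robust segmentation rescues burst-corrupted recordings (direction)", {
  n <- 20
  suite <- synth_suite(n, synth_config(duration_s = 10), seed = 500,
                       burst_gain = 10)
  score <- function(seg, truth, cfg) {
    # success in the pooled-analysis sense: every truth sound outside the
    # burst (with margin) is recovered
    burst <- cfg$bursts[[length(cfg$bursts)]]
    tr <- truth[truth$offset < burst[1] - 0.1 | truth$onset > burst[2] + 0.1, ]
    ev <- sensitivity_eval(seg, tr)
    ev$fn == 0 && ev$tp > 0
  }
  base_ok <- robust_ok <- logical(n)
  for (i in seq_len(n)) {
    s <- suite[[i]]
    base_ok[i] <- score(segment_base(s$recording), s$truth, s$config)
    robust_ok[i] <- score(segment_noise_robust(s$recording), s$truth, s$config)
  }
  expect_gte(sum(robust_ok), sum(base_ok))
  expect_gt(sum(robust_ok), 0)
})
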