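test_that("rolling local NV matches hand computations and the loop oracle", {
  # alternating 0/100, window 10: each window has five 0s and five 100s;
  # sample variance = 10 * 2500 / 9, mean = 50
  p <- intensity_profile(rep(c(0, 100), 20), pixel_size_um = 0.05)
  res <- rolling_local_nv(p, window_px = 10)
  expect_equal(unique(round(res$nv, 10)), round((25000 / 9) / 50, 10))
  expect_equal(attr(res, "summary_nv"), (25000 / 9) / 50, tolerance = 1e-12)

  # constant positive profile: zero variance everywhere
  pc <- intensity_profile(rep(7, 40), pixel_size_um = 0.05)
  expect_equal(summary_nv(pc), 0)

  # vectorized implementation vs direct loop on random profiles
  for (seed in 1:5) {
    set.seed(seed)
    x <- runif(200, 1, 200)
    got <- rolling_local_nv(intensity_profile(x, 0.05), window_px = 10)$nv
    expect_equal(got, oracle_rolling_nv(x, 10), tolerance = 1e-10)
  }
})

test_that("local NV respects reversal invariance and offset monotonicity", {
  set.seed(11)
  x <- runif(150, 5, 200)
  fwd <- rolling_local_nv(intensity_profile(x, 0.1), 10)$nv
  rev_ <- rolling_local_nv(intensity_profile(rev(x), 0.1), 10)$nv
  expect_equal(sort(fwd), sort(rev_), tolerance = 1e-12)
  expect_equal(attr(rolling_local_nv(intensity_profile(x, 0.1), 10), "summary_nv"),
               attr(rolling_local_nv(intensity_profile(rev(x), 0.1), 10), "summary_nv"),
               tolerance = 1e-12)
  # adding a positive offset leaves variances but raises means
  shifted <- rolling_local_nv(intensity_profile(x + 50, 0.1), 10)$nv
  expect_true(all(shifted < fwd))
})

test_that("local NV input contracts hold", {
  expect_error(rolling_local_nv(intensity_profile(1:5, 0.1), 10), "shorter")
  expect_error(rolling_local_nv(intensity_profile(1:20, 0.1), 1), ">= 2")
  # zero-intensity windows are excluded from the summary, not divided by 0
  x <- c(rep(0, 30), rep(100, 30))
  res <- rolling_local_nv(intensity_profile(x, 0.1), 10)
  expect_gt(attr(res, "n_excluded"), 0)
  expect_true(is.finite(attr(res, "summary_nv")))
})

test_that("mean intensity and CoV match hand values and invariances", {
  p <- intensity_profile(c(10, 20, 30), pixel_size_um = 1)
  expect_equal(mean_intensity(p), 20)
  expect_equal(coefficient_of_variation(p), 0.5) # SD 10, mean 20
  expect_equal(coefficient_of_variation(intensity_profile(rep(5, 10), 1)), 0)
  # linearity of the mean; scale invariance of the CoV
  set.seed(3)
  x <- runif(50, 10, 100)
  expect_equal(mean_intensity(intensity_profile(x + 12.5, 1)),
               mean_intensity(intensity_profile(x, 1)) + 12.5)
  expect_equal(coefficient_of_variation(intensity_profile(3 * x, 1)),
               coefficient_of_variation(intensity_profile(x, 1)),
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(intensity_profile(rep(0, 5), 1)),
               "not positive")
})

test_that("CoV ratio behaves as a scale-free irregularity contrast", {
  set.seed(4)
  x <- runif(100, 20, 120)
  p1 <- intensity_profile(x, 0.1)
  expect_equal(cov_ratio(p1, p1), 1)
  expect_equal(cov_ratio(intensity_profile(2 * x, 0.1), p1), 1,
               tolerance = 1e-12)
  # ER channel with structured peaks vs smooth PM channel
  pm <- intensity_profile(rep(80, 100) + sin(seq(0, 3, length.out = 100)),
                          0.1)
  peaks <- rep(30, 100)
  peaks[seq(5, 95, by = 10)] <- 200
  er <- intensity_profile(peaks, 0.1)
  expect_gt(cov_ratio(er, pm), 1)
  expect_error(cov_ratio(p1, intensity_profile(rep(9, 100), 0.1)),
               "zero")
})

test_that("gap detection reproduces known fractions and the run oracle", {
  cfg <- sim_config(seed = 1, noise_sd = 0)
  p <- gen_axon_profile(45, list(c(18, 27)), amplitude = 120, config = cfg)
  rep_ <- detect_gaps(p)
  expect_equal(attr(rep_, "gap_percent"), 20)
  expect_equal(nrow(rep_), 1)
  expect_equal(rep_$length_um, 9, tolerance = 1e-9)

  expect_equal(gap_percent(gen_axon_profile(45, list(), 120, cfg)), 0)
  # amplitude 0: everything below threshold after background subtraction
  expect_equal(gap_percent(gen_axon_profile(45, list(), 0, cfg)), 100)
  # background above all intensities is a valid 100% result, not an error
  expect_equal(gap_percent(p, background = 250), 100)

  # random binary masks against the run-length oracle
  for (seed in 1:300) {
    set.seed(seed)
    n <- sample(20:120, 1)
    below <- runif(n) < 0.3
    x <- ifelse(below, 5, 150) # background 0, threshold 20
    prof <- intensity_profile(x, 0.1, background = 0)
    got <- detect_gaps(prof, threshold = 20)
    want <- oracle_profile_gaps(below, 0.1)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_px, unname(want[, "start_px"]))
      expect_equal(got$end_px, unname(want[, "end_px"]))
    }
  }
})

test_that("gap percent is monotone in threshold and honors min_gap_um", {
  set.seed(9)
  x <- runif(300, 0, 120)
  p <- intensity_profile(x, 0.1, background = 0)
  gps <- vapply(c(5, 20, 50, 90), function(th) gap_percent(p, th), numeric(1))
  expect_true(all(diff(gps) >= 0))
  # min_gap_um filters short runs, and gap_percent stays consistent with
  # the retained intervals
  g <- detect_gaps(p, threshold = 60, min_gap_um = 0.5)
  expect_equal(attr(g, "gap_percent"),
               100 * sum(g$end_px - g$start_px + 1) / 300)
  expect_true(all(g$length_um >= 0.5))
})

test_that("profile QC flags saturation instead of dropping data", {
  x <- c(runif(50, 10, 100), 255)
  expect_true(is_saturated(intensity_profile(x, 0.1)))
  expect_false(is_saturated(intensity_profile(runif(50, 10, 100), 0.1)))
  p <- intensity_profile(x, 0.1, background = 5)
  expect_true(attr(detect_gaps(p), "saturated"))
})

test_that("profile_stats returns one tidy row per profile", {
  cfg <- sim_config(seed = 2)
  ps <- list(gen_axon_profile(45, list(c(10, 14)), 120, cfg),
             gen_epidermal_profile("reticular", 12, cfg))
  tb <- profile_stats(ps)
  expect_equal(nrow(tb), 2)
  expect_true(all(c("mean_intensity", "cov", "summary_nv", "gap_percent")
                  %in% names(tb)))
  expect_false(any(is.na(tb$summary_nv)))
})
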