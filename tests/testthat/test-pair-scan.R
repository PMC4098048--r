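# Scan-level M/M' signal-pair detection and m/z clustering.

test_that("the worked 30-carbon pattern yields one pair with z=1, n_c=30", {
  sp <- detect_signal_pairs(fig2c_spectrum())
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$z, 1L)
  expect_equal(sp$n_c, 30L)
  expect_equal(sp$mz_m, 624.3827 + 1.00728)
  expect_equal(sp$mz_mprime, 624.3827 + 1.00728 + 30 * 1.00335)
})

test_that("detection requires all four isotopologue signals", {
  spec <- fig2c_spectrum()
  # remove M' (condition a)
  s1 <- spec; s1$mz <- s1$mz[-4]; s1$intensity <- s1$intensity[-4]
  expect_equal(nrow(detect_signal_pairs(s1)), 0L)
  # double M+1: ratio error 100 % > 20 % tolerance (condition b)
  s2 <- spec; s2$intensity[2] <- 2 * s2$intensity[2]
  expect_equal(nrow(detect_signal_pairs(s2)), 0L)
  # remove M+1 entirely
  s3 <- spec; s3$mz <- s3$mz[-2]; s3$intensity <- s3$intensity[-2]
  expect_equal(nrow(detect_signal_pairs(s3)), 0L)
  # corrupt M'-1 ratio (condition c)
  s4 <- spec; s4$intensity[3] <- 3 * s4$intensity[3]
  expect_equal(nrow(detect_signal_pairs(s4)), 0L)
  # drop M below the 5,000-count threshold
  s5 <- spec; s5$intensity <- s5$intensity / 300
  expect_equal(nrow(detect_signal_pairs(s5)), 0L)
})

test_that("detection deduces the charge from the isotopologue spacing", {
  # doubly charged 30-carbon pattern: spacings of 1.00335/2
  n <- 30L; p_nat <- 0.0111; p_enr <- 0.995
  mz_m <- (624.3827 + 2 * 1.00728) / 2
  mz_mp <- mz_m + n * 1.00335 / 2
  spec <- list(scan_index = 0L, rt_seconds = 5,
               mz = c(mz_m, mz_m + 1.00335 / 2, mz_mp - 1.00335 / 2, mz_mp),
               intensity = c(1e6, 1e6 * expected_m1_ratio(n, p_nat),
                             5e5 * expected_mprime_minus1_ratio(n, p_enr),
                             5e5))
  sp <- detect_signal_pairs(spec)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$z, 2L)
  expect_equal(sp$n_c, 30L)
})

test_that("detection is invariant under intensity rescaling (property)", {
  set.seed(21)
  cfg <- sim_config(n_scans = 40, seed = 21, noise_peaks_per_scan = 30,
                    noise_intensity_range = c(6000, 50000))
  run <- generate_run(random_metabolites(2, cfg, rt_min_sep_scans = 12),
                      cfg, "S1")$run
  scan <- run$spectra[[which.max(vapply(run$spectra,
                                        function(s) sum(s$intensity),
                                        numeric(1)))]]
  base <- detect_signal_pairs(scan)
  expect_gt(nrow(base), 0)
  for (c_scale in c(3, 17.5)) {
    scaled <- scan
    scaled$intensity <- scaled$intensity * c_scale
    got <- detect_signal_pairs(scaled)
    expect_equal(got$mz_m, base$mz_m)
    expect_equal(got$n_c, base$n_c)
    expect_equal(got$z, base$z)
  }
})

test_that("m/z clustering splits at the +/-10 ppm criterion", {
  mk <- function(mzs) data.frame(
    scan_index = seq_along(mzs), rt_seconds = seq_along(mzs), mz_m = mzs,
    mz_mprime = mzs + 10 * 1.00335, z = 1L, n_c = 10L,
    intensity_m = 1e5, intensity_m1 = 1e4, intensity_mprime = 1e5,
    intensity_mprime_minus1 = 1e4)
  # 0.6 ppm apart stays together; 20 ppm away splits
  cl <- cluster_pairs(mk(c(500.0000, 500.0003, 500.0100)), min_scans = 1L)
  expect_equal(nrow(cl), 2L)
  expect_equal(sort(cl$n_members), c(1L, 2L))
  # five identical values: one cluster of five
  cl2 <- cluster_pairs(mk(rep(500.0, 5)))
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$n_members, 5L)
  # two members only do not survive the 3-scan rule
  expect_equal(nrow(cluster_pairs(mk(c(500.0, 500.0)))), 0L)
  # members never deviate more than 10 ppm from their cluster mean
  set.seed(3)
  noisy <- mk(500 * (1 + rnorm(60, 0, 2e-5)))
  cl3 <- cluster_pairs(noisy, min_scans = 1L)
  members <- attr(cl3, "members")
  for (id in cl3$cluster_id) {
    v <- members$mz_m[members$cluster_id == id]
    expect_true(all(abs(v - mean(v)) <= mean(v) * 10e-6))
  }
})

test_that("pairs are partitioned by carbon count and charge before clustering", {
  d <- rbind(
    data.frame(scan_index = 1:3, rt_seconds = 1:3, mz_m = 500.0,
               mz_mprime = 500 + 12 * 1.00335, z = 1L, n_c = 12L,
               intensity_m = 1e5, intensity_m1 = 1e4,
               intensity_mprime = 1e5, intensity_mprime_minus1 = 1e4),
    data.frame(scan_index = 4:6, rt_seconds = 4:6, mz_m = 500.0,
               mz_mprime = 500 + 13 * 1.00335, z = 1L, n_c = 13L,
               intensity_m = 1e5, intensity_m1 = 1e4,
               intensity_mprime = 1e5, intensity_mprime_minus1 = 1e4))
  cl <- cluster_pairs(d)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$n_c, c(12L, 13L))
})
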