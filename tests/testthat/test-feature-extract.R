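# Chromatographic peak picking, feature-pair confirmation, de-isotoping,
# grouping and the plausibility flag.

test_that("CWT picker finds Gaussian peaks with correct apexes", {
  y <- gaussian_trace(120, apex = 50, sigma = 4, height = 1e6)
  pk <- pick_peaks(y)
  expect_equal(nrow(pk), 1L)
  expect_lte(abs(pk$apex_scan - 50), 1)
  # area close to the analytic integral height * sigma * sqrt(2*pi)
  expect_equal(pk$area, 1e6 * 4 * sqrt(2 * pi), tolerance = 0.02)

  y2 <- y + gaussian_trace(120, apex = 90, sigma = 4, height = 8e5)
  pk2 <- pick_peaks(y2)
  expect_equal(nrow(pk2), 2L)
  expect_lte(abs(pk2$apex_scan[1] - 50), 1)
  expect_lte(abs(pk2$apex_scan[2] - 90), 1)

  expect_equal(nrow(pick_peaks(numeric(100))), 0L)
})

make_pair_run <- function(n_scans = 120, apex_m = 50, apex_mp = 50,
                          sigma = 4, mz_m = 500.0, n_c = 10L, z = 1L,
                          h_m = 1e6, h_mp = 8e5,
                          shape_mp = NULL) {
  mz_mp <- mz_m + n_c * 1.00335 / z
  tr_m <- gaussian_trace(n_scans, apex_m, sigma, h_m)
  tr_mp <- if (is.null(shape_mp)) {
    gaussian_trace(n_scans, apex_mp, sigma, h_mp)
  } else shape_mp
  spectra <- lapply(seq_len(n_scans), function(i) {
    mz <- c(mz_m, mz_mp)
    int <- c(tr_m[i], tr_mp[i])
    keep <- int > 1
    list(rt_seconds = i, mz = mz[keep], intensity = int[keep])
  })
  new_run(spectra)
}

cluster_row <- function(mz_m = 500.0, n_c = 10L, z = 1L)
  data.frame(cluster_id = 1L, n_c = n_c, z = z, mean_mz_m = mz_m,
             n_members = 5L)

test_that("co-eluting identical peaks give a feature pair with corr 1", {
  run <- make_pair_run()
  fp <- pair_features(cluster_row(), run)
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$corr, 1, tolerance = 1e-9)
  expect_equal(fp$n_c, 10L)
  expect_gt(fp$area_m, 0)
  expect_gt(fp$area_mprime, 0)
})

test_that("apex shifts beyond 15 scans break the pair", {
  run <- make_pair_run(apex_mp = 70)  # 20 scans > 15
  expect_equal(nrow(pair_features(cluster_row(), run)), 0L)
  # 10 scans is tolerated but correlation decides
  run2 <- make_pair_run(apex_mp = 58)
  fp2 <- pair_features(cluster_row(), run2)
  if (nrow(fp2)) expect_gt(fp2$corr, 0.5)
})

test_that("uncorrelated partner trace gives no pair", {
  set.seed(31)
  flat <- runif(120, 5e3, 1.5e4)
  run <- make_pair_run(shape_mp = flat)
  fp <- pair_features(cluster_row(), run)
  # either no M' peak survives the picker or the correlation fails
  expect_equal(nrow(fp), 0L)
})

test_that("de-isotoping removes M+1 and M'-1 shadow pairs", {
  p_true <- fp_row(625.38998, 30L)
  p_m1 <- fp_row(626.39333, 29L)     # M+1 shadow: mz + 1.00335, n_c - 1
  p_mm1 <- fp_row(625.38998, 29L)    # M'-1 shadow: same mz, n_c - 1
  out1 <- deisotope(rbind(p_true, p_m1))
  expect_equal(out1$n_c, 30L)
  out2 <- deisotope(rbind(p_true, p_mm1))
  expect_equal(out2$n_c, 30L)
  # a single pair is untouched
  expect_equal(nrow(deisotope(p_true)), 1L)
  # non-co-eluting shadow is kept
  p_far <- fp_row(626.39333, 29L, apex = 90L)
  expect_equal(nrow(deisotope(rbind(p_true, p_far))), 2L)
})

test_that("de-isotoping is idempotent (property)", {
  set.seed(32)
  pairs <- do.call(rbind, lapply(1:20, function(i) {
    fp_row(runif(1, 200, 900), sample(5:40, 1),
           z = sample(1:2, 1), apex = sample(30:70, 1))
  }))
  # salt in a few shadows
  pairs <- rbind(pairs,
                 fp_row(pairs$mz_m[1] + 1.00335 / pairs$z[1],
                        pairs$n_c[1] - 1L, z = pairs$z[1],
                        apex = pairs$apex_scan[1]),
                 fp_row(pairs$mz_m[2], pairs$n_c[2] - 1L, z = pairs$z[2],
                        apex = pairs$apex_scan[2]))
  once <- deisotope(pairs)
  twice <- deisotope(once)
  expect_equal(once$mz_m, twice$mz_m)
  expect_equal(once$n_c, twice$n_c)
  expect_equal(nrow(pairs) - nrow(once), 2L)
})

test_that("grouping is a partition driven by co-elution and shape", {
  sh <- gaussian_trace(21, 10, 4, 1e5)
  a <- fp_row(500.0, 10L, apex = 50L, shape = sh)
  b <- fp_row(522.0, 10L, apex = 50L, shape = sh)      # co-eluting adduct
  c <- fp_row(480.0, 10L, apex = 50L, shape = sh)      # third adduct
  d <- fp_row(700.0, 20L, apex = 150L,                 # 100 scans away
              left = 140L, right = 160L, shape = sh)
  g <- group_features(rbind(a, b, c, d))
  expect_equal(length(unique(g$group_id)), 2L)
  expect_equal(g$group_id[1], g$group_id[2])
  expect_equal(g$group_id[1], g$group_id[3])
  # every pair in exactly one group
  expect_false(any(is.na(g$group_id)))
  expect_equal(nrow(g), 4L)

  # co-eluting but anti-correlated shapes stay separate
  up <- seq(0, 1e5, length.out = 21)
  e <- fp_row(500.0, 10L, apex = 50L, shape = up)
  f <- fp_row(510.0, 10L, apex = 50L, shape = rev(up))
  g2 <- group_features(rbind(e, f))
  expect_equal(length(unique(g2$group_id)), 2L)
})

test_that("heavy low-carbon pairs are flagged implausible, not removed", {
  pairs <- rbind(fp_row(751.50728, 5L),    # neutral 750.5, 5 C -> flag
                 fp_row(751.50728, 30L),   # neutral 750.5, 30 C -> ok
                 fp_row(301.00728, 5L))    # neutral 300.0, 5 C -> ok
  out <- plausibility_flag(pairs)
  expect_equal(out$implausible, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(out), 3L)
})
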