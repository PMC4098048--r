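# Cross-sample bracketing and targeted re-integration.

jittered_pairs <- function(mz, rt, n_c = 12L, z = 1L, dmz_ppm = 0,
                           drt = 0, area = 1e6) {
  data.frame(mz_m = mz * (1 + dmz_ppm * 1e-6), rt = rt + drt,
             n_c = n_c, z = z, area_m = area, area_mprime = area / 2)
}

test_that("the same metabolite in three runs becomes one bracket", {
  base <- list(
    S1 = jittered_pairs(500.0, 60, dmz_ppm = 2, drt = -3),
    S2 = jittered_pairs(500.0, 60, dmz_ppm = -1, drt = 2),
    S3 = jittered_pairs(500.0, 60, dmz_ppm = 0.5, drt = 0))
  mat <- bracket(base)
  expect_equal(nrow(mat$features), 1L)
  expect_equal(unname(mat$found_by[1, ]), rep("detected", 3))
  expect_equal(mat$features$consensus_mz_m, 500.0, tolerance = 1e-3)
})

test_that("identical m/z but different carbon count never merges", {
  mat <- bracket(list(S1 = jittered_pairs(500.0, 60, n_c = 12L),
                      S2 = jittered_pairs(500.0, 60, n_c = 13L)))
  expect_equal(nrow(mat$features), 2L)
  expect_setequal(mat$features$n_c, c(12L, 13L))
})

test_that("a single sample passes through as its own brackets", {
  p <- rbind(jittered_pairs(500.0, 60), jittered_pairs(640.2, 120))
  mat <- bracket(list(only = p))
  expect_equal(nrow(mat$features), 2L)
  expect_true(all(mat$found_by == "detected"))
})

test_that("bracketing is sample-order independent (property)", {
  set.seed(41)
  mk_sample <- function(jit) do.call(rbind, lapply(1:8, function(i) {
    jittered_pairs(200 + 70 * i, 30 + 25 * i, n_c = (4 + 3 * i),
                   dmz_ppm = runif(1, -3, 3), drt = runif(1, -3, 3))
  }))
  ss <- list(A = mk_sample(), B = mk_sample(), C = mk_sample())
  m1 <- bracket(ss)
  m2 <- bracket(rev(ss))
  expect_equal(nrow(m1$features), 8L)
  expect_equal(m1$features$n_c, m2$features$n_c)
  expect_equal(m1$features$consensus_mz_m, m2$features$consensus_mz_m)
  expect_equal(m1$area_m[, c("A", "B", "C")], m2$area_m[, c("A", "B", "C")])
})

test_that("re-integration recovers features missed by the pair filter", {
  # metabolite far below the 5,000-count pair threshold in sample 2 but
  # with a clean XIC peak
  cfg <- sim_config(n_scans = 80, seed = 43)
  spec <- metabolite_spec(neutral_mass = 400.2, n_c = 20L, rt_seconds = 40,
                          base_abundance = 2e6,
                          per_sample_factor = c(S1 = 1, S2 = 0.0015))
  g1 <- generate_run(list(spec), cfg, "S1")
  g2 <- generate_run(list(spec), cfg, "S2")
  p1 <- detect_feature_pairs(g1$run, verbose = FALSE)$feature_pairs
  p2 <- detect_feature_pairs(g2$run, verbose = FALSE)$feature_pairs
  expect_equal(nrow(p1), 1L)
  expect_equal(nrow(p2), 0L)   # native apex ~3,000 counts < 5,000 threshold
  mat <- bracket(list(S1 = p1, S2 = p2))
  expect_equal(unname(mat$found_by[1, ]), c("detected", "absent"))
  mat <- reintegrate_matrix(mat, list(S1 = g1$run, S2 = g2$run))
  expect_equal(unname(mat$found_by[1, "S2"]), "reintegrated")
  expect_gt(mat$area_m[1, "S2"], 0)
  # labelled reference is at full strength in both samples
  expect_equal(unname(mat$area_mprime[1, "S2"]),
               unname(mat$area_mprime[1, "S1"]), tolerance = 0.05)
})

test_that("re-integration leaves truly absent features absent", {
  cfg <- sim_config(n_scans = 60, seed = 44)
  g_blank <- generate_run(list(), sim_config(n_scans = 60, seed = 44,
                                             mode = "blank"), "S2")
  spec <- metabolite_spec(neutral_mass = 400.2, n_c = 20L, rt_seconds = 30,
                          base_abundance = 1e6)
  g1 <- generate_run(list(spec), cfg, "S1")
  p1 <- detect_feature_pairs(g1$run, verbose = FALSE)$feature_pairs
  mat <- bracket(list(S1 = p1, S2 = p1[0, ]))
  mat <- reintegrate_matrix(mat, list(S1 = g1$run, S2 = g_blank$run))
  expect_equal(unname(mat$found_by[1, "S2"]), "absent")
  expect_true(is.na(mat$area_m[1, "S2"]))
})
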