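# mzML / mzXML reading, the Run container and XIC extraction.

test_that("write -> read round-trips a simulated mzML run losslessly", {
  set.seed(5)
  cfg <- sim_config(n_scans = 40, seed = 5, noise_peaks_per_scan = 10)
  specs <- random_metabolites(2, cfg, rt_min_sep_scans = 12)
  run <- generate_run(specs, cfg, "S1")$run
  path <- withr::local_tempfile(fileext = ".mzML")
  write_run(run, path)
  back <- read_run(path)
  expect_equal(n_scans(back), n_scans(run))
  expect_equal(back$rt, run$rt, tolerance = 1e-4)
  for (i in seq_len(n_scans(run))) {
    expect_equal(back$spectra[[i]]$mz, run$spectra[[i]]$mz,
                 tolerance = 1e-6)
    expect_equal(back$spectra[[i]]$intensity, run$spectra[[i]]$intensity,
                 tolerance = 1e-3)
  }
})

test_that("gzip-compressed mzML is accepted", {
  set.seed(6)
  cfg <- sim_config(n_scans = 12, seed = 6)
  run <- generate_run(random_metabolites(1, cfg, rt_min_sep_scans = 5),
                      cfg, "S1")$run
  plain <- withr::local_tempfile(fileext = ".mzML")
  write_run(run, plain)
  gz <- withr::local_tempfile(fileext = ".mzML.gz")
  con <- gzfile(gz, "wb")
  writeLines(readLines(plain), con)
  close(con)
  back <- read_run(gz)
  expect_equal(n_scans(back), n_scans(run))
})

test_that("MS2 spectra are skipped in both dialects", {
  # mzXML fixture: scans 1 and 3 are MS1, scan 2 is MS2; first peaks
  # block is zlib-compressed big-endian
  path <- withr::local_tempfile(fileext = ".mzXML")
  writeLines(mzxml_fixture(), path)
  run <- read_run(path)
  expect_equal(n_scans(run), 2L)
  expect_equal(run$rt, c(10.5, 12.0))
  expect_equal(run$spectra[[1]]$mz, c(100.5, 200.25))
  expect_equal(run$spectra[[2]]$intensity, 3e4)

  # mzML: rewrite the first spectrum of a valid file as MS2
  set.seed(7)
  cfg <- sim_config(n_scans = 12, seed = 7)
  run0 <- generate_run(random_metabolites(1, cfg, rt_min_sep_scans = 5),
                       cfg, "S1")$run
  p2 <- withr::local_tempfile(fileext = ".mzML")
  write_run(run0, p2)
  txt <- readChar(p2, file.info(p2)$size)
  txt <- sub('name="ms level" value="1"', 'name="ms level" value="2"', txt)
  writeLines(txt, p2)
  expect_equal(n_scans(read_run(p2)), n_scans(run0) - 1L)
})

test_that("profile-mode data and unreadable files raise errors", {
  set.seed(8)
  cfg <- sim_config(n_scans = 12, seed = 8)
  run <- generate_run(random_metabolites(1, cfg, rt_min_sep_scans = 5),
                      cfg, "S1")$run
  path <- withr::local_tempfile(fileext = ".mzML")
  write_run(run, path)
  txt <- readChar(path, file.info(path)$size)
  txt <- gsub('accession="MS:1000127" name="centroid spectrum"',
              'accession="MS:1000128" name="profile spectrum"', txt)
  writeLines(txt, path)
  expect_error(read_run(path), "centroid")

  expect_error(read_run(withr::local_tempfile()), "not found")
  empty <- withr::local_tempfile(fileext = ".mzML")
  writeLines("", empty)
  expect_error(read_run(empty), "cannot parse|no MS1")
  garbled <- withr::local_tempfile(fileext = ".mzML")
  writeLines("<mzML><spectrumList></spectrumLis", garbled)
  expect_error(read_run(garbled))
})

test_that("XIC extraction sums peaks within the ppm window", {
  run <- run_with_peak(5, scan = 3L, mz = 500.0, intensity = 1e5)
  x <- extract_xic(run, 500.0, 2.5)
  expect_equal(x$intensities, c(0, 0, 0, 1e5, 0))
  # target 20 ppm away: empty trace
  expect_equal(extract_xic(run, 500.01, 2.5)$intensities, rep(0, 5))
  # split centroids 1.2 and 0.6 ppm from the target are summed
  run2 <- new_run(list(list(rt_seconds = 1, mz = c(500.0, 500.0006),
                            intensity = c(1e4, 2e4))))
  expect_equal(extract_xic(run2, 500.0003, 2.5)$intensities, 3e4)
})

test_that("XIC intensity is monotonically non-decreasing in ppm", {
  set.seed(9)
  cfg <- sim_config(n_scans = 30, seed = 9, noise_peaks_per_scan = 40)
  run <- generate_run(random_metabolites(1, cfg, rt_min_sep_scans = 5),
                      cfg, "S1")$run
  targets <- c(runif(5, 100, 1000), run$index$mz[1])
  for (tgt in targets) {
    prev <- rep(0, n_scans(run))
    for (ppm in c(0.5, 2.5, 10, 50)) {
      cur <- extract_xic(run, tgt, ppm)$intensities
      expect_true(all(cur >= prev - 1e-9))
      prev <- cur
    }
  }
})

test_that("TSV tables round-trip", {
  d <- data.frame(mz_m = c(500.1234, 600.5), n_c = c(10L, 20L),
                  sample = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(d, path)
  expect_equal(read_tsv_table(path), d)
})
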