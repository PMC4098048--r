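# Shared in-code fixtures: no binary files, everything built at test time.

DC <- 1.00335
PROTON <- 1.00728

# One centroid spectrum holding the worked [M+H]+ pattern of a 30-carbon
# metabolite (neutral mass 624.3827 u): M, M+1, M'-1, M' with first-order
# binomial abundances at natural and enriched incorporation.
fig2c_spectrum <- function(n_c = 30L, neutral = 624.3827, p_nat = 0.0111,
                           p_enr = 0.995, intensity_m = 1e6,
                           intensity_mprime = 5e5) {
  mz_m <- neutral + PROTON
  mz_mp <- mz_m + n_c * DC
  mz <- c(mz_m, mz_m + DC, mz_mp - DC, mz_mp)
  int <- c(intensity_m,
           intensity_m * expected_m1_ratio(n_c, p_nat),
           intensity_mprime * expected_mprime_minus1_ratio(n_c, p_enr),
           intensity_mprime)
  list(scan_index = 0L, rt_seconds = 10, mz = mz, intensity = int)
}

gaussian_trace <- function(n, apex, sigma, height) {
  height * exp(-((seq_len(n) - 1 - apex)^2) / (2 * sigma^2))
}

# minimal run: one peak (mz, intensity) placed in chosen scans
run_with_peak <- function(n_scans, scan, mz, intensity) {
  spectra <- lapply(seq_len(n_scans), function(i) {
    if ((i - 1L) %in% scan) {
      list(rt_seconds = i, mz = mz, intensity = intensity)
    } else {
      list(rt_seconds = i, mz = numeric(0), intensity = numeric(0))
    }
  })
  new_run(spectra)
}

# a synthetic feature-pair row for de-isotoping / grouping tests
fp_row <- function(mz_m, n_c, z = 1L, apex = 50L, shape = NULL,
                   left = apex - 10L, right = apex + 10L,
                   area_m = 1e6, area_mprime = 1e6) {
  if (is.null(shape)) {
    shape <- gaussian_trace(right - left + 1, apex - left, 4, 1e5)
  }
  d <- data.frame(mz_m = mz_m, mz_mprime = mz_m + n_c * DC / z,
                  rt = apex, apex_scan = as.integer(apex),
                  left_scan = as.integer(left), right_scan = as.integer(right),
                  area_m = area_m, area_mprime = area_mprime,
                  n_c = as.integer(n_c), z = as.integer(z), corr = 1,
                  cluster_id = 1L)
  d$shape_m <- list(shape)
  d
}

# hand-written mzXML document (big-endian, optional zlib) as a string
mzxml_fixture <- function() {
  enc <- function(mz, int, compress = FALSE) {
    r <- writeBin(as.double(rbind(mz, int)), raw(), size = 8, endian = "big")
    if (compress) r <- memCompress(r, "gzip")
    jsonlite::base64_enc(r)
  }
  paste0(
    '<mzXML><msRun scanCount="3">',
    '<scan num="1" msLevel="1" peaksCount="2" retentionTime="PT10.5S">',
    '<peaks precision="64" compressionType="zlib">',
    enc(c(100.5, 200.25), c(1e4, 2e4), TRUE), '</peaks></scan>',
    '<scan num="2" msLevel="2" peaksCount="1" retentionTime="PT11.0S">',
    '<peaks precision="64">', enc(50, 5), '</peaks></scan>',
    '<scan num="3" msLevel="1" peaksCount="1" retentionTime="PT12.0S">',
    '<peaks precision="64">', enc(300.125, 3e4), '</peaks></scan>',
    '</msRun></mzXML>')
}

# match every ground-truth ion against a feature-pair table; returns the
# number of truth rows with a matching pair (same n_c, z, mz within ppm,
# rt within tol)
truth_hits <- function(truth, pairs, ppm = 10, rt_tol = 10) {
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    any(abs(pairs$mz_m - truth$mz_m[i]) <=
          truth$mz_m[i] * ppm * 1e-6 &
        pairs$n_c == truth$n_c[i] & pairs$z == truth$z[i] &
        abs(pairs$rt - truth$rt_seconds[i]) <= rt_tol)
  }, logical(1))
  sum(hits)
}
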