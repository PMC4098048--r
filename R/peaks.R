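# Continuous-wavelet-transform chromatographic peak detection.
#
# Mexican-hat (Ricker) wavelet responses are computed over a small set of
# scales; local maxima are linked into ridge lines across scales, filtered
# by ridge length and signal-to-noise, and peak boundaries are located on
# the raw trace around the ridge apex. Deterministic for fixed input.

ricker <- function(points, scale) {
  x <- seq(-points / 2, points / 2, length.out = points)
  a <- x / scale
  (2 / (sqrt(3 * scale) * pi^0.25)) * (1 - a^2) * exp(-a^2 / 2)
}

cwt_row <- function(y, scale) {
  n <- length(y)
  w <- ricker(min(10L * scale, n), scale)
  # centred convolution, zero-padded edges
  full <- stats::convolve(y, rev(w), type = "open")
  off <- floor(length(w) / 2)
  full[(off + 1):(off + n)]
}

local_maxima <- function(v, min_dist = 1L) {
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  idx[v[idx] > 0]
}

#' Parameters for chromatographic feature extraction
#'
#' @param max_shift_scans Maximum apex shift (scans) tolerated between the
#'   M and M' chromatographic peaks of a feature pair.
#' @param min_peak_corr Minimum Pearson correlation of the two peak shapes
#'   for a valid feature pair (strictly greater than).
#' @param group_window_scans Apex window (scans) for convoluting feature
#'   pairs of one metabolite into a feature group.
#' @param group_corr Minimum Pearson correlation for two features to be
#'   grouped (at least).
#' @param cwt_scales Wavelet scales in scans; should straddle the expected
#'   chromatographic peak sigma.
#' @param cwt_snr Minimum ridge signal-to-noise ratio.
#' @param min_ridge_len Minimum number of scales a ridge must persist over.
#' @param xic_ppm Half-width (ppm) of the XIC extraction window; slightly
#'   wider than the scan-level matching tolerance so that jittered
#'   centroids are not clipped at peak edges.
#' @return List of class `sil_feature_params`.
#' @export
feature_params <- function(max_shift_scans = 15L, min_peak_corr = 0.5,
                           group_window_scans = 10L, group_corr = 0.85,
                           cwt_scales = c(2, 3, 4, 6, 8, 12),
                           cwt_snr = 3, min_ridge_len = 3L, xic_ppm = 5) {
  stopifnot(min_peak_corr > 0, min_peak_corr <= 1,
            group_corr > 0, group_corr <= 1,
            max_shift_scans >= 1, group_window_scans >= 1, xic_ppm > 0)
  structure(list(max_shift_scans = as.integer(max_shift_scans),
                 min_peak_corr = min_peak_corr,
                 group_window_scans = as.integer(group_window_scans),
                 group_corr = group_corr, cwt_scales = cwt_scales,
                 cwt_snr = cwt_snr, min_ridge_len = as.integer(min_ridge_len),
                 xic_ppm = xic_ppm),
            class = "sil_feature_params")
}

#' Pick chromatographic peaks on an XIC
#'
#' Mexican-hat CWT ridge-line detection with SNR filtering. Boundaries are
#' the intensity minima of the raw trace within three best-scale widths of
#' the apex; the area is the trapezoidal sum of the raw XIC between the
#' boundaries (scan units).
#'
#' @param xic An [extract_xic()] object, or a bare numeric vector.
#' @param params [feature_params()].
#' @return `data.frame` with columns `apex_scan`, `left_scan`, `right_scan`
#'   (0-based scan indices), `area`, `height`, `snr`, `scale`.
#' @export
pick_peaks <- function(xic, params = feature_params()) {
  y <- if (inherits(xic, "sil_xic")) xic$intensities else as.numeric(xic)
  empty <- data.frame(apex_scan = integer(0), left_scan = integer(0),
                      right_scan = integer(0), area = numeric(0),
                      height = numeric(0), snr = numeric(0),
                      scale = numeric(0))
  n <- length(y)
  if (n < 5 || all(y <= 0)) return(empty)
  scales <- sort(params$cwt_scales)
  scales <- scales[scales * 4 < n]
  if (!length(scales)) scales <- min(params$cwt_scales)
  coefs <- vapply(scales, function(s) cwt_row(y, s), numeric(n))
  # noise level: MAD of smallest-scale coefficients (floor avoids 0 on
  # sparse traces)
  noise <- max(stats::mad(coefs[, 1]), 1e-8 * max(abs(coefs)), 1e-12)

  # ridge linking: start from maxima at the largest scale, follow down
  maxima <- lapply(seq_along(scales), function(k)
    local_maxima(coefs[, k]))
  used <- lapply(maxima, function(m) logical(length(m)))
  ridges <- list()
  for (k in rev(seq_along(scales))) {
    for (j in seq_along(maxima[[k]])) {
      if (used[[k]][j]) next
      pos <- maxima[[k]][j]
      ridge_pos <- pos
      ridge_val <- coefs[pos, k]
      ridge_scale <- scales[k]
      used[[k]][j] <- TRUE
      cur <- pos
      gap <- 0L
      if (k > 1) for (k2 in (k - 1):1) {
        cand <- maxima[[k2]]
        free <- which(!used[[k2]])
        if (!length(free)) { gap <- gap + 1L; if (gap > 2L) break; next }
        d <- abs(cand[free] - cur)
        win <- max(2, scales[k2])
        if (!length(d) || min(d) > win) {
          gap <- gap + 1L
          if (gap > 2L) break
          next
        }
        gap <- 0L
        jj <- free[which.min(d)]
        used[[k2]][jj] <- TRUE
        cur <- cand[jj]
        ridge_pos <- c(ridge_pos, cur)
        v <- coefs[cur, k2]
        if (v > ridge_val) { ridge_val <- v; ridge_scale <- scales[k2] }
      }
      ridges[[length(ridges) + 1L]] <-
        list(len = length(ridge_pos), val = ridge_val, scale = ridge_scale,
             apex = ridge_pos[which.max(
               coefs[cbind(ridge_pos,
                           match(ridge_scale, scales))] )][1],
             positions = ridge_pos)
    }
  }
  if (!length(ridges)) return(empty)
  out <- list()
  for (r in ridges) {
    if (r$len < min(params$min_ridge_len, length(scales))) next
    if (r$val / noise < params$cwt_snr) next
    # apex refined to the raw-intensity maximum near the ridge's
    # smallest-scale position (best localisation)
    w <- max(2L, ceiling(r$scale))
    apex0 <- r$positions[length(r$positions)]
    lo <- max(1L, apex0 - w); hi <- min(n, apex0 + w)
    apex <- lo + which.max(y[lo:hi]) - 1L
    if (y[apex] <= 0) next
    # boundaries: minima of the raw trace within 3 scale-widths
    bw <- max(3L, ceiling(3 * r$scale))
    ls <- max(1L, apex - bw); rs <- min(n, apex + bw)
    left <- ls + which.min(y[ls:apex]) - 1L
    right <- apex + which.min(y[apex:rs]) - 1L
    if (right - left < 2L) next
    seg <- y[left:right]
    area <- sum((seg[-1] + seg[-length(seg)]) / 2)
    out[[length(out) + 1L]] <-
      data.frame(apex_scan = apex - 1L, left_scan = left - 1L,
                 right_scan = right - 1L, area = area, height = y[apex],
                 snr = r$val / noise, scale = r$scale)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  # deduplicate ridges that landed on the same apex: keep strongest
  res <- res[order(res$apex_scan, -res$snr), , drop = FALSE]
  res <- res[!duplicated(res$apex_scan), , drop = FALSE]
  # suppress shoulder detections closer than 2 scans to a stronger apex
  res <- res[order(-res$height), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    close_by <- abs(res$apex_scan - res$apex_scan[i]) <= 2 &
      seq_len(nrow(res)) > i
    keep[close_by] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$apex_scan), , drop = FALSE]
  rownames(res) <- NULL
  res
}
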