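# Cross-sample matching (bracketing) of feature pairs into one data
# matrix, plus targeted re-integration of features initially missed by
# the restrictive pair-detection criteria.

#' Bracketing parameters
#'
#' Matching keys are compared in the order carbon count (exact), m/z
#' (ppm), retention time; the tolerances default to the values used for
#' cross-method result matching (+/-10 ppm, +/-0.15 min).
#'
#' @param ppm m/z matching tolerance (ppm).
#' @param rt_tol_seconds Retention-time tolerance (seconds).
#' @return List of class `sil_bracket_params`.
#' @export
bracket_params <- function(ppm = 10, rt_tol_seconds = 9) {
  stopifnot(ppm > 0, rt_tol_seconds > 0)
  structure(list(ppm = ppm, rt_tol_seconds = rt_tol_seconds),
            class = "sil_bracket_params")
}

#' Bracket feature pairs across samples
#'
#' Pairs from all samples are matched greedily: the unassigned pair with
#' the largest total area anchors a bracket, and from every sample the
#' nearest unassigned pair with identical `n_c` and `z`, m/z within `ppm`
#' and retention time within `rt_tol_seconds` joins it (at most one per
#' sample). Consensus m/z and rt are intensity-weighted means of the
#' members. Pairs differing in `n_c` or `z` are never merged.
#'
#' @param per_sample_pairs Named list: sample id -> feature-pair table
#'   ([group_features()] output or earlier).
#' @param params [bracket_params()].
#' @return Object of class `sil_matrix`: list with `features` (one row per
#'   bracket: `feature_id`, `consensus_mz_m`, `consensus_rt`, `n_c`, `z`),
#'   numeric matrices `area_m`, `area_mprime` (feature x sample, NA where
#'   absent) and character matrix `found_by` (`"detected"`,
#'   `"reintegrated"`, `"absent"`).
#' @export
bracket <- function(per_sample_pairs, params = bracket_params()) {
  stopifnot(length(per_sample_pairs) >= 1, !is.null(names(per_sample_pairs)))
  samples <- names(per_sample_pairs)
  pool <- do.call(rbind, lapply(samples, function(s) {
    d <- per_sample_pairs[[s]]
    if (!nrow(d)) return(NULL)
    data.frame(sample = s, mz_m = d$mz_m, rt = d$rt,
               n_c = d$n_c, z = d$z,
               area_m = d$area_m, area_mprime = d$area_mprime,
               stringsAsFactors = FALSE)
  }))
  features <- data.frame(feature_id = integer(0), consensus_mz_m = numeric(0),
                         consensus_rt = numeric(0), n_c = integer(0),
                         z = integer(0))
  nsmp <- length(samples)
  if (is.null(pool) || !nrow(pool)) {
    m <- matrix(NA_real_, 0, nsmp, dimnames = list(NULL, samples))
    fb <- matrix("absent", 0, nsmp, dimnames = list(NULL, samples))
    return(structure(list(features = features, area_m = m, area_mprime = m,
                          found_by = fb, samples = samples),
                     class = "sil_matrix"))
  }
  # deterministic greedy order: strongest total area first
  ord <- order(-(pool$area_m + pool$area_mprime), pool$mz_m, pool$sample)
  pool <- pool[ord, , drop = FALSE]
  assigned <- logical(nrow(pool))
  bracket_rows <- list()
  for (i in seq_len(nrow(pool))) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    members <- i
    anchor <- pool[i, ]
    tol_mz <- anchor$mz_m * params$ppm * 1e-6
    for (s in samples) {
      if (s == anchor$sample) next
      cand <- which(!assigned & pool$sample == s &
                      pool$n_c == anchor$n_c & pool$z == anchor$z &
                      abs(pool$mz_m - anchor$mz_m) <= tol_mz &
                      abs(pool$rt - anchor$rt) <= params$rt_tol_seconds)
      if (!length(cand)) next
      j <- cand[order(abs(pool$mz_m[cand] - anchor$mz_m),
                      abs(pool$rt[cand] - anchor$rt))][1]
      assigned[j] <- TRUE
      members <- c(members, j)
    }
    mem <- pool[members, , drop = FALSE]
    w <- mem$area_m
    if (all(w <= 0)) w <- rep(1, nrow(mem))
    bracket_rows[[length(bracket_rows) + 1L]] <- list(
      consensus_mz_m = sum(mem$mz_m * w) / sum(w),
      consensus_rt = sum(mem$rt * w) / sum(w),
      n_c = anchor$n_c, z = anchor$z, members = mem)
  }
  nb <- length(bracket_rows)
  area_m <- matrix(NA_real_, nb, nsmp, dimnames = list(NULL, samples))
  area_mp <- matrix(NA_real_, nb, nsmp, dimnames = list(NULL, samples))
  found_by <- matrix("absent", nb, nsmp, dimnames = list(NULL, samples))
  features <- data.frame(
    feature_id = seq_len(nb),
    consensus_mz_m = vapply(bracket_rows, `[[`, numeric(1), "consensus_mz_m"),
    consensus_rt = vapply(bracket_rows, `[[`, numeric(1), "consensus_rt"),
    n_c = vapply(bracket_rows, function(b) as.integer(b$n_c), integer(1)),
    z = vapply(bracket_rows, function(b) as.integer(b$z), integer(1)))
  for (b in seq_len(nb)) {
    mem <- bracket_rows[[b]]$members
    for (k in seq_len(nrow(mem))) {
      area_m[b, mem$sample[k]] <- mem$area_m[k]
      area_mp[b, mem$sample[k]] <- mem$area_mprime[k]
      found_by[b, mem$sample[k]] <- "detected"
    }
  }
  # stable row order: by mz then rt
  o <- order(features$consensus_mz_m, features$consensus_rt)
  features <- features[o, , drop = FALSE]
  features$feature_id <- seq_len(nb)
  rownames(features) <- NULL
  structure(list(features = features, area_m = area_m[o, , drop = FALSE],
                 area_mprime = area_mp[o, , drop = FALSE],
                 found_by = found_by[o, , drop = FALSE], samples = samples),
            class = "sil_matrix")
}

#' @export
print.sil_matrix <- function(x, ...) {
  cat("<sil_matrix> ", nrow(x$features), " bracketed feature pairs x ",
      length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' Targeted re-integration of one bracket in one run
#'
#' For a bracket missing from a sample, peaks are picked in the M and M'
#' XICs and accepted when their apex lies within the bracket's
#' retention-time window — without the abundance-ratio or peak-shape
#' checks of the primary detection path. M and M' must still co-elute
#' within `max_shift_scans` when both are found; otherwise only the M
#' area is returned. Nothing found leaves the cell absent (no zero
#' imputation).
#'
#' @param run The sample's `sil_run`.
#' @param feature One row of `sil_matrix$features`.
#' @param params [bracket_params()].
#' @param fparams [feature_params()].
#' @return List with `area_m`, `area_mprime` (NA when not found) and
#'   `found` (logical).
#' @export
reintegrate <- function(run, feature, params = bracket_params(),
                        fparams = feature_params()) {
  dc <- 1.00335
  mz_m <- feature$consensus_mz_m
  mz_mp <- mz_m + feature$n_c * dc / feature$z
  find_peak <- function(target) {
    pk <- pick_peaks(extract_xic(run, target, fparams$xic_ppm), fparams)
    if (!nrow(pk)) return(NULL)
    rt_apex <- run$rt[pk$apex_scan + 1L]
    ok <- which(abs(rt_apex - feature$consensus_rt) <= params$rt_tol_seconds)
    if (!length(ok)) return(NULL)
    pk[ok[which.min(abs(rt_apex[ok] - feature$consensus_rt))], , drop = FALSE]
  }
  pm <- find_peak(mz_m)
  pmp <- find_peak(mz_mp)
  if (!is.null(pm) && !is.null(pmp) &&
      abs(pm$apex_scan - pmp$apex_scan) > fparams$max_shift_scans) {
    pmp <- NULL  # co-elution still enforced in targeted mode
  }
  list(area_m = if (is.null(pm)) NA_real_ else pm$area,
       area_mprime = if (is.null(pmp)) NA_real_ else pmp$area,
       found = !is.null(pm) || !is.null(pmp))
}

#' Re-integrate all missing cells of a data matrix
#'
#' @param mat A `sil_matrix` from [bracket()].
#' @param runs Named list of `sil_run` objects (names = sample ids).
#' @param params [bracket_params()].
#' @param fparams [feature_params()].
#' @return The matrix with recovered areas filled in and `found_by` set to
#'   `"reintegrated"` where anything was recovered.
#' @export
reintegrate_matrix <- function(mat, runs, params = bracket_params(),
                               fparams = feature_params()) {
  stopifnot(inherits(mat, "sil_matrix"))
  for (s in mat$samples) {
    if (is.null(runs[[s]])) next
    miss <- which(mat$found_by[, s] == "absent")
    for (b in miss) {
      res <- reintegrate(runs[[s]], mat$features[b, ], params, fparams)
      if (res$found) {
        mat$area_m[b, s] <- res$area_m
        mat$area_mprime[b, s] <- res$area_mprime
        mat$found_by[b, s] <- "reintegrated"
      }
    }
  }
  mat
}
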