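# Chromatographic confirmation of scan-level signal pairs: XIC peak
# picking, co-elution / shape-correlation pairing, de-isotoping and
# convolution of feature pairs into per-metabolite feature groups.

# Pearson correlation of two peak shapes over the union of their boundary
# windows; scans absent from one window count as 0 intensity.
shape_correlation <- function(y1, win1, y2, win2) {
  lo <- min(win1[1], win2[1])
  hi <- max(win1[2], win2[2])
  idx <- lo:hi
  v1 <- numeric(length(idx))
  v2 <- numeric(length(idx))
  s1 <- idx >= win1[1] & idx <= win1[2]
  s2 <- idx >= win2[1] & idx <= win2[2]
  v1[s1] <- y1[idx[s1] + 1L]
  v2[s2] <- y2[idx[s2] + 1L]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(0)
  stats::cor(v1, v2)
}

empty_feature_pairs <- function() {
  d <- data.frame(mz_m = numeric(0), mz_mprime = numeric(0),
                  rt = numeric(0), apex_scan = integer(0),
                  left_scan = integer(0), right_scan = integer(0),
                  area_m = numeric(0), area_mprime = numeric(0),
                  n_c = integer(0), z = integer(0), corr = numeric(0),
                  cluster_id = integer(0))
  d$shape_m <- list()
  d
}

#' Confirm one m/z cluster chromatographically into feature pairs
#'
#' XICs are extracted at the cluster's mean monoisotopic m/z and at the
#' corresponding labelled m/z (`+ n_C * 1.00335 / z`); chromatographic
#' peaks are picked on both traces, each M peak is matched to the nearest
#' M' peak within `max_shift_scans`, and the Pearson correlation of the
#' two peak shapes (union of boundary windows, absent scans = 0) must
#' exceed `min_peak_corr`.
#'
#' @param cluster One row of [cluster_pairs()] output (or a list with
#'   `mean_mz_m`, `n_c`, `z`, `cluster_id`).
#' @param run The `sil_run` the cluster came from.
#' @param params [feature_params()].
#' @return Feature-pair `data.frame`; the M peak shape is kept in the list
#'   column `shape_m` for later grouping.
#' @export
pair_features <- function(cluster, run, params = feature_params()) {
  dc <- 1.00335
  mz_m <- cluster$mean_mz_m
  mz_mp <- mz_m + cluster$n_c * dc / cluster$z
  xic_m <- extract_xic(run, mz_m, params$xic_ppm)
  xic_mp <- extract_xic(run, mz_mp, params$xic_ppm)
  pk_m <- pick_peaks(xic_m, params)
  pk_mp <- pick_peaks(xic_mp, params)
  if (!nrow(pk_m) || !nrow(pk_mp)) return(empty_feature_pairs())
  out <- empty_feature_pairs()
  for (i in seq_len(nrow(pk_m))) {
    d <- abs(pk_mp$apex_scan - pk_m$apex_scan[i])
    cand <- which(d <= params$max_shift_scans)
    if (!length(cand)) next
    # nearest apex wins; ties toward higher M' area
    cand <- cand[order(d[cand], -pk_mp$area[cand])]
    j <- cand[1]
    corr <- shape_correlation(
      xic_m$intensities, c(pk_m$left_scan[i], pk_m$right_scan[i]),
      xic_mp$intensities, c(pk_mp$left_scan[j], pk_mp$right_scan[j]))
    if (is.na(corr) || corr <= params$min_peak_corr) next
    row <- data.frame(mz_m = mz_m, mz_mprime = mz_mp,
                      rt = run$rt[pk_m$apex_scan[i] + 1L],
                      apex_scan = pk_m$apex_scan[i],
                      left_scan = pk_m$left_scan[i],
                      right_scan = pk_m$right_scan[i],
                      area_m = pk_m$area[i], area_mprime = pk_mp$area[j],
                      n_c = as.integer(cluster$n_c),
                      z = as.integer(cluster$z),
                      corr = corr,
                      cluster_id = as.integer(cluster$cluster_id))
    row$shape_m <- list(xic_m$intensities[
      (pk_m$left_scan[i] + 1L):(pk_m$right_scan[i] + 1L)])
    out <- rbind(out, row)
  }
  out
}

#' Confirm all clusters of a run
#'
#' @param clusters [cluster_pairs()] output.
#' @param run The `sil_run`.
#' @param params [feature_params()].
#' @return Combined feature-pair table.
#' @export
pair_features_run <- function(clusters, run, params = feature_params()) {
  if (!nrow(clusters)) return(empty_feature_pairs())
  out <- lapply(seq_len(nrow(clusters)), function(i)
    pair_features(clusters[i, ], run, params))
  do.call(rbind, out)
}

#' Remove isotopologue shadows from a feature-pair list
#'
#' An M+1 feature mistakenly picked as monoisotopic, or an M'-1 feature
#' mistakenly picked as fully labelled, shows one carbon less than the
#' true pair and either an m/z increased by `1.00335 / z` (M+1 shadow) or
#' the same monoisotopic m/z (M'-1 shadow). A pair P is removed iff a
#' co-eluting pair Q with the same charge exists such that
#' `n_c(P) == n_c(Q) - 1` and the m/z relation holds within `ppm`.
#' Removal is decided against the original list in a single pass, which
#' makes the operation idempotent and order-independent.
#'
#' @param pairs Feature-pair table.
#' @param ppm m/z tolerance.
#' @param rt_tol_scans Co-elution tolerance on the apex (scans).
#' @return Filtered feature-pair table.
#' @export
deisotope <- function(pairs, ppm = 2.5, rt_tol_scans = 15L) {
  if (nrow(pairs) < 2) return(pairs)
  dc <- 1.00335
  drop <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    q <- which(pairs$z == pairs$z[i] &
                 abs(pairs$apex_scan - pairs$apex_scan[i]) <= rt_tol_scans &
                 pairs$n_c == pairs$n_c[i] + 1L)
    if (!length(q)) next
    tol <- pairs$mz_m[i] * ppm * 1e-6
    shadow_m1 <- abs(pairs$mz_m[i] -
                       (pairs$mz_m[q] + dc / pairs$z[i])) <= tol
    shadow_mm1 <- abs(pairs$mz_m[i] - pairs$mz_m[q]) <= tol
    if (any(shadow_m1 | shadow_mm1)) drop[i] <- TRUE
  }
  pairs[!drop, , drop = FALSE]
}

#' Convolute feature pairs into per-metabolite feature groups
#'
#' Two feature pairs are connected iff their monoisotopic apexes lie
#' within `group_window_scans` of each other and the Pearson correlation
#' of their M peak shapes is at least `group_corr`; feature groups are the
#' connected components of this graph, so every pair belongs to exactly
#' one group.
#'
#' @param pairs De-isotoped feature-pair table (with `shape_m` column).
#' @param params [feature_params()].
#' @return The input with a `group_id` column appended.
#' @export
group_features <- function(pairs, params = feature_params()) {
  n <- nrow(pairs)
  if (n == 0) {
    pairs$group_id <- integer(0)
    return(pairs)
  }
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(pairs$apex_scan[i] - pairs$apex_scan[j]) >
              params$group_window_scans) next
        corr <- shape_correlation(
          shifted_shape(pairs, i), c(pairs$left_scan[i], pairs$right_scan[i]),
          shifted_shape(pairs, j), c(pairs$left_scan[j], pairs$right_scan[j]))
        if (!is.na(corr) && corr >= params$group_corr) {
          edges <- rbind(edges, c(i, j))
        }
      }
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - length(igraph::V(g))))
  comp <- igraph::components(g)$membership
  # stable ids: number groups by first member appearance
  pairs$group_id <- as.integer(factor(comp, levels = unique(comp)))
  pairs
}

# peak shape re-expanded to absolute scan coordinates: shape_m is stored
# over [left_scan, right_scan], which is what shape_correlation expects,
# but it indexes the full trace — rebuild a sparse full-length stand-in.
shifted_shape <- function(pairs, i) {
  y <- numeric(pairs$right_scan[i] + 1L)
  y[(pairs$left_scan[i] + 1L):(pairs$right_scan[i] + 1L)] <- pairs$shape_m[[i]]
  y
}

#' Flag implausible feature pairs
#'
#' Heavy ions with very few carbons are chemically implausible and in
#' blank measurements were the signature of artefact pairings: pairs whose
#' estimated neutral mass exceeds `mass_limit` while `n_c < nc_limit` are
#' flagged (not removed). The neutral mass is estimated assuming
#' protonation, `(mz_m - 1.00728) * z`.
#'
#' @param pairs Feature-pair table.
#' @param mass_limit Neutral-mass threshold (u).
#' @param nc_limit Carbon-count threshold.
#' @return The input with logical column `implausible` appended.
#' @export
plausibility_flag <- function(pairs, mass_limit = 700, nc_limit = 10L) {
  mass <- (pairs$mz_m - 1.00728) * pairs$z
  pairs$implausible <- mass > mass_limit & pairs$n_c < nc_limit
  pairs
}
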