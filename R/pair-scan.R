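# Scan-wise detection of SIL-specific M/M' signal pairs and hierarchical
# clustering of their m/z values into per-(n_C, z) clusters.

#' Parameters for scan-level signal-pair detection
#'
#' Defaults are the workflow's published operating point: 5,000-count
#' intensity threshold on M and M' in at least 3 scans, 2.5 ppm m/z
#' tolerance, +/-20 % isotopologue abundance error, charges 1-3, carbon
#' counts 1-60.
#'
#' @param min_intensity Minimum intensity (counts) of both M and M'.
#' @param min_scans Minimum number of scans (cluster members) a signal
#'   pair must be seen in.
#' @param ppm m/z matching tolerance (half-width, ppm).
#' @param abundance_tol Relative isotopologue-ratio tolerance; an observed
#'   ratio r passes if `r/expected` lies in `[1 - tol, 1/(1 - tol)]`
#'   (a band symmetric on the ratio scale).
#' @param z_range Candidate charge states.
#' @param nc_range Candidate carbon-count range `c(min, max)`.
#' @param enrichment [enrichment_model()] of the labelled metabolome.
#' @return List of class `sil_pair_params`.
#' @export
pair_params <- function(min_intensity = 5000, min_scans = 3L, ppm = 2.5,
                        abundance_tol = 0.20, z_range = 1:3,
                        nc_range = c(1L, 60L),
                        enrichment = enrichment_model()) {
  stopifnot(min_intensity > 0, min_scans >= 1, ppm > 0, abundance_tol > 0,
            all(z_range >= 1), nc_range[1] >= 1, nc_range[2] >= nc_range[1])
  structure(list(min_intensity = min_intensity, min_scans = as.integer(min_scans),
                 ppm = ppm, abundance_tol = abundance_tol,
                 z_range = as.integer(z_range),
                 nc_range = as.integer(nc_range), enrichment = enrichment),
            class = "sil_pair_params")
}

# nearest peak within +/- ppm of each target; returns intensity (0 = absent)
# and matched mz (NA = absent). mz must be sorted ascending.
match_peaks <- function(mz, intensity, targets, ppm) {
  n <- length(targets)
  out_int <- numeric(n)
  out_mz <- rep(NA_real_, n)
  if (!length(mz)) return(list(intensity = out_int, mz = out_mz))
  pos <- findInterval(targets, mz)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(mz))
  d_lo <- abs(mz[lo] - targets)
  d_hi <- abs(mz[hi] - targets)
  use_hi <- d_hi < d_lo
  best <- ifelse(use_hi, hi, lo)
  d <- pmin(d_lo, d_hi)
  ok <- d <= targets * ppm * 1e-6
  out_int[ok] <- intensity[best[ok]]
  out_mz[ok] <- mz[best[ok]]
  list(intensity = out_int, mz = out_mz)
}

ratio_ok <- function(observed, expected, tol) {
  r <- observed / expected
  ok <- r >= (1 - tol) & r <= 1 / (1 - tol)
  ok[expected <= 0] <- observed == 0
  ok
}

#' Detect SIL signal pairs in one mass scan
#'
#' Inspects a centroid spectrum for the mirror-imaged isotopologue pattern
#' of a 1:1 native / U-13C mixture. For every peak M above the intensity
#' threshold, every candidate charge z and carbon count n, a signal pair is
#' emitted iff (a) a partner M' sits at `mz + n * 1.00335 / z` within the
#' ppm tolerance and above the threshold, (b) an M+1 peak exists at
#' `mz + 1.00335 / z` whose ratio to M matches the natural first-order
#' binomial expectation within the abundance tolerance, and (c) an M'-1
#' peak exists at `mz' - 1.00335 / z` whose ratio to M' matches the
#' enriched expectation. The charge is thereby deduced from the
#' isotopologue spacing that validates; ties go to the smaller z.
#'
#' @param spectrum A spectrum list (`rt_seconds`, sorted `mz`, `intensity`),
#'   e.g. an element of `run$spectra`.
#' @param params [pair_params()].
#' @return `data.frame` with columns `scan_index`, `rt_seconds`, `mz_m`,
#'   `mz_mprime`, `z`, `n_c`, `intensity_m`, `intensity_m1`,
#'   `intensity_mprime`, `intensity_mprime_minus1`.
#' @export
detect_signal_pairs <- function(spectrum, params = pair_params()) {
  dc <- 1.00335
  mz <- spectrum$mz
  intensity <- spectrum$intensity
  p_nat <- params$enrichment$p_natural
  p_enr <- params$enrichment$p_enriched
  ns <- params$nc_range[1]:params$nc_range[2]
  exp_m1 <- expected_m1_ratio(ns, p_nat)
  exp_mm1 <- expected_mprime_minus1_ratio(ns, p_enr)
  seeds <- which(intensity >= params$min_intensity)
  rows <- vector("list", 64L)
  nr <- 0L
  for (i in seeds) {
    m <- mz[i]
    im <- intensity[i]
    seen_spacing <- numeric(0)  # n/z spacings already claimed (smaller z wins)
    for (z in sort(params$z_range)) {
      # (b) M+1 presence check first: cheap gate shared by all n at this z
      m1 <- match_peaks(mz, intensity, m + dc / z, params$ppm)
      if (m1$intensity[1] <= 0) next
      # (a) candidate partners for all n at once
      tgt <- m + ns * dc / z
      mp <- match_peaks(mz, intensity, tgt, params$ppm)
      cand <- which(mp$intensity >= params$min_intensity)
      if (!length(cand)) next
      # (b) ratio gate
      cand <- cand[ratio_ok(m1$intensity[1] / im, exp_m1[cand],
                            params$abundance_tol)]
      if (!length(cand)) next
      for (k in cand) {
        spacing <- ns[k] / z
        if (any(abs(seen_spacing - spacing) < 1e-9)) next
        mprime_mz <- mp$mz[k]
        imp <- mp$intensity[k]
        # (c) M'-1 presence + ratio
        mm1 <- match_peaks(mz, intensity, mprime_mz - dc / z, params$ppm)
        if (mm1$intensity[1] <= 0) next
        if (!ratio_ok(mm1$intensity[1] / imp, exp_mm1[k],
                      params$abundance_tol)) next
        nr <- nr + 1L
        if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nr]] <- list(scan_index = spectrum$scan_index,
                           rt_seconds = spectrum$rt_seconds,
                           mz_m = m, mz_mprime = mprime_mz,
                           z = z, n_c = ns[k],
                           intensity_m = im,
                           intensity_m1 = m1$intensity[1],
                           intensity_mprime = imp,
                           intensity_mprime_minus1 = mm1$intensity[1])
        seen_spacing <- c(seen_spacing, spacing)
      }
    }
  }
  if (nr == 0L) {
    return(data.frame(scan_index = integer(0), rt_seconds = numeric(0),
                      mz_m = numeric(0), mz_mprime = numeric(0),
                      z = integer(0), n_c = integer(0),
                      intensity_m = numeric(0), intensity_m1 = numeric(0),
                      intensity_mprime = numeric(0),
                      intensity_mprime_minus1 = numeric(0)))
  }
  do.call(rbind, lapply(rows[seq_len(nr)], as.data.frame))
}

#' Detect signal pairs in every scan of a run
#'
#' @param run A `sil_run`.
#' @param params [pair_params()].
#' @return Row-bound [detect_signal_pairs()] output over all scans.
#' @export
detect_signal_pairs_run <- function(run, params = pair_params()) {
  out <- lapply(run$spectra, detect_signal_pairs, params = params)
  do.call(rbind, out)
}

# top-down cut of an hclust tree: split any node whose members deviate
# more than +/- max_ppm from the node mean
cut_tree_ppm <- function(hc, values, max_ppm) {
  n <- length(values)
  members <- function(node) {
    # node > 0: internal merge row; node < 0: singleton -node
    if (node < 0) return(-node)
    c(members(hc$merge[node, 1]), members(hc$merge[node, 2]))
  }
  assign_cluster <- integer(n)
  next_id <- 0L
  recurse <- function(node) {
    mem <- members(node)
    mu <- mean(values[mem])
    if (max(abs(values[mem] - mu)) <= mu * max_ppm * 1e-6 || node < 0) {
      next_id <<- next_id + 1L
      assign_cluster[mem] <<- next_id
    } else {
      recurse(hc$merge[node, 1])
      recurse(hc$merge[node, 2])
    }
  }
  recurse(nrow(hc$merge))
  assign_cluster
}

#' Cluster scan-level signal pairs by m/z
#'
#' Signal pairs are partitioned exactly by (n_C, z); within each partition
#' the monoisotopic m/z values are clustered by average-linkage
#' hierarchical clustering and the dendrogram is cut top-down: any node
#' whose members deviate more than `+/- max_ppm` from the node mean is
#' split into its children. Clusters with fewer than `min_scans` members
#' are discarded — this realises the "in at least 3 scans" rule.
#'
#' @param pairs Output of [detect_signal_pairs_run()].
#' @param max_ppm Cluster split tolerance (ppm).
#' @param min_scans Minimum member count for a cluster to survive.
#' @return `data.frame` of clusters (`cluster_id`, `n_c`, `z`, `mean_mz_m`,
#'   `n_members`) with the member table in attribute `"members"` (the input
#'   rows plus a `cluster_id` column).
#' @export
cluster_pairs <- function(pairs, max_ppm = 10, min_scans = 3L) {
  empty <- data.frame(cluster_id = integer(0), n_c = integer(0),
                      z = integer(0), mean_mz_m = numeric(0),
                      n_members = integer(0))
  if (!nrow(pairs)) {
    attr(empty, "members") <- cbind(pairs[0, ], cluster_id = integer(0))
    return(empty)
  }
  pairs$cluster_id <- NA_integer_
  next_id <- 0L
  key <- interaction(pairs$n_c, pairs$z, drop = TRUE)
  for (part in split(seq_len(nrow(pairs)), key)) {
    v <- pairs$mz_m[part]
    if (length(v) == 1L) {
      cl <- 1L
    } else if (length(v) == 2L) {
      mu <- mean(v)
      cl <- if (max(abs(v - mu)) <= mu * max_ppm * 1e-6) c(1L, 1L) else 1:2
    } else {
      hc <- stats::hclust(stats::dist(v), method = "average")
      cl <- cut_tree_ppm(hc, v, max_ppm)
    }
    pairs$cluster_id[part] <- next_id + cl
    next_id <- next_id + max(cl)
  }
  tab <- table(pairs$cluster_id)
  keep_ids <- as.integer(names(tab)[tab >= min_scans])
  members <- pairs[pairs$cluster_id %in% keep_ids, , drop = FALSE]
  if (!nrow(members)) {
    attr(empty, "members") <- members
    return(empty)
  }
  agg <- do.call(rbind, lapply(split(members, members$cluster_id), function(d) {
    data.frame(cluster_id = d$cluster_id[1], n_c = d$n_c[1], z = d$z[1],
               mean_mz_m = mean(d$mz_m), n_members = nrow(d))
  }))
  # renumber 1..k in mean-mz order for stable downstream ids
  agg <- agg[order(agg$mean_mz_m, agg$n_c, agg$z), , drop = FALSE]
  remap <- stats::setNames(seq_len(nrow(agg)), agg$cluster_id)
  agg$cluster_id <- as.integer(remap[as.character(agg$cluster_id)])
  members$cluster_id <- as.integer(remap[as.character(members$cluster_id)])
  rownames(agg) <- NULL
  attr(agg, "members") <- members
  agg
}
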