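# Synthetic paired native / U-13C LC-HRMS run generator with ground
# truth. Emulates the measurement model of a 1:1 mixture of a native and
# a uniformly 13C-labelled metabolome on a centroid high-resolution
# instrument: Gaussian chromatographic peaks, several ESI ion species per
# metabolite, binomial isotopologue ladders at natural and enriched 13C
# incorporation, isolated chemical-noise peaks, per-peak m/z jitter and a
# per-sample multiplicative matrix effect.

#' Specify one simulated metabolite
#'
#' @param neutral_mass Neutral monoisotopic mass (u).
#' @param n_c Carbon count.
#' @param rt_seconds Chromatographic apex retention time.
#' @param peak_sigma_scans Gaussian peak sigma in scans.
#' @param base_abundance Apex intensity (counts) of the most intense ion
#'   species at unit biological factor.
#' @param ion_species Named numeric vector: adduct name (must exist in
#'   [default_adducts()]) -> relative intensity.
#' @param per_sample_factor Named numeric vector: sample id -> biological
#'   abundance multiplier of the NATIVE metabolome (the labelled
#'   metabolome is a pooled reference, identical in every sample).
#' @return List of class `sil_metabolite`.
#' @export
metabolite_spec <- function(neutral_mass, n_c, rt_seconds,
                            peak_sigma_scans = 4, base_abundance = 1e6,
                            ion_species = c("[M+H]+" = 1),
                            per_sample_factor = numeric(0)) {
  stopifnot(n_c >= 1, neutral_mass > 12 * n_c, base_abundance > 0,
            length(ion_species) >= 1, !is.null(names(ion_species)))
  structure(list(neutral_mass = neutral_mass, n_c = as.integer(n_c),
                 rt_seconds = rt_seconds,
                 peak_sigma_scans = peak_sigma_scans,
                 base_abundance = base_abundance, ion_species = ion_species,
                 per_sample_factor = per_sample_factor),
            class = "sil_metabolite")
}

#' Simulation configuration
#'
#' @param n_scans Number of MS1 scans per run.
#' @param scan_interval_seconds Time between scans.
#' @param enrichment [enrichment_model()] of the labelled metabolome.
#' @param noise_peaks_per_scan Isolated chemical-noise peaks added per
#'   scan (uniform m/z, uniform intensity; no correlated elution).
#' @param noise_intensity_range Intensity range of noise peaks.
#' @param matrix_effect_sigma SD of the per-sample log multiplier applied
#'   to every intensity of a run (ion suppression/enhancement).
#' @param mode `"mixed"` (native + labelled ladders), `"native_only"`
#'   (no labelled partner) or `"blank"` (noise only).
#' @param jitter_ppm Per-peak uniform m/z jitter half-width (ppm); kept
#'   below the 2.5 ppm matching tolerance by default.
#' @param mz_range Instrument m/z range (noise peaks are drawn from it).
#' @param merge_u Centroids closer than this (u) within one scan are
#'   merged (intensity-weighted), mimicking finite resolution.
#' @param ladder_rel_min Isotopologue ladder truncation: relative
#'   abundance below this fraction of the ladder anchor is dropped.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return List of class `sil_sim_config`.
#' @export
sim_config <- function(n_scans = 240L, scan_interval_seconds = 1.0,
                       enrichment = enrichment_model(),
                       noise_peaks_per_scan = 0L,
                       noise_intensity_range = c(100, 10000),
                       matrix_effect_sigma = 0,
                       mode = c("mixed", "native_only", "blank"),
                       jitter_ppm = 1, mz_range = c(100, 1000),
                       merge_u = 0.0015, ladder_rel_min = 1e-4,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_scans >= 10, scan_interval_seconds > 0)
  structure(list(n_scans = as.integer(n_scans),
                 scan_interval_seconds = scan_interval_seconds,
                 enrichment = enrichment,
                 noise_peaks_per_scan = as.integer(noise_peaks_per_scan),
                 noise_intensity_range = noise_intensity_range,
                 matrix_effect_sigma = matrix_effect_sigma, mode = mode,
                 jitter_ppm = jitter_ppm, mz_range = mz_range,
                 merge_u = merge_u, ladder_rel_min = ladder_rel_min,
                 seed = as.integer(seed)),
            class = "sil_sim_config")
}

# binomial isotopologue ladder relative to its anchor (k = number of
# "minority" isotopes): returns offsets k >= 0 with relative abundance
ladder_rel <- function(n_c, p_minor, rel_min) {
  k <- 0:n_c
  rel <- stats::dbinom(k, n_c, p_minor) / stats::dbinom(0, n_c, p_minor)
  keep <- rel >= rel_min
  list(k = k[keep], rel = rel[keep])
}

sample_rng_seed <- function(seed, sample_id) {
  (as.integer(seed) * 1009L +
     sum(utf8ToInt(as.character(sample_id))) %% 100003L) %% 2000000000L
}

#' Generate one synthetic paired run
#'
#' For every metabolite and ion species, a Gaussian elution profile
#' carries two mirror-imaged binomial isotopologue ladders: the native
#' ladder anchored at the monoisotopic m/z (ascending-mass tail at
#' `p_natural`) and the labelled ladder anchored at
#' `M' = M + n_C * 1.00335 / z` (descending-mass tail at `p_enriched`).
#' The native ladder is scaled by the metabolite's biological factor for
#' this sample; the labelled ladder is the constant pooled reference. In
#' `native_only` mode the labelled ladder is omitted; `blank` emits noise
#' only. A per-sample matrix multiplier `exp(N(0, sigma^2))` scales every
#' intensity of the run.
#'
#' @param specs List of [metabolite_spec()] objects.
#' @param config [sim_config()].
#' @param sample_id Sample identifier (drives the per-sample RNG stream,
#'   biological factors and matrix effect).
#' @return List with `run` (a `sil_run`) and `truth` (`data.frame`: one
#'   row per metabolite x ion species with `metabolite`, `adduct`,
#'   `mz_m`, `mz_mprime`, `z`, `n_c`, `rt_seconds`, `apex_native`,
#'   `apex_labelled`, `matrix_factor`).
#' @export
generate_run <- function(specs, config, sample_id = "S1") {
  stopifnot(inherits(config, "sil_sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(sample_rng_seed(config$seed, sample_id))
  dc <- 1.00335
  p_nat <- config$enrichment$p_natural
  p_enr <- config$enrichment$p_enriched
  matrix_factor <- exp(stats::rnorm(1, 0, config$matrix_effect_sigma))
  scan_t <- (seq_len(config$n_scans) - 1L) * config$scan_interval_seconds

  scan_idx <- list(); mzs <- list(); ints <- list()
  truth <- list()
  if (config$mode != "blank") for (mi in seq_along(specs)) {
    sp <- specs[[mi]]
    sid <- as.character(sample_id)
    bio <- if (sid %in% names(sp$per_sample_factor))
      sp$per_sample_factor[[sid]] else 1
    nat <- ladder_rel(sp$n_c, p_nat, config$ladder_rel_min)
    lab <- ladder_rel(sp$n_c, 1 - p_enr, config$ladder_rel_min)
    win <- which(abs(scan_t - sp$rt_seconds) <=
                   4.5 * sp$peak_sigma_scans * config$scan_interval_seconds)
    if (!length(win)) next
    g <- exp(-((scan_t[win] - sp$rt_seconds) /
                 (sp$peak_sigma_scans * config$scan_interval_seconds))^2 / 2)
    for (si in seq_along(sp$ion_species)) {
      adduct <- names(sp$ion_species)[si]
      rel <- sp$ion_species[[si]]
      z <- default_adducts()$charge[match(adduct, default_adducts()$name)]
      anchor <- adduct_mz(sp$neutral_mass, adduct)
      apex_nat <- sp$base_abundance * rel * bio
      apex_lab <- sp$base_abundance * rel
      # native ascending ladder at anchor + k dc/z
      pk_mz <- anchor + nat$k * dc / z
      pk_rel <- nat$rel * apex_nat
      if (config$mode == "mixed") {
        pk_mz <- c(pk_mz, anchor + (sp$n_c - lab$k) * dc / z)
        pk_rel <- c(pk_rel, lab$rel * apex_lab)
      }
      m <- outer(g, pk_rel)  # scans x ladder peaks
      keep <- m >= 1  # sub-count signals are not recorded
      if (!any(keep)) next
      sc <- win[row(m)[keep]]
      mz0 <- rep(pk_mz, each = length(win))[keep]
      jit <- stats::runif(sum(keep), -config$jitter_ppm, config$jitter_ppm)
      scan_idx[[length(scan_idx) + 1L]] <- sc
      mzs[[length(mzs) + 1L]] <- mz0 * (1 + jit * 1e-6)
      ints[[length(ints) + 1L]] <- m[keep]
      truth[[length(truth) + 1L]] <- data.frame(
        metabolite = mi, adduct = adduct, mz_m = anchor,
        mz_mprime = anchor + sp$n_c * dc / z,
        z = z, n_c = sp$n_c, rt_seconds = sp$rt_seconds,
        apex_native = apex_nat, apex_labelled = apex_lab,
        matrix_factor = matrix_factor, stringsAsFactors = FALSE)
    }
  }
  if (config$noise_peaks_per_scan > 0) {
    nn <- config$noise_peaks_per_scan * config$n_scans
    scan_idx[[length(scan_idx) + 1L]] <-
      rep(seq_len(config$n_scans), each = config$noise_peaks_per_scan)
    mzs[[length(mzs) + 1L]] <-
      stats::runif(nn, config$mz_range[1], config$mz_range[2])
    ints[[length(ints) + 1L]] <-
      stats::runif(nn, config$noise_intensity_range[1],
                   config$noise_intensity_range[2])
  }
  all_scan <- unlist(scan_idx); all_mz <- unlist(mzs); all_int <- unlist(ints)
  spectra <- vector("list", config$n_scans)
  by_scan <- if (length(all_scan)) split(seq_along(all_scan), all_scan)
  for (s in seq_len(config$n_scans)) {
    idx <- by_scan[[as.character(s)]]
    if (is.null(idx)) {
      spectra[[s]] <- new_spectrum(s - 1L, scan_t[s], numeric(0), numeric(0))
      next
    }
    mz <- all_mz[idx]; it <- all_int[idx] * matrix_factor
    o <- order(mz); mz <- mz[o]; it <- it[o]
    # merge centroids below instrument resolution
    if (length(mz) > 1) {
      grp <- cumsum(c(TRUE, diff(mz) > config$merge_u))
      if (max(grp) < length(mz)) {
        it_g <- rowsum(it, grp)[, 1]
        mz_g <- rowsum(mz * it, grp)[, 1] / it_g
        mz <- mz_g; it <- it_g
      }
    }
    spectra[[s]] <- new_spectrum(s - 1L, scan_t[s], mz, it)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(metabolite = integer(0), adduct = character(0),
               mz_m = numeric(0), mz_mprime = numeric(0), z = integer(0),
               n_c = integer(0), rt_seconds = numeric(0),
               apex_native = numeric(0), apex_labelled = numeric(0),
               matrix_factor = numeric(0))
  list(run = new_run(spectra,
                     source_path = paste0("simulated:", sample_id),
                     metadata = list(sample_id = sample_id,
                                     mode = config$mode,
                                     matrix_factor = matrix_factor)),
       truth = truth)
}

#' Draw a random panel of plausible metabolites
#'
#' Carbon counts are uniform over `nc_range`; neutral masses follow a
#' realistic mass-per-carbon ratio (12 u of carbon plus 1.2-2.5 u/C of
#' hetero atoms and hydrogen, bracketing common metabolite stoichiometry,
#' e.g. 624.38 u at 30 C); retention times spread over the interior of
#' the gradient; apex abundances are log-uniform between 1e5 and 5e6
#' counts so that all isotopologue anchors clear the 5,000-count
#' threshold. Uses the caller's RNG stream — seed before calling.
#'
#' @param n Number of metabolites.
#' @param config [sim_config()] (for the scan count / rt span).
#' @param nc_range Carbon-count range.
#' @param n_species_range Range of ion species per metabolite (species
#'   drawn from the default adduct table; z 1-2).
#' @param per_sample_noise_sd SD of the per-sample log-normal biological
#'   factor of the native metabolome (0 = none).
#' @param samples Sample ids to draw biological factors for.
#' @param rt_min_sep_scans Minimum apex separation between metabolites,
#'   in scans. Apexes are drawn from a shuffled grid with this spacing:
#'   the panel emulates chromatographically resolved metabolites, since
#'   co-eluting distinct metabolites are by construction convoluted into
#'   one feature group by shape-correlation grouping.
#' @return List of [metabolite_spec()].
#' @export
random_metabolites <- function(n, config = sim_config(), nc_range = c(5L, 60L),
                               n_species_range = c(1L, 3L),
                               per_sample_noise_sd = 0, samples = "S1",
                               rt_min_sep_scans = 15) {
  adducts <- default_adducts()$name
  rt_span <- (config$n_scans - 1) * config$scan_interval_seconds
  slot_sep <- rt_min_sep_scans * config$scan_interval_seconds
  slots <- seq(0.1 * rt_span, 0.9 * rt_span, by = slot_sep)
  if (n > length(slots)) {
    stop("cannot place ", n, " metabolites at >= ", rt_min_sep_scans,
         " scans separation in ", config$n_scans,
         " scans; increase n_scans")
  }
  rt_slots <- sample(slots, n) +
    stats::runif(n, -0.15 * slot_sep, 0.15 * slot_sep)
  lapply(seq_len(n), function(i) {
    n_c <- sample(nc_range[1]:nc_range[2], 1)
    mass <- n_c * (12 + stats::runif(1, 1.2, 2.5))
    n_sp <- sample(n_species_range[1]:n_species_range[2], 1)
    species <- sample(adducts, n_sp)
    rel <- sort(stats::runif(n_sp, 0.25, 1), decreasing = TRUE)
    names(rel) <- species
    psf <- stats::setNames(exp(stats::rnorm(length(samples), 0,
                                            per_sample_noise_sd)), samples)
    metabolite_spec(
      neutral_mass = mass, n_c = n_c,
      rt_seconds = rt_slots[i],
      peak_sigma_scans = stats::runif(1, 3, 6),
      base_abundance = 10^stats::runif(1, 5, 6.7),
      ion_species = rel, per_sample_factor = psf)
  })
}

#' Write a run as mzML
#'
#' Emits a minimal, standard-conformant centroid mzML file (64-bit
#' little-endian uncompressed arrays, retention time in seconds) that
#' [read_run()] reads back losslessly within 1e-6 u (m/z) and 1e-3
#' relative (intensity).
#'
#' @param run A `sil_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "sil_run"))
  n <- length(run$spectra)
  spec_xml <- vapply(seq_len(n), function(i) {
    s <- run$spectra[[i]]
    np <- length(s$mz)
    paste0(
      '<spectrum index="', i - 1L, '" id="scan=', i, '" defaultArrayLength="',
      np, '">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="',
      sprintf("%.6f", s$rt_seconds), '" unitName="second"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray>',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      '<binary>', if (np) encode_binary(s$mz) else "", '</binary>',
      '</binaryDataArray>',
      '<binaryDataArray>',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      '<binary>', if (np) encode_binary(s$intensity) else "", '</binary>',
      '</binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<run id="', gsub("[^A-Za-z0-9_.-]", "_",
                      ifelse(is.na(run$source_path), "run", run$source_path)),
    '">\n<spectrumList count="', n, '">\n',
    paste(spec_xml, collapse = "\n"),
    '\n</spectrumList>\n</run>\n</mzML>\n')
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

#' Multiply every intensity of a run by a constant
#'
#' Utility for matrix-effect experiments: rescales all centroid
#' intensities (native and labelled alike), as an ESI matrix effect does.
#'
#' @param run A `sil_run`.
#' @param factor Positive multiplier.
#' @return A new `sil_run`.
#' @export
scale_run <- function(run, factor) {
  stopifnot(factor > 0)
  spectra <- lapply(run$spectra, function(s) {
    s$intensity <- s$intensity * factor
    s
  })
  new_run(spectra, source_path = run$source_path, metadata = run$metadata)
}
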