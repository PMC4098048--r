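# End-to-end wiring of the workflow stages for one run and the
# command-style entry points (detect / bracket / quantify / simulate).
# Stage counts are logged to stderr via message(), mirroring the
# MS signals -> signal pairs -> clusters -> feature pairs -> de-isotoped
# -> feature groups reduction cascade.

#' Pipeline configuration
#'
#' Bundles all stage parameters with their published defaults: 5,000
#' counts in at least 3 scans, 2.5 ppm, +/-20 % abundance error, +/-15
#' scans and corr > 0.5 for pairing, +/-10 scans and corr >= 0.85 for
#' grouping, +/-10 ppm cluster split, +/-10 ppm / +/-9 s bracketing.
#'
#' @param pair [pair_params()].
#' @param feature [feature_params()].
#' @param bracket [bracket_params()].
#' @param cluster_max_ppm Cluster split tolerance (ppm).
#' @return List of class `sil_config`.
#' @export
pipeline_config <- function(pair = pair_params(), feature = feature_params(),
                            bracket = bracket_params(),
                            cluster_max_ppm = 10) {
  structure(list(pair = pair, feature = feature, bracket = bracket,
                 cluster_max_ppm = cluster_max_ppm),
            class = "sil_config")
}

#' Detect feature pairs in one run (stages 3-b to 3-e)
#'
#' Runs scan-level signal-pair detection, m/z clustering, chromatographic
#' pairing, de-isotoping, plausibility flagging and feature grouping on a
#' single run, logging the count after every stage.
#'
#' @param run A `sil_run`.
#' @param config [pipeline_config()].
#' @param verbose Log stage counts via `message()`.
#' @return List with `signal_pairs`, `clusters`, `feature_pairs_raw`,
#'   `feature_pairs` (de-isotoped, flagged, grouped) and `counts` (named
#'   integer vector of stage totals).
#' @export
detect_feature_pairs <- function(run, config = pipeline_config(),
                                 verbose = TRUE) {
  stopifnot(inherits(run, "sil_run"))
  log <- function(...) if (verbose) message(...)
  n_signals <- length(run$index$mz)
  log("MS signals: ", n_signals)
  sp <- detect_signal_pairs_run(run, config$pair)
  log("SIL signal pairs: ", nrow(sp))
  cl <- cluster_pairs(sp, max_ppm = config$cluster_max_ppm,
                      min_scans = config$pair$min_scans)
  log("MS signal clusters: ", nrow(cl))
  fp_raw <- pair_features_run(cl, run, config$feature)
  log("feature pairs: ", nrow(fp_raw))
  fp <- deisotope(fp_raw, ppm = config$pair$ppm,
                  rt_tol_scans = config$feature$max_shift_scans)
  log("de-isotoped feature pairs: ", nrow(fp))
  fp <- plausibility_flag(fp)
  fp <- group_features(fp, config$feature)
  n_groups <- if (nrow(fp)) length(unique(fp$group_id)) else 0L
  log("feature groups: ", n_groups)
  list(signal_pairs = sp, clusters = cl, feature_pairs_raw = fp_raw,
       feature_pairs = fp,
       counts = c(ms_signals = n_signals, signal_pairs = nrow(sp),
                  clusters = nrow(cl), feature_pairs = nrow(fp_raw),
                  deisotoped = nrow(fp), groups = n_groups))
}

feature_pair_columns <- c("mz_m", "mz_mprime", "rt", "apex_scan",
                          "left_scan", "right_scan", "area_m",
                          "area_mprime", "n_c", "z", "corr", "cluster_id",
                          "implausible", "group_id")

#' Detect feature pairs in files and write per-sample TSV tables
#'
#' @param paths Character vector of mzML/mzXML paths.
#' @param out_dir Output directory for `<sample>.pairs.tsv` tables.
#' @param config [pipeline_config()].
#' @param verbose Log stage counts.
#' @return Invisible named character vector of written TSV paths.
#' @export
cmd_detect <- function(paths, out_dir = ".", config = pipeline_config(),
                       verbose = TRUE) {
  stopifnot(length(paths) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (p in paths) {
    if (!file.exists(p)) stop("input file not found: ", p)
    sample <- sub("\\.(mzML|mzXML)(\\.gz)?$", "", basename(p),
                  ignore.case = TRUE)
    if (verbose) message("== ", sample, " ==")
    run <- read_run(p)
    res <- detect_feature_pairs(run, config, verbose = verbose)
    path <- file.path(out_dir, paste0(sample, ".pairs.tsv"))
    write_tsv_table(res$feature_pairs[, feature_pair_columns], path)
    out[sample] <- path
  }
  invisible(out)
}

#' Bracket per-sample feature-pair tables into a data matrix
#'
#' @param pair_tsvs Named character vector (sample id -> TSV path) or
#'   unnamed (sample ids derived from file names).
#' @param out_path Path of the data-matrix TSV to write.
#' @param runs Optional named list of `sil_run`s (or file paths) for
#'   targeted re-integration of initially missed features.
#' @param config [pipeline_config()].
#' @return The `sil_matrix`, invisibly; the TSV holds one row per bracket
#'   with paired `area_m`/`area_mprime`/`found_by` columns per sample.
#' @export
cmd_bracket <- function(pair_tsvs, out_path = "data_matrix.tsv",
                        runs = NULL, config = pipeline_config()) {
  stopifnot(length(pair_tsvs) >= 1)
  if (is.null(names(pair_tsvs))) {
    names(pair_tsvs) <- sub("\\.pairs\\.tsv$", "", basename(pair_tsvs))
  }
  tables <- lapply(pair_tsvs, read_tsv_table)
  mat <- bracket(tables, config$bracket)
  if (!is.null(runs)) {
    runs <- lapply(runs, function(r) if (inherits(r, "sil_run")) r
                   else read_run(r))
    mat <- reintegrate_matrix(mat, runs, config$bracket, config$feature)
  }
  write_tsv_table(as.data.frame(mat), out_path)
  invisible(mat)
}

#' Flatten a `sil_matrix` into one table
#'
#' @param x A `sil_matrix`.
#' @param ... Unused.
#' @return `data.frame` with feature metadata and, per sample,
#'   `area_m.<s>`, `area_mprime.<s>`, `found_by.<s>` columns.
#' @export
as.data.frame.sil_matrix <- function(x, ...) {
  out <- x$features
  for (s in x$samples) {
    out[[paste0("area_m.", s)]] <- x$area_m[, s]
    out[[paste0("area_mprime.", s)]] <- x$area_mprime[, s]
    out[[paste0("found_by.", s)]] <- x$found_by[, s]
  }
  out
}

#' Internal standardisation, CV and PCA outputs for a data matrix
#'
#' @param mat A `sil_matrix` (or data-matrix TSV path written by
#'   [cmd_bracket()]).
#' @param design Named character vector mapping every sample to a group
#'   label (e.g. replicate sets).
#' @param out_dir Directory for `ratio_matrix.tsv`, `cv_summary.tsv` and
#'   `pca_scores.tsv`.
#' @return List with `ratios` (`sil_ratio_matrix`), per-group `cv_raw`
#'   and `cv_ratio` ([cv_summary()] objects) and `pca` ([pca_scores()]),
#'   invisibly.
#' @export
cmd_quantify <- function(mat, design, out_dir = ".") {
  if (is.character(mat)) mat <- matrix_from_tsv(mat)
  stopifnot(inherits(mat, "sil_matrix"))
  if (is.null(names(design)) || !all(mat$samples %in% names(design))) {
    stop("design must name every sample in the matrix")
  }
  if (!all(names(design) %in% mat$samples)) {
    stop("unknown sample(s) in design: ",
         paste(setdiff(names(design), mat$samples), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ratios <- internal_standardise(mat, sample_groups = design)
  cv_raw <- list(); cv_ratio <- list()
  for (g in unique(design)) {
    smp <- names(design)[design == g]
    if (length(smp) < 2) stop("group '", g, "' has < 2 replicates")
    cv_raw[[g]] <- cv_summary(mat$area_m[, smp, drop = FALSE])
    cv_ratio[[g]] <- cv_summary(ratios$ratio[, smp, drop = FALSE])
  }
  complete <- stats::complete.cases(ratios$ratio)
  pca <- NULL
  if (sum(complete) >= 2) {
    scaled <- suppressWarnings(
      range_scale(ratios$ratio[complete, , drop = FALSE]))
    if (nrow(scaled) >= 2) {
      pca <- pca_scores(scaled, groups = unname(design[mat$samples]))
    }
  }
  ratio_tab <- cbind(mat$features, as.data.frame(ratios$ratio))
  write_tsv_table(ratio_tab, file.path(out_dir, "ratio_matrix.tsv"))
  cv_tab <- do.call(rbind, lapply(names(cv_raw), function(g) {
    data.frame(group = g,
               median_cv_raw = cv_raw[[g]]$median_cv,
               p90_cv_raw = cv_raw[[g]]$p90_cv,
               n_raw = cv_raw[[g]]$n_features,
               median_cv_ratio = cv_ratio[[g]]$median_cv,
               p90_cv_ratio = cv_ratio[[g]]$p90_cv,
               n_ratio = cv_ratio[[g]]$n_features)
  }))
  write_tsv_table(cv_tab, file.path(out_dir, "cv_summary.tsv"))
  if (!is.null(pca)) {
    sc <- data.frame(sample = rownames(pca$scores),
                     group = unname(design[mat$samples]),
                     PC1 = pca$scores[, 1],
                     PC2 = if (ncol(pca$scores) > 1) pca$scores[, 2] else 0)
    write_tsv_table(sc, file.path(out_dir, "pca_scores.tsv"))
  }
  invisible(list(ratios = ratios, cv_raw = cv_raw, cv_ratio = cv_ratio,
                 pca = pca))
}

#' Rebuild a `sil_matrix` from a data-matrix TSV
#'
#' @param path TSV written by [cmd_bracket()].
#' @return A `sil_matrix`.
#' @export
matrix_from_tsv <- function(path) {
  d <- read_tsv_table(path)
  am_cols <- grep("^area_m\\.", names(d), value = TRUE)
  samples <- sub("^area_m\\.", "", am_cols)
  features <- d[, c("feature_id", "consensus_mz_m", "consensus_rt",
                    "n_c", "z")]
  grab <- function(prefix, mode = "numeric") {
    m <- sapply(samples, function(s) {
      v <- d[[paste0(prefix, ".", s)]]
      if (mode == "numeric") as.numeric(v) else as.character(v)
    })
    m <- matrix(m, nrow = nrow(d), dimnames = list(NULL, samples))
    m
  }
  structure(list(features = features, area_m = grab("area_m"),
                 area_mprime = grab("area_mprime"),
                 found_by = grab("found_by", "character"),
                 samples = samples),
            class = "sil_matrix")
}

#' Simulate an experiment and write mzML files plus ground truth
#'
#' @param n_metabolites Number of metabolites in the panel.
#' @param samples Character vector of sample ids.
#' @param config [sim_config()].
#' @param out_dir Output directory (`<sample>.mzML`, `truth.tsv`).
#' @param nc_range,n_species_range,per_sample_noise_sd Passed to
#'   [random_metabolites()].
#' @return Invisible list with `paths`, `specs` and `truth`.
#' @export
cmd_simulate <- function(n_metabolites = 20L, samples = "S1",
                         config = sim_config(), out_dir = ".",
                         nc_range = c(5L, 60L), n_species_range = c(1L, 3L),
                         per_sample_noise_sd = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  specs <- random_metabolites(n_metabolites, config, nc_range,
                              n_species_range, per_sample_noise_sd, samples)
  paths <- character(0)
  truth_all <- list()
  for (s in samples) {
    g <- generate_run(specs, config, s)
    p <- file.path(out_dir, paste0(s, ".mzML"))
    write_run(g$run, p)
    paths[s] <- p
    tr <- g$truth
    if (nrow(tr)) tr$sample <- s
    truth_all[[s]] <- tr
  }
  truth <- do.call(rbind, truth_all)
  write_tsv_table(truth, file.path(out_dir, "truth.tsv"))
  invisible(list(paths = paths, specs = specs, truth = truth))
}
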