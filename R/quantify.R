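# Metabolome-wide internal standardisation and its evaluation: 12C/13C
# ratio matrix, CV histograms, range scaling and PCA with group ellipses.

#' Internal standardisation of a bracketed data matrix
#'
#' Divides, per file and feature pair, the area of the monoisotopic 12C
#' feature by the area of its U-13C labelled partner. Cells with a
#' missing M or M' area — or a zero M' area — stay undefined (`NA`); no
#' division by zero ever occurs.
#'
#' @param mat A `sil_matrix` from [bracket()] /
#'   [reintegrate_matrix()].
#' @param sample_groups Optional named character vector mapping samples to
#'   group labels.
#' @return Object of class `sil_ratio_matrix`: list with `ratio`
#'   (feature x sample matrix), `features`, `sample_groups` and
#'   `zero_denominator` (logical matrix flagging suppressed divisions).
#' @export
internal_standardise <- function(mat, sample_groups = NULL) {
  stopifnot(inherits(mat, "sil_matrix"))
  zero_den <- !is.na(mat$area_mprime) & mat$area_mprime == 0
  ratio <- mat$area_m / mat$area_mprime
  ratio[zero_den] <- NA_real_
  structure(list(ratio = ratio, features = mat$features,
                 area_m = mat$area_m, area_mprime = mat$area_mprime,
                 samples = mat$samples,
                 sample_groups = sample_groups,
                 zero_denominator = zero_den),
            class = "sil_ratio_matrix")
}

#' Coefficient-of-variation summary across replicates
#'
#' Per feature (row), the CV is the sample (n-1) standard deviation over
#' the mean, in percent, computed only over rows complete in all
#' replicates (no imputation). The histogram uses 5 % bins with every CV
#' above 120 % capped into the final bin; the median and 90th percentile
#' are reported as precision estimates.
#'
#' @param x Numeric matrix, features x replicates.
#' @param bin_width Histogram bin width (%).
#' @param cap Overflow cap (%).
#' @return Object of class `sil_cv_summary`: list with `cv` (per analysed
#'   feature), `n_features`, `breaks`, `counts`, `median_cv`, `p90_cv`.
#' @export
cv_summary <- function(x, bin_width = 5, cap = 120) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 replicates to compute CVs")
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]
  if (!nrow(x)) stop("no feature is complete in all replicates")
  cv <- apply(x, 1, function(v) stats::sd(v) / mean(v) * 100)
  capped <- pmin(cv, cap)
  breaks <- seq(0, cap, by = bin_width)
  # right = FALSE + include.lowest closes the final bin, so capped values
  # land in the overflow bin exactly once
  counts <- as.integer(table(cut(capped, breaks, include.lowest = TRUE,
                                 right = FALSE)))
  structure(list(cv = cv, n_features = length(cv), breaks = breaks,
                 counts = counts,
                 median_cv = stats::median(cv),
                 p90_cv = unname(stats::quantile(cv, 0.9))),
            class = "sil_cv_summary")
}

#' @export
print.sil_cv_summary <- function(x, ...) {
  cat("<sil_cv_summary> ", x$n_features, " features; median CV ",
      sprintf("%.1f %%", x$median_cv), ", 90th percentile ",
      sprintf("%.1f %%", x$p90_cv), "\n", sep = "")
  invisible(x)
}

#' Range scaling of a feature matrix
#'
#' Per feature (row): `(x - mean(x)) / (max(x) - min(x))`; every scaled
#' value then lies in [-1, 1]. Constant rows have no range and are
#' dropped with a warning.
#'
#' @param x Numeric matrix, features x samples.
#' @return Scaled matrix (possibly fewer rows).
#' @export
range_scale <- function(x) {
  x <- as.matrix(x)
  rng <- apply(x, 1, function(v) max(v) - min(v))
  const <- rng == 0 | !is.finite(rng)
  if (any(const)) {
    warning(sum(const), " constant row(s) dropped before range scaling")
    x <- x[!const, , drop = FALSE]
    rng <- rng[!const]
  }
  sweep(sweep(x, 1, rowMeans(x)), 1, rng, "/")
}

#' Principal component analysis with per-group confidence ellipses
#'
#' Eigendecomposition of the sample covariance of a (range-scaled)
#' feature matrix, with samples as observations and features as
#' variables. Scores, per-component variance explained and, when groups
#' are given, the 95 % covariance ellipse of each group in the PC1/PC2
#' plane are returned.
#'
#' @param x Numeric matrix, features x samples (as produced by
#'   [range_scale()]).
#' @param groups Optional character vector of group labels, one per
#'   sample (column).
#' @param conf Ellipse confidence level.
#' @return Object of class `sil_pca`: list with `scores` (samples x PCs),
#'   `loadings`, `var_explained` (percent, non-increasing), and
#'   `ellipses` — per group a list with `center` (PC1/PC2), `cov`,
#'   `radius` (`sqrt(qchisq(conf, 2))`) and `path` (closed polygon of the
#'   ellipse outline).
#' @export
pca_scores <- function(x, groups = NULL, conf = 0.95) {
  x <- as.matrix(x)
  if (ncol(x) < 2 || nrow(x) < 2) {
    stop("need at least 2 samples and 2 features for PCA")
  }
  obs <- t(x)  # samples as rows
  pc <- stats::prcomp(obs, center = TRUE, scale. = FALSE)
  var_exp <- pc$sdev^2 / sum(pc$sdev^2) * 100
  scores <- pc$x
  ellipses <- NULL
  if (!is.null(groups)) {
    stopifnot(length(groups) == ncol(x))
    radius <- sqrt(stats::qchisq(conf, df = 2))
    theta <- seq(0, 2 * pi, length.out = 100)
    circle <- cbind(cos(theta), sin(theta))
    ellipses <- lapply(split(seq_along(groups), groups), function(idx) {
      s12 <- scores[idx, 1:2, drop = FALSE]
      ctr <- colMeans(s12)
      cv <- if (length(idx) > 1) stats::cov(s12) else matrix(0, 2, 2)
      ev <- eigen(cv, symmetric = TRUE)
      lam <- pmax(ev$values, 0)
      path <- sweep(circle %*% diag(sqrt(lam)) %*% t(ev$vectors) * radius,
                    2, ctr, "+")
      colnames(path) <- c("PC1", "PC2")
      list(center = ctr, cov = cv, radius = radius, path = path)
    })
  }
  structure(list(scores = scores, loadings = pc$rotation,
                 var_explained = var_exp, groups = groups,
                 ellipses = ellipses),
            class = "sil_pca")
}

#' @export
print.sil_pca <- function(x, ...) {
  cat("<sil_pca> ", nrow(x$scores), " samples; PC1 ",
      sprintf("%.1f %%", x$var_explained[1]), ", PC2 ",
      sprintf("%.1f %%", if (length(x$var_explained) > 1)
        x$var_explained[2] else 0), " variance explained\n", sep = "")
  invisible(x)
}
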