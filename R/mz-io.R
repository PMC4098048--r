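# Minimal centroid mzML / mzXML reader, Run container and XIC extraction.
#
# No mass-spectrometry raw-file reader ships with this R installation, so
# the subset of both dialects needed for centroid MS1 data is parsed here
# directly: base64-encoded binary arrays, 32/64-bit floats, optional zlib
# compression, MS-level filtering, retention-time unit normalisation to
# seconds. Profile-mode spectra are rejected, MS2+ spectra are skipped.

new_spectrum <- function(scan_index, rt_seconds, mz, intensity) {
  o <- order(mz)
  list(scan_index = scan_index, rt_seconds = rt_seconds,
       mz = mz[o], intensity = intensity[o])
}

#' Construct an in-memory LC-HRMS run
#'
#' A run is an ordered list of centroid MS1 spectra with strictly
#' increasing retention times plus a flat m/z-sorted peak index used for
#' fast XIC extraction.
#'
#' @param spectra List of spectra, each a list with `rt_seconds`, `mz`
#'   (ascending) and `intensity`.
#' @param source_path Provenance string.
#' @param metadata Free-form named list.
#' @return An object of class `sil_run`.
#' @export
new_run <- function(spectra, source_path = NA_character_, metadata = list()) {
  rt <- vapply(spectra, `[[`, numeric(1), "rt_seconds")
  if (length(rt) > 1 && any(diff(rt) <= 0)) {
    stop("retention times must be strictly increasing")
  }
  for (i in seq_along(spectra)) spectra[[i]]$scan_index <- i - 1L
  n_peaks <- vapply(spectra, function(s) length(s$mz), integer(1))
  all_mz <- unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE)
  all_int <- unlist(lapply(spectra, `[[`, "intensity"), use.names = FALSE)
  all_scan <- rep.int(seq_along(spectra), n_peaks)
  o <- order(all_mz)
  structure(list(
    spectra = spectra,
    rt = rt,
    source_path = source_path,
    metadata = metadata,
    index = list(mz = all_mz[o], intensity = all_int[o], scan = all_scan[o])
  ), class = "sil_run")
}

#' @export
print.sil_run <- function(x, ...) {
  cat("<sil_run> ", length(x$spectra), " MS1 spectra, rt ",
      sprintf("%.1f-%.1f s", min(x$rt), max(x$rt)), ", ",
      length(x$index$mz), " centroid peaks\n", sep = "")
  invisible(x)
}

#' Number of scans in a run
#' @param run A `sil_run`.
#' @return Integer scan count.
#' @export
n_scans <- function(run) length(run$spectra)

# ---- binary array decoding -------------------------------------------------

decode_binary <- function(b64, precision, compressed, n) {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64))
  if (compressed) raw <- memDecompress(raw, type = "gzip")
  readBin(raw, "double", n = n, size = precision / 8, endian = "little")
}

encode_binary <- function(x) {
  jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                endian = "little"))
}

# big-endian network order used by mzXML
decode_mzxml_peaks <- function(b64, precision, compressed, n_pairs) {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64))
  if (compressed) raw <- memDecompress(raw, type = "gzip")
  v <- readBin(raw, "double", n = 2 * n_pairs, size = precision / 8,
               endian = "big")
  list(mz = v[seq(1, length(v), 2)], intensity = v[seq(2, length(v), 2)])
}

read_maybe_gz <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 2)
  close(con); on.exit()
  if (length(head) == 2 && head[1] == as.raw(0x1f) && head[2] == as.raw(0x8b)) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    chunks <- list()
    repeat {
      b <- readBin(con, "raw", 1e6)
      if (!length(b)) break
      chunks[[length(chunks) + 1L]] <- b
    }
    rawToChar(do.call(c, chunks))
  } else {
    readChar(path, file.info(path)$size, useBytes = TRUE)
  }
}

# ---- mzML ------------------------------------------------------------------

parse_rt_seconds <- function(value, unit) {
  v <- as.numeric(value)
  if (grepl("minute", unit, ignore.case = TRUE)) v * 60 else v
}

read_mzml <- function(path) {
  doc <- xml2::read_xml(read_maybe_gz(path))
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (!length(nodes)) nodes <- xml2::xml_find_all(doc, ".//spectrum")
  spectra <- list()
  for (node in nodes) {
    cv <- xml2::xml_find_all(node, "./cvParam")
    acc <- xml2::xml_attr(cv, "accession")
    val <- xml2::xml_attr(cv, "value")
    ms_level <- suppressWarnings(as.integer(val[acc == "MS:1000511"][1]))
    if (!is.na(ms_level) && ms_level != 1L) next
    if ("MS:1000128" %in% acc) {
      stop("profile-mode spectrum found in '", path,
           "': centroid data required")
    }
    rt_cv <- xml2::xml_find_first(
      node, ".//scan/cvParam[@accession='MS:1000016']")
    if (inherits(rt_cv, "xml_missing")) {
      rt_cv <- xml2::xml_find_first(node, ".//cvParam[@accession='MS:1000016']")
    }
    rt <- parse_rt_seconds(xml2::xml_attr(rt_cv, "value"),
                           xml2::xml_attr(rt_cv, "unitName"))
    n_pk <- as.integer(xml2::xml_attr(node, "defaultArrayLength"))
    arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
    mz <- intensity <- numeric(0)
    for (arr in arrays) {
      acv <- xml2::xml_find_all(arr, "./cvParam")
      aacc <- xml2::xml_attr(acv, "accession")
      precision <- if ("MS:1000521" %in% aacc) 32L else 64L
      compressed <- "MS:1000574" %in% aacc
      b64 <- xml2::xml_text(xml2::xml_find_first(arr, "./binary"))
      vals <- if (n_pk > 0) decode_binary(b64, precision, compressed, n_pk)
              else numeric(0)
      if ("MS:1000514" %in% aacc) mz <- vals
      if ("MS:1000515" %in% aacc) intensity <- vals
    }
    spectra[[length(spectra) + 1L]] <-
      new_spectrum(length(spectra), rt, mz, intensity)
  }
  spectra
}

# ---- mzXML -----------------------------------------------------------------

parse_mzxml_rt <- function(s) {
  # ISO-8601 duration "PT123.4S" or plain seconds
  s <- gsub("^PT|S$", "", s)
  as.numeric(s)
}

read_mzxml <- function(path) {
  doc <- xml2::read_xml(read_maybe_gz(path))
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//scan")
  spectra <- list()
  for (node in nodes) {
    lvl <- suppressWarnings(as.integer(xml2::xml_attr(node, "msLevel")))
    if (!is.na(lvl) && lvl != 1L) next
    centroided <- xml2::xml_attr(node, "centroided")
    if (!is.na(centroided) && centroided == "0") {
      stop("profile-mode scan found in '", path, "': centroid data required")
    }
    rt <- parse_mzxml_rt(xml2::xml_attr(node, "retentionTime"))
    n_pk <- as.integer(xml2::xml_attr(node, "peaksCount"))
    pk <- xml2::xml_find_first(node, "./peaks")
    precision <- as.integer(xml2::xml_attr(pk, "precision"))
    if (is.na(precision)) precision <- 32L
    comp <- xml2::xml_attr(pk, "compressionType")
    compressed <- !is.na(comp) && comp == "zlib"
    vals <- if (n_pk > 0) {
      decode_mzxml_peaks(xml2::xml_text(pk), precision, compressed, n_pk)
    } else list(mz = numeric(0), intensity = numeric(0))
    spectra[[length(spectra) + 1L]] <-
      new_spectrum(length(spectra), rt, vals$mz, vals$intensity)
  }
  spectra
}

#' Read a centroid MS1 run from mzML or mzXML
#'
#' Reads all MS1 spectra in acquisition order; MS2+ spectra are skipped.
#' Retention times are normalised to seconds. Gzip-compressed files and
#' zlib-compressed binary arrays are handled. Profile-mode data raise an
#' error: the workflow operates on centroid spectra only.
#'
#' @param path File path.
#' @param format `"auto"` (by extension/sniffing), `"mzML"` or `"mzXML"`.
#' @return A [new_run()] object.
#' @export
read_run <- function(path, format = c("auto", "mzML", "mzXML")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    low <- tolower(sub("\\.gz$", "", path))
    format <- if (grepl("\\.mzxml$", low)) "mzXML"
              else if (grepl("\\.mzml$", low)) "mzML"
              else {
                txt <- substr(read_maybe_gz(path), 1, 400)
                if (grepl("mzXML", txt, fixed = TRUE)) "mzXML" else "mzML"
              }
  }
  spectra <- tryCatch(
    switch(format, mzML = read_mzml(path), mzXML = read_mzxml(path)),
    error = function(e) {
      if (grepl("centroid data required", conditionMessage(e))) stop(e)
      stop("cannot parse '", path, "' as ", format, ": ",
           conditionMessage(e), call. = FALSE)
    })
  if (!length(spectra)) {
    stop("no MS1 spectra found in '", path, "'")
  }
  new_run(spectra, source_path = path)
}

# ---- XIC -------------------------------------------------------------------

#' Extract an ion chromatogram
#'
#' Per-scan summed intensity of all centroid peaks within `+/- ppm` of
#' `target_mz`; scans without a matching peak contribute 0. Summing (rather
#' than taking the most intense match) makes the trace deterministic and
#' robust against split centroids.
#'
#' @param run A `sil_run`.
#' @param target_mz Target m/z (u).
#' @param ppm Half-width of the extraction window in ppm.
#' @return Object of class `sil_xic`: list with `target_mz`, `ppm`,
#'   `intensities` (one entry per scan).
#' @export
extract_xic <- function(run, target_mz, ppm) {
  stopifnot(inherits(run, "sil_run"), ppm > 0, target_mz > 0)
  idx <- run$index
  lo <- target_mz * (1 - ppm * 1e-6)
  hi <- target_mz * (1 + ppm * 1e-6)
  i0 <- findInterval(lo, idx$mz, left.open = TRUE) + 1L
  i1 <- findInterval(hi, idx$mz)
  intens <- numeric(length(run$spectra))
  if (i1 >= i0) {
    sel <- i0:i1
    agg <- rowsum(idx$intensity[sel], idx$scan[sel])
    intens[as.integer(rownames(agg))] <- agg[, 1]
  }
  structure(list(target_mz = target_mz, ppm = ppm, intensities = intens),
            class = "sil_xic")
}

# summed intensities for many targets in one scan-set; internal fast path
xic_matrix <- function(run, targets, ppm) {
  vapply(targets, function(m) extract_xic(run, m, ppm)$intensities,
         numeric(length(run$spectra)))
}

#' Write a result table as TSV
#'
#' Fixed column order, tab separation, no quoting; list columns (peak
#' shapes) are dropped.
#'
#' @param x `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  keep <- !vapply(x, is.list, logical(1))
  utils::write.table(x[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_table()]
#' @param path File path.
#' @return `data.frame`.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
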