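#' Construct an MS/MS spectrum
#'
#' A spectrum holds one tandem-MS scan: the precursor m/z, retention time
#' (minutes), charge, ionization mode and the fragment peak list. Peaks are
#' stored sorted ascending by m/z; intensities must be finite and
#' non-negative.
#'
#' @param feature_id character key linking the spectrum to a feature table row.
#' @param precursor_mz precursor m/z in Da (> 0).
#' @param peaks two-column numeric matrix (mz, intensity), any row order.
#' @param rt retention time in minutes (>= 0).
#' @param charge integer charge; sign follows `mode` when defaulted.
#' @param mode `"positive"` or `"negative"`.
#' @return an object of class `"spectrum"`.
#' @export
spectrum <- function(feature_id, precursor_mz, peaks, rt = 0,
                     charge = NULL, mode = "positive") {
  mode <- match.arg(mode, c("positive", "negative"))
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1 || precursor_mz <= 0)
    stopf("precursor_mz must be a single positive number (feature '%s')", feature_id)
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2) stopf("peaks must have two columns (mz, intensity)")
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks) > 0) {
    if (any(!is.finite(peaks))) stopf("non-finite peak values in feature '%s'", feature_id)
    if (any(peaks[, 1] <= 0)) stopf("peak m/z must be positive (feature '%s')", feature_id)
    if (any(peaks[, 2] < 0)) stopf("peak intensity must be >= 0 (feature '%s')", feature_id)
    peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  }
  if (is.null(charge)) charge <- if (mode == "positive") 1L else -1L
  structure(
    list(feature_id = as.character(feature_id),
         precursor_mz = as.double(precursor_mz),
         rt = as.double(rt), charge = as.integer(charge),
         mode = mode, peaks = peaks),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> precursor %.4f m/z, rt %.2f min, %s mode, %d peaks\n",
              x$feature_id, x$precursor_mz, x$rt, x$mode, nrow(x$peaks)))
  invisible(x)
}

#' Read an MGF file of MS/MS spectra
#'
#' Parses the Mascot Generic Format dialect exported by MZmine/GNPS:
#' `BEGIN IONS` blocks with `PEPMASS`, `RTINSECONDS` (or `RTINMINUTES`),
#' `FEATURE_ID` (or `SCANS`) and optional `CHARGE`/`IONMODE` headers,
#' followed by `mz intensity` peak lines. Retention times are normalised to
#' minutes and peaks re-sorted ascending by m/z.
#'
#' Blocks without a precursor mass are skipped with a warning; a block that
#' cannot be parsed raises an error naming the block index.
#'
#' @param path path to an MGF file.
#' @param mode fallback ionization mode when the file carries none.
#' @return a list of [spectrum()] objects (possibly empty).
#' @export
read_mgf <- function(path, mode = "positive") {
  if (!file.exists(path)) stopf("MGF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stopf("malformed MGF: %d BEGIN IONS vs %d END IONS", length(starts), length(ends))
  out <- vector("list", length(starts))
  keep <- logical(length(starts))
  ids_seen <- character(0)
  for (b in seq_along(starts)) {
    body <- lines[(starts[b] + 1):(ends[b] - 1)]
    body <- body[nzchar(body)]
    is_kv <- grepl("=", body, fixed = TRUE)
    kv <- body[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
    pep <- getv("PEPMASS")
    if (is.null(pep)) {
      warnf("MGF block %d has no PEPMASS; skipped", b)
      next
    }
    prec <- suppressWarnings(as.numeric(strsplit(pep, "[ \t]+")[[1]][1]))
    if (!is.finite(prec)) stopf("MGF block %d: unparseable PEPMASS '%s'", b, pep)
    id <- getv("FEATURE_ID") %||% getv("SCANS") %||% as.character(b)
    rt <- 0
    if (!is.null(getv("RTINSECONDS"))) rt <- as.numeric(getv("RTINSECONDS")) / 60
    else if (!is.null(getv("RTINMINUTES"))) rt <- as.numeric(getv("RTINMINUTES"))
    ch_raw <- getv("CHARGE")
    spec_mode <- tolower(getv("IONMODE") %||% mode)
    charge <- NULL
    if (!is.null(ch_raw)) {
      sign <- if (grepl("-", ch_raw, fixed = TRUE)) -1L else 1L
      num <- suppressWarnings(as.integer(gsub("[^0-9]", "", ch_raw)))
      if (is.na(num)) stopf("MGF block %d: unparseable CHARGE '%s'", b, ch_raw)
      charge <- sign * num
      if (is.null(getv("IONMODE"))) spec_mode <- if (sign < 0) "negative" else "positive"
    }
    pk_lines <- body[!is_kv]
    pk_lines <- pk_lines[!grepl("^[A-Za-z]", pk_lines)]
    if (length(pk_lines) > 0) {
      pk <- do.call(rbind, lapply(pk_lines, function(l) {
        v <- suppressWarnings(as.numeric(strsplit(l, "[ \t]+")[[1]]))
        if (length(v) < 2 || any(!is.finite(v[1:2])))
          stopf("MGF block %d: unparseable peak line '%s'", b, l)
        v[1:2]
      }))
    } else pk <- matrix(numeric(0), ncol = 2)
    if (id %in% ids_seen) stopf("duplicate feature id '%s' in %s", id, path)
    ids_seen <- c(ids_seen, id)
    out[[b]] <- spectrum(id, prec, pk, rt = rt, charge = charge, mode = spec_mode)
    keep[b] <- TRUE
  }
  out[keep]
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: round-tripping preserves ids, precursor m/z
#' (to 1e-6 Da) and peak lists.
#'
#' @param spectra list of [spectrum()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stopf("cannot write MGF to %s", path)
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      sprintf("FEATURE_ID=%s", s$feature_id),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      sprintf("RTINSECONDS=%.6f", s$rt * 60),
      sprintf("CHARGE=%d%s", abs(s$charge), if (s$charge < 0) "-" else "+"),
      sprintf("IONMODE=%s", s$mode),
      "MSLEVEL=2"), con)
    if (nrow(s$peaks) > 0)
      writeLines(sprintf("%.6f %.6f", s$peaks[, 1], s$peaks[, 2]), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Construct a feature quantification table
#'
#' Features x samples matrix of chromatographic peak areas with per-feature
#' m/z and retention time.
#'
#' @param areas numeric matrix (features x samples), non-negative, with
#'   feature ids as rownames and sample ids as colnames.
#' @param feature_meta data frame with columns `feature_id`, `mz`, `rt`.
#' @param has_ms2 optional logical flag per feature.
#' @return an object of class `"feature_table"`.
#' @export
feature_table <- function(areas, feature_meta, has_ms2 = NULL) {
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  if (is.null(rownames(areas))) {
    if (nrow(areas) > 0)
      stopf("areas must carry feature ids as rownames")
    rownames(areas) <- character(0)
  }
  if (is.null(colnames(areas))) {
    if (ncol(areas) > 0)
      stopf("areas must carry sample ids as colnames")
    colnames(areas) <- character(0)
  }
  if (anyDuplicated(rownames(areas))) stopf("duplicate feature ids")
  if (anyDuplicated(colnames(areas))) stopf("duplicate sample ids")
  if (any(!is.finite(areas)) || any(areas < 0))
    stopf("areas must be finite and non-negative")
  feature_meta <- as.data.frame(feature_meta)
  stopifnot(all(c("feature_id", "mz", "rt") %in% names(feature_meta)))
  feature_meta$feature_id <- as.character(feature_meta$feature_id)
  if (!identical(feature_meta$feature_id, rownames(areas)))
    feature_meta <- feature_meta[match(rownames(areas), feature_meta$feature_id), ]
  if (anyNA(feature_meta$feature_id)) stopf("feature_meta does not cover all features")
  if (is.null(has_ms2)) has_ms2 <- rep(NA, nrow(areas))
  structure(list(areas = areas, feature_meta = feature_meta,
                 has_ms2 = has_ms2), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples\n",
              nrow(x$areas), ncol(x$areas)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$areas)

#' Read a feature quantification table (CSV)
#'
#' Two dialects. `"plain"` expects columns `feature_id`, `mz`, `rt` and one
#' area column per sample. `"mzmine"` expects the MZmine export layout
#' (`row ID`, `row m/z`, `row retention time`, `<file> Peak area` columns);
#' sample ids are recovered by stripping the peak-area suffix and raw-file
#' extension, both regex-configurable because export dialects vary between
#' MZmine versions.
#'
#' @param path CSV path.
#' @param dialect `"mzmine"` or `"plain"`.
#' @param area_suffix regex stripped from sample column names (mzmine).
#' @param file_ext regex of raw-file extensions stripped from sample names.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, dialect = c("mzmine", "plain"),
                               area_suffix = "[ .]Peak area[ .]*$",
                               file_ext = "\\.(mzX?ML|mzml|raw|cdf|CDF)$") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("feature table not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  cn <- names(raw)
  if (dialect == "mzmine") {
    idc <- grep("^row ID$", cn, ignore.case = TRUE)
    mzc <- grep("^row m/z$", cn, ignore.case = TRUE)
    rtc <- grep("^row retention time$", cn, ignore.case = TRUE)
    if (!length(idc) || !length(mzc) || !length(rtc))
      stopf("mzmine dialect needs 'row ID', 'row m/z', 'row retention time' columns")
    sample_cols <- setdiff(seq_along(cn), c(idc, mzc, rtc))
    sample_cols <- sample_cols[nzchar(trimws(cn[sample_cols]))]
    sample_ids <- sub(area_suffix, "", cn[sample_cols])
    sample_ids <- sub(file_ext, "", sample_ids)
  } else {
    idc <- match("feature_id", cn); mzc <- match("mz", cn); rtc <- match("rt", cn)
    if (anyNA(c(idc, mzc, rtc)))
      stopf("plain dialect needs 'feature_id', 'mz', 'rt' columns")
    sample_cols <- setdiff(seq_along(cn), c(idc, mzc, rtc))
    sample_ids <- cn[sample_cols]
  }
  ids <- as.character(raw[[idc[1]]])
  if (anyDuplicated(ids)) stopf("duplicate feature ids in %s", path)
  areas <- matrix(NA_real_, nrow(raw), length(sample_cols),
                  dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_cols)) {
    cell <- trimws(raw[[sample_cols[j]]])
    bad <- which(!nzchar(cell) | is.na(suppressWarnings(as.numeric(cell))))
    if (length(bad))
      stopf("non-numeric area at row '%s', column '%s'", ids[bad[1]],
            sample_ids[j])
    areas[, j] <- as.numeric(cell)
  }
  meta <- data.frame(feature_id = ids,
                     mz = as.numeric(raw[[mzc[1]]]),
                     rt = as.numeric(raw[[rtc[1]]]))
  feature_table(areas, meta)
}

#' Write a feature table as a plain-dialect CSV
#' @param table a [feature_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(feature_id = table$feature_meta$feature_id,
                   mz = table$feature_meta$mz, rt = table$feature_meta$rt,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(table$areas, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table (TSV)
#'
#' Columns: `sample_id`, `species`, `genus`, `clade`, plus optional
#' `solvent`, `mode`, `is_blank`.
#'
#' @param path TSV path.
#' @return a data frame of class `"sample_metadata"`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  sample_metadata(md)
}

#' Validate a sample metadata data frame
#' @param md data frame with at least `sample_id`, `species`, `genus`, `clade`.
#' @return `md` with class `"sample_metadata"` prepended.
#' @export
sample_metadata <- function(md) {
  md <- as.data.frame(md)
  need <- c("sample_id", "species", "genus", "clade")
  miss <- setdiff(need, names(md))
  if (length(miss)) stopf("metadata missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stopf("duplicate sample ids in metadata")
  if (any(!nzchar(md$genus))) stopf("empty genus in metadata")
  if (!"is_blank" %in% names(md)) md$is_blank <- FALSE
  class(md) <- c("sample_metadata", class(md))
  md
}

#' Write sample metadata as TSV
#' @param md a [sample_metadata()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(md, path) {
  utils::write.table(as.data.frame(md), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only features that have an MS/MS spectrum
#'
#' Restricts a feature table to rows whose feature id appears in the given
#' spectrum collection (the pre-networking filter applied to MZmine
#' exports). Idempotent; the sample set is unchanged.
#'
#' @param table a [feature_table()].
#' @param spectra list of [spectrum()] objects.
#' @return the filtered [feature_table()].
#' @export
filter_features_with_ms2 <- function(table, spectra) {
  ids <- vapply(spectra, function(s) s$feature_id, character(1))
  keep <- rownames(table$areas) %in% ids
  if (!any(keep)) warnf("no features have MS/MS spectra; returning empty table")
  feature_table(table$areas[keep, , drop = FALSE],
                table$feature_meta[keep, , drop = FALSE],
                has_ms2 = rep(TRUE, sum(keep)))
}
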