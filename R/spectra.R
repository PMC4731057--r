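#' Construct a mass spectrum
#'
#' A `spectrum` is a pair of equal-length numeric vectors: strictly
#' increasing m/z values and non-negative intensities, plus minimal
#' acquisition metadata and a processing-stage tag.
#'
#' @param mz numeric, mass-to-charge values (Da/e).  Sorted on input if
#'   needed (a stable sort; intensities follow their m/z).
#' @param intensity numeric, same length as `mz`.
#' @param sample_id character scalar.
#' @param replicate integer >= 1, technical replicate index.
#' @param stage processing stage, one of `"raw"`, `"resampled"`,
#'   `"aligned"`, `"baselined"`, `"smoothed"`, `"normalized"`.
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(mz, intensity, sample_id = NA_character_,
                     replicate = 1L, stage = "raw") {
  stages <- c("raw", "resampled", "aligned", "baselined", "smoothed", "normalized")
  stage <- match.arg(stage, stages)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length", call. = FALSE)
  if (length(mz) == 0L)
    stop("empty spectrum", call. = FALSE)
  if (is.unsorted(mz)) {
    o <- order(mz)                       # order() is stable
    mz <- mz[o]
    intensity <- intensity[o]
  }
  if (any(diff(mz) <= 0))
    stop("mz values must be strictly increasing (duplicated m/z present)",
         call. = FALSE)
  structure(
    list(mz = mz, intensity = intensity,
         sample_id = as.character(sample_id),
         replicate = as.integer(replicate), stage = stage),
    class = "spectrum")
}

#' @export
#' @method print spectrum
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s (rep %d), %d points, m/z %.1f-%.1f, stage: %s\n",
              x$sample_id, x$replicate, length(x$mz),
              min(x$mz), max(x$mz), x$stage))
  invisible(x)
}

#' @export
#' @method length spectrum
length.spectrum <- function(x) length(x$mz)

#' Read a spectrum from mzML or two-column text
#'
#' Text spectra are two whitespace- or tab-separated numeric columns
#' (m/z, intensity); a non-numeric header line is tolerated.  mzML files
#' are read through the mzR backend (first scan).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"mzml"`.
#' @param sample_id,replicate metadata attached to the result.
#' @return a [spectrum()] with `stage = "raw"`, m/z sorted ascending.
#' @export
read_spectrum <- function(path, format = c("auto", "tsv", "mzml"),
                          sample_id = NA_character_, replicate = 1L) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read spectrum: no such file: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "tsv"
  if (is.na(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("mzML support requires the mzR package", call. = FALSE)
    fh <- mzR::openMSfile(path)
    on.exit(mzR::close(fh))
    pk <- mzR::peaks(fh, 1L)
    if (NROW(pk) == 0L) stop("empty spectrum in ", path, call. = FALSE)
    return(spectrum(pk[, 1], pk[, 2], sample_id = sample_id,
                    replicate = replicate))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty spectrum file: ", path, call. = FALSE)
  start <- 1L
  first <- strsplit(trimws(lines[1L]), "[\t ,]+")[[1L]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) start <- 2L
  if (start > length(lines)) stop("empty spectrum file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[start:length(lines)]), "[\t ,]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s", bad[1L] + start - 1L, path),
         call. = FALSE)
  mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  nn <- which(is.na(mz) | is.na(it))
  if (length(nn))
    stop(sprintf("non-numeric value at line %d of %s", nn[1L] + start - 1L, path),
         call. = FALSE)
  spectrum(mz, it, sample_id = sample_id, replicate = replicate)
}

#' Write a spectrum to mzML or two-column text
#'
#' @param spec a [spectrum()].
#' @param path output path.
#' @param format `"auto"` (by extension), `"tsv"` or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, format = c("auto", "tsv", "mzml")) {
  stopifnot(inherits(spec, "spectrum"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "tsv"
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(format(spec$mz, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     format(spec$intensity, digits = 15, trim = TRUE),
                     sep = "\t"), con)
    return(invisible(path))
  }
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML support requires the mzR package", call. = FALSE)
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = length(spec$mz), totIonCurrent = sum(spec$intensity),
    retentionTime = 0, basePeakMZ = spec$mz[which.max(spec$intensity)],
    basePeakIntensity = max(spec$intensity), collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = min(spec$mz), highMZ = max(spec$mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_, stringsAsFactors = FALSE)
  mzR::writeMSData(list(cbind(spec$mz, spec$intensity)), file = path,
                   header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read and validate a sample manifest
#'
#' The manifest is a CSV with columns `sample_id`, `file`, `n_cells_A`,
#' `n_cells_B`, `replicate`, mapping each recorded spectrum to the known
#' composition of its two-component calibration mixture (component A the
#' host line, component B the contaminant).
#'
#' @param path CSV path.
#' @param total optional declared total cell count per sample
#'   (e.g. `1e6` or `0.5e6`); when given, `n_cells_A + n_cells_B` is
#'   checked against it for every row.
#' @return a `data.frame` of class `sample_manifest`.
#' @export
read_manifest <- function(path, total = NULL) {
  if (!file.exists(path))
    stop("cannot read manifest: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df, total = total)
}

#' @rdname read_manifest
#' @param manifest a data.frame with the manifest columns.
#' @export
validate_manifest <- function(manifest, total = NULL) {
  req <- c("sample_id", "file", "n_cells_A", "n_cells_B", "replicate")
  miss <- setdiff(req, names(manifest))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(manifest$n_cells_A < 0) || any(manifest$n_cells_B < 0))
    stop("negative cell counts in manifest", call. = FALSE)
  key <- paste(manifest$sample_id, manifest$replicate)
  if (anyDuplicated(key))
    stop("duplicate (sample_id, replicate) pair: ",
         key[duplicated(key)][1L], call. = FALSE)
  if (!is.null(total)) {
    s <- manifest$n_cells_A + manifest$n_cells_B
    bad <- which(s != total)
    if (length(bad))
      stop(sprintf("row %d: n_cells_A + n_cells_B = %s, declared total %s",
                   bad[1L], format(s[bad[1L]], scientific = FALSE),
                   format(total, scientific = FALSE)), call. = FALSE)
  }
  class(manifest) <- c("sample_manifest", "data.frame")
  manifest
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' Construct an intensity matrix
#'
#' The m-by-n table of fingerprints: one row per spectrum (in manifest
#' order), one column per m/z bin or selected peak.
#'
#' @param values numeric matrix.
#' @param row_ids character row labels (`sample_id:replicate`).
#' @param col_mz numeric m/z value per column.
#' @param stage processing stage of the rows (a spectrum stage, or
#'   `"thresholded"` / `"selected"`).
#' @return an object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, row_ids, col_mz, stage) {
  values <- as.matrix(values)
  stopifnot(length(row_ids) == nrow(values), length(col_mz) == ncol(values))
  stages <- c("raw", "resampled", "aligned", "baselined", "smoothed",
              "normalized", "thresholded", "selected")
  stage <- match.arg(stage, stages)
  dimnames(values) <- NULL
  structure(list(values = values, row_ids = as.character(row_ids),
                 col_mz = as.numeric(col_mz), stage = stage),
            class = "intensity_matrix")
}

#' @export
#' @method print intensity_matrix
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d spectra x %d m/z, stage: %s\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
#' @method dim intensity_matrix
dim.intensity_matrix <- function(x) dim(x$values)

#' Write / read an intensity matrix as CSV
#'
#' The CSV has a `# stage:` comment line, a header of m/z values
#' (prefixed `mz_`) after the `row_id` column, and one row per spectrum.
#' The round trip is lossless to full double precision.
#'
#' @param mat an [intensity_matrix()].
#' @param path CSV path.
#' @return `write_matrix`: `path` invisibly; `read_matrix`: the matrix.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "intensity_matrix"))
  if (nrow(mat$values) == 0L || ncol(mat$values) == 0L)
    stop("refusing to write an empty matrix", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stage: ", mat$stage), con)
  hdr <- paste(c("row_id", paste0("mz_", format(mat$col_mz, digits = 17,
                                                scientific = FALSE,
                                                trim = TRUE))),
               collapse = ",")
  writeLines(hdr, con)
  for (i in seq_len(nrow(mat$values)))
    writeLines(paste(c(mat$row_ids[i],
                       format(mat$values[i, ], digits = 17, trim = TRUE)),
                     collapse = ","), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path))
    stop("cannot read matrix: no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  stage <- if (startsWith(first, "# stage:"))
    trimws(sub("^# stage:", "", first)) else "normalized"
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!"row_id" %in% names(df) || ncol(df) < 2L)
    stop("not an intensity-matrix CSV: ", path, call. = FALSE)
  mzcols <- setdiff(names(df), "row_id")
  col_mz <- as.numeric(sub("^mz_", "", mzcols))
  intensity_matrix(as.matrix(df[, mzcols, drop = FALSE]),
                   row_ids = df$row_id, col_mz = col_mz, stage = stage)
}
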