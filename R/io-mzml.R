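#' Read a stepped-isolation MS2 scan series
#'
#' Reads all MS2 scans of a centroided mzML file (via mzR), ordered by
#' acquisition, with isolation centre and width taken from the mzML
#' isolation-window elements and the NCE from the collision-energy element.
#' Files with `.tsv` extension are read through the plain scan-table
#' dialect ([read_scan_table()]) instead.
#'
#' Profile-mode spectra are rejected: centroiding (e.g. by msConvert) is an
#' upstream step this tool does not perform.
#'
#' @param path mzML (or scan-table TSV) file.
#' @return a [scan_series()] (plan slot `NULL`).
#' @export
read_scan_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.tsv$", path, ignore.case = TRUE))
    return(read_scan_table(path))
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  ms2 <- which(hdr$msLevel == 2L)
  if (!length(ms2)) stop("no MS2 scans in ", path)
  if (any(!is.na(hdr$centroided[ms2]) & !hdr$centroided[ms2]))
    stop("profile-mode MS2 spectra in ", path,
         "; centroid them first (e.g. with msConvert)")
  ms2 <- ms2[order(hdr$seqNum[ms2])]
  bad <- ms2[is.na(hdr$isolationWindowTargetMZ[ms2])]
  if (length(bad))
    stop("scan ", hdr$seqNum[bad[1L]], " in ", path,
         " lacks isolation-window metadata")
  scans <- lapply(seq_along(ms2), function(i) {
    k <- ms2[i]
    pk <- mzR::peaks(ms, k)
    width <- hdr$isolationWindowLowerOffset[k] +
      hdr$isolationWindowUpperOffset[k]
    if (is.na(width) || width <= 0) width <- 1
    ms2_scan(peaklist(pk[, 1L], pk[, 2L]),
             isolation_center = hdr$isolationWindowTargetMZ[k],
             isolation_width = width,
             nce = hdr$collisionEnergy[k],
             scan_index = i - 1L)
  })
  scan_series(scans)
}

#' Write a scan series to mzML
#'
#' Serialises a [scan_series()] as centroided MS2 spectra with full
#' isolation-window metadata, readable back with [read_scan_series()].
#' Paths ending in `.tsv` are written through the scan-table dialect.
#'
#' @param series a [scan_series()].
#' @param path output file (`.mzML` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_scan_series <- function(series, path) {
  stopifnot(inherits(series, "scan_series"))
  if (grepl("\\.tsv$", path, ignore.case = TRUE))
    return(write_scan_table(series, path))
  n <- length(series$scans)
  pk <- lapply(series$scans, function(s)
    cbind(mz = s$peaks$mz, intensity = s$peaks$intensity))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 2L,
    polarity = 1L,
    peaksCount = vapply(pk, nrow, integer(1)),
    totIonCurrent = vapply(pk, function(p) sum(p[, 2L]), numeric(1)),
    retentionTime = seq_len(n),
    basePeakMZ = vapply(pk, function(p)
      if (nrow(p)) p[which.max(p[, 2L]), 1L] else 0, numeric(1)),
    basePeakIntensity = vapply(pk, function(p)
      if (nrow(p)) max(p[, 2L]) else 0, numeric(1)),
    collisionEnergy = vapply(series$scans, function(s)
      ifelse(is.na(s$nce), 0, s$nce), numeric(1)),
    ionisationEnergy = 0,
    lowMZ = vapply(pk, function(p) if (nrow(p)) min(p[, 1L]) else 0,
                   numeric(1)),
    highMZ = vapply(pk, function(p) if (nrow(p)) max(p[, 1L]) else 0,
                    numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = vapply(series$scans, `[[`, numeric(1),
                         "isolation_center"),
    precursorCharge = 1L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = vapply(series$scans, `[[`, numeric(1),
                                     "isolation_center"),
    isolationWindowLowerOffset = vapply(series$scans, function(s)
      s$isolation_width / 2, numeric(1)),
    isolationWindowUpperOffset = vapply(series$scans, function(s)
      s$isolation_width / 2, numeric(1)),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read the plain-text scan-table dialect
#'
#' A tab-separated desk-scale stand-in for mzML with columns `scan_index`,
#' `isolation_center`, `isolation_width`, `nce`, `mz`, `intensity` — one
#' row per peak.
#'
#' @param path TSV file.
#' @return a [scan_series()].
#' @export
read_scan_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t")
  need <- c("scan_index", "isolation_center", "isolation_width", "nce",
            "mz", "intensity")
  if (!all(need %in% names(tab)))
    stop("scan table must have columns: ", paste(need, collapse = ", "))
  scans <- lapply(split(tab, tab$scan_index), function(g)
    ms2_scan(peaklist(g$mz, g$intensity),
             isolation_center = g$isolation_center[1L],
             isolation_width = g$isolation_width[1L],
             nce = g$nce[1L], scan_index = g$scan_index[1L]))
  scan_series(scans[order(as.integer(names(scans)))])
}

#' Write the plain-text scan-table dialect
#'
#' @param series a [scan_series()].
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(series, path) {
  stopifnot(inherits(series, "scan_series"))
  rows <- do.call(rbind, lapply(series$scans, function(s)
    data.frame(scan_index = s$scan_index,
               isolation_center = s$isolation_center,
               isolation_width = s$isolation_width, nce = s$nce,
               mz = s$peaks$mz, intensity = s$peaks$intensity)))
  utils::write.table(format(rows, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
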