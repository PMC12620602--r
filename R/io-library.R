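#' Write spectra to an MGF or MSP library file
#'
#' One entry per spectrum with precursor m/z, NCE and the peak table. MGF
#' entries are `BEGIN IONS`/`END IONS` blocks with `TITLE=`, `PEPMASS=` and
#' `COLLISION_ENERGY=`; MSP records use `Name:`, `PrecursorMZ:`, `NCE:`,
#' `Comment:` and `Num Peaks:`. Theoretical m/z annotations of reference
#' spectra are carried in the MSP `Comment:` field as `theo=obs|theo`
#' pairs, since neither dialect has a standard slot for them.
#'
#' @param spectra non-empty list of [reconstructed_spectrum()] and/or
#'   [reference_spectrum()] objects.
#' @param path output file.
#' @param dialect `"mgf"` or `"msp"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
write_spectrum_library <- function(spectra, path, dialect = NULL) {
  if (!length(spectra)) stop("write_spectrum_library: no spectra")
  dialect <- resolve_dialect(path, dialect)
  entry <- function(x) {
    id <- if (inherits(x, "reference_spectrum")) x$compound_id else
      x$precursor_id
    pmz <- if (inherits(x, "reference_spectrum")) x$precursor_mz else
      x$precursor_mz
    pk <- x$peaks
    if (nrow(pk) == 0L)
      warning("write_spectrum_library: entry '", id, "' has zero peaks")
    peak_lines <- sprintf("%.6f\t%.6g", pk$mz, pk$intensity)
    if (dialect == "mgf") {
      c("BEGIN IONS",
        paste0("TITLE=", id),
        sprintf("PEPMASS=%.6f", pmz),
        if (!is.na(x$nce)) sprintf("COLLISION_ENERGY=%g", x$nce),
        peak_lines,
        "END IONS", "")
    } else {
      comment <- if ("mz_theo" %in% names(pk) && nrow(pk))
        paste0("Comment: ",
               paste(sprintf("theo=%.6f|%.6f", pk$mz, pk$mz_theo),
                     collapse = " "))
      c(paste0("Name: ", id),
        sprintf("PrecursorMZ: %.6f", pmz),
        if (!is.na(x$nce)) sprintf("NCE: %g", x$nce),
        comment,
        sprintf("Num Peaks: %d", nrow(pk)),
        peak_lines, "")
    }
  }
  writeLines(unlist(lapply(spectra, entry)), path)
  invisible(path)
}

resolve_dialect <- function(path, dialect) {
  if (is.null(dialect))
    dialect <- tolower(tools::file_ext(path))
  dialect <- tolower(dialect)
  if (!dialect %in% c("mgf", "msp"))
    stop("unknown spectral library dialect: '", dialect,
         "' (use \"mgf\" or \"msp\")")
  dialect
}

# Parse an MGF or MSP file into raw entries:
# list(id, precursor_mz, nce, peaks, mz_theo or NULL)
parse_spectrum_library <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- resolve_dialect(path, dialect)
  lines <- trimws(readLines(path))
  entries <- list()
  if (dialect == "mgf") {
    starts <- grep("^BEGIN IONS$", lines)
    ends <- grep("^END IONS$", lines)
    if (length(starts) != length(ends) || any(ends < starts))
      stop("malformed MGF: unbalanced BEGIN/END IONS")
    for (e in seq_along(starts)) {
      block <- lines[(starts[e] + 1L):(ends[e] - 1L)]
      kv <- grepl("=", block, fixed = TRUE)
      keys <- sub("=.*$", "", block[kv])
      vals <- sub("^[^=]*=", "", block[kv])
      pk_lines <- block[!kv & nzchar(block)]
      pk <- parse_peak_lines(pk_lines, path, e)
      pmz <- suppressWarnings(as.numeric(vals[match("PEPMASS", keys)]))
      if (is.na(pmz)) stop("malformed MGF entry ", e, ": missing PEPMASS")
      entries[[e]] <- list(
        id = vals[match("TITLE", keys)],
        precursor_mz = pmz,
        nce = suppressWarnings(
          as.numeric(vals[match("COLLISION_ENERGY", keys)])),
        peaks = pk, mz_theo = NULL)
    }
  } else {
    starts <- grep("^Name:", lines)
    if (!length(starts)) stop("malformed MSP: no Name: records")
    bounds <- c(starts, length(lines) + 1L)
    for (e in seq_along(starts)) {
      block <- lines[bounds[e]:(bounds[e + 1L] - 1L)]
      field <- function(key) {
        hit <- grep(paste0("^", key, ":"), block, value = TRUE)
        if (length(hit)) trimws(sub(paste0("^", key, ":"), "", hit[1L]))
        else NA_character_
      }
      np_line <- grep("^Num Peaks:", block)
      if (!length(np_line))
        stop("malformed MSP entry ", e, ": missing Num Peaks")
      np <- as.integer(field("Num Peaks"))
      pk_lines <- block[np_line + seq_len(np)]
      pk <- parse_peak_lines(pk_lines[nzchar(pk_lines)], path, e)
      mz_theo <- NULL
      comment <- field("Comment")
      if (!is.na(comment) && grepl("theo=", comment)) {
        pairs <- regmatches(comment,
                            gregexpr("theo=[0-9.]+\\|[0-9.]+", comment))[[1L]]
        obs <- as.numeric(sub("theo=([0-9.]+)\\|.*", "\\1", pairs))
        theo <- as.numeric(sub(".*\\|", "", pairs))
        mz_theo <- theo[match(round(pk$mz, 6L), round(obs, 6L))]
        mz_theo[is.na(mz_theo)] <- pk$mz[is.na(mz_theo)]
      }
      entries[[e]] <- list(
        id = field("Name"),
        precursor_mz = as.numeric(field("PrecursorMZ")),
        nce = suppressWarnings(as.numeric(field("NCE"))),
        peaks = pk, mz_theo = mz_theo)
    }
  }
  entries
}

parse_peak_lines <- function(pk_lines, path, entry_index) {
  if (!length(pk_lines)) return(peaklist())
  parts <- strsplit(pk_lines, "[\t ]+")
  bad <- vapply(parts, length, integer(1)) < 2L
  if (any(bad))
    stop("malformed peak line in entry ", entry_index, " of ", path)
  mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1L)))
  int <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(mz) || anyNA(int))
    stop("non-numeric peak values in entry ", entry_index, " of ", path)
  peaklist(mz, int)
}

#' Read a reference spectral library
#'
#' Parses an MGF or MSP file into [reference_spectrum()] objects, applying
#' the standard library cleanup on load: peaks with intensity strictly
#' below 0.3% of the entry's base peak are discarded. Theoretical m/z
#' values are taken from the MSP `Comment:` annotation when present;
#' otherwise the observed m/z is used and a warning is issued once.
#'
#' @param path library file.
#' @param dialect `"mgf"` or `"msp"` (default: from the file extension).
#' @param noise_frac cleanup threshold relative to the base peak.
#' @return named list of [reference_spectrum()] objects.
#' @export
read_reference_library <- function(path, dialect = NULL,
                                   noise_frac = 0.003) {
  entries <- parse_spectrum_library(path, dialect)
  warned <- FALSE
  out <- lapply(seq_along(entries), function(e) {
    x <- entries[[e]]
    if (is.null(x$id) || is.na(x$id))
      stop("malformed library entry ", e, ": no compound id")
    if (is.null(x$mz_theo) && !warned) {
      warned <<- TRUE
      warning("no theoretical m/z annotations in ", path,
              "; using observed m/z")
    }
    reference_spectrum(x$id, x$precursor_mz, x$peaks, nce = x$nce,
                       mz_theo = x$mz_theo %||% x$peaks$mz,
                       noise_frac = noise_frac, clean = TRUE)
  })
  names(out) <- vapply(out, `[[`, character(1), "compound_id")
  out
}

#' Read a spectral library without cleanup
#'
#' Raw round-trip companion of [write_spectrum_library()]: returns the
#' entries as [reconstructed_spectrum()] objects with peaks exactly as
#' stored.
#'
#' @inheritParams read_reference_library
#' @return named list of [reconstructed_spectrum()] objects.
#' @export
read_spectrum_library <- function(path, dialect = NULL) {
  entries <- parse_spectrum_library(path, dialect)
  out <- lapply(entries, function(x)
    reconstructed_spectrum(x$id, x$peaks, precursor_mz = x$precursor_mz,
                           nce = x$nce))
  names(out) <- vapply(out, `[[`, character(1), "precursor_id")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
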