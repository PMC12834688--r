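#' Read spectra from a Mascot generic format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, and optional
#' `CHARGE`, `RTINSECONDS`, `TITLE`, `SCANS`, `NAME` and `PATHWAY` headers
#' (the latter two are used by reference-library files). Peak lines are
#' whitespace-separated `m/z intensity` pairs. Within each block, peaks are
#' sorted by m/z and equal-m/z peaks merged by intensity sum.
#'
#' @param path Path to an MGF file.
#' @return A list of [spectrum()] objects, one per block, in file order.
#'   When a block has no `TITLE`, the spectrum id is
#'   `"<basename>:<block ordinal>"`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  base <- basename(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) == 0L) {
    warning("no spectra found in ", path)
    return(list())
  }
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF ", path, ": unbalanced BEGIN IONS/END IONS")
  }
  out <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_header <- grepl("=", block, fixed = TRUE)
    headers <- block[is_header]
    keys <- toupper(sub("=.*$", "", headers))
    vals <- sub("^[^=]*=", "", headers)
    hv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA_character_

    pep <- hv("PEPMASS")
    if (is.na(pep)) {
      stop("malformed MGF block ", b, " in ", path, ": missing PEPMASS")
    }
    precursor_mz <- suppressWarnings(as.numeric(strsplit(trimws(pep),
                                                         "\\s+")[[1]][1]))
    if (is.na(precursor_mz)) {
      stop("malformed MGF block ", b, " in ", path, ": non-numeric PEPMASS")
    }
    charge <- 1L
    ch <- hv("CHARGE")
    if (!is.na(ch)) {
      charge <- suppressWarnings(as.integer(gsub("[^0-9]", "", ch)))
      if (is.na(charge) || charge < 1L) charge <- 1L
    }
    rt <- suppressWarnings(as.numeric(hv("RTINSECONDS")))
    title <- hv("TITLE")
    sid <- if (!is.na(title) && nzchar(title)) title else
      sprintf("%s:%d", base, b)
    scan <- suppressWarnings(as.integer(hv("SCANS")))
    if (is.na(scan)) scan <- b - 1L

    peak_lines <- trimws(block[!is_header])
    if (length(peak_lines) > 0L) {
      fields <- strsplit(peak_lines, "[ \t]+")
      bad <- vapply(fields, length, integer(1)) < 2L
      mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
      int <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
      if (any(bad) || anyNA(mz) || anyNA(int)) {
        stop("malformed MGF block ", b, " in ", path,
             ": non-numeric peak line")
      }
      peaks <- cbind(mz, int)
    } else {
      peaks <- matrix(numeric(0), ncol = 2L)
    }
    out[[b]] <- spectrum(
      precursor_mz = precursor_mz, peaks = peaks, spectrum_id = sid,
      precursor_charge = charge, retention_time = rt, source_file = base,
      scan_index = scan, name = hv("NAME"), pathway = hv("PATHWAY")
    )
  }
  out
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: emits one `BEGIN IONS` block per spectrum in
#' input order, with full numeric precision so that a read/write round trip
#' reproduces the peak lists.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    hdr <- c(
      "BEGIN IONS",
      sprintf("TITLE=%s", s$spectrum_id),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      sprintf("CHARGE=%d+", s$precursor_charge),
      if (!is.na(s$retention_time))
        sprintf("RTINSECONDS=%.3f", s$retention_time),
      sprintf("SCANS=%d", s$scan_index),
      if (!is.na(s$name)) sprintf("NAME=%s", s$name),
      if (!is.na(s$pathway)) sprintf("PATHWAY=%s", s$pathway)
    )
    pk <- if (nrow(s$peaks) > 0L) {
      sprintf("%.6f %.8g", s$peaks[, 1L], s$peaks[, 2L])
    } else character(0)
    paste(c(hdr, pk, "END IONS"), collapse = "\n")
  }, character(1))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write MGF: ", path))
  on.exit(close(con))
  writeLines(blocks, con, sep = "\n\n")
  invisible(path)
}
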