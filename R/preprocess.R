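#' Remove fragment ions near the precursor m/z
#'
#' Drops every fragment peak within `window` Da of the precursor (inclusive:
#' a peak at exactly `precursor_mz - window` is removed). Removing the
#' precursor region strips residual precursor and its isotopes/neutral-loss
#' satellites, which otherwise dominate cosine scores.
#'
#' @param s A [spectrum()].
#' @param window Da half-width (default 17).
#' @return The spectrum with only peaks satisfying
#'   `|mz - precursor_mz| > window`. May have an empty peak list.
#' @export
remove_precursor_region <- function(s, window = 17.0) {
  stopifnot(window > 0)
  keep <- abs(s$peaks[, 1L] - s$precursor_mz) > window
  s$peaks <- s$peaks[keep, , drop = FALSE]
  s
}

#' Windowed top-k intensity filter
#'
#' A fragment peak is retained iff its intensity ranks in the top `k` among
#' all peaks within `width` Da of its own m/z (each peak judged in its own
#' sliding neighborhood, the convention of GNPS preprocessing — not disjoint
#' bins). Intensity ties are broken toward the lower-m/z peak, so the filter
#' is deterministic.
#'
#' @param s A [spectrum()].
#' @param k Peaks kept per window (default 6).
#' @param width Da half-width of the neighborhood (default 50).
#' @return The filtered spectrum, peaks still sorted by m/z.
#' @export
window_filter_top_peaks <- function(s, k = 6L, width = 50.0) {
  stopifnot(k >= 1L, width > 0)
  pk <- s$peaks
  n <- nrow(pk)
  if (n <= k) return(s)
  mz <- pk[, 1L]
  int <- pk[, 2L]
  keep <- logical(n)
  lo <- findInterval(mz - width, mz) + 1L     # first index with mz >= mz_i - width
  hi <- findInterval(mz + width, mz)          # last index with mz <= mz_i + width
  for (i in seq_len(n)) {
    idx <- lo[i]:hi[i]
    # rank of peak i in its own window; ties favor lower m/z
    better <- int[idx] > int[i] | (int[idx] == int[i] & idx < i)
    keep[i] <- sum(better) < k
  }
  s$peaks <- pk[keep, , drop = FALSE]
  s
}

#' Apply the standard spectral cleanup to a list of spectra
#'
#' Precursor-region removal followed by the windowed top-k filter, the two
#' deterministic filters applied to both query and library spectra before
#' any similarity scoring. Both steps are idempotent, so preprocessed
#' spectra pass through unchanged.
#'
#' @param spectra List of [spectrum()] objects.
#' @param params A [networking_params()] object.
#' @param drop_empty Drop spectra whose peak list becomes empty
#'   (default TRUE).
#' @return List of preprocessed spectra.
#' @export
preprocess_spectra <- function(spectra, params = networking_params(),
                               drop_empty = TRUE) {
  out <- lapply(spectra, function(s) {
    s <- remove_precursor_region(s, params$precursor_region_window)
    window_filter_top_peaks(s, params$window_filter_k,
                            params$window_filter_width)
  })
  if (drop_empty) out <- out[vapply(out, n_peaks, integer(1)) > 0L]
  out
}

#' Build a precursor exclusion list from blank runs
#'
#' Collects the precursor m/z values observed in blank (culture-media-only)
#' runs and deduplicates them by single-linkage within `mz_tol`; each merged
#' entry is the mean of its member precursors. This emulates, on the data
#' side, the acquisition-time exclusion lists used to avoid fragmenting
#' medium components.
#'
#' @param blank_spectra List of [spectrum()] objects from blank runs (may be
#'   empty).
#' @param mz_tol Da tolerance for merging entries (default 0.01).
#' @return Sorted numeric vector of exclusion m/z values.
#' @export
build_exclusion_list <- function(blank_spectra, mz_tol = 0.01) {
  if (length(blank_spectra) == 0L) return(numeric(0))
  mz <- sort(vapply(blank_spectra, function(s) s$precursor_mz, numeric(1)))
  # single-linkage on a line: split where adjacent gap exceeds mz_tol
  grp <- cumsum(c(TRUE, diff(mz) > mz_tol))
  as.numeric(tapply(mz, grp, mean))
}

#' Remove spectra whose precursor falls on an exclusion list
#'
#' @param spectra List of [spectrum()] objects.
#' @param exclusion Sorted numeric vector from [build_exclusion_list()].
#' @param mz_tol Da tolerance (default 0.01).
#' @return Spectra whose precursor is farther than `mz_tol` from every entry.
#' @export
apply_exclusion_list <- function(spectra, exclusion, mz_tol = 0.01) {
  if (length(exclusion) == 0L) return(spectra)
  keep <- vapply(spectra, function(s) {
    min(abs(exclusion - s$precursor_mz)) > mz_tol
  }, logical(1))
  spectra[keep]
}
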