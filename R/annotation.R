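#' Read a reference spectral library from MGF
#'
#' Library MGF files carry `NAME=` (compound name, required) and optional
#' `PATHWAY=` headers per block. Entries are preprocessed with the same
#' filters as query spectra, the standard parity requirement of library
#' searching.
#'
#' @param path Library MGF path.
#' @param params [networking_params()] used for preprocessing.
#' @return List of [spectrum()] objects with `name`/`pathway` set.
#' @export
read_library <- function(path, params = networking_params()) {
  lib <- read_mgf(path)
  bad <- vapply(lib, function(s) is.na(s$name) || !nzchar(s$name), logical(1))
  if (any(bad)) {
    stop("library entries without NAME in ", path, ": blocks ",
         paste(which(bad), collapse = ", "))
  }
  preprocess_spectra(lib, params)
}

best_hit <- function(query, library, lib_prec, cand, params,
                     min_cosine, min_matched) {
  best <- NULL
  for (i in cand) {
    mc <- modified_cosine(library[[i]], query, params$fragment_tol)
    if (mc$score < min_cosine || mc$n_matched < min_matched) next
    if (is.null(best) ||
        mc$score > best$score + 1e-12 ||
        (abs(mc$score - best$score) <= 1e-12 &&
         (mc$n_matched > best$n_matched ||
          (mc$n_matched == best$n_matched &&
           library[[i]]$spectrum_id < library[[best$i]]$spectrum_id)))) {
      best <- list(i = i, score = mc$score, n_matched = mc$n_matched,
                   delta = mc$delta)
    }
  }
  best
}

annotation_row <- function(cs, entry, hit, mode) {
  data.frame(
    consensus_id = cs$spectrum_id, entry_id = entry$spectrum_id,
    compound_name = entry$name, pathway = entry$pathway,
    cosine = hit$score, n_matched = hit$n_matched,
    precursor_delta = hit$delta, mode = mode, stringsAsFactors = FALSE)
}

empty_annotations <- function() {
  data.frame(consensus_id = character(0), entry_id = character(0),
             compound_name = character(0), pathway = character(0),
             cosine = numeric(0), n_matched = integer(0),
             precursor_delta = numeric(0), mode = character(0))
}

#' Exact spectral-library search (dereplication)
#'
#' For each consensus spectrum, finds the best-scoring library entry whose
#' precursor lies within `precursor_tol` Da, requiring cosine >=
#' `library_min_cosine` and >= `library_min_matched` matched peaks. At most
#' one exact annotation per consensus; ties broken by higher matched-peak
#' count, then entry id.
#'
#' @param consensus List of consensus spectra (preprocessed).
#' @param library List from [read_library()].
#' @param params [networking_params()].
#' @return Annotation data frame (`consensus_id`, `entry_id`,
#'   `compound_name`, `pathway`, `cosine`, `n_matched`, `precursor_delta`,
#'   `mode = "exact"`).
#' @export
exact_library_search <- function(consensus, library,
                                 params = networking_params()) {
  if (length(library) == 0L) {
    warning("empty spectral library: no exact annotations")
    return(empty_annotations())
  }
  lib_prec <- vapply(library, function(s) s$precursor_mz, numeric(1))
  rows <- list()
  for (cs in consensus) {
    cand <- which(abs(lib_prec - cs$precursor_mz) <= params$precursor_tol)
    if (length(cand) == 0L) next
    hit <- best_hit(cs, library, lib_prec, cand, params,
                    params$library_min_cosine, params$library_min_matched)
    if (!is.null(hit)) {
      rows[[length(rows) + 1L]] <-
        annotation_row(cs, library[[hit$i]], hit, "exact")
    }
  }
  if (length(rows) == 0L) return(empty_annotations())
  do.call(rbind, rows)
}

#' Analog (propagated/suspect-style) library search
#'
#' Extends annotation to consensus spectra without an exact hit: the best
#' library entry whose precursor differs by more than `precursor_tol` but at
#' most `analog_max_delta` Da, at the same cosine/matched-peak thresholds.
#' The modified cosine lets fragment pairs match across the precursor delta,
#' so a compound differing from a library entry by one modification still
#' aligns. Each annotation carries the delta; the shifted/unshifted fragment
#' partition is available via [localize_mass_shift()].
#'
#' @param consensus List of consensus spectra.
#' @param library List from [read_library()].
#' @param params [networking_params()].
#' @param exact Annotations from [exact_library_search()]; consensus spectra
#'   present there are skipped.
#' @return Annotation data frame with `mode = "analog"`.
#' @export
analog_library_search <- function(consensus, library,
                                  params = networking_params(),
                                  exact = NULL) {
  if (length(library) == 0L) return(empty_annotations())
  done <- if (is.null(exact)) character(0) else exact$consensus_id
  lib_prec <- vapply(library, function(s) s$precursor_mz, numeric(1))
  rows <- list()
  for (cs in consensus) {
    if (cs$spectrum_id %in% done) next
    d <- abs(lib_prec - cs$precursor_mz)
    cand <- which(d > params$precursor_tol & d <= params$analog_max_delta)
    if (length(cand) == 0L) next
    hit <- best_hit(cs, library, lib_prec, cand, params,
                    params$library_min_cosine, params$library_min_matched)
    if (!is.null(hit)) {
      rows[[length(rows) + 1L]] <-
        annotation_row(cs, library[[hit$i]], hit, "analog")
    }
  }
  if (length(rows) == 0L) return(empty_annotations())
  do.call(rbind, rows)
}

#' Localize a mass shift on the fragment series
#'
#' For an analog match, partitions the matched peak pairs into direct
#' (unshifted) and delta-shifted sets and reports the smallest shifted
#' fragment m/z on the query side — the tightest bound on where along the
#' fragment series the modification resides. A deliberately simplified
#' localization: it reports shift-carrying fragments, not atom-level
#' placement.
#'
#' @param query Consensus [spectrum()] (the putative analog).
#' @param entry Library [spectrum()].
#' @param params [networking_params()].
#' @return List: `delta` (query - library precursor difference), `direct`
#'   and `shifted` (matched-pair data frames with library/query m/z),
#'   `min_shifted_mz` (smallest shifted query fragment, `NA` if none),
#'   `all_shifted` (TRUE when every matched pair carries the shift, i.e.
#'   the modification lies within the smallest matched fragment).
#' @export
localize_mass_shift <- function(query, entry,
                                params = networking_params()) {
  delta <- query$precursor_mz - entry$precursor_mz
  if (abs(delta) <= params$precursor_tol) {
    stop("localize_mass_shift requires an analog match ",
         "(|precursor delta| > precursor_tol)")
  }
  mc <- modified_cosine(entry, query, params$fragment_tol)
  pairs <- mc$pairs
  names(pairs)[names(pairs) == "a_mz"] <- "library_mz"
  names(pairs)[names(pairs) == "b_mz"] <- "query_mz"
  direct <- pairs[!pairs$shifted, c("library_mz", "query_mz"), drop = FALSE]
  shifted <- pairs[pairs$shifted, c("library_mz", "query_mz"), drop = FALSE]
  list(
    delta = mc$delta,
    direct = direct,
    shifted = shifted,
    min_shifted_mz = if (nrow(shifted) > 0L) min(shifted$query_mz)
      else NA_real_,
    all_shifted = nrow(pairs) > 0L && all(pairs$shifted)
  )
}

#' Propagate annotations to molecular families
#'
#' A family is annotated iff at least one member consensus carries an exact
#' or analog annotation; contributing compound names are listed.
#'
#' @param families Family table from [extract_families()].
#' @param annotations Combined annotation data frame.
#' @return Data frame: `family_id`, `size`, `annotated`, `compound_names`,
#'   `n_annotated_nodes`.
#' @export
propagate_family_annotations <- function(families, annotations) {
  out <- do.call(rbind, lapply(split(families, families$family_id),
                               function(d) {
    hits <- annotations[annotations$consensus_id %in% d$consensus_id, ,
                        drop = FALSE]
    data.frame(
      family_id = d$family_id[1L], size = nrow(d),
      annotated = nrow(hits) > 0L,
      compound_names = paste(sort(unique(hits$compound_name)),
                             collapse = ";"),
      n_annotated_nodes = length(unique(hits$consensus_id)),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
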