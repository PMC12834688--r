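# Monoisotopic ion masses (Da) used for adduct arithmetic throughout.
PROTON_MASS <- 1.007276
SODIUM_ION_MASS <- 22.989218

#' The five culture media of the strains-by-media design
#'
#' Media identifiers accepted in sample metadata: ISP-2, ISP-4, TSA, NSG and
#' CZP agar, written without punctuation.
#'
#' @export
MEDIA_LEVELS <- c("ISP2", "ISP4", "TSA", "NSG", "CZP")

#' Biosynthetic pathway labels carried by library entries
#'
#' Seven coarse natural-product pathway classes used to stratify annotation
#' counts by culture condition.
#'
#' @export
PATHWAY_LEVELS <- c(
  "Alkaloids", "Amino acids and Peptides", "Carbohydrates", "Fatty acids",
  "Polyketides", "Shikimates and Phenylpropanoids", "Terpenoids"
)

#' Construct an MS/MS spectrum
#'
#' The elementary record of the pipeline: one tandem-MS scan with its
#' precursor description and centroided peak list. On construction the peak
#' list is normalized: zero/negative intensities dropped, peaks sorted by
#' m/z, and peaks at identical m/z merged by summing intensity, so that the
#' m/z column is strictly increasing.
#'
#' @param precursor_mz Precursor ion m/z in Da (> 0).
#' @param peaks Two-column numeric matrix (m/z, intensity) or a list/data
#'   frame coercible to one. Intensities are arbitrary units; peaks with
#'   intensity <= 0 are discarded.
#' @param spectrum_id Identifier unique within a run.
#' @param precursor_charge Integer charge state (>= 1, default 1).
#' @param retention_time Retention time in seconds (optional, `NA` if absent).
#' @param source_file Originating file name.
#' @param scan_index Zero-based scan ordinal within the source file.
#' @param name,pathway Optional compound name and pathway label (library
#'   entries only).
#'
#' @return An object of class `"spectrum"`: a list with the above fields,
#'   `peaks` a strictly m/z-increasing matrix with columns `mz`, `intensity`.
#' @export
spectrum <- function(precursor_mz, peaks, spectrum_id = "",
                     precursor_charge = 1L, retention_time = NA_real_,
                     source_file = "", scan_index = 0L,
                     name = NA_character_, pathway = NA_character_) {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L,
            precursor_mz > 0)
  if (is.data.frame(peaks)) peaks <- as.matrix(peaks)
  if (is.null(peaks) || length(peaks) == 0L) {
    peaks <- matrix(numeric(0), ncol = 2L)
  }
  if (!is.matrix(peaks) || ncol(peaks) != 2L) {
    stop("peaks must be a two-column (mz, intensity) matrix")
  }
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  peaks <- peaks[peaks[, 2L] > 0, , drop = FALSE]
  if (nrow(peaks) > 0L) {
    if (any(peaks[, 1L] <= 0)) stop("fragment m/z values must be positive")
    peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
    # merge equal-m/z peaks by intensity sum
    if (anyDuplicated(peaks[, 1L])) {
      mz <- unique(peaks[, 1L])
      int <- vapply(mz, function(m) sum(peaks[peaks[, 1L] == m, 2L]),
                    numeric(1))
      peaks <- cbind(mz = mz, intensity = int)
    }
  }
  structure(
    list(
      spectrum_id = as.character(spectrum_id),
      precursor_mz = as.numeric(precursor_mz),
      precursor_charge = as.integer(precursor_charge),
      retention_time = as.numeric(retention_time),
      peaks = peaks,
      source_file = as.character(source_file),
      scan_index = as.integer(scan_index),
      name = as.character(name),
      pathway = as.character(pathway)
    ),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> precursor %.4f m/z (charge %d), %d peaks\n",
              x$spectrum_id, x$precursor_mz, x$precursor_charge,
              nrow(x$peaks)))
  invisible(x)
}

n_peaks <- function(s) nrow(s$peaks)

#' Networking, clustering and annotation parameters
#'
#' Bundles every threshold of the classical molecular-networking workflow.
#' Defaults follow the GNPS settings used for large microbial-extract
#' studies: fragment ions within +/-17 Da of the precursor removed; only the
#' top 6 fragment ions kept per +/-50 Da window; 0.02 Da precursor and
#' fragment tolerances; network edges require cosine >= 0.7 and >= 6 matched
#' peaks and must be mutual top-10 neighbors; molecular families capped at
#' 100 nodes; library matches require score >= 0.7 and >= 6 matched peaks.
#'
#' @param precursor_region_window Da half-width of the precursor region whose
#'   fragment ions are removed (default 17).
#' @param window_filter_k Number of fragment ions kept per window (default 6).
#' @param window_filter_width Da half-width of the peak-rank window
#'   (default 50).
#' @param precursor_tol,fragment_tol Precursor / fragment m/z tolerances in
#'   Da (default 0.02 each).
#' @param min_cosine,min_matched_peaks Edge thresholds (default 0.7 and 6).
#' @param top_k Mutual nearest-neighbor rank cutoff (default 10).
#' @param max_family_size Molecular-family size cap (default 100).
#' @param library_min_cosine,library_min_matched Library-search thresholds
#'   (default 0.7 and 6).
#' @param analog_max_delta Maximum precursor mass difference (Da) considered
#'   in analog search (default 200).
#' @param cluster_precursor_tol,cluster_min_cosine Consensus-clustering
#'   thresholds (default 0.02 Da and 0.7).
#' @param exclusion_mz_tol Precursor tolerance (Da) for blank-derived
#'   exclusion lists (default 0.01).
#'
#' @return A list of class `"networking_params"`.
#' @export
networking_params <- function(precursor_region_window = 17.0,
                              window_filter_k = 6L,
                              window_filter_width = 50.0,
                              precursor_tol = 0.02,
                              fragment_tol = 0.02,
                              min_cosine = 0.7,
                              min_matched_peaks = 6L,
                              top_k = 10L,
                              max_family_size = 100L,
                              library_min_cosine = 0.7,
                              library_min_matched = 6L,
                              analog_max_delta = 200.0,
                              cluster_precursor_tol = 0.02,
                              cluster_min_cosine = 0.7,
                              exclusion_mz_tol = 0.01) {
  p <- list(
    precursor_region_window = precursor_region_window,
    window_filter_k = as.integer(window_filter_k),
    window_filter_width = window_filter_width,
    precursor_tol = precursor_tol,
    fragment_tol = fragment_tol,
    min_cosine = min_cosine,
    min_matched_peaks = as.integer(min_matched_peaks),
    top_k = as.integer(top_k),
    max_family_size = as.integer(max_family_size),
    library_min_cosine = library_min_cosine,
    library_min_matched = as.integer(library_min_matched),
    analog_max_delta = analog_max_delta,
    cluster_precursor_tol = cluster_precursor_tol,
    cluster_min_cosine = cluster_min_cosine,
    exclusion_mz_tol = exclusion_mz_tol
  )
  numeric_positive <- vapply(p, function(v) is.numeric(v) && v > 0,
                             logical(1))
  if (!all(numeric_positive)) {
    stop("all networking parameters must be positive numbers: ",
         paste(names(p)[!numeric_positive], collapse = ", "))
  }
  if (p$min_cosine > 1 || p$library_min_cosine > 1) {
    stop("cosine thresholds must lie in (0, 1]")
  }
  if (p$top_k < 1L) stop("top_k must be >= 1")
  if (p$max_family_size < 2L) stop("max_family_size must be >= 2")
  class(p) <- "networking_params"
  p
}

#' Load the sample metadata table
#'
#' Reads a tab-separated table with header columns `filename`, `strain_id`,
#' `genus`, `media`, `sample_type`. `media` must be one of ISP2, ISP4, TSA,
#' NSG, CZP (required for rows with `sample_type == "sample"`; may be empty
#' for blanks/QCs run outside a culture condition). `sample_type` must be
#' one of sample, blank, qc.
#'
#' @param path Path to the TSV file.
#' @return A data frame of sample records, one row per file.
#' @export
load_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("filename", "strain_id", "genus", "media", "sample_type")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("sample table ", path, " lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  dup <- tab$filename[duplicated(tab$filename)]
  if (length(dup) > 0L) {
    stop("duplicate filenames in sample table: ",
         paste(unique(dup), collapse = ", "))
  }
  bad_type <- setdiff(unique(tab$sample_type), c("sample", "blank", "qc"))
  if (length(bad_type) > 0L) {
    stop("unknown sample_type values: ", paste(bad_type, collapse = ", "))
  }
  nonempty <- !is.na(tab$media) & tab$media != ""
  bad_media <- setdiff(unique(tab$media[nonempty]), MEDIA_LEVELS)
  if (length(bad_media) > 0L) {
    stop("unknown media values: ", paste(bad_media, collapse = ", "),
         " (expected ", paste(MEDIA_LEVELS, collapse = "/"), ")")
  }
  need_media <- tab$sample_type == "sample" & !nonempty
  if (any(need_media)) {
    stop("media is required for sample rows; missing for: ",
         paste(tab$filename[need_media], collapse = ", "))
  }
  tab[required]
}
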