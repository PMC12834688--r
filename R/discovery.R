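#' Build a strain-by-item incidence matrix
#'
#' @param item_strains Named list: for each item (consensus spectrum or
#'   molecular family id), the character vector of strains it was observed
#'   in. Family incidence is the union of its member nodes' strains.
#' @param units Ordered character vector of accumulation units (strain ids).
#'   Every strain referenced by an item must be present.
#' @return Logical matrix, items x units; all-zero item rows are an error
#'   upstream of any statistic, so they are dropped with a warning here.
#' @export
build_incidence <- function(item_strains, units) {
  unknown <- setdiff(unique(unlist(item_strains)), units)
  if (length(unknown) > 0L) {
    stop("items reference unknown strain(s): ",
         paste(unknown, collapse = ", "))
  }
  M <- t(vapply(item_strains, function(s) units %in% s,
                logical(length(units))))
  colnames(M) <- units
  empty <- rowSums(M) == 0L
  if (any(empty)) {
    warning(sum(empty), " item(s) observed in no unit were dropped")
    M <- M[!empty, , drop = FALSE]
  }
  M
}

incidence_from_consensus <- function(consensus, units) {
  ids <- vapply(consensus, function(s) s$spectrum_id, character(1))
  build_incidence(stats::setNames(lapply(consensus, `[[`, "strain_set"),
                                  ids), units)
}

incidence_from_families <- function(families, consensus, units) {
  strains <- stats::setNames(lapply(consensus, `[[`, "strain_set"),
                             vapply(consensus, function(s) s$spectrum_id,
                                    character(1)))
  fam_strains <- lapply(split(families$consensus_id, families$family_id),
                        function(members)
                          sort(unique(unlist(strains[members]))))
  build_incidence(fam_strains, units)
}

#' Closed-form expected rarefaction curve
#'
#' The hypergeometric expectation of the number of distinct items seen after
#' k of N units, `E[S(k)] = sum_i (1 - choose(N - n_i, k) / choose(N, k))`,
#' where `n_i` is the number of units containing item i.
#'
#' @param M Incidence matrix from [build_incidence()].
#' @return Numeric vector of length N (units).
#' @export
expected_rarefaction <- function(M) {
  N <- ncol(M)
  ni <- rowSums(M)
  vapply(seq_len(N), function(k)
    sum(1 - choose(N - ni, k) / choose(N, k)), numeric(1))
}

#' Permutation-averaged rarefaction (accumulation) curve
#'
#' For each of `n_permutations` random orderings of the units, counts the
#' cumulative number of distinct items after k units; reports mean and sd
#' across permutations together with the closed-form expectation from
#' [expected_rarefaction()]. `order = "fixed"` instead accumulates the units
#' in the matrix's column order (single pass, sd 0) — the narrative
#' "add one sample at a time" reading.
#'
#' @param M Incidence matrix.
#' @param n_permutations Number of random orderings (default 100).
#' @param seed Integer seed making the orderings reproducible.
#' @param order `"permutation"` (default) or `"fixed"`.
#' @return Data frame: `k`, `mean`, `sd`, `expected`.
#' @export
rarefaction_curve <- function(M, n_permutations = 100L, seed = 1L,
                              order = c("permutation", "fixed")) {
  order <- match.arg(order)
  if (nrow(M) == 0L || ncol(M) == 0L) stop("empty incidence matrix")
  stopifnot(n_permutations >= 1L)
  N <- ncol(M)
  curve_for <- function(perm) {
    pos <- integer(N); pos[perm] <- seq_len(N)
    first <- Reduce(pmin, lapply(seq_len(N), function(u)
      ifelse(M[, u], pos[u], N + 1L)))
    cumsum(tabulate(first[first <= N], nbins = N))
  }
  if (order == "fixed") {
    cv <- curve_for(seq_len(N))
    return(data.frame(k = seq_len(N), mean = cv, sd = 0,
                      expected = expected_rarefaction(M)))
  }
  curves <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) curve_for(sample.int(N)),
           numeric(N))
  })
  curves <- matrix(curves, nrow = N)
  data.frame(
    k = seq_len(N),
    mean = rowMeans(curves),
    sd = apply(curves, 1L, stats::sd),
    expected = expected_rarefaction(M))
}

#' Rarefaction curves for all strata of a study
#'
#' Computes the six curves of a discovery-potential figure: all / annotated /
#' unannotated, at the consensus-spectrum and molecular-family level, all
#' under the same unit permutations (same seed), so annotated + unannotated
#' equals the overall curve at every k.
#'
#' @param consensus Consensus spectra (with strain provenance).
#' @param families Family table from [extract_families()].
#' @param annotations Combined annotation data frame.
#' @param units Ordered strain ids.
#' @param n_permutations,seed Passed to [rarefaction_curve()].
#' @return Data frame with columns of [rarefaction_curve()] plus `stratum`
#'   (`all`/`annotated`/`unannotated`) and `level` (`spectra`/`families`).
#' @export
rarefaction_by_stratum <- function(consensus, families, annotations, units,
                                   n_permutations = 100L, seed = 1L) {
  ann_nodes <- unique(annotations$consensus_id)
  fam_ann <- propagate_family_annotations(families, annotations)
  ann_fams <- fam_ann$family_id[fam_ann$annotated]
  ids <- vapply(consensus, function(s) s$spectrum_id, character(1))

  Msp <- incidence_from_consensus(consensus, units)
  Mfam <- incidence_from_families(families, consensus, units)
  pieces <- list(
    list("all", "spectra", Msp),
    list("annotated", "spectra", Msp[rownames(Msp) %in% ann_nodes, ,
                                     drop = FALSE]),
    list("unannotated", "spectra", Msp[!rownames(Msp) %in% ann_nodes, ,
                                       drop = FALSE]),
    list("all", "families", Mfam),
    list("annotated", "families", Mfam[rownames(Mfam) %in% ann_fams, ,
                                       drop = FALSE]),
    list("unannotated", "families", Mfam[!rownames(Mfam) %in% ann_fams, ,
                                         drop = FALSE]))
  out <- lapply(pieces, function(p) {
    M <- p[[3L]]
    if (nrow(M) == 0L) {
      cv <- data.frame(k = seq_len(length(units)), mean = 0, sd = 0,
                       expected = 0)
    } else {
      cv <- rarefaction_curve(M, n_permutations, seed)
    }
    cv$stratum <- p[[1L]]
    cv$level <- p[[2L]]
    cv
  })
  do.call(rbind, out)
}

#' Media-overlap (upset) counts
#'
#' For every nonempty combination of culture media observed, the exclusive
#' count of items whose media set is exactly that combination (the
#' intersection bars of an upset plot), plus the per-medium set sizes
#' (items observed in that medium regardless of overlap).
#'
#' @param consensus Consensus spectra with `media_set` provenance.
#' @return List: `exclusive` (data frame `combination`, `n_media`, `count`)
#'   and `set_sizes` (data frame `media`, `size`).
#' @export
media_overlap_counts <- function(consensus) {
  sets <- lapply(consensus, `[[`, "media_set")
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    stop(sum(empty), " consensus spectra have an empty media set")
  }
  keys <- vapply(sets, function(m)
    paste(sort(m), collapse = "+"), character(1))
  tab <- table(keys)
  exclusive <- data.frame(
    combination = names(tab),
    n_media = lengths(strsplit(names(tab), "+", fixed = TRUE)),
    count = as.integer(tab), stringsAsFactors = FALSE)
  exclusive <- exclusive[order(-exclusive$count, exclusive$combination), ,
                         drop = FALSE]
  rownames(exclusive) <- NULL
  media_seen <- sort(unique(unlist(sets)))
  set_sizes <- data.frame(
    media = media_seen,
    size = vapply(media_seen, function(m)
      sum(vapply(sets, function(s) m %in% s, logical(1))), integer(1)),
    stringsAsFactors = FALSE)
  rownames(set_sizes) <- NULL
  list(exclusive = exclusive, set_sizes = set_sizes)
}

#' Annotation-rate summary
#'
#' Reports both denominators in use for "annotation rate": annotated raw
#' MS/MS spectra over all raw spectra (a consensus annotation covers all its
#' member scans), and annotated consensus spectra over all consensus
#' spectra, plus annotated/unannotated family counts.
#'
#' @param n_raw_spectra Total raw MS/MS count entering clustering.
#' @param consensus Consensus spectra.
#' @param annotations Combined annotation data frame.
#' @param families Family table.
#' @return Named list of counts and rates.
#' @export
annotation_rate_summary <- function(n_raw_spectra, consensus, annotations,
                                    families) {
  ids <- vapply(consensus, function(s) s$spectrum_id, character(1))
  members <- vapply(consensus, function(s) nrow(s$members), numeric(1))
  ann_ids <- unique(annotations$consensus_id)
  fam_ann <- propagate_family_annotations(families, annotations)
  fam_sizes <- unique(families[, c("family_id", "family_size")])
  n_exact <- length(unique(
    annotations$consensus_id[annotations$mode == "exact"]))
  n_analog <- length(unique(
    annotations$consensus_id[annotations$mode == "analog"]))
  list(
    n_raw_spectra = n_raw_spectra,
    n_consensus = length(consensus),
    n_annotated_exact = n_exact,
    n_annotated_analog = n_analog,
    n_annotated_consensus = length(ann_ids),
    n_annotated_raw_spectra = sum(members[ids %in% ann_ids]),
    rate_raw = if (n_raw_spectra > 0)
      sum(members[ids %in% ann_ids]) / n_raw_spectra else 0,
    rate_consensus = if (length(consensus) > 0L)
      length(ann_ids) / length(consensus) else 0,
    n_families = nrow(fam_sizes),
    n_annotated_families = sum(fam_ann$annotated),
    n_unannotated_families = sum(!fam_ann$annotated)
  )
}

#' Pathway-by-medium normalized annotation matrix
#'
#' Counts annotated consensus spectra per (biosynthetic pathway, culture
#' medium) — a consensus observed in several media counts in each — and
#' normalizes every pathway row to its maximum, so the best medium for each
#' pathway scores 1. Pathways with no counts are dropped.
#'
#' @param consensus Consensus spectra with `media_set` provenance.
#' @param annotations Annotation data frame with `pathway` labels.
#' @return Numeric matrix, pathways x media, each retained row's max = 1.
#' @export
pathway_media_matrix <- function(consensus, annotations) {
  media <- MEDIA_LEVELS
  ann <- annotations[!is.na(annotations$pathway), , drop = FALSE]
  counts <- matrix(0, nrow = length(PATHWAY_LEVELS), ncol = length(media),
                   dimnames = list(PATHWAY_LEVELS, media))
  media_sets <- stats::setNames(lapply(consensus, `[[`, "media_set"),
                                vapply(consensus, function(s) s$spectrum_id,
                                       character(1)))
  for (r in seq_len(nrow(ann))) {
    for (m in media_sets[[ann$consensus_id[r]]]) {
      counts[ann$pathway[r], m] <- counts[ann$pathway[r], m] + 1
    }
  }
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(counts) == 0L) return(counts)
  sweep(counts, 1L, apply(counts, 1L, max), "/")
}
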