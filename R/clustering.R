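#' Merge near-identical MS/MS spectra into consensus spectra
#'
#' Single-linkage clustering: two spectra are joinable iff their precursors
#' differ by at most `cluster_precursor_tol` Da and their modified cosine
#' (with near-zero precursor delta this is a plain cosine) is at least
#' `cluster_min_cosine`; clusters are the connected components of the
#' joinability relation, so the result does not depend on input order.
#' Implemented with a union-find over the precursor-sorted spectra; a pair
#' already connected through earlier links is not re-scored, which leaves
#' the final partition unchanged but avoids the quadratic cosine cost on
#' files full of replicated ions.
#'
#' @param spectra List of preprocessed [spectrum()] objects.
#' @param params [networking_params()]; uses `cluster_precursor_tol`,
#'   `cluster_min_cosine` and `fragment_tol`.
#' @return List of consensus spectra (class `"consensus_spectrum"`): each is
#'   a [spectrum()] whose precursor is the intensity-weighted mean of the
#'   members' precursors and whose peaks come from [build_consensus()], plus
#'   a `members` data frame (`spectrum_id`, `source_file`). Ordered and
#'   identified (`C00001`, ...) by (precursor m/z, first member id).
#' @export
cluster_spectra <- function(spectra, params = networking_params()) {
  n <- length(spectra)
  if (n == 0L) return(list())
  prec <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  ord <- order(prec, ids)
  spectra <- spectra[ord]; prec <- prec[ord]; ids <- ids[ord]

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  tol <- params$cluster_precursor_tol
  for (i in seq_len(n)[-1L]) {
    j <- i - 1L
    while (j >= 1L && prec[i] - prec[j] <= tol) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) {
        mc <- modified_cosine(spectra[[j]], spectra[[i]],
                              params$fragment_tol)
        if (mc$score >= params$cluster_min_cosine) parent[ri] <- rj
      }
      j <- j - 1L
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  clusters <- split(seq_len(n), roots)
  # deterministic ordering by (cluster precursor, first member id)
  key <- vapply(clusters, function(ix) min(prec[ix]), numeric(1))
  key2 <- vapply(clusters, function(ix) min(ids[ix]), character(1))
  clusters <- clusters[order(key, key2)]

  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    members <- spectra[clusters[[ci]]]
    cons <- build_consensus(members, params$fragment_tol)
    cons$spectrum_id <- sprintf("C%05d", ci)
    cons$members <- data.frame(
      spectrum_id = vapply(members, function(s) s$spectrum_id, character(1)),
      source_file = vapply(members, function(s) s$source_file, character(1)),
      stringsAsFactors = FALSE)
    class(cons) <- c("consensus_spectrum", "spectrum")
    out[[ci]] <- cons
  }
  out
}

#' Build the consensus peak list of a cluster
#'
#' Member peaks are pooled and grouped by single-linkage within
#' `fragment_tol` (on a line this is: split the sorted pool wherever the gap
#' between adjacent m/z values exceeds the tolerance); each group emits an
#' intensity-weighted mean m/z and the summed intensity. The result is
#' rescaled to a maximum intensity of 1000. The consensus precursor is the
#' mean of member precursors weighted by each member's total ion intensity.
#'
#' @param members List of [spectrum()] objects (>= 1).
#' @param fragment_tol Da grouping tolerance (default 0.02).
#' @return A [spectrum()] holding the consensus precursor and peaks.
#' @export
build_consensus <- function(members, fragment_tol = 0.02) {
  stopifnot(length(members) >= 1L)
  pooled <- do.call(rbind, lapply(members, function(s) s$peaks))
  tic <- vapply(members, function(s) sum(s$peaks[, 2L]), numeric(1))
  if (all(tic == 0)) tic <- rep(1, length(members))
  prec <- sum(vapply(members, function(s) s$precursor_mz, numeric(1)) * tic) /
    sum(tic)
  if (nrow(pooled) == 0L) {
    return(spectrum(prec, NULL))
  }
  pooled <- pooled[order(pooled[, 1L]), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(pooled[, 1L]) > fragment_tol))
  mz <- as.numeric(tapply(pooled[, 1L] * pooled[, 2L], grp, sum) /
                     tapply(pooled[, 2L], grp, sum))
  int <- as.numeric(tapply(pooled[, 2L], grp, sum))
  int <- int / max(int) * 1000
  spectrum(prec, cbind(mz, int),
           retention_time = members[[1L]]$retention_time,
           source_file = members[[1L]]$source_file)
}

# Attach strain/media/blank provenance from the sample table.
# Errors if any member's source file has no metadata row.
add_provenance <- function(consensus, metadata) {
  lookup <- metadata
  rownames(lookup) <- lookup$filename
  lapply(consensus, function(cs) {
    files <- cs$members$source_file
    missing <- setdiff(unique(files), lookup$filename)
    if (length(missing) > 0L) {
      stop("member file(s) absent from sample table: ",
           paste(missing, collapse = ", "))
    }
    rows <- lookup[files, , drop = FALSE]
    is_blank <- rows$sample_type == "blank"
    cs$strain_set <- sort(unique(rows$strain_id[!is_blank]))
    cs$media_set <- sort(unique(rows$media[rows$media != ""]))
    cs$media_members <- table(factor(rows$media[!is_blank],
                                     levels = MEDIA_LEVELS))
    cs$blank_member_count <- sum(is_blank)
    cs
  })
}

#' Remove consensus spectra explained by blanks
#'
#' A consensus spectrum is discarded iff its fraction of members coming from
#' blank runs exceeds `max_blank_fraction`. The default 0 is strict: any
#' blank membership removes the consensus, the usual background filter of
#' molecular networking.
#'
#' @param consensus List of consensus spectra.
#' @param metadata Sample table from [load_sample_table()]; must cover every
#'   member file.
#' @param max_blank_fraction Tolerated blank-member fraction (default 0).
#' @return Filtered list, with provenance fields (`strain_set`, `media_set`,
#'   `blank_member_count`) attached.
#' @export
remove_blank_clusters <- function(consensus, metadata,
                                  max_blank_fraction = 0) {
  consensus <- add_provenance(consensus, metadata)
  keep <- vapply(consensus, function(cs) {
    cs$blank_member_count / nrow(cs$members) <= max_blank_fraction
  }, logical(1))
  consensus[keep]
}

#' Write the cluster-info table
#'
#' One row per consensus spectrum: id, member count, member files, strains,
#' media and blank-member count — the bookkeeping twin of the consensus MGF.
#'
#' @param consensus List of consensus spectra (with provenance).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_info <- function(consensus, path) {
  tab <- do.call(rbind, lapply(consensus, function(cs) data.frame(
    consensus_id = cs$spectrum_id,
    precursor_mz = cs$precursor_mz,
    n_members = nrow(cs$members),
    files = paste(sort(unique(cs$members$source_file)), collapse = ";"),
    strains = paste(cs$strain_set, collapse = ";"),
    media = paste(cs$media_set, collapse = ";"),
    blank_members = cs$blank_member_count,
    stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
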