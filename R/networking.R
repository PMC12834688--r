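#' Score all consensus pairs and keep thresholded candidate edges
#'
#' Computes the modified cosine for every unordered pair of consensus
#' spectra and keeps pairs with cosine >= `min_cosine` and at least
#' `min_matched_peaks` matched peaks. Quadratic in the number of nodes; an
#' optional precursor-delta cap restricts scoring to pairs within
#' `max_precursor_delta` Da (off by default).
#'
#' @param consensus List of consensus spectra.
#' @param params [networking_params()].
#' @param max_precursor_delta Optional Da cap on |precursor difference|
#'   (default `Inf`).
#' @return Edge data frame: `node_a`, `node_b` (ids, `node_a < node_b`),
#'   `cosine`, `n_matched`, `delta` (precursor m/z difference, b - a).
#' @export
score_all_pairs <- function(consensus, params = networking_params(),
                            max_precursor_delta = Inf) {
  n <- length(consensus)
  ids <- vapply(consensus, function(s) s$spectrum_id, character(1))
  prec <- vapply(consensus, function(s) s$precursor_mz, numeric(1))
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (abs(prec[j] - prec[i]) > max_precursor_delta) next
        mc <- modified_cosine(consensus[[i]], consensus[[j]],
                              params$fragment_tol)
        if (mc$score >= params$min_cosine &&
            mc$n_matched >= params$min_matched_peaks) {
          swap <- ids[i] > ids[j]
          rows[[length(rows) + 1L]] <- data.frame(
            node_a = if (swap) ids[j] else ids[i],
            node_b = if (swap) ids[i] else ids[j],
            cosine = mc$score, n_matched = mc$n_matched,
            delta = if (swap) -mc$delta else mc$delta,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(node_a = character(0), node_b = character(0),
                      cosine = numeric(0), n_matched = integer(0),
                      delta = numeric(0)))
  }
  edges <- do.call(rbind, rows)
  edges[order(edges$node_a, edges$node_b), , drop = FALSE]
}

#' Mutual top-K edge filter
#'
#' An edge (a, b) survives iff b ranks among a's `k` highest-cosine
#' neighbors and a ranks among b's. Ranks are computed on the
#' threshold-filtered edge set; ties are ordered by (higher cosine, then
#' lexical neighbor id), so the filter is deterministic.
#'
#' @param edges Edge data frame from [score_all_pairs()].
#' @param k Rank cutoff (default 10).
#' @return The retained subset of `edges`.
#' @export
mutual_topk_filter <- function(edges, k = 10L) {
  stopifnot(k >= 1L)
  if (nrow(edges) == 0L) return(edges)
  long <- rbind(
    data.frame(node = edges$node_a, nbr = edges$node_b,
               cosine = edges$cosine, stringsAsFactors = FALSE),
    data.frame(node = edges$node_b, nbr = edges$node_a,
               cosine = edges$cosine, stringsAsFactors = FALSE))
  rank_of <- function(df) {
    ord <- order(-df$cosine, df$nbr)
    r <- integer(nrow(df)); r[ord] <- seq_len(nrow(df))
    r
  }
  long$rank <- NA_integer_
  for (ix in split(seq_len(nrow(long)), long$node)) {
    long$rank[ix] <- rank_of(long[ix, , drop = FALSE])
  }
  key <- paste(long$node, long$nbr)
  rank_lookup <- stats::setNames(long$rank, key)
  keep <- rank_lookup[paste(edges$node_a, edges$node_b)] <= k &
    rank_lookup[paste(edges$node_b, edges$node_a)] <= k
  edges[keep, , drop = FALSE]
}

# Connected component membership for a node/edge set, as a named integer
# vector over all node ids (isolated nodes included).
component_membership <- function(node_ids, edges) {
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = node_ids))
  igraph::components(g)$membership[node_ids]
}

#' Cap molecular-family size by pruning weakest edges
#'
#' While any connected component exceeds `max_family_size` nodes, the
#' lowest-cosine edge of that component is removed (ties broken by lexical
#' edge id) and components are recomputed. Exact but O(E * components), fine
#' at desk scale.
#'
#' @param edges Edge data frame.
#' @param node_ids Character vector of all node ids (isolated nodes count).
#' @param max_family_size Maximum component size (default 100).
#' @return The pruned edge data frame.
#' @export
enforce_family_size_cap <- function(edges, node_ids, max_family_size = 100L) {
  stopifnot(max_family_size >= 2L)
  repeat {
    if (nrow(edges) == 0L) return(edges)
    memb <- component_membership(node_ids, edges)
    sizes <- table(memb)
    over <- as.integer(names(sizes)[sizes > max_family_size])
    if (length(over) == 0L) return(edges)
    comp <- over[1L]
    in_comp <- memb[edges$node_a] == comp
    cand <- which(in_comp)
    eid <- paste(edges$node_a[cand], edges$node_b[cand])
    worst <- cand[order(edges$cosine[cand], eid)[1L]]
    edges <- edges[-worst, , drop = FALSE]
  }
}

#' Extract molecular families (connected components)
#'
#' @param edges Final edge data frame.
#' @param node_ids All node ids; nodes without edges become singleton
#'   families.
#' @return Data frame `family_id`, `consensus_id`, `family_size`,
#'   `singleton`. Families are numbered by their smallest member id.
#' @export
extract_families <- function(edges, node_ids) {
  memb <- component_membership(node_ids, edges)
  comps <- split(names(memb), memb)
  comps <- comps[order(vapply(comps, min, character(1)))]
  rows <- lapply(seq_along(comps), function(i) {
    nodes <- sort(comps[[i]])
    data.frame(family_id = sprintf("FAM%04d", i), consensus_id = nodes,
               family_size = length(nodes),
               singleton = length(nodes) == 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the full molecular network from consensus spectra
#'
#' Convenience wrapper chaining [score_all_pairs()], [mutual_topk_filter()],
#' [enforce_family_size_cap()] and [extract_families()].
#'
#' @param consensus List of consensus spectra.
#' @param params [networking_params()].
#' @return List: `edges`, `families`, `node_ids`.
#' @export
build_network <- function(consensus, params = networking_params()) {
  node_ids <- vapply(consensus, function(s) s$spectrum_id, character(1))
  edges <- score_all_pairs(consensus, params)
  edges <- mutual_topk_filter(edges, params$top_k)
  edges <- enforce_family_size_cap(edges, node_ids, params$max_family_size)
  families <- extract_families(edges, node_ids)
  list(edges = edges, families = families, node_ids = node_ids)
}

#' Export the molecular network as GraphML plus TSV twins
#'
#' Node attributes: consensus id, precursor m/z, member count, per-medium
#' member proportions, and the annotation name when present; edge
#' attributes: cosine, matched peaks, precursor delta.
#'
#' @param consensus List of consensus spectra (with provenance).
#' @param network Result of [build_network()].
#' @param annotations Annotation data frame (may be empty) with
#'   `consensus_id` and `compound_name`.
#' @param dir Output directory.
#' @param prefix File name prefix (default `"network"`).
#' @return Named vector of written paths.
#' @export
export_network <- function(consensus, network, annotations = NULL,
                           dir = ".", prefix = "network") {
  ids <- vapply(consensus, function(s) s$spectrum_id, character(1))
  nodes <- data.frame(
    name = ids,
    precursor_mz = vapply(consensus, function(s) s$precursor_mz, numeric(1)),
    n_members = vapply(consensus, function(s) nrow(s$members), numeric(1)),
    stringsAsFactors = FALSE)
  media_prop <- t(vapply(consensus, function(s) {
    m <- as.numeric(s$media_members)
    if (sum(m) > 0) m / sum(m) else m
  }, numeric(length(MEDIA_LEVELS))))
  colnames(media_prop) <- paste0("prop_", MEDIA_LEVELS)
  nodes <- cbind(nodes, media_prop)
  fam <- network$families
  nodes$family_id <- fam$family_id[match(ids, fam$consensus_id)]
  nodes$annotation <- ""
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    hit <- match(ids, annotations$consensus_id)
    nodes$annotation <- ifelse(is.na(hit), "",
                               annotations$compound_name[hit])
  }
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = nodes)
  graphml_path <- file.path(dir, paste0(prefix, ".graphml"))
  igraph::write_graph(g, graphml_path, format = "graphml")
  edges_path <- file.path(dir, paste0(prefix, "_edges.tsv"))
  utils::write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fam_path <- file.path(dir, paste0(prefix, "_families.tsv"))
  fam_tab <- do.call(rbind, lapply(split(fam, fam$family_id), function(d)
    data.frame(family_id = d$family_id[1L], size = nrow(d),
               member_ids = paste(sort(d$consensus_id), collapse = ";"),
               stringsAsFactors = FALSE)))
  utils::write.table(fam_tab, fam_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nodes_path <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(graphml = graphml_path, edges = edges_path, families = fam_path,
    nodes = nodes_path)
}
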