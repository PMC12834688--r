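# Independent brute-force oracles used to verify the package's algorithms.
# These deliberately re-derive everything from first principles (plain
# enumeration, O(n^2) loops) and share no code with the implementation.

random_spectrum <- function(n_peaks, precursor = runif(1, 200, 1200),
                            mz_range = c(50, precursor)) {
  spectrum(precursor,
           cbind(sort(runif(n_peaks, mz_range[1], mz_range[2])),
                 runif(n_peaks, 0.1, 10)))
}

# Exhaustive modified cosine: enumerate every one-to-one assignment of
# candidate peak pairs (direct or precursor-delta-shifted), keeping the
# assignment with the largest summed product of unit-normalized sqrt
# intensities (more pairs win ties). Feasible for <= 8 peaks per spectrum.
oracle_modified_cosine <- function(a, b, tol = 0.02) {
  if (nrow(a$peaks) == 0 || nrow(b$peaks) == 0) {
    return(list(score = 0, n_matched = 0L))
  }
  delta <- b$precursor_mz - a$precursor_mz
  wa <- sqrt(a$peaks[, 2]); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(b$peaks[, 2]); wb <- wb / sqrt(sum(wb^2))
  na <- nrow(a$peaks); nb <- nrow(b$peaks)
  ok <- function(i, j) {
    abs(a$peaks[i, 1] - b$peaks[j, 1]) <= tol ||
      abs(a$peaks[i, 1] + delta - b$peaks[j, 1]) <= tol
  }
  best <- c(score = 0, n = 0)
  recurse <- function(i, used_b, score, n) {
    if (i > na) {
      if (score > best["score"] + 1e-15 ||
          (abs(score - best["score"]) <= 1e-15 && n > best["n"])) {
        best <<- c(score = score, n = n)
      }
      return(invisible(NULL))
    }
    recurse(i + 1, used_b, score, n)              # leave peak i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && ok(i, j)) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, score + wa[i] * wb[j], n + 1)
        used_b[j] <- FALSE
      }
    }
    invisible(NULL)
  }
  recurse(1, rep(FALSE, nb), 0, 0L)
  list(score = unname(best["score"]), n_matched = as.integer(best["n"]))
}

# Brute-force windowed top-k filter: for every peak, explicitly enumerate
# its +/- width neighborhood and rank intensities (ties -> lower m/z first).
oracle_window_filter <- function(s, k, width) {
  pk <- s$peaks
  keep <- vapply(seq_len(nrow(pk)), function(i) {
    nb <- which(abs(pk[, 1] - pk[i, 1]) <= width)
    better <- sum(pk[nb, 2] > pk[i, 2] |
                    (pk[nb, 2] == pk[i, 2] & pk[nb, 1] < pk[i, 1]))
    better < k
  }, logical(1))
  pk[keep, , drop = FALSE]
}

# O(n^2) single-linkage grouping of values within tol; returns group labels.
oracle_tolerance_groups <- function(x, tol) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(x[i] - x[j]) <= tol) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# All-pairs single-linkage spectral clustering oracle: joinable iff both the
# precursor tolerance and the cosine threshold hold; partition = connected
# components of the joinability graph.
oracle_single_linkage_clusters <- function(spectra, params) {
  n <- length(spectra)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  prec <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && abs(prec[i] - prec[j]) <= params$cluster_precursor_tol) {
      mc <- modified_cosine(spectra[[i]], spectra[[j]], params$fragment_tol)
      if (mc$score >= params$cluster_min_cosine) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  unname(lapply(split(ids, roots), sort))
}

# Brute-force mutual top-k filter by explicit rank enumeration.
oracle_mutual_topk <- function(edges, k) {
  rank_in <- function(node, nbr) {
    ix <- which(edges$node_a == node | edges$node_b == node)
    other <- ifelse(edges$node_a[ix] == node, edges$node_b[ix],
                    edges$node_a[ix])
    ord <- order(-edges$cosine[ix], other)
    which(other[ord] == nbr)
  }
  keep <- vapply(seq_len(nrow(edges)), function(e) {
    rank_in(edges$node_a[e], edges$node_b[e]) <= k &&
      rank_in(edges$node_b[e], edges$node_a[e]) <= k
  }, logical(1))
  edges[keep, , drop = FALSE]
}

# Plain-R connected components (BFS over adjacency lists), avoiding igraph.
oracle_components <- function(node_ids, edges) {
  adj <- stats::setNames(vector("list", length(node_ids)), node_ids)
  for (e in seq_len(nrow(edges))) {
    a <- edges$node_a[e]; b <- edges$node_b[e]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- stats::setNames(rep(NA_integer_, length(node_ids)), node_ids)
  cid <- 0L
  for (start in node_ids) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# Step-by-step family-size-cap reference: recompute components after every
# single removal, remove the over-cap component's weakest edge each time.
oracle_size_cap <- function(edges, node_ids, cap) {
  repeat {
    comp <- oracle_components(node_ids, edges)
    sizes <- table(comp)
    over <- as.integer(names(sizes)[sizes > cap])
    if (length(over) == 0 || nrow(edges) == 0) return(edges)
    cand <- which(comp[edges$node_a] == over[1])
    eid <- paste(edges$node_a[cand], edges$node_b[cand])
    edges <- edges[-cand[order(edges$cosine[cand], eid)[1]], , drop = FALSE]
  }
}

# Exhaustive rarefaction: average the accumulation curve over all N!
# orderings of the units (N <= 6).
oracle_rarefaction_exhaustive <- function(M) {
  N <- ncol(M)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  all_p <- perms(seq_len(N))
  curves <- vapply(all_p, function(p) {
    seen <- rep(FALSE, nrow(M))
    out <- numeric(N)
    for (k in seq_len(N)) {
      seen <- seen | M[, p[k]]
      out[k] <- sum(seen)
    }
    out
  }, numeric(N))
  rowMeans(matrix(curves, nrow = N))
}

# Canonical sorted membership lists for comparing partitions.
cluster_membership <- function(consensus) {
  unname(lapply(consensus, function(cs) sort(cs$members$spectrum_id)))
}
sort_partition <- function(p) p[order(vapply(p, `[`, "", 1L))]
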