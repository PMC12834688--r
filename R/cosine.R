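#' Modified-cosine similarity between two MS/MS spectra
#'
#' The edge score of classical molecular networking. A fragment of spectrum
#' `a` may be paired with a fragment of spectrum `b` either directly
#' (`|mz_a - mz_b| <= fragment_tol`) or shifted by the precursor mass
#' difference `delta = precursor(b) - precursor(a)`
#' (`|mz_a + delta - mz_b| <= fragment_tol`); a pair satisfying both counts
#' once and is classed as direct. Intensities are square-root transformed
#' and each spectrum's transformed intensity vector scaled to unit Euclidean
#' norm; the score is the maximum over one-to-one peak assignments of the
#' summed products of normalized intensities, i.e. a maximum-weight
#' bipartite matching, solved exactly. Identical spectra score 1.
#'
#' @param a,b [spectrum()] objects (preprocessed).
#' @param fragment_tol Fragment m/z tolerance in Da (default 0.02).
#' @param method `"exact"` (default) solves the assignment exactly by
#'   branch-and-bound over connected components of the candidate pair graph;
#'   `"greedy"` takes candidate pairs in decreasing weight order (faster,
#'   not guaranteed optimal).
#' @return A list with elements `score` (in \[0, 1\]), `n_matched` (pairs in
#'   the maximizing assignment), `delta` (precursor mass difference b - a,
#'   Da) and `pairs`: a data frame with one row per matched pair — indices
#'   `a_peak`/`b_peak`, m/z values `a_mz`/`b_mz`, logical `shifted`, and the
#'   pair's contribution `weight`. Empty peak lists give score 0.
#' @export
modified_cosine <- function(a, b, fragment_tol = 0.02,
                            method = c("exact", "greedy")) {
  method <- match.arg(method)
  stopifnot(fragment_tol > 0)
  empty <- data.frame(a_peak = integer(0), b_peak = integer(0),
                      a_mz = numeric(0), b_mz = numeric(0),
                      shifted = logical(0), weight = numeric(0))
  delta <- b$precursor_mz - a$precursor_mz
  na <- n_peaks(a); nb <- n_peaks(b)
  if (na == 0L || nb == 0L) {
    return(list(score = 0, n_matched = 0L, delta = delta, pairs = empty))
  }
  mza <- a$peaks[, 1L]; mzb <- b$peaks[, 1L]
  wa <- sqrt(a$peaks[, 2L]); wa <- wa / sqrt(sum(wa * wa))
  wb <- sqrt(b$peaks[, 2L]); wb <- wb / sqrt(sum(wb * wb))

  direct <- abs(outer(mza, mzb, "-")) <= fragment_tol
  cand <- if (abs(delta) <= 1e-12) direct else
    direct | (abs(outer(mza + delta, mzb, "-")) <= fragment_tol)
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list(score = 0, n_matched = 0L, delta = delta, pairs = empty))
  }
  ei <- idx[, 1L]; ej <- idx[, 2L]
  ew <- wa[ei] * wb[ej]

  sel <- if (method == "greedy") {
    greedy_matching(ei, ej, ew)
  } else {
    exact_matching(ei, ej, ew, na, nb)
  }
  score <- min(sum(ew[sel]), 1)
  pairs <- data.frame(
    a_peak = ei[sel], b_peak = ej[sel],
    a_mz = mza[ei[sel]], b_mz = mzb[ej[sel]],
    shifted = !direct[cbind(ei[sel], ej[sel])],
    weight = ew[sel]
  )
  pairs <- pairs[order(pairs$a_mz), , drop = FALSE]
  rownames(pairs) <- NULL
  list(score = score, n_matched = length(sel), delta = delta, pairs = pairs)
}

# Greedy assignment: descending weight, first-come-first-served.
greedy_matching <- function(ei, ej, ew) {
  ord <- order(-ew, ei, ej)
  used_a <- logical(max(ei)); used_b <- logical(max(ej))
  sel <- integer(0)
  for (e in ord) {
    if (!used_a[ei[e]] && !used_b[ej[e]]) {
      used_a[ei[e]] <- TRUE; used_b[ej[e]] <- TRUE
      sel <- c(sel, e)
    }
  }
  sel
}

# Exact maximum-weight bipartite matching over the candidate pair graph.
# The graph is decomposed into connected components; at a 0.02 Da tolerance
# components are nearly always single edges or disjoint stars, so exhaustive
# branch-and-bound per component is exact and cheap. Among equal-weight
# assignments the one with more pairs is preferred (deterministic reporting
# of n_matched).
exact_matching <- function(ei, ej, ew, na, nb) {
  ne <- length(ew)
  if (ne == 1L) return(1L)
  # union-find over a-nodes (1..na) and b-nodes (na+1..na+nb)
  parent <- seq_len(na + nb)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_len(ne)) {
    ra <- find(ei[e]); rb <- find(na + ej[e])
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_len(ne), function(e) find(ei[e]), integer(1))
  sel <- integer(0)
  for (cc in unique(comp)) {
    edges <- which(comp == cc)
    if (length(edges) == 1L) {
      sel <- c(sel, edges)
      next
    }
    deg_a <- table(ei[edges]); deg_b <- table(ej[edges])
    if (all(deg_a == 1L) && all(deg_b == 1L)) {
      sel <- c(sel, edges)   # component is already a matching
      next
    }
    sel <- c(sel, edges[bb_matching(ei[edges], ej[edges], ew[edges])])
  }
  sel
}

# Branch-and-bound over the edges of one component. Returns local indices of
# the optimal assignment. Edges are visited in decreasing weight order; the
# running upper bound is the current weight plus the sum of all remaining
# edge weights (loose but sufficient for the tiny components seen here).
bb_matching <- function(ei, ej, ew) {
  ord <- order(-ew)
  ei <- ei[ord]; ej <- ej[ord]; ew <- ew[ord]
  ne <- length(ew)
  suffix <- rev(cumsum(rev(ew)))
  best <- list(score = -1, n = -1L, sel = integer(0))
  recurse <- function(k, used_a, used_b, cur_w, cur_sel) {
    if (k > ne) {
      if (cur_w > best$score + 1e-15 ||
          (abs(cur_w - best$score) <= 1e-15 &&
           length(cur_sel) > best$n)) {
        best <<- list(score = cur_w, n = length(cur_sel), sel = cur_sel)
      }
      return(invisible(NULL))
    }
    if (cur_w + suffix[k] < best$score - 1e-15) return(invisible(NULL))
    if (!(ei[k] %in% used_a) && !(ej[k] %in% used_b)) {
      recurse(k + 1L, c(used_a, ei[k]), c(used_b, ej[k]),
              cur_w + ew[k], c(cur_sel, k))
    }
    recurse(k + 1L, used_a, used_b, cur_w, cur_sel)
    invisible(NULL)
  }
  recurse(1L, integer(0), integer(0), 0, integer(0))
  ord[best$sel]
}
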