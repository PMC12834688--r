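# Random consensus-like spectra (any spectrum works for edge scoring).
random_nodes <- function(n, id_prefix = "C") {
  lapply(seq_len(n), function(i) {
    s <- random_spectrum(sample(8:15, 1))
    s$spectrum_id <- sprintf("%s%03d", id_prefix, i)
    s
  })
}

# Synthetic edge tables for graph-level operations.
random_edge_table <- function(n_nodes, p = 0.3) {
  ids <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(node_a = pairs[keep, 1], node_b = pairs[keep, 2],
             cosine = round(runif(sum(keep), 0.7, 1), 3),
             n_matched = 6L, delta = 0, stringsAsFactors = FALSE)
}

test_that("score_all_pairs emits exactly the thresholded pairs (brute-force check)", {
  set.seed(51)
  nodes <- random_nodes(12)
  # add near-duplicates so some edges exist
  for (i in 1:4) {
    dup <- nodes[[i]]
    dup$spectrum_id <- sprintf("C9%02d", i)
    dup$peaks[, 1] <- dup$peaks[, 1] + runif(nrow(dup$peaks), -0.01, 0.01)
    dup$peaks <- dup$peaks[order(dup$peaks[, 1]), ]
    nodes[[length(nodes) + 1]] <- dup
  }
  params <- networking_params()
  edges <- score_all_pairs(nodes, params)
  expect_gt(nrow(edges), 0)
  # naive double loop oracle
  want <- 0L
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i < j) {
      mc <- modified_cosine(nodes[[i]], nodes[[j]], params$fragment_tol)
      if (mc$score >= params$min_cosine &&
          mc$n_matched >= params$min_matched_peaks) {
        want <- want + 1L
        ids <- sort(c(nodes[[i]]$spectrum_id, nodes[[j]]$spectrum_id))
        row <- edges[edges$node_a == ids[1] & edges$node_b == ids[2], ]
        expect_equal(nrow(row), 1L)
        expect_equal(row$cosine, mc$score)
      }
    }
  }
  expect_equal(nrow(edges), want)
  # every retained edge satisfies the thresholds
  expect_true(all(edges$cosine >= params$min_cosine))
  expect_true(all(edges$n_matched >= params$min_matched_peaks))
  # single node -> no edges
  expect_equal(nrow(score_all_pairs(nodes[1], params)), 0L)
})

test_that("mutual top-k: triangle case and identity when k exceeds degrees", {
  tri <- data.frame(node_a = c("A", "B", "A"), node_b = c("B", "C", "C"),
                    cosine = c(0.9, 0.95, 0.8), n_matched = 6L, delta = 0,
                    stringsAsFactors = FALSE)
  out <- mutual_topk_filter(tri, k = 1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$node_a, "B")
  expect_equal(out$node_b, "C")
  # k >= all degrees -> identity
  expect_equal(mutual_topk_filter(tri, k = 10), tri)
})

test_that("mutual top-k equals the brute-force rank oracle on random graphs", {
  set.seed(52)
  for (rep in 1:15) {
    edges <- random_edge_table(sample(8:20, 1))
    if (nrow(edges) == 0) next
    for (k in c(1, 2, 3)) {
      got <- mutual_topk_filter(edges, k)
      want <- oracle_mutual_topk(edges, k)
      expect_equal(got, want)
    }
  }
})

test_that("family-size cap: hand-simulated path and identity cases", {
  path <- data.frame(node_a = c("A", "B", "C"), node_b = c("B", "C", "D"),
                     cosine = c(0.9, 0.71, 0.8), n_matched = 6L, delta = 0,
                     stringsAsFactors = FALSE)
  ids <- c("A", "B", "C", "D")
  out <- enforce_family_size_cap(path, ids, max_family_size = 3)
  expect_equal(nrow(out), 2L)
  expect_false(any(out$cosine == 0.71))   # middle (weakest) edge removed
  fam <- extract_families(out, ids)
  expect_equal(sort(unique(fam$family_size)), 2L)

  # already under the cap -> identity
  expect_equal(enforce_family_size_cap(path, ids, max_family_size = 10),
               path)
})

test_that("size cap equals the step-by-step reference on random graphs", {
  set.seed(53)
  for (rep in 1:12) {
    n <- sample(10:30, 1)
    edges <- random_edge_table(n, p = 0.25)
    ids <- sprintf("N%02d", seq_len(n))
    got <- enforce_family_size_cap(edges, ids, max_family_size = 5)
    want <- oracle_size_cap(edges, ids, cap = 5)
    expect_equal(got, want)
    memb <- oracle_components(ids, got)
    expect_true(all(table(memb) <= 5))
  }
})

test_that("families are connected components; counts and sizes conserved", {
  ids <- sprintf("N%d", 1:5)
  none <- data.frame(node_a = character(0), node_b = character(0),
                     cosine = numeric(0), n_matched = integer(0),
                     delta = numeric(0))
  fam <- extract_families(none, ids)
  expect_equal(nrow(fam), 5L)
  expect_true(all(fam$singleton))

  edges <- data.frame(node_a = c("N1", "N2", "N3"),
                      node_b = c("N2", "N3", "N4"),
                      cosine = 0.9, n_matched = 6L, delta = 0,
                      stringsAsFactors = FALSE)
  fam2 <- extract_families(edges, ids)
  expect_setequal(unique(fam2$family_size), c(4L, 1L))
  expect_equal(nrow(fam2), 5L)   # sum of sizes = node count

  set.seed(54)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    e <- random_edge_table(n, 0.2)
    f <- extract_families(e, sprintf("N%02d", seq_len(n)))
    expect_equal(nrow(f), n)
    sizes <- unique(f[, c("family_id", "family_size")])
    expect_equal(sum(sizes$family_size), n)
  }
})

test_that("network export round-trips node and edge counts through GraphML", {
  set.seed(55)
  nodes <- random_nodes(2)
  nodes[[2]] <- nodes[[1]]
  nodes[[2]]$spectrum_id <- "C999"
  for (cs in seq_along(nodes)) {
    nodes[[cs]]$members <- data.frame(spectrum_id = "x",
                                      source_file = "f.mgf")
    nodes[[cs]]$media_members <- table(factor("ISP2",
                                              levels = MEDIA_LEVELS))
    nodes[[cs]]$strain_set <- "S1"
    nodes[[cs]]$media_set <- "ISP2"
  }
  net <- build_network(nodes)
  expect_equal(nrow(net$edges), 1L)
  dir <- withr::local_tempdir()
  paths <- export_network(nodes, net, NULL, dir)
  g <- igraph::read_graph(paths["graphml"], format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  # media proportions sum to 1 per node
  expect_equal(igraph::V(g)$prop_ISP2, c(1, 1))
})

test_that("same-family consensus nodes predominantly land in one network family", {
  # end-to-end recovery on the synthetic study: ground-truth family pairs
  # that share enough fragments should end up in the same molecular family
  d <- study_design(n_strains = 6L, n_molecules = 20L, n_families = 6L,
                    blank_background_molecules = 0L, seed = 42L)
  dir <- withr::local_tempdir()
  man <- simulate_study(d, dir)
  params <- networking_params()
  metadata <- load_sample_table(man$metadata_path)
  spectra <- unlist(lapply(man$sample_files, read_mgf), recursive = FALSE)
  pre <- preprocess_spectra(spectra, params)
  cons <- remove_blank_clusters(cluster_spectra(pre, params), metadata)
  net <- build_network(cons, params)

  truth <- man$truth
  node_mol <- vapply(cons, function(c)
    truth$molecule_id[match(c$members$spectrum_id[1], truth$spectrum_id)],
    character(1))
  node_fam_truth <- vapply(cons, function(c)
    truth$family_id[match(c$members$spectrum_id[1], truth$spectrum_id)],
    character(1))
  node_fam_net <- net$families$family_id[
    match(vapply(cons, `[[`, "", "spectrum_id"), net$families$consensus_id)]

  # candidate pairs: same ground-truth family, >= 6 shared matched peaks
  same <- 0L; together <- 0L
  for (i in seq_along(cons)) for (j in seq_along(cons)) {
    if (i < j && node_fam_truth[i] == node_fam_truth[j] &&
        node_mol[i] != node_mol[j]) {
      mc <- modified_cosine(cons[[i]], cons[[j]], params$fragment_tol)
      if (mc$n_matched >= params$min_matched_peaks &&
          mc$score >= params$min_cosine) {
        same <- same + 1L
        if (node_fam_net[i] == node_fam_net[j]) together <- together + 1L
      }
    }
  }
  expect_gt(same, 10L)
  expect_gte(together / same, 0.8)
})
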