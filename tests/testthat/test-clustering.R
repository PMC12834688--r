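# Jittered copies of a template spectrum (ppm-level m/z error, small
# intensity wobble) emulating repeated acquisitions of the same ion.
jittered_copies <- function(template, n, ppm = 3, file_prefix = "f") {
  lapply(seq_len(n), function(i) {
    s <- template
    s$peaks[, 1] <- s$peaks[, 1] * (1 + rnorm(nrow(s$peaks), 0, ppm * 1e-6))
    s$peaks[, 2] <- s$peaks[, 2] * runif(nrow(s$peaks), 0.8, 1.2)
    s$precursor_mz <- s$precursor_mz * (1 + rnorm(1, 0, ppm * 1e-6))
    s$spectrum_id <- sprintf("%s%s:%03d", file_prefix, template$spectrum_id, i)
    s$source_file <- sprintf("%s%d.mgf", file_prefix, i)
    spectrum(s$precursor_mz, s$peaks, s$spectrum_id,
             source_file = s$source_file)
  })
}

test_that("identical spectra merge; distant precursors never do", {
  s <- spectrum(500, cbind(c(100, 200, 300), c(1, 2, 3)), "a",
                source_file = "f1.mgf")
  s2 <- s; s2$spectrum_id <- "b"; s2$source_file <- "f2.mgf"
  cons <- cluster_spectra(list(s, s2))
  expect_length(cons, 1L)
  expect_equal(nrow(cons[[1]]$members), 2L)

  t2 <- spectrum(500.05, cbind(c(100, 200, 300), c(1, 2, 3)), "c")
  cons2 <- cluster_spectra(list(s, t2))
  expect_length(cons2, 2L)
})

test_that("clustering partitions the input and is idempotent", {
  set.seed(31)
  templates <- lapply(1:8, function(i) {
    s <- random_spectrum(12); s$spectrum_id <- sprintf("T%d", i); s
  })
  spectra <- unlist(lapply(templates, jittered_copies, n = 6),
                    recursive = FALSE)
  cons <- cluster_spectra(spectra)
  expect_equal(sum(vapply(cons, function(c) nrow(c$members), integer(1))),
               length(spectra))
  expect_equal(anyDuplicated(unlist(lapply(cons, function(c)
    c$members$spectrum_id))), 0L)
  # clustering the consensus spectra again yields no further merging
  again <- cluster_spectra(cons)
  expect_length(again, length(cons))
})

test_that("greedy union equals the all-pairs single-linkage oracle", {
  set.seed(32)
  params <- networking_params()
  # 25 ground-truth ion forms, 10 jittered copies each = 250 spectra
  d <- study_design(n_strains = 2L, n_molecules = 10L, n_families = 3L,
                    seed = 33L)
  g <- generate_ground_truth(d)
  templates <- list()
  for (m in g) {
    sps <- render_ion_spectra(m, d, clean = TRUE)
    for (f in names(sps)) {
      sps[[f]]$spectrum_id <- paste0(m$molecule_id, ":", f)
      templates[[length(templates) + 1]] <- sps[[f]]
    }
  }
  templates <- templates[1:25]
  spectra <- unlist(lapply(templates, jittered_copies, n = 10),
                    recursive = FALSE)
  spectra <- preprocess_spectra(spectra, params)
  cons <- cluster_spectra(spectra, params)
  got <- sort_partition(cluster_membership(cons))
  want <- sort_partition(oracle_single_linkage_clusters(spectra, params))
  expect_equal(got, want)
  expect_length(cons, 25L)
})

test_that("lowering the cosine threshold never increases the cluster count", {
  set.seed(34)
  templates <- lapply(1:6, function(i) {
    s <- random_spectrum(15); s$spectrum_id <- sprintf("T%d", i); s
  })
  spectra <- unlist(lapply(templates, jittered_copies, n = 5, ppm = 8),
                    recursive = FALSE)
  n_prev <- Inf
  for (thr in c(0.95, 0.8, 0.6, 0.3)) {
    p <- networking_params(cluster_min_cosine = thr)
    n <- length(cluster_spectra(spectra, p))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("consensus peak building pools, groups and renormalizes", {
  m1 <- spectrum(500, cbind(100.00, 1), "a")
  m2 <- spectrum(500, cbind(100.01, 1), "b")
  cons <- build_consensus(list(m1, m2), fragment_tol = 0.02)
  expect_equal(unname(cons$peaks[, 1]), 100.005)
  expect_equal(unname(cons$peaks[, 2]), 1000)

  # single-member cluster: peaks rescaled only
  s <- spectrum(500, cbind(c(100, 200), c(2, 4)), "c")
  cons1 <- build_consensus(list(s))
  expect_equal(unname(cons1$peaks[, 2]), c(500, 1000))
  expect_equal(unname(cons1$peaks[, 1]), c(100, 200))
})

test_that("consensus grouping equals the O(n^2) tolerance-clustering oracle", {
  set.seed(35)
  for (rep in 1:15) {
    members <- lapply(1:4, function(i)
      spectrum(500, cbind(sort(runif(25, 100, 120)), runif(25, 0.5, 5)),
               sprintf("m%d", i)))
    cons <- build_consensus(members, fragment_tol = 0.02)
    pooled <- do.call(rbind, lapply(members, function(s) s$peaks))
    pooled <- pooled[order(pooled[, 1]), ]
    grp <- oracle_tolerance_groups(pooled[, 1], 0.02)
    want_mz <- as.numeric(tapply(pooled[, 1] * pooled[, 2], grp, sum) /
                            tapply(pooled[, 2], grp, sum))
    expect_equal(sort(unname(cons$peaks[, 1])), sort(want_mz))
  }
})

test_that("blank removal drops blank-touched consensus and audits cleanly", {
  d <- study_design(n_strains = 4L, n_molecules = 12L, n_families = 4L,
                    blank_background_molecules = 5L, seed = 41L)
  dir <- withr::local_tempdir()
  man <- simulate_study(d, dir)
  metadata <- load_sample_table(man$metadata_path)
  params <- networking_params()
  spectra <- unlist(lapply(c(man$sample_files, man$blank_files), read_mgf),
                    recursive = FALSE)
  pre <- preprocess_spectra(spectra, params)
  cons <- cluster_spectra(pre, params)
  kept <- remove_blank_clusters(cons, metadata)

  truth <- man$truth
  bg_ids <- truth$spectrum_id[truth$is_background]
  kept_members <- unlist(lapply(kept, function(c) c$members$spectrum_id))
  # no background-derived spectrum survives (background is in every sample
  # file of its media AND in the blank, so its clusters are blank-touched)
  expect_length(intersect(kept_members, bg_ids), 0L)

  # true-molecule consensus retention
  true_cons <- vapply(cons, function(c)
    !any(c$members$spectrum_id %in% bg_ids), logical(1))
  expect_gte(sum(vapply(kept, function(c)
    !any(c$members$spectrum_id %in% bg_ids), logical(1))) /
      max(sum(true_cons), 1), 0.99)

  # metadata gap is an error naming the file
  bad_meta <- metadata[metadata$filename != "S001_ISP2.mgf", ]
  expect_error(remove_blank_clusters(cons, bad_meta), "S001_ISP2.mgf")

  # consensus with members only from blanks -> removed; 0 blank members -> kept
  expect_true(all(vapply(kept, function(c) c$blank_member_count == 0,
                         logical(1))))
})
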