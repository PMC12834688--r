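mock_consensus <- function(id, strains, media, n_members = 1L) {
  s <- spectrum(500, cbind(100, 1), id)
  s$members <- data.frame(spectrum_id = sprintf("%s:%d", id,
                                                seq_len(n_members)),
                          source_file = "f.mgf")
  s$strain_set <- strains
  s$media_set <- media
  s$media_members <- table(factor(media, levels = MEDIA_LEVELS))
  class(s) <- c("consensus_spectrum", "spectrum")
  s
}

test_that("incidence matrix follows strain provenance and the family union rule", {
  units <- c("S1", "S2", "S3")
  M <- build_incidence(list(a = c("S1", "S3")), units)
  expect_equal(unname(M[1, ]), c(TRUE, FALSE, TRUE))

  cons <- list(mock_consensus("C1", "S1", "ISP2"),
               mock_consensus("C2", "S2", "TSA"))
  fam <- data.frame(family_id = "FAM0001", consensus_id = c("C1", "C2"),
                    family_size = 2L, singleton = FALSE,
                    stringsAsFactors = FALSE)
  Mf <- incidence_from_families(fam, cons, units)
  expect_equal(unname(Mf[1, ]), c(TRUE, TRUE, FALSE))

  expect_error(build_incidence(list(a = "S9"), units), "unknown strain")

  # column sums = per-strain item counts (brute-force recount)
  set.seed(71)
  items <- lapply(1:30, function(i) sample(units, sample(1:3, 1)))
  names(items) <- sprintf("I%02d", 1:30)
  M2 <- build_incidence(items, units)
  for (u in units) {
    expect_equal(sum(M2[, u]),
                 sum(vapply(items, function(s) u %in% s, logical(1))))
  }
})

test_that("rarefaction saturates immediately for identical units and is trivially exact for one unit", {
  M <- matrix(TRUE, nrow = 2, ncol = 3,
              dimnames = list(c("a", "b"), c("S1", "S2", "S3")))
  cv <- rarefaction_curve(M, n_permutations = 10, seed = 1)
  expect_equal(cv$mean, c(2, 2, 2))
  expect_equal(cv$sd, c(0, 0, 0))
  expect_equal(cv$expected, c(2, 2, 2))

  M1 <- matrix(TRUE, nrow = 7, ncol = 1)
  expect_equal(rarefaction_curve(M1, 5, 1)$mean, 7)
  expect_error(rarefaction_curve(M1[0, , drop = FALSE], 5, 1), "empty")
})

test_that("closed form matches the frozen 3-unit example and exhaustive enumeration", {
  # items present in 1, 2 and 3 of N = 3 units: E[S(1)] = 1/3 + 2/3 + 1 = 2
  M <- rbind(a = c(TRUE, FALSE, FALSE),
             b = c(TRUE, TRUE, FALSE),
             c = c(TRUE, TRUE, TRUE))
  colnames(M) <- c("S1", "S2", "S3")
  ex <- expected_rarefaction(M)
  expect_equal(ex[1], 2.0)
  expect_equal(ex[3], 3.0)
  expect_equal(oracle_rarefaction_exhaustive(M), ex, tolerance = 1e-12)

  set.seed(72)
  for (rep in 1:10) {
    N <- sample(2:5, 1)
    M <- matrix(runif(8 * N) < 0.5, nrow = 8, ncol = N)
    M <- M[rowSums(M) > 0, , drop = FALSE]
    if (nrow(M) == 0) next
    expect_equal(oracle_rarefaction_exhaustive(M), expected_rarefaction(M),
                 tolerance = 1e-12)
  }
})

test_that("permutation curves are monotone, conserve totals, track the closed form", {
  set.seed(73)
  M <- matrix(runif(50 * 12) < 0.25, nrow = 50, ncol = 12,
              dimnames = list(NULL, sprintf("S%02d", 1:12)))
  M <- M[rowSums(M) > 0, , drop = FALSE]
  cv <- rarefaction_curve(M, n_permutations = 200, seed = 9)
  expect_true(all(diff(cv$mean) >= 0))
  expect_equal(cv$mean[12], nrow(M))       # conservation at k = N
  expect_equal(cv$expected[12], nrow(M))
  expect_lt(max(abs(cv$mean - cv$expected)), 1.0)  # permutation mean ~ E[S(k)]
  # determinism in the seed
  cv2 <- rarefaction_curve(M, n_permutations = 200, seed = 9)
  expect_identical(cv, cv2)
})

test_that("stratified curves add up: annotated + unannotated = all at every k", {
  set.seed(74)
  units <- sprintf("S%d", 1:6)
  cons <- lapply(1:40, function(i)
    mock_consensus(sprintf("C%05d", i), sample(units, sample(1:3, 1)),
                   sample(MEDIA_LEVELS, 1)))
  fam <- data.frame(family_id = sprintf("FAM%04d", sample(1:10, 40, TRUE)),
                    consensus_id = sprintf("C%05d", 1:40),
                    family_size = 1L, singleton = FALSE,
                    stringsAsFactors = FALSE)
  ann <- data.frame(consensus_id = sample(sprintf("C%05d", 1:40), 12),
                    entry_id = "L", compound_name = "X",
                    pathway = "Terpenoids", cosine = 0.8, n_matched = 7L,
                    precursor_delta = 0, mode = "exact",
                    stringsAsFactors = FALSE)
  rc <- rarefaction_by_stratum(cons, fam, ann, units,
                               n_permutations = 50, seed = 4)
  for (lev in c("spectra", "families")) {
    all_c <- rc$mean[rc$stratum == "all" & rc$level == lev]
    a <- rc$mean[rc$stratum == "annotated" & rc$level == lev]
    u <- rc$mean[rc$stratum == "unannotated" & rc$level == lev]
    expect_equal(a + u, all_c, tolerance = 1e-12)
  }
})

test_that("media overlap counts partition items; set sizes recount correctly", {
  cons <- list(
    mock_consensus("C1", "S1", "ISP2"),
    mock_consensus("C2", "S1", "ISP2"),
    mock_consensus("C3", "S1", c("ISP2", "TSA")),
    mock_consensus("C4", "S1", MEDIA_LEVELS))
  ov <- media_overlap_counts(cons)
  expect_equal(ov$exclusive$count[ov$exclusive$combination == "ISP2"], 2L)
  expect_equal(ov$exclusive$count[ov$exclusive$combination == "ISP2+TSA"], 1L)
  all5 <- paste(sort(MEDIA_LEVELS), collapse = "+")
  expect_equal(ov$exclusive$count[ov$exclusive$combination == all5], 1L)
  expect_equal(sum(ov$exclusive$count), 4L)   # partition of the item set
  expect_equal(ov$set_sizes$size[ov$set_sizes$media == "ISP2"], 4L)
  expect_equal(ov$set_sizes$size[ov$set_sizes$media == "TSA"], 2L)

  expect_error(media_overlap_counts(list(mock_consensus("C9", "S1",
                                                        character(0)))),
               "empty media set")

  # random partition identity + brute-force recount
  set.seed(75)
  cons2 <- lapply(1:60, function(i)
    mock_consensus(sprintf("D%02d", i), "S1",
                   sample(MEDIA_LEVELS, sample(1:5, 1))))
  ov2 <- media_overlap_counts(cons2)
  expect_equal(sum(ov2$exclusive$count), 60L)
  for (m in MEDIA_LEVELS) {
    want <- sum(vapply(cons2, function(c) m %in% c$media_set, logical(1)))
    got <- ov2$set_sizes$size[ov2$set_sizes$media == m]
    expect_equal(got, want)
  }
})

test_that("annotation-rate summary reports both denominators and family splits", {
  cons <- lapply(1:100, function(i)
    mock_consensus(sprintf("C%05d", i), "S1", "ISP2", n_members = 2L))
  fam <- data.frame(family_id = sprintf("FAM%04d", rep(1:20, each = 5)),
                    consensus_id = sprintf("C%05d", 1:100),
                    family_size = 5L, singleton = FALSE,
                    stringsAsFactors = FALSE)
  ann <- data.frame(consensus_id = sprintf("C%05d", 1:13), entry_id = "L",
                    compound_name = "X", pathway = "Terpenoids",
                    cosine = 0.8, n_matched = 7L, precursor_delta = 0,
                    mode = "exact", stringsAsFactors = FALSE)
  s <- annotation_rate_summary(200, cons, ann, fam)
  expect_equal(s$rate_consensus, 0.13)
  expect_equal(s$n_annotated_raw_spectra, 26)
  expect_equal(s$rate_raw, 0.13)
  expect_equal(s$n_annotated_families + s$n_unannotated_families,
               s$n_families)

  # zero annotations
  s0 <- annotation_rate_summary(200, cons, ann[0, ], fam)
  expect_equal(s0$rate_consensus, 0)
  expect_equal(s0$n_annotated_families, 0L)
})

test_that("pathway-by-media matrix normalizes each row to its maximum", {
  cons <- c(lapply(1:10, function(i)
    mock_consensus(sprintf("C1%02d", i), "S1", "ISP2")),
    lapply(1:5, function(i) mock_consensus(sprintf("C2%02d", i), "S1", "TSA")))
  ann <- data.frame(consensus_id = vapply(cons, `[[`, "", "spectrum_id"),
                    entry_id = "L", compound_name = "X",
                    pathway = "Terpenoids", cosine = 0.8, n_matched = 7L,
                    precursor_delta = 0, mode = "exact",
                    stringsAsFactors = FALSE)
  pm <- pathway_media_matrix(cons, ann)
  expect_equal(nrow(pm), 1L)
  expect_equal(pm["Terpenoids", "ISP2"], 1.0)
  expect_equal(pm["Terpenoids", "TSA"], 0.5)
  expect_true(all(apply(pm, 1, max) == 1))

  # brute-force group-count-normalize on a random annotations table
  set.seed(76)
  cons3 <- lapply(1:50, function(i)
    mock_consensus(sprintf("C%05d", i), "S1",
                   sample(MEDIA_LEVELS, sample(1:3, 1))))
  ann3 <- data.frame(
    consensus_id = vapply(cons3, `[[`, "", "spectrum_id"), entry_id = "L",
    compound_name = "X", pathway = sample(PATHWAY_LEVELS, 50, TRUE),
    cosine = 0.8, n_matched = 7L, precursor_delta = 0, mode = "exact",
    stringsAsFactors = FALSE)
  pm3 <- pathway_media_matrix(cons3, ann3)
  for (p in rownames(pm3)) {
    raw <- vapply(MEDIA_LEVELS, function(m) {
      sum(vapply(seq_along(cons3), function(i)
        ann3$pathway[i] == p && m %in% cons3[[i]]$media_set, logical(1)))
    }, numeric(1))
    expect_equal(unname(pm3[p, ]), unname(raw / max(raw)))
  }
})
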