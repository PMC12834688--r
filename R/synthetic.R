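# Run code under a temporary RNG state so generators are pure in their seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Mass offsets between structural-family members: common biochemical deltas
# (CH2, H2O, C2H2, C2H4, acetyl, glycine residue, alanine residue).
FAMILY_MASS_DELTAS <- c(14.01565, 18.01056, 26.01565, 28.03130,
                        42.01057, 57.02146, 71.03711)

#' Describe a synthetic strains-by-media study
#'
#' Collects every knob of the synthetic-data generator. The defaults define
#' the demo study used throughout: 20 strains cultured on all five media, 60
#' ground-truth molecules grouped into 15 structural families, roughly three
#' ion forms per molecule, a reference library covering 13% of the
#' molecules, 5 ppm mass error, Poisson(3) noise peaks per spectrum, and 8
#' medium-background molecules observed in blanks and samples alike.
#'
#' @param n_strains Number of strains.
#' @param media Character subset of [MEDIA_LEVELS].
#' @param n_molecules,n_families Ground-truth molecule and family counts
#'   (`n_families <= n_molecules`).
#' @param ion_form_distribution Named probabilities over the four ion forms
#'   `mh` (\[M+H\]+), `na` (\[M+Na\]+), `m2` (\[2M+H\]+) and `insrc`
#'   (in-source fragment); must sum to 1. The \[M+H\]+ form is always
#'   emitted; the other forms are attached to a molecule independently with
#'   probabilities proportional to these weights, scaled so the expected
#'   number of forms per molecule is `mean_ion_forms`.
#' @param mean_ion_forms Expected ion forms per molecule (default 3).
#' @param library_fraction Fraction of molecules present in the reference
#'   library (default 0.13).
#' @param noise_peaks_lambda Poisson rate of spurious peaks per spectrum.
#' @param mz_error_ppm Gaussian m/z error (ppm, 1 sd) applied to fragment
#'   and precursor masses at emission.
#' @param blank_background_molecules Number of medium-background molecules.
#' @param seed Integer seed; everything the generator emits is a pure
#'   function of the design including this seed.
#' @return A list of class `"study_design"`.
#' @export
study_design <- function(n_strains = 20L,
                         media = MEDIA_LEVELS,
                         n_molecules = 60L,
                         n_families = 15L,
                         ion_form_distribution = c(mh = 0.40, na = 0.25,
                                                   m2 = 0.15, insrc = 0.20),
                         mean_ion_forms = 3,
                         library_fraction = 0.13,
                         noise_peaks_lambda = 3,
                         mz_error_ppm = 5,
                         blank_background_molecules = 8L,
                         seed = 42L) {
  media <- as.character(unlist(media))
  ion_form_distribution <- unlist(ion_form_distribution)
  stopifnot(n_strains >= 1L, n_molecules >= 1L,
            all(media %in% MEDIA_LEVELS), length(media) >= 1L,
            library_fraction >= 0, library_fraction <= 1,
            mean_ion_forms >= 1, noise_peaks_lambda >= 0, mz_error_ppm >= 0)
  if (n_families > n_molecules) {
    stop("n_families must not exceed n_molecules")
  }
  if (!setequal(names(ion_form_distribution), c("mh", "na", "m2", "insrc")) ||
      abs(sum(ion_form_distribution) - 1) > 1e-8) {
    stop("ion_form_distribution must be named probabilities over ",
         "mh/na/m2/insrc summing to 1")
  }
  structure(list(
    n_strains = as.integer(n_strains), media = media,
    n_molecules = as.integer(n_molecules), n_families = as.integer(n_families),
    ion_form_distribution = ion_form_distribution,
    mean_ion_forms = mean_ion_forms,
    library_fraction = library_fraction,
    noise_peaks_lambda = noise_peaks_lambda,
    mz_error_ppm = mz_error_ppm,
    blank_background_molecules = as.integer(blank_background_molecules),
    seed = as.integer(seed)
  ), class = "study_design")
}

#' Generate the ground-truth molecules of a synthetic study
#'
#' Molecules are organized into near-equal-size structural families. Each
#' family has a base molecule (monoisotopic mass uniform on 200-1600 Da,
#' 8-40 fragment ions with log-normal intensities); further members carry
#' distinct cumulative mass offsets drawn from common biochemical deltas
#' (CH2, H2O, glycine residue, ...) applied to the precursor and to a suffix
#' of the m/z-sorted fragments — emulating a modification site partway along
#' a fragment series — so that family members remain connectable by the
#' modified cosine. Exactly `round(library_fraction * n_molecules)` molecules
#' are flagged as library members. Media-dependent production is encoded as
#' a per-molecule Bernoulli probability per medium (a random ~70% subset of
#' the media is productive with probability uniform on 0.4-0.9; the rest
#' never produce).
#'
#' @param design A [study_design()].
#' @return A list of ground-truth molecule records (fields: `molecule_id`,
#'   `family_id`, `monoisotopic_mass`, `base_fragments` (mz/intensity
#'   matrix), `shifted_from` (index of the first offset-shifted fragment, NA
#'   if none), `pathway`, `in_library`, `media_production_prob`,
#'   `ion_forms`, `insrc_fragment`).
#' @export
generate_ground_truth <- function(design) {
  stopifnot(inherits(design, "study_design"))
  with_seed(design$seed, generate_ground_truth_impl(design))
}

generate_ground_truth_impl <- function(design) {
  n <- design$n_molecules
  fam_of <- sort(rep_len(seq_len(design$n_families), n))
  in_lib <- rep(FALSE, n)
  in_lib[sample.int(n, round(design$library_fraction * n))] <- TRUE

  pf <- design$ion_form_distribution
  extra_p <- pmin(1, (design$mean_ion_forms - 1) * pf[c("na", "m2", "insrc")] /
                       sum(pf[c("na", "m2", "insrc")]))

  molecules <- vector("list", n)
  idx <- 0L
  for (f in seq_len(design$n_families)) {
    members <- which(fam_of == f)
    base_mass <- runif(1, 200, 1600)
    n_frag <- sample(8:40, 1L)
    frag_mz <- sort(runif(n_frag, 50, base_mass - 20))
    frag_int <- rlnorm(n_frag, 0, 1)
    pathway <- sample(PATHWAY_LEVELS, 1L)
    offset <- 0
    for (k in seq_along(members)) {
      idx <- idx + 1L
      if (k > 1L) offset <- offset + sample(FAMILY_MASS_DELTAS, 1L)
      mass <- base_mass + offset
      mz <- frag_mz
      shifted_from <- NA_integer_
      if (k > 1L) {
        # shift a suffix of the fragment series by the cumulative offset
        shifted_from <- sample(ceiling(n_frag * 0.5):n_frag, 1L)
        mz[shifted_from:n_frag] <- mz[shifted_from:n_frag] + offset
      }
      int <- frag_int * rlnorm(n_frag, 0, 0.3)  # member-specific abundances
      prod_media <- runif(length(design$media)) < 0.7
      if (!any(prod_media)) prod_media[sample.int(length(design$media), 1L)] <- TRUE
      prob <- ifelse(prod_media, runif(length(design$media), 0.4, 0.9), 0)
      names(prob) <- design$media

      forms <- c("mh",
                 c("na", "m2", "insrc")[runif(3) < extra_p])
      # in-source fragment form needs a high fragment with >= 6 sub-peaks
      # clear of its own precursor region
      insrc_frag <- NA_integer_
      if ("insrc" %in% forms) {
        viable <- which(vapply(seq_len(n_frag), function(i)
          sum(mz < mz[i] - 17) >= 8L, logical(1)))
        if (length(viable) == 0L) {
          forms <- setdiff(forms, "insrc")
        } else {
          insrc_frag <- viable[which.max(mz[viable])]
        }
      }
      molecules[[idx]] <- list(
        molecule_id = sprintf("M%03d", idx),
        family_id = sprintf("F%02d", f),
        monoisotopic_mass = mass,
        base_fragments = cbind(mz = mz, intensity = int),
        shifted_from = shifted_from,
        pathway = pathway,
        in_library = in_lib[idx],
        media_production_prob = prob,
        ion_forms = forms,
        insrc_fragment = insrc_frag
      )
    }
  }
  molecules
}

ION_FORM_LABELS <- c(mh = "[M+H]+", na = "[M+Na]+", m2 = "[2M+H]+",
                     insrc = "in-source fragment")

ion_form_precursor <- function(mol, form) {
  switch(form,
         mh = mol$monoisotopic_mass + PROTON_MASS,
         na = mol$monoisotopic_mass + SODIUM_ION_MASS,
         m2 = 2 * mol$monoisotopic_mass + PROTON_MASS,
         insrc = mol$base_fragments[mol$insrc_fragment, 1L],
         stop("unknown ion form: ", form))
}

#' Render the MS/MS spectra of one molecule's ion forms
#'
#' Emits one spectrum per ion form carried by the molecule. The \[M+H\]+,
#' \[M+Na\]+ and \[2M+H\]+ forms share the molecule's fragment ions (sodiated
#' and dimeric precursors still fragmenting to protonated monomer ions); the
#' in-source-fragment form promotes one high-mass fragment to precursor and
#' keeps only the fragments below it. Fragment and precursor m/z are
#' jittered with Gaussian ppm error and Poisson-many uniform noise peaks at
#' 1-5% relative intensity are added, unless `clean = TRUE`.
#'
#' @param mol One record from [generate_ground_truth()].
#' @param design The [study_design()].
#' @param clean If TRUE, no m/z jitter and no noise peaks (library and
#'   truth-side rendering).
#' @param forms Ion forms to render (default: the molecule's own).
#' @param id_prefix Prefix for spectrum ids.
#' @return List of [spectrum()] objects with names equal to the ion forms.
#' @export
render_ion_spectra <- function(mol, design, clean = FALSE,
                               forms = mol$ion_forms, id_prefix = "") {
  out <- lapply(forms, function(form) {
    prec <- ion_form_precursor(mol, form)
    pk <- mol$base_fragments
    if (form == "insrc") {
      pk <- pk[pk[, 1L] <= pk[mol$insrc_fragment, 1L], , drop = FALSE]
    }
    mz <- pk[, 1L]; int <- pk[, 2L]
    if (!clean) {
      ppm <- design$mz_error_ppm * 1e-6
      mz <- mz * (1 + rnorm(length(mz), 0, ppm))
      prec <- prec * (1 + rnorm(1, 0, ppm))
      n_noise <- rpois(1, design$noise_peaks_lambda)
      if (n_noise > 0L) {
        mz <- c(mz, runif(n_noise, 50, prec))
        int <- c(int, runif(n_noise, 0.01, 0.05) * max(int))
      }
    }
    spectrum(precursor_mz = prec, peaks = cbind(mz, int),
             spectrum_id = paste0(id_prefix, mol$molecule_id, ":", form),
             retention_time = if (clean) NA_real_ else runif(1, 30, 600))
  })
  names(out) <- forms
  out
}

# Background (culture-medium) molecules: simple spectra, one medium each.
generate_background <- function(design) {
  n <- design$blank_background_molecules
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) {
    mass <- runif(1, 150, 800)
    n_frag <- sample(8:15, 1L)
    list(
      molecule_id = sprintf("BG%02d", i),
      family_id = sprintf("BGF%02d", i),
      monoisotopic_mass = mass,
      base_fragments = cbind(mz = sort(runif(n_frag, 50, mass - 20)),
                             intensity = rlnorm(n_frag, 0, 1)),
      shifted_from = NA_integer_,
      pathway = NA_character_,
      in_library = FALSE,
      media = design$media[((i - 1L) %% length(design$media)) + 1L],
      ion_forms = "mh",
      insrc_fragment = NA_integer_
    )
  })
}

#' Simulate a complete synthetic study on disk
#'
#' Writes one MGF per strain x medium (a molecule appears in a file iff an
#' independent Bernoulli draw with its per-medium production probability
#' succeeds, contributing one spectrum per ion form), one blank MGF per
#' medium carrying that medium's background molecules, the sample metadata
#' TSV, the reference library MGF (clean \[M+H\]+ spectra of the library
#' molecules with NAME/PATHWAY headers) and truth tables mapping every
#' emitted spectrum to its molecule, family, ion form, strain and medium.
#' Background molecules also appear in every sample file of their medium, as
#' medium components do. Fully reproducible from `design$seed`.
#'
#' @param design A [study_design()].
#' @param out_dir Output directory (created if needed).
#' @return A manifest list: `sample_files`, `blank_files`, `metadata_path`,
#'   `library_path`, `truth_path`, `molecules_path`, `truth` (data frame),
#'   `molecules` (ground-truth list), `design`.
#' @export
simulate_study <- function(design, out_dir) {
  stopifnot(inherits(design, "study_design"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  molecules <- generate_ground_truth(design)
  with_seed(design$seed + 1L, {
    background <- generate_background(design)
    bg_by_media <- split(background,
                         vapply(background, `[[`, "", "media"))

    strains <- sprintf("S%03d", seq_len(design$n_strains))
    truth <- list()
    meta <- list()
    sample_files <- character(0)

    emit_file <- function(stem, mols, strain, media, is_background) {
      spectra <- list()
      rows <- list()
      scan <- 0L
      for (m in seq_along(mols)) {
        mol <- mols[[m]]
        sps <- render_ion_spectra(mol, design,
                                  id_prefix = paste0(stem, ":"))
        for (form in names(sps)) {
          scan <- scan + 1L
          s <- sps[[form]]
          s$spectrum_id <- sprintf("%s:scan%04d", stem, scan)
          s$scan_index <- scan - 1L
          s$source_file <- paste0(stem, ".mgf")
          spectra[[scan]] <- s
          rows[[scan]] <- data.frame(
            spectrum_id = s$spectrum_id, molecule_id = mol$molecule_id,
            family_id = mol$family_id, ion_form = form,
            strain = strain, media = media,
            is_background = is_background[m],
            source_file = s$source_file, stringsAsFactors = FALSE)
        }
      }
      path <- file.path(out_dir, paste0(stem, ".mgf"))
      write_mgf(spectra, path)
      truth[[length(truth) + 1L]] <<- if (length(rows)) do.call(rbind, rows)
      path
    }

    for (st in strains) {
      for (md in design$media) {
        present <- vapply(molecules, function(mol)
          runif(1) < mol$media_production_prob[[md]], logical(1))
        mols <- c(molecules[present], bg_by_media[[md]])
        is_bg <- c(rep(FALSE, sum(present)),
                   rep(TRUE, length(bg_by_media[[md]])))
        stem <- paste0(st, "_", md)
        p <- emit_file(stem, mols, st, md, is_bg)
        sample_files <- c(sample_files, p)
        meta[[length(meta) + 1L]] <- data.frame(
          filename = basename(p), strain_id = st, genus = "Streptomyces",
          media = md, sample_type = "sample", stringsAsFactors = FALSE)
      }
    }
    blank_files <- character(0)
    for (md in design$media) {
      stem <- paste0("blank_", md)
      p <- emit_file(stem, bg_by_media[[md]], "blank", md,
                     rep(TRUE, length(bg_by_media[[md]])))
      blank_files <- c(blank_files, p)
      meta[[length(meta) + 1L]] <- data.frame(
        filename = basename(p), strain_id = "blank", genus = "",
        media = md, sample_type = "blank", stringsAsFactors = FALSE)
    }

    truth <- do.call(rbind, truth)
    meta <- do.call(rbind, meta)

    metadata_path <- file.path(out_dir, "metadata.tsv")
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth_path <- file.path(out_dir, "truth.tsv")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    lib <- lapply(Filter(function(m) m$in_library, molecules), function(mol) {
      s <- render_ion_spectra(mol, design, clean = TRUE, forms = "mh")[[1]]
      s$spectrum_id <- paste0("LIB_", mol$molecule_id)
      s$name <- paste("Compound", mol$molecule_id)
      s$pathway <- mol$pathway
      s
    })
    library_path <- file.path(out_dir, "library.mgf")
    write_mgf(lib, library_path)

    mol_tab <- do.call(rbind, lapply(molecules, function(m) data.frame(
      molecule_id = m$molecule_id, family_id = m$family_id,
      monoisotopic_mass = m$monoisotopic_mass, pathway = m$pathway,
      in_library = m$in_library,
      ion_forms = paste(m$ion_forms, collapse = ","),
      stringsAsFactors = FALSE)))
    molecules_path <- file.path(out_dir, "molecules.tsv")
    utils::write.table(mol_tab, molecules_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    list(sample_files = sample_files, blank_files = blank_files,
         metadata_path = metadata_path, library_path = library_path,
         truth_path = truth_path, molecules_path = molecules_path,
         truth = truth, molecules = molecules, design = design)
  })
}

#' Truth-side annotatable fraction
#'
#' The noise-free reference value for annotation-recovery checks: every
#' (molecule, ion form) pair of the ground truth is rendered without jitter
#' or noise, preprocessed with the standard filters, and searched against
#' the clean library spectra with the pipeline's own thresholds — exactly
#' (precursor within `precursor_tol`) or as an analog (precursor delta up to
#' `analog_max_delta`). The fraction of pairs that find a hit is what a
#' perfect pipeline run on noiseless data would annotate.
#'
#' @param molecules Output of [generate_ground_truth()].
#' @param design The [study_design()].
#' @param params [networking_params()].
#' @return A list: `table` (molecule_id, ion_form, mode) and `fraction`.
#' @export
truth_annotatable <- function(molecules, design,
                              params = networking_params()) {
  lib_mols <- Filter(function(m) m$in_library, molecules)
  lib <- lapply(lib_mols, function(mol)
    render_ion_spectra(mol, design, clean = TRUE, forms = "mh")[[1]])
  lib <- preprocess_spectra(lib, params)
  lib_prec <- vapply(lib, function(s) s$precursor_mz, numeric(1))

  rows <- list()
  for (mol in molecules) {
    sps <- render_ion_spectra(mol, design, clean = TRUE)
    for (form in names(sps)) {
      q <- preprocess_spectra(sps[form], params)
      mode <- NA_character_
      if (length(q) == 1L && length(lib) > 0L) {
        q <- q[[1L]]
        deltas <- abs(lib_prec - q$precursor_mz)
        hit <- function(cands) {
          for (i in cands) {
            mc <- modified_cosine(lib[[i]], q, params$fragment_tol)
            if (mc$score >= params$library_min_cosine &&
                mc$n_matched >= params$library_min_matched) return(TRUE)
          }
          FALSE
        }
        if (hit(which(deltas <= params$precursor_tol))) {
          mode <- "exact"
        } else if (hit(which(deltas > params$precursor_tol &
                             deltas <= params$analog_max_delta))) {
          mode <- "analog"
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = mol$molecule_id, ion_form = form, mode = mode,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab, fraction = mean(!is.na(tab$mode)))
}
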