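#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `simulate` (a [study_design()] to generate the study) or
#' `input` (paths to existing data: `spectra_dir` with sample/blank MGFs,
#' `metadata`, `library`) must be given.
#'
#' @param out_dir Output directory for all stage products.
#' @param simulate Optional [study_design()].
#' @param input Optional list with `spectra_dir`, `metadata`, `library`.
#' @param params [networking_params()] (thresholds for every stage).
#' @param seed Integer seed for the stochastic stages (rarefaction
#'   permutations; also the generator seed when `simulate` carries none).
#' @param n_permutations Rarefaction permutations (default 50).
#' @param max_blank_fraction Blank-membership tolerance (default 0, strict).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, input = NULL,
                            params = networking_params(), seed = 1L,
                            n_permutations = 50L, max_blank_fraction = 0) {
  if (is.null(simulate) == is.null(input)) {
    stop("exactly one of 'simulate' or 'input' must be provided")
  }
  if (!is.null(simulate) && !inherits(simulate, "study_design")) {
    stop("'simulate' must be a study_design()")
  }
  if (!is.null(input)) {
    need <- c("spectra_dir", "metadata", "library")
    missing <- setdiff(need, names(input))
    if (length(missing) > 0L) {
      stop("input block lacks: ", paste(missing, collapse = ", "))
    }
    absent <- !vapply(unlist(input[need]), file.exists, logical(1))
    if (any(absent)) {
      stop("input path(s) do not exist: ",
           paste(unlist(input[need])[absent], collapse = ", "))
    }
  }
  structure(list(out_dir = out_dir, simulate = simulate, input = input,
                 params = params, seed = as.integer(seed),
                 n_permutations = as.integer(n_permutations),
                 max_blank_fraction = max_blank_fraction),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys: `out_dir`, `seed`, `n_permutations`,
#' `max_blank_fraction`, a `params` mapping of [networking_params()]
#' overrides, and exactly one of a `simulate` mapping ([study_design()]
#' fields) or an `input` mapping (`spectra_dir`, `metadata`, `library`).
#'
#' @param path YAML file path.
#' @return A validated [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate) && !is.null(y$input)) {
    stop("config must not contain both 'simulate' and 'input' blocks")
  }
  params <- do.call(networking_params, if (is.null(y$params)) list()
                    else y$params)
  simulate <- if (!is.null(y$simulate)) do.call(study_design, y$simulate)
  pipeline_config(
    out_dir = y$out_dir %||% ".",
    simulate = simulate, input = y$input, params = params,
    seed = y$seed %||% 1L,
    n_permutations = y$n_permutations %||% 50L,
    max_blank_fraction = y$max_blank_fraction %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run the full molecular-networking pipeline
#'
#' Stage order: (simulate ->) read -> blank-derived exclusion -> preprocess
#' -> consensus clustering -> blank-cluster removal -> networking (edge
#' scoring, mutual top-K, family-size cap) -> library annotation (exact,
#' then analog) -> discovery statistics. All tabular products, the network
#' GraphML, a summary JSON and a run manifest (parameters, seed, file
#' checksums) are written under `config$out_dir`. Reruns with an identical
#' config reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage products: `consensus`,
#'   `network`, `annotations`, `family_annotations`, `summary`,
#'   `rarefaction`, `overlap`, `pathway_matrix`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  params <- config$params
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    pipeline_log("simulating study (seed ", config$simulate$seed, ")")
    data_dir <- file.path(out_dir, "data")
    man <- simulate_study(config$simulate, data_dir)
    metadata_path <- man$metadata_path
    library_path <- man$library_path
    spectra_dir <- data_dir
  } else {
    metadata_path <- config$input$metadata
    library_path <- config$input$library
    spectra_dir <- config$input$spectra_dir
  }

  metadata <- load_sample_table(metadata_path)
  read_files <- function(rows) {
    unlist(lapply(rows, function(f) {
      p <- file.path(spectra_dir, f)
      if (!file.exists(p)) stop("spectra file missing: ", p)
      read_mgf(p)
    }), recursive = FALSE)
  }
  sample_rows <- metadata$filename[metadata$sample_type == "sample"]
  blank_rows <- metadata$filename[metadata$sample_type == "blank"]
  pipeline_log("reading ", length(sample_rows), " sample and ",
               length(blank_rows), " blank file(s)")
  sample_spectra <- read_files(sample_rows)
  blank_spectra <- read_files(blank_rows)
  n_raw <- length(sample_spectra)

  exclusion <- build_exclusion_list(blank_spectra, params$exclusion_mz_tol)
  sample_spectra <- apply_exclusion_list(sample_spectra, exclusion,
                                         params$exclusion_mz_tol)
  pipeline_log(length(exclusion), " exclusion entries; ",
               n_raw - length(sample_spectra), " sample spectra excluded")

  pre <- preprocess_spectra(c(sample_spectra, blank_spectra), params)
  pipeline_log("clustering ", length(pre), " preprocessed spectra")
  consensus <- cluster_spectra(pre, params)
  n_consensus_all <- length(consensus)
  consensus <- remove_blank_clusters(consensus, metadata,
                                     config$max_blank_fraction)
  pipeline_log(n_consensus_all, " consensus spectra; ",
               n_consensus_all - length(consensus), " removed via blanks")

  network <- build_network(consensus, params)
  pipeline_log(nrow(network$edges), " network edges, ",
               length(unique(network$families$family_id)), " families")

  library <- read_library(library_path, params)
  exact <- exact_library_search(consensus, library, params)
  analog <- analog_library_search(consensus, library, params, exact)
  annotations <- rbind(exact, analog)
  pipeline_log(nrow(exact), " exact + ", nrow(analog), " analog annotations")

  family_annotations <- propagate_family_annotations(network$families,
                                                     annotations)
  units <- sort(unique(unlist(lapply(consensus, `[[`, "strain_set"))))
  rarefaction <- rarefaction_by_stratum(consensus, network$families,
                                        annotations, units,
                                        config$n_permutations, config$seed)
  overlap <- media_overlap_counts(consensus)
  pmat <- pathway_media_matrix(consensus, annotations)
  summary <- annotation_rate_summary(n_raw, consensus, annotations,
                                     network$families)
  summary$n_strain_units <- length(units)
  summary$n_edges <- nrow(network$edges)

  # ---- outputs -------------------------------------------------------
  paths <- character(0)
  wt <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  paths["consensus.mgf"] <- write_mgf(consensus,
                                      file.path(out_dir, "consensus.mgf"))
  paths["clusterinfo.tsv"] <- write_cluster_info(
    consensus, file.path(out_dir, "clusterinfo.tsv"))
  net_paths <- export_network(consensus, network, annotations, out_dir)
  paths[basename(net_paths)] <- net_paths
  wt(annotations, "annotations.tsv")
  wt(family_annotations, "family_annotations.tsv")
  wt(rarefaction, "rarefaction.tsv")
  wt(overlap$exclusive, "upset_exclusive.tsv")
  wt(overlap$set_sizes, "upset_set_sizes.tsv")
  wt(data.frame(pathway = rownames(pmat), as.data.frame(pmat),
                check.names = FALSE), "pathway_media.tsv")
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  paths["summary.json"] <- summary_path

  manifest <- list(
    package_version = as.character(utils::packageVersion("molnetr")),
    seed = config$seed,
    n_permutations = config$n_permutations,
    max_blank_fraction = config$max_blank_fraction,
    params = unclass(params),
    simulate = if (!is.null(config$simulate)) unclass(config$simulate),
    counts = summary,
    outputs = as.list(vapply(paths, function(p)
      unname(tools::md5sum(p)), character(1)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(
    consensus = consensus, network = network, annotations = annotations,
    family_annotations = family_annotations, summary = summary,
    rarefaction = rarefaction, overlap = overlap, pathway_matrix = pmat,
    manifest = manifest, metadata = metadata, n_raw_spectra = n_raw,
    truth = if (!is.null(config$simulate)) man$truth,
    molecules = if (!is.null(config$simulate)) man$molecules
  ))
}
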