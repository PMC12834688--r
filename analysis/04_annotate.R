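#!/usr/bin/env Rscript
# Stage 4: spectral-library annotation.
#
# Consensus spectra are dereplicated against the reference library (exact
# precursor match within 0.02 Da, cosine >= 0.7, >= 6 matched peaks), then
# extended by analog search (precursor delta up to 200 Da), the propagated
# route that roughly doubles annotations in practice. For one analog hit we
# localize the mass shift on the fragment series. Annotations propagate to
# molecular families.

suppressMessages(library(molnetr))

out_dir <- "results/study"
state <- readRDS(file.path(out_dir, "state_cluster.rds"))
network <- readRDS(file.path(out_dir, "state_network.rds"))
sim <- readRDS(file.path(out_dir, "state_simulate.rds"))
params <- state$params

library_spectra <- read_library(sim$manifest$library_path, params)
cat(sprintf("library: %d reference spectra\n", length(library_spectra)))

exact <- exact_library_search(state$consensus, library_spectra, params)
analog <- analog_library_search(state$consensus, library_spectra, params,
                                exact)
annotations <- rbind(exact, analog)
cat(sprintf("%d exact + %d analog = %d annotated consensus spectra\n",
            nrow(exact), nrow(analog), nrow(annotations)))

if (nrow(analog) > 0) {
  ids <- vapply(state$consensus, `[[`, "", "spectrum_id")
  lib_ids <- vapply(library_spectra, `[[`, "", "spectrum_id")
  locs <- lapply(seq_len(nrow(analog)), function(r)
    localize_mass_shift(state$consensus[[match(analog$consensus_id[r], ids)]],
                        library_spectra[[match(analog$entry_id[r], lib_ids)]],
                        params))
  pick <- which.max(vapply(locs, function(l) nrow(l$shifted), integer(1)))
  top <- analog[pick, ]; loc <- locs[[pick]]
  where <- if (nrow(loc$shifted) > 0) {
    sprintf("modification at or below m/z %.3f", loc$min_shifted_mz)
  } else {
    "all matched pairs unshifted (adduct-type delta)"
  }
  cat(sprintf(
    "example analog: %s vs %s, delta %+0.4f Da; %d direct / %d shifted pairs; %s\n",
    top$consensus_id, top$compound_name, loc$delta, nrow(loc$direct),
    nrow(loc$shifted), where))
}

fam_ann <- propagate_family_annotations(network$families, annotations)
cat(sprintf("%d of %d molecular families annotated\n",
            sum(fam_ann$annotated), nrow(fam_ann)))

utils::write.table(annotations, file.path(out_dir, "annotations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(fam_ann, file.path(out_dir, "family_annotations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(list(annotations = annotations, family_annotations = fam_ann),
        file.path(out_dir, "state_annotate.rds"))
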