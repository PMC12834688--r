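#!/usr/bin/env Rscript
# Stage 2: exclusion lists, spectral preprocessing, consensus clustering,
# blank-based background removal.
#
# Blank precursors form an exclusion list (software stand-in for the
# acquisition-time lists built per culture medium); sample spectra on the
# list are dropped. Remaining spectra get the standard cleanup (fragment
# ions within +/-17 Da of the precursor removed; top 6 peaks per +/-50 Da
# window) and are merged into consensus spectra ("unique MS/MS").
# Consensus spectra with any blank membership are discarded as background.

suppressMessages(library(molnetr))

out_dir <- "results/study"
state <- readRDS(file.path(out_dir, "state_simulate.rds"))
man <- state$manifest
params <- networking_params()

metadata <- load_sample_table(man$metadata_path)
sample_spectra <- unlist(lapply(man$sample_files, read_mgf),
                         recursive = FALSE)
blank_spectra <- unlist(lapply(man$blank_files, read_mgf),
                        recursive = FALSE)
n_raw <- length(sample_spectra)
cat(sprintf("read %d sample and %d blank MS/MS spectra\n",
            n_raw, length(blank_spectra)))

exclusion <- build_exclusion_list(blank_spectra, params$exclusion_mz_tol)
sample_spectra <- apply_exclusion_list(sample_spectra, exclusion,
                                       params$exclusion_mz_tol)
cat(sprintf("exclusion list: %d entries; %d sample spectra excluded\n",
            length(exclusion), n_raw - length(sample_spectra)))

pre <- preprocess_spectra(c(sample_spectra, blank_spectra), params)
consensus <- cluster_spectra(pre, params)
n_all <- length(consensus)
consensus <- remove_blank_clusters(consensus, metadata)
cat(sprintf("%d consensus spectra after merging; %d removed via blanks\n",
            n_all, n_all - length(consensus)))

write_mgf(consensus, file.path(out_dir, "consensus.mgf"))
write_cluster_info(consensus, file.path(out_dir, "clusterinfo.tsv"))
saveRDS(list(consensus = consensus, n_raw = n_raw, params = params,
             metadata = metadata),
        file.path(out_dir, "state_cluster.rds"))
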