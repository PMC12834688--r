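#!/usr/bin/env Rscript
# Stage 1: generate the synthetic strains-by-media study.
#
# Emulates an untargeted LC-MS/MS survey of Actinomycetes extracts: 20
# strains cultured on five media (ISP-2, ISP-4, TSA, NSG, CZP), 60
# ground-truth molecules in 15 structural families with adduct/in-source/
# multimer redundancy (~3 ion forms per molecule), media-dependent
# production, 5 ppm mass error, and a reference library covering 13% of the
# molecules. One MGF per strain x medium plus one blank per medium.

suppressMessages(library(molnetr))

out_dir <- "results/study"
design <- study_design(seed = 42L)
manifest <- simulate_study(design, file.path(out_dir, "data"))

cat(sprintf("wrote %d sample files and %d blank files under %s\n",
            length(manifest$sample_files), length(manifest$blank_files),
            file.path(out_dir, "data")))
cat(sprintf("ground truth: %d molecules in %d families; %d in the library\n",
            design$n_molecules, design$n_families,
            sum(vapply(manifest$molecules, `[[`, logical(1), "in_library"))))
cat(sprintf("truth table: %d emitted MS/MS spectra\n", nrow(manifest$truth)))

saveRDS(list(design = design, manifest = manifest),
        file.path(out_dir, "state_simulate.rds"))
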