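#!/usr/bin/env Rscript
# Stage 3: molecular networking.
#
# All consensus pairs are scored with the modified cosine; edges need
# cosine >= 0.7 and >= 6 matched peaks, must be mutual top-10 neighbors,
# and molecular families (connected components) are capped at 100 nodes by
# removing their weakest edges. The network is exported as GraphML (for
# Cytoscape-style viewing) plus TSV twins.

suppressMessages(library(molnetr))

out_dir <- "results/study"
state <- readRDS(file.path(out_dir, "state_cluster.rds"))

network <- build_network(state$consensus, state$params)
fam_sizes <- table(unique(network$families[,
  c("family_id", "family_size")])$family_size)
cat(sprintf("network: %d nodes, %d edges, %d molecular families\n",
            length(network$node_ids), nrow(network$edges),
            length(unique(network$families$family_id))))
cat("family size distribution:\n")
print(fam_sizes)

paths <- export_network(state$consensus, network, NULL, out_dir)
cat("wrote:", paste(basename(paths), collapse = ", "), "\n")
saveRDS(network, file.path(out_dir, "state_network.rds"))
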