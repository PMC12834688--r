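#!/usr/bin/env Rscript
# Stage 5: discovery-potential statistics and figures.
#
# Rarefaction curves over strains (all / annotated / unannotated, at the
# consensus-spectrum and molecular-family level), media-overlap (upset)
# counts, annotation rates under both denominators, and the
# pathway-by-medium matrix normalized to each pathway's best medium.

suppressMessages(library(molnetr))

out_dir <- "results/study"
fig_dir <- file.path("results", "figures")
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

state <- readRDS(file.path(out_dir, "state_cluster.rds"))
network <- readRDS(file.path(out_dir, "state_network.rds"))
ann <- readRDS(file.path(out_dir, "state_annotate.rds"))

units <- sort(unique(unlist(lapply(state$consensus, `[[`, "strain_set"))))
rar <- rarefaction_by_stratum(state$consensus, network$families,
                              ann$annotations, units,
                              n_permutations = 100L, seed = 42L)
overlap <- media_overlap_counts(state$consensus)
pmat <- pathway_media_matrix(state$consensus, ann$annotations)
summary <- annotation_rate_summary(state$n_raw, state$consensus,
                                   ann$annotations, network$families)

cat(sprintf("raw MS/MS: %d; consensus: %d; families: %d\n",
            summary$n_raw_spectra, summary$n_consensus, summary$n_families))
cat(sprintf("annotation rate: %.1f%% of consensus (%.1f%% of raw spectra)\n",
            100 * summary$rate_consensus, 100 * summary$rate_raw))
cat(sprintf("annotated families: %d; unannotated: %d\n",
            summary$n_annotated_families, summary$n_unannotated_families))
all5 <- paste(sort(MEDIA_LEVELS), collapse = "+")
cat(sprintf("consensus shared across all five media: %d\n",
            sum(overlap$exclusive$count[overlap$exclusive$combination ==
                                          all5])))

utils::write.table(rar, file.path(out_dir, "rarefaction.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(overlap$exclusive,
                   file.path(out_dir, "upset_exclusive.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(overlap$set_sizes,
                   file.path(out_dir, "upset_set_sizes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(pathway = rownames(pmat),
                              as.data.frame(pmat), check.names = FALSE),
                   file.path(out_dir, "pathway_media.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                     auto_unbox = TRUE, digits = NA)

# figures (rarefaction curves and upset-style bars)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p1 <- ggplot(rar, aes(k, mean, color = stratum)) +
    geom_line() +
    geom_ribbon(aes(ymin = mean - sd, ymax = mean + sd, fill = stratum),
                alpha = 0.2, color = NA) +
    facet_wrap(~level, scales = "free_y") +
    labs(x = "number of strains", y = "distinct items",
         title = "Accumulation of MS/MS spectra and molecular families") +
    theme_minimal()
  ggsave(file.path(fig_dir, "rarefaction.png"), p1, width = 9, height = 4,
         dpi = 150)

  ov <- overlap$exclusive
  ov$combination <- factor(ov$combination,
                           levels = ov$combination[order(-ov$count)])
  p2 <- ggplot(ov, aes(combination, count)) +
    geom_col() +
    labs(x = NULL, y = "exclusive consensus count",
         title = "Media overlap of consensus spectra") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
  ggsave(file.path(fig_dir, "media_overlap.png"), p2, width = 9,
         height = 4.5, dpi = 150)

  pm <- as.data.frame(as.table(pmat))
  names(pm) <- c("pathway", "media", "value")
  p3 <- ggplot(pm, aes(media, value)) +
    geom_col() +
    facet_wrap(~pathway) +
    labs(x = NULL, y = "annotated MS/MS (normalized to pathway max)") +
    theme_minimal()
  ggsave(file.path(fig_dir, "pathway_media.png"), p3, width = 9, height = 6,
         dpi = 150)
  cat("figures written under", fig_dir, "\n")
}
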