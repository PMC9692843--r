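#!/usr/bin/env Rscript
# Cross-run overlap analysis: pairwise contingency tables among the six
# proposed runs, relation classification, threads, the six-level agreement
# grouping, and the comparison against the truth annotation axes.

suppressMessages(library(testaclust))

master_seed <- 20L
pcfg <- preprocess_config(downsample_side = 4)
# overlap floor scaled to this corpus (60 images, clusters of ~20)
ocfg <- overlap_config(report_floor = 5L)

cfg <- pipeline_config(image_dir = "results/images",
                       preprocess = pcfg, overlap = ocfg,
                       master_seed = master_seed)
report <- run_pipeline(cfg)
write_report(report, "results/consensus")

ag <- report$consensus$agreement
cat("agreement group counts (SI..PD):\n")
print(ag$counts)
cat(sprintf("\npairwise tables emitted: %d (= C(6,2) = %g)\n",
            report$n_tables, combination_count(6, 2)))
cat(sprintf("threads found: %d\n", length(report$consensus$threads)))
for (th in report$consensus$threads)
  cat("  thread:", paste(sprintf("%s-C%d", th$nodes$run, th$nodes$cluster + 1L),
                         collapse = " ~ "), "\n")

hm <- report$human
if (!is.null(hm)) {
  ident <- subset(hm$anticlinal$relations, category == "identical")
  cat(sprintf("\nanticlinal axis: %d identical machine clusters\n", nrow(ident)))
  utils::write.csv(hm$anticlinal$relations,
                   "results/human_vs_machine_anticlinal.csv", row.names = FALSE)
  utils::write.csv(hm$periclinal$relations,
                   "results/human_vs_machine_periclinal.csv", row.names = FALSE)
}
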