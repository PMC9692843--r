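#!/usr/bin/env Rscript
# Scan k = 2..10 per representation with the elbow (SSE) and silhouette
# criteria and record the chosen cluster counts.

suppressMessages(library(testaclust))

master_seed <- 20L
pcfg <- preprocess_config(downsample_side = 4)

images <- read_images("results/images", pcfg)
feats <- build_features(images, pcfg,
                        color_seed = derive_seed(master_seed, "colorize"))

curves <- list()
chosen <- list()
for (rp in c("grayscale", "threshold", "colored")) {
  ks <- choose_k(feats[[rp]], 2:10, restarts = 10L,
                 seed = derive_seed(master_seed, paste0("select-", rp)),
                 representation = rp)
  curves[[rp]] <- data.frame(representation = rp, k = ks$k_grid,
                             sse = ks$sse, silhouette = ks$silhouette)
  chosen[[rp]] <- list(elbow = ks$k_elbow, silhouette = ks$k_silhouette)
  cat(sprintf("%-10s k_elbow = %d   k_silhouette = %d\n",
              rp, ks$k_elbow, ks$k_silhouette))
}
utils::write.csv(do.call(rbind, curves), "results/k_selection_curves.csv",
                 row.names = FALSE)
jsonlite::write_json(chosen, "results/k_selected.json", auto_unbox = TRUE,
                     pretty = TRUE)
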