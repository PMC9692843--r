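# Shared study fixture: the three-class separated synthetic set (n = 60) with
# its features, k selections and battery, generated once per test session.
.demo_cache <- new.env(parent = emptyenv())

demo_battery <- function() {
  if (!is.null(.demo_cache$res)) return(.demo_cache$res)
  master_seed <- 20L
  imgs <- generate_dataset(separated_class_spec(20), seed = master_seed)
  pcfg <- preprocess_config(downsample_side = 4)
  feats <- build_features(imgs, pcfg)
  selection <- list()
  for (rp in c("grayscale", "threshold", "colored"))
    selection[[rp]] <- choose_k(feats[[rp]], 2:10, restarts = 10L,
                                seed = derive_seed(master_seed, rp),
                                representation = rp)
  runs <- run_battery(feats, battery_config(master_seed = master_seed),
                      selection)
  .demo_cache$res <- list(
    images = imgs, features = feats, selection = selection, runs = runs,
    truth_int = rep(1:3, each = 20),
    truth = lapply(imgs, `[[`, "truth"))
  .demo_cache$res
}
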