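# Reduced study configuration for fast pipeline tests.
small_config <- function(master_seed = 7L) {
  cfg <- default_study_config(master_seed)
  cfg$activity$n_animals <- 3
  cfg$activity$n_days <- 10
  cfg$activity$conditions <- cfg$activity$conditions[c("LD12_12", "DD", "LL")]
  cfg$imaging$fields_per_cell <- 3
  cfg$imaging$field$width_px <- 128
  cfg$imaging$field$height_px <- 128
  pair <- cfg$imaging$pairs$Syp1_PSD95
  for (nm in c("n_pre", "n_post", "sigma_post", "coloc"))
    pair[[nm]] <- pair[[nm]][c("LD12_12", "DD")]
  pair$n_pre <- lapply(pair$n_pre, function(v) round(v / 3))
  pair$n_post <- lapply(pair$n_post, function(v) round(v / 3))
  cfg$imaging$pairs <- list(Syp1_PSD95 = pair)
  cfg
}
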