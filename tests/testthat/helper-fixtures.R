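# Shared fixtures, all generated in code under fixed seeds.

suppressPackageStartupMessages(library(SummarizedExperiment))

tiny_cfg <- function(channels = 8L) {
  archConfig(n_groups = 2L, blocks_per_group = 1L,
             dilation_schedule = c(1L, 2L), channels = channels)
}

# A small trained-free model with randomized head, so logits depend on the
# input (buildModel zero-initializes the head on purpose).
tiny_model <- function(seed = 1L, channels = 8L) {
  m <- buildModel(tiny_cfg(channels), seed = seed)
  set.seed(seed + 1000L)
  m@params$head$pos$W[[1]][] <- rnorm(channels, sd = 0.3)
  m@params$head$dist_w[] <- rnorm(channels, sd = 0.3)
  m@params$head$pos_bias[] <- rnorm(206, sd = 0.05)
  m@params$head$Wlib[] <- rnorm(206 * 13, sd = 0.02)
  m
}

tiny_bundle <- function(n = 50, seed = 3, depth = 100) {
  generatePASLibrary(n, defaultLaw(), seed = seed, depth = depth)
}

random_seq <- function(n = 1, len = 205L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# A sequence-independent law: zero CSE weights and no motif effects, so every
# record has the same strength.
flat_law <- function(kernel = NULL) {
  law <- defaultLaw()
  law@cse_pwm[] <- 0
  law@motif_effects <- list()
  if (!is.null(kernel)) law@cleavage_kernel <- kernel
  law@distal_baseline_logit <- 0
  law
}
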