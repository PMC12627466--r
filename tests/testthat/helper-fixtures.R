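# Shared fixtures, built once per test run.

# A small configuration whose full forward/backward runs in milliseconds:
# 64-pixel input (window 2), 8 embedding channels, semantic length 16.
micro_config <- function() {
  model_config(depths = c(1, 1, 1, 1), embed_channels = 8, input_size = 64L,
               semantic_len = 16L, hyper_width = 32L)
}

micro_params <- function(seed = 42L) init_fthnet(micro_config(), seed = seed)

random_image <- function(size, seed = 7L, channels = 3L) {
  withr::with_seed(seed, array(stats::runif(size * size * channels),
                               c(size, size, channels)))
}

# A rendered-and-degraded synthetic dataset, cached across tests.
fixture_env <- new.env(parent = emptyenv())

micro_dataset <- function(n = 24L, size = 64L, seed = 101L) {
  key <- paste0("ds", n, "x", size, "s", seed)
  if (is.null(fixture_env[[key]])) {
    dir <- file.path(tempdir(), paste0("fthnet-", key))
    fixture_env[[key]] <- generate_fqs_dataset(n, seed = seed, out_dir = dir,
                                               size = size)
  }
  fixture_env[[key]]
}

manifest_from_scores <- function(scores_df, root = tempdir()) {
  fqs_manifest(scores_df, root = root)
}
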