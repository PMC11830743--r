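# Trains the seeded harness model once per test run and memoizes it so the
# latent-organization, reconstruction, QC and classification batteries all
# reuse the same checkpoint.
.harness_cache <- new.env(parent = emptyenv())

get_harness <- function() {
  if (is.null(.harness_cache$ck)) {
    .harness_cache$ck <- harness_train(seed = 7L)
    .harness_cache$metrics <- harness_eval(.harness_cache$ck, seed = 7L)
  }
  .harness_cache
}

get_harness_classify <- function() {
  if (is.null(.harness_cache$classify))
    .harness_cache$classify <- harness_classify(get_harness()$ck, seed = 7L)
  .harness_cache$classify
}

# small deterministic phantom helpers shared across test files
tiny_map <- function(cls = "normal", severity = 0, seed = 1, img = 32,
                     ...) {
  make_gcipl_map(phantom_params(cls, severity = severity, ...),
                 seed = seed, img_px = img)
}
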