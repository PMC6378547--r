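# Memoized canonical fixture and pipeline shared across test files.
.canonical_cache <- new.env(parent = emptyenv())

get_canonical <- function() {
  if (is.null(.canonical_cache$fx)) {
    .canonical_cache$fx <- build_canonical_fixture()
  }
  .canonical_cache$fx
}

get_canonical_kept <- function() {
  if (is.null(.canonical_cache$kept)) {
    fx <- get_canonical()
    .canonical_cache$kept <- filter_completeness(fx$entries, fx$config,
                                                 quiet = TRUE)
  }
  .canonical_cache$kept
}

get_canonical_pipeline <- function() {
  if (is.null(.canonical_cache$pipe)) {
    fx <- get_canonical()
    .canonical_cache$pipe <- run_pipeline(get_canonical_kept(),
                                          fx$config,
                                          directory = fx$phone_directory)
  }
  .canonical_cache$pipe
}
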