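# Shared fixtures, built once per test run. Heavy objects (parent,
# embeddings) are memoised so individual test files stay fast.

.fixtures <- new.env()

fixture_parent <- function() {
  if (is.null(.fixtures$parent)) .fixtures$parent <- make_parent(seed = 101)
  .fixtures$parent
}

# small embedding width keeps the protein branch cheap in unit tests;
# the default 1280-width contract is asserted separately
fixture_backend <- function(width = 32L) {
  embedder_backend("stub", width = width, seed = 7)
}

fixture_embeddings <- function(variants = c("WT-SpCas9", "SpCas9-HF1"),
                               width = 32L) {
  key <- paste(c(variants, width), collapse = "|")
  if (is.null(.fixtures$emb)) .fixtures$emb <- list()
  if (is.null(.fixtures$emb[[key]])) {
    reg <- builtin_registry()
    be <- fixture_backend(width)
    .fixtures$emb[[key]] <- lapply(reg[variants], function(d) {
      embed_protein(apply_mutations(fixture_parent(), d), be)
    })
  }
  .fixtures$emb[[key]]
}

fixture_records <- function(n_guides = 10L,
                            variants = c("WT-SpCas9", "SpCas9-HF1"),
                            seed = 5L, noise_sd = 0.3) {
  generate_dataset(sim_config(n_guides = n_guides, variants = variants,
                              seed = seed, noise_sd = noise_sd))
}

# all permutations of 1..n (for exhaustive small-n checks)
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

random_protospacer <- function(n = 1L, len = 20L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
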