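# Small fixture builders shared across test files.

tinyUniverse <- function(n) geneUniverse(sprintf("G%04d", seq_len(n)))

# A random signed gene set over a universe, drawn from the current RNG
# state (callers wrap in withr::with_seed).
randomSignedSet <- function(universe, size, label = "s") {
  ids <- sample(geneIds(universe), size)
  signedGeneSet(ids, direction = sample(c(1L, -1L), size, replace = TRUE),
                label = label)
}

writeTempLines <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
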