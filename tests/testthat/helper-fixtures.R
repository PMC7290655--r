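# Shared lightweight fixtures. Heavier objects are built inside the test
# files that need them.

# A tiny one-constraint motif on short windows for brute-force oracles.
toy_motif_k5 <- function(q = 1) {
  motif_spec("toy-k5", "S",
             tibble::tibble(offset = -2L, residues = "R", q = q))
}

# Small classifier configuration keeping unit tests fast.
tiny_dnn <- function(epochs = 25, seed = 1L, ...) {
  dnn_config(hidden = c(16, 12, 8, 6, 4), epochs = epochs, seed = seed,
             batch_size = 32, validation_fraction = 0, ...)
}

# Reduced hill-climb budget for unit tests of downstream machinery.
fast_pwd <- function() pwd_control(max_iter = 300)

# Deterministic random peptides over the standard alphabet.
random_peptides <- function(n, k, seed, center = NULL) {
  withr::with_seed(seed, {
    out <- vapply(seq_len(n), function(i) {
      ch <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ""),
                   k, replace = TRUE)
      if (!is.null(center)) ch[(k + 1) %/% 2] <- center
      paste(ch, collapse = "")
    }, character(1))
  })
  out
}
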