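# build a DNA sequence from RNA-alphabet codons
dna_from <- function(...) paste(chartr("U", "T", c(...)), collapse = "")

# a valid 300-nt ORF: AUG + 98 repeats of `body` codon + stop
valid_orf_seq <- function(body = "GCU", stop = "UAA") {
  dna_from("AUG", rep(body, 98), stop)
}

# tiny ORF sets for unit tests (validation relaxed to short sequences)
tiny_orf_set <- function(seqs, ids = sprintf("orf%02d", seq_along(seqs)),
                         ...) {
  orf_set(ids, seqs, min_length = 6L, ...)
}

# definition-level adjusted-residual oracle: explicit double loop over cells,
# independent of the vectorized implementation
adjres_oracle <- function(o) {
  n <- sum(o)
  r <- matrix(NA_real_, nrow(o), ncol(o))
  for (i in seq_len(nrow(o))) {
    for (j in seq_len(ncol(o))) {
      e <- sum(o[i, ]) * sum(o[, j]) / n
      p <- sum(o[i, ]) / n
      q <- sum(o[, j]) / n
      if (e > 0) r[i, j] <- (o[i, j] - e) / sqrt(e * (1 - p) * (1 - q))
    }
  }
  r
}

# random per-codon count vector with every family populated
random_codon_counts <- function(seed) {
  set.seed(seed)
  stats::setNames(sample(1:500, 64, replace = TRUE), codons())
}
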