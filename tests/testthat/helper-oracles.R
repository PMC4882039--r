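# Independent oracles used across the suite. These deliberately avoid the
# package's own implementation paths: the DFT oracle is a direct O(N^2)
# summation and the ORF oracle enumerates every ATG in every forward frame
# and walks codons to the first stop.

random_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# direct O(N^2) DFT power spectrum over the four indicator tracks
oracle_power_spectrum <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  ks <- 0:(n - 1)
  E <- exp(-2i * pi * outer(ks, ks) / n)  # E[n+1, k+1] = e^{-2*pi*i*n*k/N}
  P <- numeric(n)
  for (b in c("A", "C", "G", "T")) {
    u <- as.numeric(chars == b)
    P <- P + Mod(as.vector(u %*% E))^2
  }
  P
}

oracle_snr <- function(seq) {
  n <- nchar(seq)
  P <- oracle_power_spectrum(seq)
  P[round(n / 3) + 1] / (sum(P) / n)
}

# exhaustive ATG-to-stop scan, O(N^2) in the worst case
oracle_max_orf <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  codon_at <- function(i) paste0(chars[i], chars[i + 1], chars[i + 2])
  best <- 0
  for (start in seq_len(max(n - 2, 0))) {
    if (codon_at(start) != "ATG") next
    i <- start
    while (i + 2 <= n) {
      if (codon_at(i) %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, i + 2 - start + 1)
        break
      }
      i <- i + 3
    }
  }
  best
}

# small labelled feature set for classifier tests
make_labelled_features <- function(n_per_class = 120, seed = 7,
                                   length_range = c(200, 800)) {
  spec <- generator_spec(n_per_class = n_per_class,
                         length_range = length_range, seed = seed)
  tx <- rbind(generate_coding(spec), generate_noncoding(spec))
  fm <- feature_matrix(tx)
  X <- as.matrix(fm[, -1])
  rownames(X) <- fm$id
  list(X = X, y = tx$label, transcripts = tx)
}
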