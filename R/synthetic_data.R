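#' Default biased codon-usage table for the coding-like generator
#'
#' A strongly skewed probability table over the 61 sense codons: ten
#' preferred codons carry eight-fold the weight of the remaining 51. The
#' preferred set is chosen so that the pooled single-base composition of the
#' codon stream stays close to uniform (within about 1%) while the
#' codon-position composition is strongly skewed — coding-like sequences
#' then acquire the period-3 spectral peak of real coding regions without a
#' give-away shift in overall base composition.
#'
#' @return Named numeric vector over the 61 sense codons, summing to 1.
#' @export
default_codon_table <- function() {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- sort(setdiff(all64, STOP_CODONS))
  preferred <- c("AAG", "ACC", "ACG", "ATT", "GAC", "GAG", "GCG", "TAT",
                 "TCG", "TCT")
  w <- stats::setNames(rep(1, length(sense)), sense)
  w[preferred] <- 8
  w / sum(w)
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Specification for the synthetic transcript generator
#'
#' Defines the study conditions under which the classifier is exercised
#' without external downloads: coding-like transcripts carry a long,
#' codon-usage-biased ORF (hence a period-3 spectral peak and a large
#' MaxORF) while non-coding-like transcripts are Markov sequences with
#' near-uniform codon-position composition.
#'
#' @param n_per_class Transcripts per class (default 1000).
#' @param length_range Min/max transcript length in nt, within
#'   `[200, 20000)`; default 200-3000 nt, the typical transcript range.
#' @param codon_bias Probability table over the 61 sense codons (default
#'   [default_codon_table()]).
#' @param codon_concentration Dirichlet concentration for per-transcript
#'   codon usage: each coding transcript draws its own codon table from
#'   `Dirichlet(codon_concentration * codon_bias)`, emulating between-gene
#'   codon-usage variability (smaller = more variable; default 50).
#' @param utr_base_distribution Base probabilities for UTR positions.
#' @param noncoding_model `"order0"` (iid) or `"order1"` (lag-1 Markov).
#' @param noncoding_gc Mean GC content of non-coding sequences.
#' @param gc_sd Between-transcript standard deviation of non-coding GC
#'   content (per-transcript GC is drawn from a normal truncated to
#'   \[0.2, 0.8\]; default 0.06, the spread seen across real transcripts).
#' @param markov_lambda Lag-1 copy probability for the order-1 model; the
#'   stationary base distribution is unchanged.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return A validated `generator_spec` list.
#' @export
generator_spec <- function(n_per_class = 1000L,
                           length_range = c(200L, 3000L),
                           codon_bias = default_codon_table(),
                           codon_concentration = 50,
                           utr_base_distribution = c(A = 0.25, C = 0.25,
                                                     G = 0.25, T = 0.25),
                           noncoding_model = c("order0", "order1"),
                           noncoding_gc = 0.5,
                           gc_sd = 0.06,
                           markov_lambda = 0.25,
                           seed = 42L) {
  noncoding_model <- match.arg(noncoding_model)
  stopifnot(n_per_class >= 1L,
            length(length_range) == 2L,
            length_range[1L] >= 200L, length_range[2L] < 20000L,
            length_range[1L] <= length_range[2L],
            length(codon_bias) == 61L,
            abs(sum(codon_bias) - 1) < 1e-9,
            !any(names(codon_bias) %in% STOP_CODONS),
            length(utr_base_distribution) == 4L,
            abs(sum(utr_base_distribution) - 1) < 1e-9,
            noncoding_gc > 0, noncoding_gc < 1,
            codon_concentration > 0, gc_sd >= 0,
            markov_lambda >= 0, markov_lambda < 1)
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 codon_bias = codon_bias,
                 codon_concentration = codon_concentration,
                 gc_sd = gc_sd,
                 utr_base_distribution = utr_base_distribution,
                 noncoding_model = noncoding_model,
                 noncoding_gc = noncoding_gc,
                 markov_lambda = markov_lambda,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

.random_utr <- function(len, p) {
  if (len == 0L) return("")
  paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = "")
}

#' Generate coding-like transcripts
#'
#' Each transcript is a 5' UTR, an `ATG`, a run of codons drawn iid from a
#' per-transcript codon table (a Dirichlet perturbation of the shared biased
#' table, emulating between-gene codon-usage variability; sense codons only,
#' so the designed reading frame has no premature stop), one stop codon, and
#' a 3' UTR. The designed ORF spans at least 62% of the transcript, so every
#' emitted sequence satisfies `MaxORF >= 0.6 * Length` by construction.
#'
#' @param spec A `generator_spec`.
#' @return Transcript data.frame (`id`, `seq`, `label = "CODING"`).
#' @export
generate_coding <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  codons <- names(spec$codon_bias)
  p_utr <- spec$utr_base_distribution
  seqs <- vapply(seq_len(spec$n_per_class), function(i) {
    ltot <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
    orf_frac <- stats::runif(1L, 0.62, 0.88)
    orf_len <- 3L * as.integer(ceiling(orf_frac * ltot / 3))
    utr5 <- as.integer(floor(stats::runif(1L, 0, 0.08) * ltot))
    if (utr5 + orf_len > ltot) utr5 <- ltot - orf_len
    utr3 <- ltot - utr5 - orf_len
    p_codon <- .rdirichlet(spec$codon_concentration * spec$codon_bias)
    body <- paste(sample(codons, orf_len %/% 3L - 2L, replace = TRUE,
                         prob = p_codon), collapse = "")
    paste0(.random_utr(utr5, p_utr), "ATG", body,
           sample(STOP_CODONS, 1L), .random_utr(utr3, p_utr))
  }, character(1L))
  data.frame(id = sprintf("coding_%04d", seq_len(spec$n_per_class)),
             seq = seqs, label = "CODING", stringsAsFactors = FALSE)
}

#' Generate non-coding-like transcripts
#'
#' Sequences are drawn from an order-0 or order-1 Markov model whose
#' stationary base distribution matches a per-transcript GC content
#' (`A = T = (1-GC)/2`, `C = G = GC/2`, GC drawn per transcript around the
#' target); no ORF structure is imposed, so long ORFs occur only by chance
#' and the codon-position composition is uniform (no period-3 signal in
#' expectation). The order-1 model copies the previous base with probability
#' `markov_lambda` and otherwise draws fresh from the stationary
#' distribution.
#'
#' @param spec A `generator_spec`.
#' @return Transcript data.frame (`id`, `seq`, `label = "NONCODING"`).
#' @export
generate_noncoding <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed + 1L)
  lam <- if (spec$noncoding_model == "order1") spec$markov_lambda else 0
  seqs <- vapply(seq_len(spec$n_per_class), function(i) {
    ltot <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
    gc <- min(0.8, max(0.2, stats::rnorm(1L, spec$noncoding_gc, spec$gc_sd)))
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    fresh <- sample(DNA_BASES, ltot, replace = TRUE, prob = p)
    if (lam > 0) {
      keep <- c(TRUE, stats::runif(ltot - 1L) >= lam)
      fresh <- fresh[cummax(ifelse(keep, seq_len(ltot), 0L))]
    }
    paste(fresh, collapse = "")
  }, character(1L))
  data.frame(id = sprintf("noncoding_%04d", seq_len(spec$n_per_class)),
             seq = seqs, label = "NONCODING", stringsAsFactors = FALSE)
}

#' Write a labelled synthetic dataset to disk
#'
#' @param spec A `generator_spec`.
#' @param out_dir Writable output directory (created if absent).
#' @return Invisibly, a list with the written paths (`coding_fasta`,
#'   `noncoding_fasta`, `labels`) and the combined transcript data.frame.
#' @export
make_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  coding <- generate_coding(spec)
  noncoding <- generate_noncoding(spec)
  paths <- list(coding_fasta = file.path(out_dir, "coding.fasta"),
                noncoding_fasta = file.path(out_dir, "noncoding.fasta"),
                labels = file.path(out_dir, "labels.tsv"))
  write_fasta(coding, paths$coding_fasta)
  write_fasta(noncoding, paths$noncoding_fasta)
  both <- rbind(coding, noncoding)
  utils::write.table(both[, c("id", "label")], paths$labels, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$transcripts <- both
  invisible(paths)
}
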