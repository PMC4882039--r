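DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Canonical names of the 89 transcript features
#'
#' The hybrid feature vector: the two ORF features (`MaxORF` in nt and its
#' length-normalized form `RMaxORF`), the period-3 spectral signal-to-noise
#' ratio `SNR`, transcript `Length`, GC content `(G+C)%`, and overlapping
#' k-mer frequencies for k = 1, 2, 3 in lexicographic A < C < G < T order
#' (4 + 16 + 64 = 84 composition features), 89 in total.
#'
#' @return Character vector of length 89 in canonical order.
#' @export
feature_names <- function() {
  k2 <- sort(as.vector(outer(DNA_BASES, DNA_BASES, paste0)))
  k3 <- sort(as.vector(outer(k2, DNA_BASES, paste0)))
  c("MaxORF", "RMaxORF", "SNR", "Length", "(G+C)%",
    paste0(c(DNA_BASES, k2, k3), "%"))
}

.check_normalized <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  m <- regexpr("[^ACGT]", seq)
  if (m > 0L) {
    stop("disallowed character '", substr(seq, m, m), "' at position ", m,
         "; normalize with clean_transcripts() first")
  }
}

#' Voss mapping: binary indicator tracks of a nucleotide sequence
#'
#' Encodes a sequence of length N as four binary tracks, one per base, where
#' track b has a 1 exactly at the positions carrying base b. At every
#' position the four tracks sum to 1.
#'
#' @param seq Normalized sequence (uppercase, `{A,C,G,T}` only).
#' @return Integer matrix with rows `A`, `C`, `G`, `T` and N columns.
#' @export
#' @examples
#' voss_mapping("ATCTCACTGGT")
voss_mapping <- function(seq) {
  .check_normalized(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  tracks <- vapply(DNA_BASES, function(b) as.integer(chars == b),
                   integer(length(chars)))
  if (length(chars) == 1L) tracks <- matrix(tracks, nrow = 1L,
                                            dimnames = list(NULL, DNA_BASES))
  t(tracks)
}

#' Power spectrum of a transcript's indicator tracks
#'
#' Applies the DFT to each of the four Voss indicator tracks and sums the
#' squared moduli: `P[k] = |U_A[k]|^2 + |U_C[k]|^2 + |U_G[k]|^2 + |U_T[k]|^2`
#' for k = 0..N-1. By Parseval's identity the spectrum sums to N^2, so the
#' mean spectral power equals N.
#'
#' @param tracks Indicator-track matrix from [voss_mapping()].
#' @return Numeric vector `P` of length N (index k = 0 at position 1).
#' @export
power_spectrum <- function(tracks) {
  stopifnot(is.matrix(tracks), nrow(tracks) == 4L, ncol(tracks) >= 1L)
  P <- rowSums(vapply(seq_len(4L),
                      function(i) Mod(stats::fft(tracks[i, ]))^2,
                      numeric(ncol(tracks))))
  as.numeric(P)
}

#' Period-3 signal-to-noise ratio
#'
#' The power spectrum bin at the period-3 frequency k = N/3 divided by the
#' mean spectral power. Protein-coding sequences show elevated period-3 power
#' because codon-position nucleotide usage is biased; non-coding sequences do
#' not. For N not divisible by 3, the nearest integer bin `round(N/3)` is
#' used (the fractional part is 1/3 or 2/3, so there is never a tie).
#'
#' @param seq Normalized sequence, length >= 3.
#' @return Nonnegative real; equals `P[N/3] / N` since the mean power is N.
#' @export
#' @examples
#' snr(strrep("ACG", 100))  # perfect 3-periodicity: N/3 = 100
snr <- function(seq) {
  .check_normalized(seq)
  n <- nchar(seq)
  if (n < 3L) stop("sequence length must be >= 3 to define the period-3 bin")
  P <- power_spectrum(voss_mapping(seq))
  k_star <- as.integer(round(n / 3))
  e_bar <- sum(P) / n
  P[k_star + 1L] / e_bar
}

#' Length of the longest open reading frame (nt)
#'
#' Scans the three forward reading frames for spans starting at `ATG` and
#' ending at the first in-frame stop codon (`TAA`, `TAG`, `TGA`), stop
#' included, and returns the longest such span in nucleotides (0 when none
#' exists). With `require_stop = FALSE` an `ATG` with no downstream in-frame
#' stop instead contributes a span running to the last complete codon.
#' Reverse-complement frames are not scanned.
#'
#' @param seq Normalized sequence.
#' @param require_stop Require an in-frame stop codon (default).
#' @return Integer nt length; 0, or >= 6 and divisible by 3 when
#'   `require_stop` holds.
#' @export
#' @examples
#' max_orf("ATGTAA")       # minimal ORF: 6
#' max_orf("AATGAAATAGC")  # frame 2: ATG AAA TAG -> 9
max_orf <- function(seq, require_stop = TRUE) {
  .check_normalized(seq)
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  best <- 0L
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    starts <- seq.int(frame + 1L, by = 3L, length.out = ncod)
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    atg <- which(codons == "ATG")
    if (!length(atg)) next
    stops <- which(codons %in% STOP_CODONS)
    if (length(stops)) {
      # index of the first stop strictly after each ATG
      nxt <- findInterval(atg, stops) + 1L
      has_stop <- nxt <= length(stops)
      if (any(has_stop)) {
        lens <- (stops[nxt[has_stop]] - atg[has_stop] + 1L) * 3L
        best <- max(best, lens)
      }
      if (!require_stop) {
        open <- atg[!has_stop]
        if (length(open)) best <- max(best, (ncod - min(open) + 1L) * 3L)
      }
    } else if (!require_stop) {
      best <- max(best, (ncod - min(atg) + 1L) * 3L)
    }
  }
  best
}

#' Length-normalized longest ORF
#'
#' @param max_orf Longest-ORF length in nt.
#' @param length Transcript length in nt (> 0).
#' @return `max_orf / length`, in \[0, 1\].
#' @export
rmax_orf <- function(max_orf, length) {
  if (any(length <= 0)) stop("transcript length must be positive")
  if (any(max_orf < 0) || any(max_orf > length)) {
    stop("max_orf must lie in [0, length]")
  }
  max_orf / length
}

#' Overlapping k-mer frequencies
#'
#' Counts of every length-k word over overlapping windows, divided by the
#' number of windows (N - k + 1), in lexicographic A < C < G < T order.
#'
#' @param seq Normalized sequence with `nchar(seq) >= k`.
#' @param k Word size, one of 1, 2, 3.
#' @return Named numeric vector of length `4^k` summing to 1.
#' @export
kmer_frequencies <- function(seq, k) {
  .check_normalized(seq)
  stopifnot(length(k) == 1L, k %in% 1:3)
  if (nchar(seq) < k) stop("sequence shorter than k = ", k)
  Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                       width = k, step = 1L, as.prob = TRUE)
}

#' Extract the 89-dimensional hybrid feature vector
#'
#' @param seq A normalized transcript sequence (or a one-row transcript
#'   data.frame with a `seq` column).
#' @param require_stop Passed to [max_orf()].
#' @return Named numeric vector of length 89 in [feature_names()] order.
#' @export
extract_features <- function(seq, require_stop = TRUE) {
  if (is.data.frame(seq)) seq <- seq$seq[[1L]]
  .check_normalized(seq)
  n <- nchar(seq)
  f1 <- kmer_frequencies(seq, 1L)
  f2 <- kmer_frequencies(seq, 2L)
  f3 <- kmer_frequencies(seq, 3L)
  orf <- max_orf(seq, require_stop = require_stop)
  out <- c(MaxORF = orf,
           RMaxORF = rmax_orf(orf, n),
           SNR = snr(seq),
           Length = n,
           `(G+C)%` = unname(f1[["G"]] + f1[["C"]]),
           f1, f2, f3)
  names(out) <- feature_names()
  out
}

#' Feature matrix for a batch of transcripts
#'
#' @param transcripts Transcript data.frame (`id`, `seq`).
#' @param require_stop Passed to [max_orf()].
#' @return data.frame with an `id` column followed by the 89 canonical
#'   feature columns.
#' @export
feature_matrix <- function(transcripts, require_stop = TRUE) {
  stopifnot(is.data.frame(transcripts),
            all(c("id", "seq") %in% names(transcripts)))
  if (nrow(transcripts) == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0L, 89L,
                                dimnames = list(NULL, feature_names())),
                         check.names = FALSE)
    return(cbind(data.frame(id = character(0), stringsAsFactors = FALSE), out))
  }
  mat <- t(vapply(transcripts$seq, extract_features, numeric(89L),
                  require_stop = require_stop, USE.NAMES = FALSE))
  colnames(mat) <- feature_names()
  out <- as.data.frame(mat, check.names = FALSE)
  cbind(data.frame(id = transcripts$id, stringsAsFactors = FALSE), out)
}
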