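#' Read transcripts from a FASTA file
#'
#' Parses a (possibly multi-line, multi-record) FASTA file into a transcript
#' table. Sequence case and alphabet are preserved as found in the file;
#' normalization happens in [clean_transcripts()].
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` (first whitespace-delimited header
#'   token), `seq` (raw sequence, case preserved) and `label` (all
#'   `"UNKNOWN"`), one row per record in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 demo", "ACGT", "ACGT"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(recs))
  widths <- Biostrings::width(recs)
  if (any(widths == 0L)) {
    stop("FASTA record(s) with empty sequence: ",
         paste(ids[widths == 0L], collapse = ", "))
  }
  data.frame(id = ids, seq = as.character(recs), label = "UNKNOWN",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Clean, normalize and filter transcripts
#'
#' Applies the dataset-construction filters: sequences containing any
#' character outside the DNA/RNA alphabet `{A,a,C,c,G,g,T,t,U,u}` are rejected
#' whole; kept sequences are uppercased with `U` replaced by `T`; sequences
#' outside the half-open length window `[min_len, max_len)` are rejected; and
#' exact duplicate sequences (after normalization) beyond the first are
#' rejected when `drop_duplicates` is set. When `enforce_length = FALSE`
#' (prediction mode) out-of-window records are kept and flagged in a
#' `length_flag` column instead of being dropped.
#'
#' @param records Transcript data.frame from [read_fasta()] (columns `id`,
#'   `seq`, and optionally `label`).
#' @param min_len,max_len Length window; a record is kept when
#'   `min_len <= nchar(seq) < max_len`.
#' @param drop_duplicates Drop exact duplicate sequences after normalization.
#' @param enforce_length If `FALSE`, flag rather than reject out-of-window
#'   records.
#' @return A list with elements:
#'   \describe{
#'     \item{transcripts}{cleaned transcript data.frame (plus `length_flag`
#'       when `enforce_length = FALSE`)}
#'     \item{report}{a `cleaning_report`: counts `kept`, `rejected_alphabet`,
#'       `rejected_length`, `rejected_duplicate` (always reconciling with the
#'       input record count)}
#'     \item{rejects}{data.frame of rejected record ids with reason codes}
#'   }
#' @export
clean_transcripts <- function(records, min_len = 200L, max_len = 20000L,
                              drop_duplicates = TRUE, enforce_length = TRUE) {
  if (min_len > max_len) {
    stop("min_len (", min_len, ") must not exceed max_len (", max_len, ")")
  }
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  n_in <- nrow(records)
  if (!"label" %in% names(records)) records$label <- "UNKNOWN"

  bad_alpha <- grepl("[^ACGTUacgtu]", records$seq)
  rejects <- data.frame(id = records$id[bad_alpha],
                        reason = rep("alphabet", sum(bad_alpha)),
                        stringsAsFactors = FALSE)
  kept <- records[!bad_alpha, , drop = FALSE]
  kept$seq <- chartr("acgtuU", "ACGTTT", kept$seq)

  len <- nchar(kept$seq)
  out_of_window <- len < min_len | len >= max_len
  if (enforce_length) {
    rejects <- rbind(rejects,
                     data.frame(id = kept$id[out_of_window],
                                reason = rep("length", sum(out_of_window)),
                                stringsAsFactors = FALSE))
    kept <- kept[!out_of_window, , drop = FALSE]
    n_len <- sum(out_of_window)
  } else {
    kept$length_flag <- out_of_window
    n_len <- 0L
  }

  if (drop_duplicates) {
    dup <- duplicated(kept$seq)
    rejects <- rbind(rejects,
                     data.frame(id = kept$id[dup],
                                reason = rep("duplicate", sum(dup)),
                                stringsAsFactors = FALSE))
    kept <- kept[!dup, , drop = FALSE]
    n_dup <- sum(dup)
  } else {
    n_dup <- 0L
  }

  rownames(kept) <- NULL
  report <- structure(
    list(kept = nrow(kept),
         rejected_alphabet = sum(bad_alpha),
         rejected_length = n_len,
         rejected_duplicate = n_dup),
    class = "cleaning_report")
  stopifnot(report$kept + report$rejected_alphabet + report$rejected_length +
              report$rejected_duplicate == n_in)
  list(transcripts = kept, report = report, rejects = rejects)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Transcript cleaning report\n")
  cat(sprintf("  kept:               %d\n", x$kept))
  cat(sprintf("  rejected alphabet:  %d\n", x$rejected_alphabet))
  cat(sprintf("  rejected length:    %d\n", x$rejected_length))
  cat(sprintf("  rejected duplicate: %d\n", x$rejected_duplicate))
  invisible(x)
}

#' Write a prediction report
#'
#' Writes predictions as a tab-separated file: `id`, `noncoding_score`,
#' `predicted_class`, `shortcut_applied`, followed by any additional columns
#' present (flags, selected feature values). One row per prediction, input
#' order preserved.
#'
#' @param predictions Prediction data.frame from
#'   [predict.coding_potential_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(predictions, path) {
  stopifnot(is.data.frame(predictions))
  lead <- c("id", "noncoding_score", "predicted_class", "shortcut_applied")
  stopifnot(all(lead %in% names(predictions)))
  ord <- c(lead, setdiff(names(predictions), lead))
  utils::write.table(predictions[, ord, drop = FALSE], file = path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix as TSV
#'
#' @param features Feature data.frame with an `id` column (see
#'   [feature_matrix()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.table(features, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts Transcript data.frame (`id`, `seq`).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(transcripts, path) {
  set <- Biostrings::BStringSet(transcripts$seq)
  names(set) <- transcripts$id
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
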