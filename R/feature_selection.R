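#' Feature score criterion (FSC) ranking
#'
#' Scores each feature by the Golub-style criterion
#' `|mu_plus - mu_minus| / (sd_plus + sd_minus)` — the absolute difference of
#' class means over the sum of the per-class sample standard deviations — and
#' ranks features in descending order. The score is symmetric under swapping
#' the two class labels and invariant under affine rescaling of a feature.
#'
#' Degenerate denominators (both classes constant): the score is `+Inf` when
#' the class means differ (a perfect separator, ranked first) and 0 when they
#' coincide (an uninformative constant).
#'
#' @param X Numeric feature matrix or data.frame (samples x features) with
#'   column names.
#' @param y Binary class labels (factor, character or logical), one per row.
#' @return An `fsc_ranking`: data.frame with columns `rank`, `feature`,
#'   `score`, `mu_pos`, `sd_pos`, `mu_neg`, `sd_neg`, sorted by decreasing
#'   score with ties broken by original column order.
#' @export
fsc_scores <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), ncol(X) >= 1L, nrow(X) == length(y))
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) != 2L) stop("y must contain exactly two classes")
  if (any(table(y) < 2L)) {
    stop("each class needs >= 2 samples for a standard deviation")
  }
  pos <- y == classes[[1L]]
  mu_p <- colMeans(X[pos, , drop = FALSE])
  mu_n <- colMeans(X[!pos, , drop = FALSE])
  sd_p <- apply(X[pos, , drop = FALSE], 2L, stats::sd)
  sd_n <- apply(X[!pos, , drop = FALSE], 2L, stats::sd)
  denom <- sd_p + sd_n
  num <- abs(mu_p - mu_n)
  score <- ifelse(denom > 0, num / denom, ifelse(num > 0, Inf, 0))
  ord <- order(-score, seq_along(score))
  out <- data.frame(rank = seq_along(score),
                    feature = colnames(X)[ord],
                    score = score[ord],
                    mu_pos = mu_p[ord], sd_pos = sd_p[ord],
                    mu_neg = mu_n[ord], sd_neg = sd_n[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("fsc_ranking", "data.frame")
  out
}

#' Select the top-p features of an FSC ranking
#'
#' @param ranking An `fsc_ranking` from [fsc_scores()].
#' @param p Number of features to retain (default 30, the accuracy-maximizing
#'   cut on the original study's sweep).
#' @return Character vector of the first `p` feature names, ranking order
#'   preserved.
#' @export
select_top <- function(ranking, p = 30L) {
  stopifnot(inherits(ranking, "fsc_ranking"))
  if (p < 1L || p > nrow(ranking)) {
    stop("p must lie in [1, ", nrow(ranking), "], got ", p)
  }
  ranking$feature[seq_len(p)]
}

#' Write an FSC ranking as TSV
#'
#' @param ranking An `fsc_ranking`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
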