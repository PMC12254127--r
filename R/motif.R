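#' Position-wise nucleotide enrichment in high- vs low-activity guides
#'
#' Guides are split at the median activity into a high-activity
#' foreground and low-activity background; at every position of the
#' analysed region and for every nucleotide, a signed log10 binomial tail
#' probability scores enrichment (positive) or depletion (negative) of
#' the foreground against background frequencies, with a Bonferroni
#' significance line -- the same statistic family the pLogo sequence-logo
#' tool visualises.
#'
#' @name motif
NULL

#' Median split into high/low-activity groups
#'
#' The threshold is the sample median (average-of-middle-two for even
#' n). Records strictly above it are "high"; ties at the median fall to
#' "low".
#'
#' @param records sgRNA record data.frame with an `activity` column.
#' @return an `activity_groups` list: `high`, `low` (data.frames),
#'   `threshold`.
#' @export
median_split <- function(records) {
  if (nrow(records) < 2L) stop("median split needs at least 2 records")
  threshold <- stats::median(records$activity)
  hi <- records$activity > threshold
  if (!any(hi)) {
    stop("all activities are <= the median (constant data?); ",
         "high-activity group would be empty")
  }
  structure(list(high = records[hi, , drop = FALSE],
                 low = records[!hi, , drop = FALSE],
                 threshold = threshold),
            class = "activity_groups")
}

#' @export
print.activity_groups <- function(x, ...) {
  cat("Activity groups: ", nrow(x$high), " high / ", nrow(x$low),
      " low (median threshold ", format(x$threshold, digits = 4), ")\n",
      sep = "")
  invisible(x)
}

#' Position-wise binomial enrichment scores
#'
#' For each position and nucleotide, the background probability is the
#' low-group frequency; the score is `-log10` of the upper binomial tail
#' of the foreground count when the foreground frequency exceeds it
#' (enrichment), else `+log10` of the lower tail (so depletion scores are
#' negative). 'N' symbols are excluded from both counts. A Bonferroni
#' line at `alpha = 0.05` over positions x 4 tests is recorded; zero
#' background frequencies for an observed foreground nucleotide fall back
#' to a 0.5 pseudocount (messaged).
#'
#' @param groups an [median_split()] result.
#' @param positions 1-based positions of the 59-nt guide to analyse;
#'   defaults to the 23-nt protospacer + PAM region, which dominates
#'   activity.
#' @param alpha family-wise significance level before Bonferroni
#'   correction.
#' @return an `enrichment_matrix`: `scores` (positions x 4, signed
#'   log10), foreground/background count tables, and
#'   `significance_threshold` (the |score| that crosses the corrected
#'   alpha).
#' @export
enrichment <- function(groups, positions = seq_len(23L), alpha = 0.05) {
  stopifnot(inherits(groups, "activity_groups"))
  if (!nrow(groups$high) || !nrow(groups$low)) {
    stop("both activity groups must be non-empty")
  }
  nts <- c("A", "C", "G", "T")
  count_at <- function(seqs, pos) {
    ch <- substring(seqs, pos, pos)
    vapply(nts, function(b) sum(ch == b), numeric(1))
  }
  P <- length(positions)
  fg <- bg <- matrix(0, P, 4L, dimnames = list(positions, nts))
  for (i in seq_len(P)) {
    fg[i, ] <- count_at(groups$high$sequence, positions[i])
    bg[i, ] <- count_at(groups$low$sequence, positions[i])
  }
  fg_tot <- rowSums(fg); bg_tot <- rowSums(bg)

  tiny <- .Machine$double.xmin
  scores <- matrix(0, P, 4L, dimnames = list(positions, nts))
  used_pseudo <- FALSE
  for (i in seq_len(P)) {
    if (fg_tot[i] == 0 || bg_tot[i] == 0) next
    for (j in seq_len(4L)) {
      k <- fg[i, j]; n <- fg_tot[i]
      p <- bg[i, j] / bg_tot[i]
      if ((p == 0 && k > 0) || (p == 1 && k < n)) {
        p <- (bg[i, j] + 0.5) / (bg_tot[i] + 1)
        used_pseudo <- TRUE
      }
      if (p == 0 || p == 1) next # degenerate and concordant: score 0
      if (k / n > p) {
        scores[i, j] <- -log10(max(stats::pbinom(k - 1, n, p,
                                                 lower.tail = FALSE), tiny))
      } else {
        scores[i, j] <- log10(max(stats::pbinom(k, n, p), tiny))
      }
    }
  }
  if (used_pseudo) {
    message("zero background frequency encountered; 0.5 pseudocount applied")
  }
  n_tests <- P * 4L
  structure(list(scores = scores, fg_counts = fg, bg_counts = bg,
                 fg_totals = fg_tot, bg_totals = bg_tot,
                 positions = positions, alpha = alpha,
                 significance_threshold = -log10(alpha / n_tests)),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("Position-wise enrichment over", length(x$positions), "positions",
      "(Bonferroni |score| line", format(x$significance_threshold, digits = 4),
      ")\n")
  top <- top_enriched(x, 5L)
  cat("top |score| cells:\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' Rank enrichment cells by |score|
#'
#' @param x an `enrichment_matrix`.
#' @param n number of cells to return.
#' @return data.frame (position, nucleotide, score, significant) sorted
#'   by decreasing |score|.
#' @export
top_enriched <- function(x, n = 10L) {
  stopifnot(inherits(x, "enrichment_matrix"))
  df <- data.frame(position = rep(x$positions, 4L),
                   nucleotide = rep(colnames(x$scores), each = length(x$positions)),
                   score = as.vector(x$scores))
  df$significant <- abs(df$score) >= x$significance_threshold
  df <- df[order(-abs(df$score)), ]
  utils::head(df, n)
}

#' CSV export of an enrichment matrix
#'
#' @param x an `enrichment_matrix`.
#' @param path output CSV path.
#' @export
write_enrichment_csv <- function(x, path) {
  stopifnot(inherits(x, "enrichment_matrix"))
  df <- data.frame(position = x$positions, x$scores, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
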