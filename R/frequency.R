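#' Filter interactions by aggregate rank
#'
#' Keeps interactions detected with high consensus confidence: aggregate
#' rank (a p-value proxy) at or below the cutoff. The boundary is inclusive
#' and the input row order is preserved; the operation is idempotent.
#'
#' @param records an interaction data frame with an `aggregate_rank` column.
#' @param cutoff aggregate-rank cutoff in (0, 1]; default 0.1.
#' @return The filtered data frame.
#' @export
filter_significant <- function(records, cutoff = 0.1) {
  if (cutoff <= 0 || cutoff > 1)
    stop("'cutoff' must be in (0, 1]", call. = FALSE)
  out <- records[records$aggregate_rank <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample interaction frequencies per directed cell-type pair
#'
#' Counts the distinct detected interactions attributed to each directed
#' (sender, receiver) cell-type pair per sample and normalizes by the
#' sample's total number of detected interactions. Pairs with no detected
#' interaction get frequency 0; self-pairs are valid directed pairs. Rows sum
#' to 1, except for samples with no detected interaction, which yield an
#' all-zero row.
#'
#' @param tables named list of (already filtered, see [filter_significant()])
#'   interaction data frames.
#' @param cell_types character vector of cell-type labels; all directed pairs
#'   over these types form the columns. Defaults to the types observed.
#' @return Numeric matrix (samples x directed pairs), columns named
#'   `"sender->receiver"`.
#' @export
pair_frequencies <- function(tables, cell_types = NULL) {
  if (is.null(cell_types))
    cell_types <- sort(unique(unlist(lapply(tables, function(df)
      c(df$source, df$target)), use.names = FALSE)))
  cell_types <- sort(unique(cell_types))
  grid <- expand.grid(receiver = cell_types, sender = cell_types,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$sender, grid$receiver), ]
  pair_ids <- paste0(grid$sender, "->", grid$receiver)
  freq <- matrix(0, nrow = length(tables), ncol = length(pair_ids),
                 dimnames = list(names(tables), pair_ids))
  for (sid in names(tables)) {
    df <- tables[[sid]]
    if (nrow(df) == 0L) next
    counts <- table(factor(paste0(df$source, "->", df$target),
                           levels = pair_ids))
    freq[sid, ] <- as.numeric(counts) / nrow(df)
  }
  freq
}

#' Log2 fold change of per-pair median frequencies between groups
#'
#' The per-pair statistic behind the group-comparison heatmaps:
#' `log2((median_A + pseudocount) / (median_B + pseudocount))`, with a small
#' pseudocount added to both medians so all-zero pairs are defined (and map
#' to 0).
#'
#' @param freq_a,freq_b frequency-matrix rows (samples x pairs) for the two
#'   groups, with identical columns.
#' @param pseudocount value added to both medians; default 0.001.
#' @return Named numeric vector of per-pair log2 fold changes (A vs B).
#' @export
median_log2_fc <- function(freq_a, freq_b, pseudocount = 0.001) {
  if (nrow(freq_a) == 0L || nrow(freq_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (!identical(colnames(freq_a), colnames(freq_b)))
    stop("groups must share identical pair columns", call. = FALSE)
  med_a <- apply(freq_a, 2L, median)
  med_b <- apply(freq_b, 2L, median)
  log2((med_a + pseudocount) / (med_b + pseudocount))
}

#' Wilcoxon rank-sum comparison of pair frequencies between two groups
#'
#' Applies a two-sided Wilcoxon rank-sum test per directed cell-type pair
#' column.
#'
#' @param freq frequency matrix from [pair_frequencies()].
#' @param labels group label per row of `freq`; exactly two groups, each with
#'   at least one sample.
#' @return Data frame with `pair`, the two group labels' sizes, `statistic`
#'   (rank-sum W) and two-sided `p_value` per pair.
#' @export
compare_pair_frequencies <- function(freq, labels) {
  labels <- as.character(labels)
  if (length(labels) != nrow(freq))
    stop("'labels' must match the rows of 'freq'", call. = FALSE)
  lev <- unique(labels)
  if (length(lev) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  res <- lapply(colnames(freq), function(pp) {
    tst <- wilcoxon_two_group(freq[, pp], labels)
    data.frame(pair = pp, n1 = tst$n[1], n2 = tst$n[2],
               statistic = tst$statistic, p_value = tst$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
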