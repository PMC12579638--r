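#' Cell-type proportions from a count table
#'
#' Normalizes a sample-by-cell-type count table so each row gives the
#' fraction of the sample's cells attributed to each type.
#'
#' @param counts non-negative matrix or data frame of counts; every row must
#'   have a positive total.
#' @return Matrix of row-normalized fractions (rows sum to 1).
#' @export
proportions_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("all-zero count row", call. = FALSE)
  sweep(counts, 1L, tot, "/")
}

#' Two-group Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test comparing a numeric variable between two groups.
#' For small samples (at most 200,000 group assignments) the p-value is
#' computed by exact enumeration of the permutation null of the rank-sum
#' statistic, which handles ties correctly (identical groups give p = 1);
#' larger samples use the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param values numeric vector.
#' @param labels group label per value; exactly two groups, each non-empty.
#' @return List with `statistic` (the Mann-Whitney U of the first group),
#'   `p_value`, `n` (named group sizes) and `groups` (the two labels, in
#'   first-appearance order).
#' @export
wilcoxon_two_group <- function(values, labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  x <- values[labels == lev[1]]
  y <- values[labels == lev[2]]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  rk <- rank(c(x, y))
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (choose(n1 + n2, n1) <= 2e5) {
    idx <- utils::combn(n1 + n2, n1)
    u <- colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    p <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                      correct = TRUE)$p.value)
  }
  list(statistic = u_obs, p_value = p,
       n = stats::setNames(c(n1, n2), lev), groups = lev)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Omnibus Kruskal-Wallis test across three or more groups, followed by
#' Dunn's pairwise z tests on the joint ranks with tie correction, with
#' multiplicity adjustment of the pairwise p-values.
#'
#' @param values numeric vector.
#' @param labels group label per value; at least three groups, each
#'   non-empty.
#' @param adjust multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @return List with `h` (Kruskal-Wallis statistic), `p_value` (omnibus),
#'   and `pairwise`, a data frame with `group1`, `group2`, Dunn `z`, raw `p`
#'   and adjusted `p_adj`.
#' @export
kruskal_dunn <- function(values, labels, adjust = "holm") {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) < 3L)
    stop("fewer than 3 groups: use wilcoxon_two_group()", call. = FALSE)
  if (any(table(labels) == 0L))
    stop("every group must be non-empty", call. = FALSE)
  kw <- kruskal.test(values, factor(labels))

  n <- length(values)
  rk <- rank(values)
  mean_rk <- tapply(rk, labels, mean)
  n_g <- tapply(rk, labels, length)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  combs <- utils::combn(lev, 2L)
  z <- p <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[i] <- (mean_rk[[a]] - mean_rk[[b]]) / se
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  pw <- data.frame(group1 = combs[1, ], group2 = combs[2, ], z = z,
                   p = p, p_adj = p.adjust(p, method = adjust),
                   stringsAsFactors = FALSE)
  list(h = unname(kw$statistic), p_value = kw$p.value, pairwise = pw,
       adjust = adjust)
}
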