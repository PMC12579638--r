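#' Pairwise Pearson correlations around selected center features
#'
#' Correlates each center feature against every other interaction column of
#' the (unimputed) mean-rank matrix using pairwise-complete samples, so
#' interactions that were filtered out of the multivariate stage for
#' missingness still participate. Edges supported by fewer than
#' `min_overlap` common samples, or with zero variance on the overlap, are
#' skipped. Center-center pairs are kept once (undirected).
#'
#' @param centers character vector of center feature ids (must be columns of
#'   `mat`).
#' @param mat sample-by-interaction matrix with `NA` for missing values.
#' @param min_overlap minimum number of samples with both values present
#'   (default 5).
#' @return Data frame of edges: `center`, `partner`, `r`, `n_pairs`, `sign`.
#' @export
pairwise_pearson <- function(centers, mat, min_overlap = 5L) {
  missing_c <- setdiff(centers, colnames(mat))
  if (length(missing_c))
    stop("center(s) not in matrix: ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  empty <- centers[colSums(!is.na(mat[, centers, drop = FALSE])) == 0L]
  if (length(empty))
    stop("center column(s) entirely missing: ",
         paste(empty, collapse = ", "), call. = FALSE)
  obs <- !is.na(mat)
  n_pairs <- crossprod(obs[, centers, drop = FALSE] * 1, obs * 1)
  r <- suppressWarnings(cor(mat[, centers, drop = FALSE], mat,
                            use = "pairwise.complete.obs"))
  edges <- NULL
  seen <- character(0)
  for (ci in centers) {
    for (f in colnames(mat)) {
      if (f == ci) next
      if (f %in% centers) {           # undirected center-center edge
        key <- paste(sort(c(ci, f)), collapse = "\r")
        if (key %in% seen) next
        seen <- c(seen, key)
      }
      np <- n_pairs[ci, f]
      rr <- r[ci, f]
      if (np < min_overlap || is.na(rr)) next
      edges <- rbind(edges, data.frame(
        center = ci, partner = f, r = rr, n_pairs = np,
        sign = if (rr >= 0) "positive" else "negative",
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges))
    edges <- data.frame(center = character(0), partner = character(0),
                        r = numeric(0), n_pairs = integer(0),
                        sign = character(0), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  edges
}

#' Strongest co-correlates per center feature
#'
#' Keeps, for each center, the `k` edges with the largest absolute Pearson
#' correlation (positive or negative alike). Ties are broken by
#' lexicographic partner id so the output is deterministic.
#'
#' @param edges edge data frame from [pairwise_pearson()].
#' @param k edges kept per center (default 5).
#' @return The filtered edge data frame.
#' @export
top_k_edges <- function(edges, k = 5L) {
  if (k < 1) stop("'k' must be >= 1", call. = FALSE)
  if (nrow(edges) == 0L) return(edges)
  parts <- split(edges, edges$center)
  out <- lapply(parts, function(df) {
    df <- df[order(-abs(df$r), df$partner, method = "radix"), , drop = FALSE]
    head(df, k)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Export the co-correlate network
#'
#' Writes the network as GraphML plus TSV node and edge tables. Nodes carry
#' an `is_center` flag and an optional enrichment-direction annotation for
#' centers; edges are weighted by the Pearson correlation coefficient with
#' the correlation direction as an attribute.
#'
#' @param edges edge data frame (typically from [top_k_edges()]).
#' @param file_prefix output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>_edges.tsv`, `<prefix>_nodes.tsv`.
#' @param centers optional character vector of center ids, so centers with
#'   no surviving edge still appear as isolated nodes.
#' @param annotations optional named character vector mapping center ids to
#'   an enrichment direction (e.g. `"R"`/`"NR"`).
#' @return Invisibly, the [igraph][igraph::graph_from_data_frame] graph.
#' @export
export_network <- function(edges, file_prefix, centers = NULL,
                           annotations = NULL) {
  centers <- sort(unique(c(centers, edges$center)))
  node_ids <- sort(unique(c(centers, edges$partner)))
  nodes <- data.frame(
    name = node_ids,
    is_center = node_ids %in% centers,
    enrichment = if (is.null(annotations)) NA_character_
      else unname(annotations[node_ids]),
    stringsAsFactors = FALSE)
  nodes$enrichment[is.na(nodes$enrichment)] <- ""
  g <- igraph::graph_from_data_frame(
    edges[, c("center", "partner", "r", "n_pairs", "sign")],
    directed = FALSE, vertices = nodes)
  if (nrow(edges)) igraph::E(g)$weight <- abs(edges$r)
  dir.create(dirname(file_prefix), showWarnings = FALSE, recursive = TRUE)
  igraph::write_graph(g, paste0(file_prefix, ".graphml"),
                      format = "graphml")
  write.table(edges, paste0(file_prefix, "_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(nodes, paste0(file_prefix, "_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(g)
}
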