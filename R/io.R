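#' Canonical feature identity of a directed ligand-receptor interaction
#'
#' A feature is identified by the full directed key: sender cell type,
#' receiver cell type, ligand complex and receptor complex, so the same LR
#' pair between different cell-type pairs is a distinct feature. Complex
#' subunits (underscore-separated) are put into a canonical sorted order so
#' keys are stable across files.
#'
#' @param source,target sender and receiver cell-type labels.
#' @param ligand,receptor complex strings; subunits joined by `_`.
#' @return Character vector of feature ids `sender|receiver|ligand|receptor`.
#' @export
make_feature_id <- function(source, target, ligand, receptor) {
  paste(source, target, canonical_complex(ligand),
        canonical_complex(receptor), sep = "|")
}

#' @rdname make_feature_id
#' @param x a character vector of complex strings.
#' @export
canonical_complex <- function(x) {
  vapply(strsplit(as.character(x), "_", fixed = TRUE),
         function(p) paste(sort(p), collapse = "_"), character(1))
}

.required_cols <- c("sample_id", "source", "target",
                    "ligand_complex", "receptor_complex", "aggregate_rank")

#' Read ranked interaction tables
#'
#' Reads delimited interaction tables (TSV, or CSV when the file extension is
#' `.csv`) with columns `sample_id`, `source`, `target`, `ligand_complex`,
#' `receptor_complex`, one `<method>_rank` column per inference method, and
#' `aggregate_rank`. The mean rank is (re)computed as the arithmetic mean of
#' the method ranks present in each row.
#'
#' @param paths character vector of file paths; files may contain several
#'   samples, distinguished by `sample_id`.
#' @return Named list mapping each sample id to its interaction data frame
#'   (with a `feature_id` and `mean_rank` column appended).
#' @export
read_interaction_tables <- function(paths) {
  recs <- list()
  for (path in paths) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- if (grepl("\\.csv$", path, ignore.case = TRUE))
      read.csv(path, stringsAsFactors = FALSE)
    else read.delim(path, stringsAsFactors = FALSE)
    missing_cols <- setdiff(.required_cols, names(df))
    if (length(missing_cols))
      stop("file ", path, ": missing column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    method_cols <- setdiff(grep("_rank$", names(df), value = TRUE),
                           c("aggregate_rank", "mean_rank"))
    if (length(method_cols) == 0L)
      stop("file ", path, ": no <method>_rank columns found", call. = FALSE)
    if (nrow(df) == 0L) next
    for (cc in c(method_cols, "aggregate_rank")) {
      if (!is.numeric(df[[cc]]))
        stop("file ", path, ": column '", cc, "' is not numeric",
             call. = FALSE)
    }
    bad <- which(is.na(df$aggregate_rank) | df$aggregate_rank <= 0 |
                   df$aggregate_rank > 1)
    if (length(bad))
      stop("file ", path, ", line ", bad[1] + 1L,
           ": aggregate_rank outside (0, 1]", call. = FALSE)
    mr <- as.matrix(df[, method_cols, drop = FALSE])
    bad <- which(apply(mr, 1L, function(r) any(r[!is.na(r)] < 1)))
    if (length(bad))
      stop("file ", path, ", line ", bad[1] + 1L,
           ": method rank < 1", call. = FALSE)
    bad <- which(rowSums(!is.na(mr)) == 0L)
    if (length(bad))
      stop("file ", path, ", line ", bad[1] + 1L,
           ": no method rank present", call. = FALSE)
    df$mean_rank <- rowMeans(mr, na.rm = TRUE)
    df$feature_id <- make_feature_id(df$source, df$target,
                                     df$ligand_complex, df$receptor_complex)
    for (sid in unique(df$sample_id)) {
      sub <- df[df$sample_id == sid, , drop = FALSE]
      if (anyDuplicated(sub$feature_id))
        stop("file ", path, ": duplicated interaction key '",
             sub$feature_id[duplicated(sub$feature_id)][1],
             "' in sample ", sid, call. = FALSE)
      if (!is.null(recs[[sid]]))
        stop("sample ", sid, " appears in more than one table", call. = FALSE)
      rownames(sub) <- NULL
      recs[[sid]] <- sub
    }
  }
  recs
}

#' Write interaction tables to delimited text
#'
#' Inverse of [read_interaction_tables()]: writes one TSV per sample into
#' `dir`, named `<sample_id>.tsv`. Derived columns (`mean_rank`,
#' `feature_id`) are recomputed on read, so write-then-read is the identity
#' on records.
#'
#' @param tables named list of interaction data frames.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_interaction_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sid in names(tables)) {
    df <- tables[[sid]]
    df$feature_id <- NULL
    path <- file.path(dir, paste0(sid, ".tsv"))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Mean rank across inference methods
#'
#' The per-interaction mean rank is the arithmetic mean of the interaction's
#' rank across the inference methods; when a method's rank is absent the mean
#' is taken over the methods present.
#'
#' @param method_ranks numeric vector of per-method ranks (NA = absent).
#' @return The mean rank.
#' @export
compute_mean_rank <- function(method_ranks) {
  r <- method_ranks[!is.na(method_ranks)]
  if (length(r) == 0L) stop("no method rank present", call. = FALSE)
  if (any(r < 1)) stop("method ranks must be >= 1", call. = FALSE)
  mean(r)
}

#' Assemble the sample-by-interaction mean-rank matrix
#'
#' Columns are the union of all interaction keys across samples, ordered
#' lexicographically; a cell is `NA` wherever a sample lacks that
#' interaction.
#'
#' @param records named list of interaction data frames (one per sample), as
#'   returned by [read_interaction_tables()] or
#'   [simulate_interaction_cohort()].
#' @param annotations data frame with at least a `sample_id` column; every
#'   sample in `records` must be annotated.
#' @return Numeric matrix (samples x interactions) of mean ranks with `NA`
#'   for missing entries.
#' @export
build_rank_matrix <- function(records, annotations) {
  sids <- names(records)
  missing_ann <- setdiff(sids, annotations$sample_id)
  if (length(missing_ann))
    stop("no annotation for sample(s): ",
         paste(missing_ann, collapse = ", "), call. = FALSE)
  keys <- sort(unique(unlist(lapply(records, `[[`, "feature_id"),
                             use.names = FALSE)), method = "radix")
  mat <- matrix(NA_real_, nrow = length(sids), ncol = length(keys),
                dimnames = list(sids, keys))
  for (sid in sids) {
    df <- records[[sid]]
    mat[sid, df$feature_id] <- df$mean_rank
  }
  mat
}

#' Interaction display score
#'
#' `1 / ln(mean rank)`: a strictly decreasing transform of the mean rank, so
#' larger scores correspond to stronger (better-ranked) interactions. Only
#' defined for mean ranks > 1.
#'
#' @param mean_rank numeric vector of mean ranks, all > 1.
#' @return `1 / log(mean_rank)`.
#' @export
interaction_score <- function(mean_rank) {
  if (any(is.na(mean_rank)) || any(mean_rank <= 1))
    stop("interaction_score requires mean ranks > 1", call. = FALSE)
  1 / log(mean_rank)
}
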