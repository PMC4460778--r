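#' Genes-by-samples expression container
#'
#' A `coex_matrix` bundles a numeric genes x samples matrix with per-sample
#' batch and class annotation.  It is the single currency passed between the
#' integration, biclustering and refinement stages.  Gene and sample
#' identifiers live in the matrix `dimnames`; the metadata is an ordinary
#' tibble so it can be manipulated with dplyr.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.  Row and
#'   column names are required and must be unique.
#' @param sample_meta Data frame with columns `sample_id`, `batch`, `class`;
#'   one row per column of `values` (order is aligned automatically).
#' @return An object of class `coex_matrix`: a list with elements `values`
#'   (the matrix) and `meta` (a tibble, in column order of `values`).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    batch = "b1", class = c("AD", "AD", "CTRL", "CTRL"))
#' cm <- coex_matrix(m, meta)
#' dim(cm)
#' @export
coex_matrix <- function(values, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene row names and sample column names.")
  }
  if (anyDuplicated(rownames(values))) abort("Duplicate gene ids.")
  if (anyDuplicated(colnames(values))) abort("Duplicate sample ids.")
  meta <- as_tibble(sample_meta)
  req <- c("sample_id", "batch", "class")
  if (!all(req %in% names(meta))) {
    abort("`sample_meta` needs columns sample_id, batch, class.")
  }
  meta <- meta[, req]
  if (!setequal(meta$sample_id, colnames(values)) ||
      nrow(meta) != ncol(values)) {
    abort("`sample_meta` must describe exactly the samples in `values`.")
  }
  meta <- meta[match(colnames(values), meta$sample_id), ]
  bad <- setdiff(unique(meta$class), all_classes())
  if (length(bad)) {
    abort(paste0("Unknown class label(s): ", paste(bad, collapse = ", ")))
  }
  structure(list(values = values, meta = meta), class = "coex_matrix")
}

#' @export
dim.coex_matrix <- function(x) dim(x$values)

#' @export
print.coex_matrix <- function(x, ...) {
  cat(sprintf("<coex_matrix> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("batches: ", paste(unique(x$meta$batch), collapse = ", "), "\n")
  cls <- table(x$meta$class)
  cat("classes: ",
      paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

stopifnot_coex <- function(x) {
  if (!inherits(x, "coex_matrix")) abort("Expected a `coex_matrix`.")
  invisible(x)
}

#' Map classes to their sample ids
#'
#' Builds the class -> sample-id lookup used by the refinement stage: one
#' entry per class present in the metadata.  Classes are the eight disease
#' labels plus `"CTRL"`; sample sets are disjoint by construction.
#'
#' @param x A [coex_matrix()].
#' @return Named list of character vectors of sample ids.
#' @export
class_map <- function(x) {
  stopifnot_coex(x)
  split(x$meta$sample_id, x$meta$class)
}

#' Read and write expression tables
#'
#' Plain TSV interchange: the expression table has gene ids in the first
#' column (`gene_id`) and one column per sample; the metadata table has
#' columns `sample_id`, `batch`, `class`.
#'
#' @param expr_path,meta_path Paths to tab-separated files.
#' @return `read_coex_tsv()` returns a [coex_matrix()]; the writers return
#'   their path invisibly.
#' @export
read_coex_tsv <- function(expr_path, meta_path) {
  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  values <- as.matrix(expr[, -1, drop = FALSE])
  rownames(values) <- expr[[1]]
  coex_matrix(values, meta)
}

#' @rdname read_coex_tsv
#' @param x A [coex_matrix()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix for the two TSVs.
#' @export
write_coex_tsv <- function(x, dir, prefix = "expression") {
  stopifnot_coex(x)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_path <- file.path(dir, paste0(prefix, ".tsv"))
  meta_path <- file.path(dir, paste0(prefix, "_meta.tsv"))
  df <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr = expr_path, meta = meta_path))
}

#' Subset a coex_matrix by samples
#'
#' @param x A [coex_matrix()].
#' @param samples Character vector of sample ids to keep.
#' @return A [coex_matrix()] restricted to `samples` (in matrix order).
#' @keywords internal
subset_samples <- function(x, samples) {
  keep <- colnames(x$values) %in% samples
  coex_matrix(x$values[, keep, drop = FALSE], x$meta[keep, ])
}
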