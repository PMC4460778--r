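#' Invert a log transform
#'
#' Replaces every value `v` by `base^v`.  Used to undo log2 preprocessing
#' of a dataset before quantile normalization, so all cohorts enter the
#' merge on a comparable intensity scale.
#'
#' @param x A [coex_matrix()].
#' @param base Logarithm base that was originally applied; the default 2
#'   matches log2-transformed microarray intensities.
#' @return A [coex_matrix()] of identical shape and metadata.
#' @export
unlog_transform <- function(x, base = 2) {
  stopifnot_coex(x)
  if (!is.numeric(base) || base <= 0) abort("`base` must be positive.")
  if (!all(is.finite(x$values))) abort("All values must be finite.")
  out <- x
  out$values <- base^x$values
  out
}

#' Quantile-normalize samples
#'
#' Forces every sample (column) onto the common reference distribution of
#' row-wise mean order statistics; ties within a column receive the mean
#' of the reference values at their tied ranks.  Delegates to
#' `limma::normalizeQuantiles()`, the same routine used in the analysis
#' this package reproduces.
#'
#' @param x A [coex_matrix()] with at least 2 samples and no missing
#'   values (filter incomplete probes first).
#' @return A [coex_matrix()], same shape and metadata.
#' @export
quantile_normalize <- function(x) {
  stopifnot_coex(x)
  if (ncol(x$values) < 2) abort("Need at least 2 samples.")
  if (anyNA(x$values)) {
    abort("Missing values present; drop incomplete probes before normalizing.")
  }
  out <- x
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  out$values <- v
  out
}

#' Collapse probes to genes by averaging
#'
#' Maps probe-level rows to gene ids and averages all probes of a gene
#' into one row.  Probes absent from the map are dropped.
#'
#' @param x A [coex_matrix()] whose rows are probe ids.
#' @param probe_map Data frame with columns `probe_id` and `gene_id`
#'   (many probes to one gene; each probe maps to exactly one gene).
#' @return A [coex_matrix()] with one row per mapped gene, rows in
#'   lexicographic gene order.
#' @export
collapse_probes <- function(x, probe_map) {
  stopifnot_coex(x)
  pm <- as_tibble(probe_map)
  if (!all(c("probe_id", "gene_id") %in% names(pm))) {
    abort("`probe_map` needs columns probe_id and gene_id.")
  }
  if (anyDuplicated(pm$probe_id)) {
    abort("Each probe must map to exactly one gene id.")
  }
  pm <- pm[pm$probe_id %in% gene_ids(x), ]
  if (!nrow(pm)) abort("No probe of the matrix appears in `probe_map`.")
  grouped <- rowsum(x$values[pm$probe_id, , drop = FALSE],
                    group = pm$gene_id)
  counts <- as.vector(table(pm$gene_id)[rownames(grouped)])
  collapsed <- grouped / counts
  collapsed <- collapsed[order(rownames(collapsed)), , drop = FALSE]
  coex_matrix(collapsed, x$meta)
}

#' Stack datasets over their common genes
#'
#' Restricts every input matrix to the gene-id intersection and
#' concatenates samples, keeping each dataset's batch labels.  Genes come
#' out in lexicographic order for reproducibility.
#'
#' @param matrices List of two or more [coex_matrix()] objects with
#'   disjoint sample ids and a gene intersection of at least 2.
#' @return A single [coex_matrix()].
#' @export
intersect_and_stack <- function(matrices) {
  if (length(matrices) < 2) abort("Need at least 2 matrices.")
  lapply(matrices, stopifnot_coex)
  common <- Reduce(intersect, lapply(matrices, gene_ids))
  if (length(common) < 2) abort("Gene intersection has fewer than 2 genes.")
  common <- sort(common)
  all_samples <- unlist(lapply(matrices, sample_ids))
  if (anyDuplicated(all_samples)) {
    abort("Sample ids collide across datasets.")
  }
  values <- do.call(cbind, lapply(matrices, function(m) {
    m$values[common, , drop = FALSE]
  }))
  meta <- dplyr::bind_rows(lapply(matrices, `[[`, "meta"))
  coex_matrix(values, meta)
}

#' Empirical-Bayes batch adjustment (parametric ComBat)
#'
#' Removes additive and multiplicative batch effects by the parametric
#' empirical-Bayes location/scale model: genes are standardized against
#' the batch-size-weighted grand mean and pooled variance, per-batch
#' gene-wise location (normal prior) and scale (inverse-gamma prior)
#' effects are shrunk by iterated conditional posterior means, removed,
#' and the data back-transformed.  No biological covariates enter the
#' model, so class labels cannot leak into the adjustment.
#'
#' Genes with zero overall variance cannot be standardized; they are
#' passed through unchanged with a warning.
#'
#' @param x A [coex_matrix()] with at least 2 batches of at least 2
#'   samples each.
#' @param conv Convergence tolerance of the empirical-Bayes iteration
#'   (maximum relative parameter change).
#' @return A [coex_matrix()], same shape and metadata.
#' @export
combat_adjust <- function(x, conv = 1e-4) {
  stopifnot_coex(x)
  batches <- x$meta$batch
  levels_b <- unique(batches)
  if (length(levels_b) < 2) abort("ComBat needs at least 2 batches.")
  n_per <- table(batches)[levels_b]
  if (any(n_per < 2)) abort("Every batch needs at least 2 samples.")

  dat <- x$values
  n_array <- ncol(dat)
  gene_var <- apply(dat, 1, var)
  flat <- gene_var == 0
  if (any(flat)) {
    warn(sprintf("%d zero-variance gene(s) passed through unadjusted.",
                 sum(flat)))
  }
  work <- dat[!flat, , drop = FALSE]

  # per-batch gene means and batch-size-weighted grand mean
  batch_mean <- vapply(levels_b, function(b) {
    rowMeans(work[, batches == b, drop = FALSE])
  }, numeric(nrow(work)))
  w <- as.vector(n_per) / n_array
  grand <- as.vector(batch_mean %*% w)
  resid <- work - batch_mean[, match(batches, levels_b), drop = FALSE]
  var_pooled <- rowSums(resid^2) / n_array
  s_data <- (work - grand) / sqrt(var_pooled)

  gamma_star <- delta_star <- matrix(0, nrow(work), length(levels_b))
  for (j in seq_along(levels_b)) {
    cols <- batches == levels_b[j]
    n_b <- sum(cols)
    g_hat <- rowMeans(s_data[, cols, drop = FALSE])
    d_hat <- apply(s_data[, cols, drop = FALSE], 1, var)
    g_bar <- mean(g_hat); t2 <- var(g_hat)
    m_d <- mean(d_hat); s2_d <- var(d_hat)
    a_prior <- (2 * s2_d + m_d^2) / s2_d
    b_prior <- (m_d * s2_d + m_d^3) / s2_d
    g_new <- g_hat; d_new <- d_hat
    repeat {
      g_old <- g_new; d_old <- d_new
      g_new <- (t2 * n_b * g_hat + d_old * g_bar) / (t2 * n_b + d_old)
      sum2 <- rowSums((s_data[, cols, drop = FALSE] - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior) / (n_b / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old))
      if (change < conv) break
    }
    gamma_star[, j] <- g_new
    delta_star[, j] <- d_new
  }

  idx <- match(batches, levels_b)
  adj <- (s_data - gamma_star[, idx, drop = FALSE]) /
    sqrt(delta_star[, idx, drop = FALSE])
  adj <- adj * sqrt(var_pooled) + grand

  out <- x
  out$values[!flat, ] <- adj
  out
}

#' Merge preprocessed datasets into one adjusted matrix
#'
#' Convenience wrapper for the whole integration stage: optionally un-log
#' selected datasets, quantile-normalize each, collapse probes where a map
#' is given, stack over the common gene set and adjust batch effects.
#'
#' @param matrices List of [coex_matrix()] objects (one per dataset, each
#'   with its own batch label).
#' @param probe_maps Optional list (same length, `NULL` entries allowed)
#'   of probe-to-gene maps for [collapse_probes()].
#' @param unlog Logical vector marking datasets stored on a log scale that
#'   must be inverted first; `unlog_base` is the log base used.
#' @param unlog_base Base for [unlog_transform()].
#' @return A batch-adjusted [coex_matrix()] over the common genes.
#' @export
integrate_datasets <- function(matrices, probe_maps = NULL,
                               unlog = rep(FALSE, length(matrices)),
                               unlog_base = 2) {
  prepped <- lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    if (isTRUE(unlog[i])) m <- unlog_transform(m, base = unlog_base)
    m <- quantile_normalize(m)
    if (!is.null(probe_maps) && !is.null(probe_maps[[i]])) {
      m <- collapse_probes(m, probe_maps[[i]])
    }
    m
  })
  combat_adjust(intersect_and_stack(prepped))
}

#' Quantile-normalize and batch-adjust one pre-stacked cohort
#'
#' For a single matrix that already contains several batches (the
#' synthetic generator's output), the per-dataset half of the integration
#' stage is applied batch by batch before the joint ComBat adjustment.
#'
#' @param x A multi-batch [coex_matrix()].
#' @return A [coex_matrix()], quantile-normalized within each batch and
#'   batch-adjusted.
#' @export
integrate_cohort <- function(x) {
  stopifnot_coex(x)
  per_batch <- lapply(unique(x$meta$batch), function(b) {
    quantile_normalize(subset_samples(x, x$meta$sample_id[x$meta$batch == b]))
  })
  if (length(per_batch) == 1) return(per_batch[[1]])
  combat_adjust(intersect_and_stack(per_batch))
}
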