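#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a refined coexpression result
#'
#' One row per significant gene set, with a readable combination label
#' alongside the raw statistics.
#'
#' @param x A `coex_refined` object from [refine_all()].
#' @param ... Unused.
#' @return A tibble with columns `combination` (label like `"ALS+MS"`),
#'   `n_diseases`, `n_genes`, `pcc_disease`, `pcc_normal`, `delta`,
#'   `direction`, `p_value`, `q_value`, `genes` (list-column).
#' @export
tidy.coex_refined <- function(x, ...) {
  sets <- x$sets
  tibble(
    combination = vapply(sets$combination, paste, "", collapse = "+"),
    n_diseases = lengths(sets$combination),
    n_genes = lengths(sets$genes),
    pcc_disease = sets$pcc_disease,
    pcc_normal = sets$pcc_normal,
    delta = sets$delta,
    direction = sets$direction,
    p_value = sets$p_value,
    q_value = sets$q_value,
    genes = sets$genes)
}

#' @rdname tidy.coex_refined
#' @export
glance.coex_refined <- function(x, ...) {
  parts <- partition_shared(x$sets)
  tibble(n_input = x$n_input,
         n_rejected = x$n_rejected,
         n_ctrl_only = x$n_ctrl_only,
         n_tested = nrow(x$tested),
         n_significant = nrow(x$sets),
         n_shared = nrow(parts$shared),
         n_specific = nrow(parts$specific),
         n_gain = sum(x$sets$direction == "gain"),
         n_loss = sum(x$sets$direction == "loss"),
         alpha = x$alpha, n_draws = x$n_draws, seed = x$seed)
}

#' Heatmap of pairwise disease sharing counts
#'
#' @param counts Symmetric count matrix from [pairwise_counts()].
#' @return A ggplot object.
#' @export
plot_pairwise_counts <- function(counts) {
  df <- as.data.frame.table(counts, responseName = "n",
                            stringsAsFactors = FALSE)
  names(df)[1:2] <- c("disease_a", "disease_b")
  dz <- disease_classes()
  df$disease_a <- factor(df$disease_a, levels = dz)
  df$disease_b <- factor(df$disease_b, levels = rev(dz))
  ggplot2::ggplot(df, ggplot2::aes(.data$disease_a, .data$disease_b,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#c0392b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "gene sets",
                  title = "Gene sets shared between disease pairs") +
    ggplot2::theme_minimal()
}

#' Bar chart of the most frequent genes
#'
#' @param top Tibble from [top_genes()].
#' @return A ggplot object.
#' @export
plot_top_genes <- function(top) {
  top$gene <- factor(top$gene, levels = rev(top$gene))
  ggplot2::ggplot(top, ggplot2::aes(.data$n_sets, .data$gene)) +
    ggplot2::geom_col(fill = "#2c3e50") +
    ggplot2::labs(x = "gene sets containing the gene", y = NULL) +
    ggplot2::theme_minimal()
}

#' Fold-ratio chart of category enrichment
#'
#' @param fold Tibble from [fold_comparison()] (infinite folds are
#'   dropped from the plot).
#' @return A ggplot object.
#' @export
plot_fold_comparison <- function(fold) {
  df <- fold[is.finite(fold$fold), ]
  df$category <- factor(df$category, levels = rev(df$category))
  ggplot2::ggplot(df, ggplot2::aes(.data$fold, .data$category)) +
    ggplot2::geom_col(fill = "#16a085") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "shared / specific fraction", y = NULL,
                  title = "Category representation, shared vs specific") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for pipeline result objects
#'
#' `autoplot()` on a bicluster table shows the size/quality landscape of
#' the search; on a refined result it shows each tested set's disease
#' and normal coexpression with survivors highlighted.
#'
#' @param object A `coex_biclusters` tibble or `coex_refined` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coex_biclusters <- function(object, ...) {
  df <- tibble(n_genes = object$n_genes, n_samples = object$n_samples,
               avg_pcc = object$avg_pcc)
  ggplot2::ggplot(df, ggplot2::aes(.data$n_samples, .data$n_genes,
                                   colour = .data$avg_pcc)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_viridis_c(limits = c(NA, 1)) +
    ggplot2::labs(x = "samples", y = "genes", colour = "avg PCC",
                  title = "Emitted biclusters") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.coex_biclusters
#' @export
autoplot.coex_refined <- function(object, ...) {
  df <- object$tested
  df$significant <- df$q_value <= object$alpha
  ggplot2::ggplot(df, ggplot2::aes(.data$pcc_normal, .data$pcc_disease,
                                   colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#c0392b")) +
    ggplot2::labs(x = "avg PCC, normal", y = "avg PCC, disease",
                  colour = sprintf("q <= %g", object$alpha),
                  title = "Gain and loss of coexpression") +
    ggplot2::theme_minimal()
}
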