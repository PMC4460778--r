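#' Select class-complete biclusters and trim partial classes
#'
#' A bicluster is kept only if it contains *all* samples of at least one
#' disease class (or, failing that, all controls).  Samples belonging to
#' classes only partially covered -- including a partial control class --
#' are removed.  The set of completely covered disease classes becomes the
#' bicluster's disease combination.
#'
#' @param bicluster List with character vectors `genes` and `samples`.
#' @param class_map Named list mapping class labels to sample-id vectors,
#'   as from [class_map()].
#' @return `NULL` when rejected; otherwise a list with `genes`,
#'   `combination` (complete disease classes, possibly empty when only
#'   CTRL is complete) and `samples` (union of complete classes' samples).
#' @export
select_and_trim <- function(bicluster, class_map) {
  samp <- bicluster$samples
  complete <- names(class_map)[vapply(class_map, function(s) {
    length(s) > 0 && all(s %in% samp)
  }, TRUE)]
  combination <- intersect(disease_classes(), complete)
  ctrl_complete <- control_class() %in% complete
  if (!length(combination) && !ctrl_complete) return(NULL)
  keep <- sort(unique(unlist(class_map[complete])))
  list(genes = sort(bicluster$genes),
       combination = combination,
       samples = intersect(keep, samp) |> sort())
}

#' Gain/loss of coexpression between disease and normal
#'
#' Computes the average pairwise PCC of a gene set separately over the
#' pooled samples of its disease combination and over all control
#' samples, and returns the difference.  A positive difference is a gain
#' of coexpression in disease, a negative one a loss.
#'
#' @param x A [coex_matrix()].
#' @param genes Character vector of at least 2 gene ids.
#' @param combination Character vector of disease class labels.
#' @param class_map Named list from [class_map()].
#' @return Tibble with columns `pcc_disease`, `pcc_normal`, `delta`.
#' @export
coexpression_delta <- function(x, genes, combination, class_map) {
  if (length(genes) < 2) abort("Need at least 2 genes.")
  if (!length(combination)) abort("Empty disease combination.")
  disease <- sort(unique(unlist(class_map[combination])))
  normal <- class_map[[control_class()]]
  if (length(disease) < 3 || length(normal) < 3) {
    abort("Need at least 3 samples on both the disease and control side.")
  }
  pd <- avg_pcc(x, genes, disease)
  pn <- avg_pcc(x, genes, normal)
  tibble(pcc_disease = pd, pcc_normal = pn, delta = pd - pn)
}

#' Permutation null for the coexpression difference
#'
#' Draws `n_draws` gene groups of the tested set's size uniformly without
#' replacement from all genes and records each group's disease-vs-normal
#' average-PCC difference over the *same* disease combination.  The
#' distribution is reusable for every tested set with the same size and
#' combination.
#'
#' @inheritParams coexpression_delta
#' @param set_size Number of genes per random group (>= 2).
#' @param n_draws Number of random groups (the reference analysis used
#'   100,000).
#' @param seed Integer seed; identical seeds give identical draws.
#' @return A `null_distribution` object: list with `set_size`,
#'   `combination`, `deltas`, `n_draws`, `seed`.
#' @export
build_null <- function(x, set_size, combination, class_map,
                       n_draws = 100000L, seed = 1L) {
  stopifnot_coex(x)
  if (set_size < 2) abort("`set_size` must be >= 2.")
  if (n_draws < 1) abort("`n_draws` must be >= 1.")
  n_genes <- nrow(x$values)
  if (set_size > n_genes) abort("`set_size` exceeds the gene count.")
  disease <- sort(unique(unlist(class_map[combination])))
  normal <- class_map[[control_class()]]
  Zd <- scaled_rows(x$values[, disease, drop = FALSE])
  Zn <- scaled_rows(x$values[, normal, drop = FALSE])
  npairs <- set_size * (set_size - 1)
  deltas <- numeric(n_draws)
  withr::with_seed(seed, {
    for (i in seq_len(n_draws)) {
      idx <- sample.int(n_genes, set_size)
      deltas[i] <- block_avg(Zd, idx, npairs) - block_avg(Zn, idx, npairs)
    }
  })
  structure(list(set_size = as.integer(set_size),
                 combination = sort(combination),
                 deltas = deltas, n_draws = as.integer(n_draws),
                 seed = as.integer(seed)),
            class = "null_distribution")
}

# rows standardized so that tcrossprod gives correlations; zero-variance
# rows become all-zero (their pairs contribute 0, matching avg_pcc)
scaled_rows <- function(mat) {
  m <- ncol(mat)
  sds <- apply(mat, 1, sd)
  Z <- matrix(0, nrow(mat), m, dimnames = dimnames(mat))
  ok <- sds > 0
  Z[ok, ] <- t(scale(t(mat[ok, , drop = FALSE]))) / sqrt(m - 1)
  attr(Z, "nonzero") <- ok
  Z
}

block_avg <- function(Z, idx, npairs) {
  u <- colSums(Z[idx, , drop = FALSE])
  n_nz <- sum(attr(Z, "nonzero")[idx])
  (sum(u * u) - n_nz) / npairs
}

#' Add-one empirical p-value
#'
#' Two-sided permutation p-value of an observed difference against a null
#' distribution: `(1 + #\{|d| >= |delta|\}) / (n_draws + 1)`.  The add-one
#' form keeps p strictly positive and inside (0, 1].
#'
#' @param delta Observed coexpression difference.
#' @param null A `null_distribution` from [build_null()].
#' @return A single p-value.
#' @export
empirical_p <- function(delta, null) {
  if (!inherits(null, "null_distribution") || !length(null$deltas)) {
    abort("`null` must be a non-empty null_distribution.")
  }
  (1 + sum(abs(null$deltas) >= abs(delta))) / (null$n_draws + 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order (delegates to
#' `stats::p.adjust`).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, capped at 1.
#' @export
bh_correct <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) ||
      any(p_values > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Refine biclusters into significant gain/loss gene sets
#'
#' The full refinement stage: each bicluster is reduced to its complete
#' disease classes ([select_and_trim()]); the disease-vs-normal average
#' PCC difference is computed ([coexpression_delta()]) and referred to a
#' permutation null of random same-size gene groups over the same
#' combination (nulls cached per size/combination, seeds derived
#' deterministically from `seed`); p-values are BH-adjusted jointly over
#' all tested sets and survivors at `q <= alpha` are returned with their
#' gain/loss direction.
#'
#' Biclusters whose only complete class is CTRL carry no disease
#' combination and are not testable under this scheme; they are counted
#' but not tested.
#'
#' @param biclusters A `coex_biclusters` tibble from [run_biclic()] (or
#'   any tibble with `genes`/`samples` list-columns).
#' @param x The [coex_matrix()] the biclusters came from.
#' @param class_map Named list from [class_map()]; defaults to
#'   `class_map(x)`.
#' @param alpha FDR threshold on the adjusted q-value (reference analysis:
#'   0.005).
#' @param n_draws Random gene groups per null distribution.
#' @param seed Master seed for all nulls.
#' @return A `coex_refined` object; `tidy()` gives the surviving sets,
#'   `glance()` a one-row run summary, and `$tested` holds every tested
#'   set with its statistics.
#' @export
refine_all <- function(biclusters, x, class_map = NULL, alpha = 0.005,
                       n_draws = 100000L, seed = 1L) {
  stopifnot_coex(x)
  cmap <- class_map %||% class_map(x)
  cache <- new.env(parent = emptyenv())
  rows <- list()
  n_rejected <- 0L; n_ctrl_only <- 0L
  for (i in seq_len(nrow(biclusters))) {
    sel <- select_and_trim(list(genes = biclusters$genes[[i]],
                                samples = biclusters$samples[[i]]), cmap)
    if (is.null(sel)) { n_rejected <- n_rejected + 1L; next }
    if (!length(sel$combination)) { n_ctrl_only <- n_ctrl_only + 1L; next }
    stats <- coexpression_delta(x, sel$genes, sel$combination, cmap)
    key <- paste(length(sel$genes),
                 paste(sort(sel$combination), collapse = "+"))
    if (is.null(cache[[key]])) {
      cache[[key]] <- build_null(x, length(sel$genes), sel$combination,
                                 cmap, n_draws = n_draws,
                                 seed = derive_seed(seed, key))
    }
    rows[[length(rows) + 1L]] <- tibble(
      genes = list(sel$genes), combination = list(sort(sel$combination)),
      pcc_disease = stats$pcc_disease, pcc_normal = stats$pcc_normal,
      delta = stats$delta,
      p_value = empirical_p(stats$delta, cache[[key]]))
  }
  tested <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(genes = list(), combination = list(), pcc_disease = numeric(),
           pcc_normal = numeric(), delta = numeric(), p_value = numeric())
  if (nrow(tested)) {
    key <- vapply(seq_len(nrow(tested)), function(i) {
      paste(set_key(tested$genes[[i]]),
            paste(tested$combination[[i]], collapse = "+"))
    }, "")
    tested <- tested[order(key), ]
    tested <- tested[!duplicated(key[order(key)]), ]
    tested$q_value <- bh_correct(tested$p_value)
    tested$direction <- ifelse(tested$delta > 0, "gain", "loss")
  } else {
    tested$q_value <- numeric(0)
    tested$direction <- character(0)
  }
  structure(list(sets = tested[tested$q_value <= alpha, , drop = FALSE],
                 tested = tested,
                 n_input = nrow(biclusters),
                 n_rejected = n_rejected,
                 n_ctrl_only = n_ctrl_only,
                 alpha = alpha, n_draws = as.integer(n_draws),
                 seed = as.integer(seed)),
            class = "coex_refined")
}

#' @export
print.coex_refined <- function(x, ...) {
  cat(sprintf(paste0("<coex_refined> %d biclusters -> %d tested -> %d ",
                     "significant at q <= %g\n"),
              x$n_input, nrow(x$tested), nrow(x$sets), x$alpha))
  cat(sprintf("  rejected (no complete class): %d; control-only: %d; ",
              x$n_rejected, x$n_ctrl_only))
  cat(sprintf("null draws: %d, seed: %d\n", x$n_draws, x$seed))
  invisible(x)
}

# deterministic 31-bit seed from a master seed and a cache key, so each
# null distribution is reproducible independent of evaluation order
derive_seed <- function(master, key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer((as.double(master) * 48271 + h) %% 2147483647)
}

#' Write refined gene sets as a flat table
#'
#' One row per significant set: a 0/1 flag column per disease, the two
#' average PCCs, p and q, direction, and the comma-joined gene list.
#'
#' @param refined A `coex_refined` object.
#' @param path Output TSV path (use `tidy(refined)` for the in-memory
#'   version).
#' @return `path`, invisibly.
#' @export
write_refined_tsv <- function(refined, path) {
  utils::write.table(refined_flat(refined$sets), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

refined_flat <- function(sets) {
  flags <- vapply(disease_classes(), function(d) {
    vapply(sets$combination, function(cmb) as.integer(d %in% cmb), 0L)
  }, integer(nrow(sets)))
  if (nrow(sets) == 0) {
    flags <- matrix(integer(0), 0, length(disease_classes()),
                    dimnames = list(NULL, disease_classes()))
  }
  dplyr::bind_cols(
    as_tibble(flags),
    tibble(pcc_disease = sets$pcc_disease, pcc_normal = sets$pcc_normal,
           delta = sets$delta, p_value = sets$p_value,
           q_value = sets$q_value, direction = sets$direction,
           genes = vapply(sets$genes, paste, "", collapse = ",")))
}
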