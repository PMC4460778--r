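#' Biclustering parameters
#'
#' Tunables of the correlation-based bicluster search.  The defaults follow
#' the analysis the package reproduces: average pairwise Pearson
#' correlation threshold 0.7, at most 50 genes per bicluster, at least 2
#' genes and 3 samples (the minimum for a meaningful correlation), and
#' within-sample seed windows of 5 genes.
#'
#' @param pcc_threshold Average-PCC threshold every emitted bicluster must
#'   meet, in (0, 1].
#' @param max_genes Upper bound on genes per bicluster (samples are
#'   deliberately uncapped).
#' @param min_genes,min_samples Minimum bicluster dimensions.
#' @param seed_window Width of the within-sample expression-rank windows
#'   used for identity seeding.
#' @param cor_seeds Also derive seeds from within-class correlation graphs
#'   (see [correlation_seeds()]); recommended, since identity seeding alone
#'   has no power when gene baselines are weak relative to noise.
#' @param cor_seed_alpha Per-pair significance level of the Fisher-z gate
#'   used by [correlation_seeds()].
#' @return A `biclic_params` list.
#' @export
biclic_params <- function(pcc_threshold = 0.7, max_genes = 50L,
                          min_genes = 2L, min_samples = 3L,
                          seed_window = 5L, cor_seeds = TRUE,
                          cor_seed_alpha = 1e-5) {
  if (!(pcc_threshold > 0 && pcc_threshold <= 1)) {
    abort("`pcc_threshold` must lie in (0, 1].")
  }
  if (min_genes < 2) abort("`min_genes` must be >= 2.")
  if (min_samples < 3) abort("`min_samples` must be >= 3.")
  if (seed_window < 2) abort("`seed_window` must be >= 2.")
  structure(list(pcc_threshold = pcc_threshold,
                 max_genes = as.integer(max_genes),
                 min_genes = as.integer(min_genes),
                 min_samples = as.integer(min_samples),
                 seed_window = as.integer(seed_window),
                 cor_seeds = isTRUE(cor_seeds),
                 cor_seed_alpha = cor_seed_alpha),
            class = "biclic_params")
}

# Pearson correlation matrix where zero-variance rows contribute 0 (never
# NA), so degenerate genes cannot inflate a bicluster's average.
safe_cor <- function(mat) {
  ctr <- mat - rowMeans(mat)
  ss <- rowSums(ctr^2)
  ok <- ss > 0
  C <- matrix(0, nrow(mat), nrow(mat),
              dimnames = list(rownames(mat), rownames(mat)))
  if (sum(ok) >= 2) {
    Z <- ctr[ok, , drop = FALSE] / sqrt(ss[ok])
    C[ok, ok] <- tcrossprod(Z)
  }
  diag(C) <- as.numeric(ok)
  C
}

mean_upper <- function(C) {
  k <- nrow(C)
  (sum(C) - sum(diag(C))) / (k * (k - 1))
}

#' Average pairwise Pearson correlation of a gene set
#'
#' The bicluster quality score: the mean of Pearson correlations over all
#' unordered gene pairs, each computed across the given samples.  A pair
#' involving a zero-variance gene contributes 0.
#'
#' @param x A [coex_matrix()].
#' @param genes Character vector of at least 2 gene ids.
#' @param samples Character vector of at least 3 sample ids.
#' @return A single number in \[-1, 1\].
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6), 2, 3, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' meta <- data.frame(sample_id = colnames(m), batch = "b", class = "CTRL")
#' avg_pcc(coex_matrix(m, meta), c("g1", "g2"), colnames(m))  # 1
#' @export
avg_pcc <- function(x, genes, samples) {
  stopifnot_coex(x)
  if (length(genes) < 2) abort("Need at least 2 genes.")
  if (length(samples) < 3) abort("Need at least 3 samples.")
  missing_g <- setdiff(genes, gene_ids(x))
  if (length(missing_g)) abort("Unknown gene id(s).")
  if (length(setdiff(samples, sample_ids(x)))) abort("Unknown sample id(s).")
  mean_upper(safe_cor(x$values[genes, samples, drop = FALSE]))
}

#' Within-sample seed windows
#'
#' Orders all genes by their expression in one sample (ties broken by gene
#' id for determinism) and cuts the ordering into consecutive windows of
#' `seed_window` genes.  A short trailing window is kept only if it still
#' has `min_genes` members.  Window membership depends only on the
#' within-sample ranks, not on the values themselves.
#'
#' @param x A [coex_matrix()].
#' @param sample_id One sample id.
#' @param params A [biclic_params()].
#' @return List of character vectors (gene-id sets).
#' @export
sample_seed_clusters <- function(x, sample_id, params = biclic_params()) {
  stopifnot_coex(x)
  if (!sample_id %in% sample_ids(x)) abort("Unknown sample id.")
  ids <- gene_ids(x)
  o <- order(x$values[, sample_id], ids)
  grp <- rep(seq_len(ceiling(length(o) / params$seed_window)),
             each = params$seed_window)[seq_along(o)]
  wins <- split(ids[o], grp)
  unname(wins[lengths(wins) >= params$min_genes])
}

set_key <- function(genes) paste(sort(genes), collapse = "\r")

#' Identity seeds from per-sample windows
#'
#' Collects, across samples, windows containing exactly the same gene set;
#' a set recurring in at least `min_samples` samples becomes a seed
#' bicluster over precisely those samples.
#'
#' @param per_sample_clusters Named list (by sample id) of window lists, as
#'   returned by [sample_seed_clusters()] for every sample.
#' @param params A [biclic_params()].
#' @return Tibble with list-columns `genes` and `samples`; zero rows when
#'   nothing recurs.
#' @export
find_seeds <- function(per_sample_clusters, params = biclic_params()) {
  n_win <- vapply(per_sample_clusters, length, 0L)
  keys <- unlist(lapply(per_sample_clusters, function(ws) {
    vapply(ws, set_key, "")
  }), use.names = FALSE)
  samp <- rep(names(per_sample_clusters), n_win)
  inc <- split(samp, keys)
  inc <- lapply(inc, unique)
  keep <- sort(names(inc)[lengths(inc) >= params$min_samples])
  tibble(genes = lapply(keep, function(k) strsplit(k, "\r", fixed = TRUE)[[1]]),
         samples = lapply(inc[keep], sort))
}

#' Correlation seeds from class strata
#'
#' For every class with at least `min_samples` samples, genes are linked
#' whenever their Pearson correlation across that class's samples exceeds
#' both `pcc_threshold` and the Fisher-z critical value at
#' `cor_seed_alpha` (one-sided, so small strata demand proportionally
#' stronger correlation and chance pairs stay rare).  Connected components
#' with at least `min_genes` genes become seeds over the stratum's
#' samples.  This supplements identity seeding, which requires near-tied
#' expression values and loses all power when gene baselines are weak.
#'
#' @inheritParams sample_seed_clusters
#' @return Tibble with list-columns `genes` and `samples`.
#' @export
correlation_seeds <- function(x, params = biclic_params()) {
  stopifnot_coex(x)
  out_g <- list(); out_s <- list()
  strata <- split(x$meta$sample_id, x$meta$class)
  for (cl in sort(names(strata))) {
    samp <- sort(strata[[cl]])
    n <- length(samp)
    if (n < params$min_samples) next
    crit <- params$pcc_threshold
    if (n > 3) {
      crit <- max(crit, tanh(stats::qnorm(1 - params$cor_seed_alpha) /
                               sqrt(n - 3)))
    }
    if (crit >= 1) next
    C <- safe_cor(x$values[, samp, drop = FALSE])
    A <- C >= crit
    diag(A) <- FALSE
    deg <- rowSums(A)
    if (!any(deg > 0)) next
    comp <- graph_components(A)
    for (genes in comp) {
      if (length(genes) < params$min_genes) next
      out_g[[length(out_g) + 1L]] <- sort(genes)
      out_s[[length(out_s) + 1L]] <- samp
    }
  }
  tibble(genes = out_g, samples = out_s)
}

# connected components (>= 2 nodes) of a logical adjacency matrix
graph_components <- function(A) {
  ids <- rownames(A)
  seen <- rep(FALSE, nrow(A))
  comps <- list()
  for (i in seq_len(nrow(A))) {
    if (seen[i] || !any(A[i, ])) next
    stack <- i; members <- integer(0)
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      members <- c(members, v)
      stack <- c(stack, which(A[v, ] & !seen))
    }
    if (length(members) >= 2) comps[[length(comps) + 1L]] <- ids[sort(members)]
  }
  comps
}

#' Greedy gene-direction expansion of a seed
#'
#' Over the seed's fixed sample set, repeatedly adds the candidate gene
#' whose inclusion yields the highest resulting average PCC, as long as
#' (a) that average stays at or above `pcc_threshold`, (b) the candidate's
#' mean correlation with the current genes itself reaches the threshold,
#' and (c) the gene count does not exceed `max_genes`.  Ties are broken by
#' lexicographic gene id.  Condition (b) keeps an uncorrelated gene from
#' hitching a ride on a strong module: a perfect 10-gene block tolerates
#' roughly 20% unrelated genes before its average dips below 0.7, and
#' without the compatibility gate every strong bicluster would absorb
#' that much noise.
#'
#' @param x A [coex_matrix()].
#' @param seed List (or one-row tibble slice) with elements `genes` and
#'   `samples`.
#' @param params A [biclic_params()].
#' @return Character vector of gene ids, a superset of the seed genes.
#' @export
expand_genes <- function(x, seed, params = biclic_params()) {
  stopifnot_coex(x)
  samples <- seed$samples
  cur <- sort(seed$genes)
  if (length(samples) < params$min_samples) {
    abort("Seed has fewer than `min_samples` samples.")
  }
  if (length(cur) < 2) abort("Seed has fewer than 2 genes.")
  m <- length(samples)
  vals <- x$values[, samples, drop = FALSE]
  sds <- apply(vals, 1, sd)
  Z <- vals
  Z[] <- 0
  ok <- sds > 0
  Z[ok, ] <- t(scale(t(vals[ok, , drop = FALSE]))) / sqrt(m - 1)
  # corr(g, h) = Z[g, ] %*% Z[h, ]; zero-variance rows are all-zero
  ids <- gene_ids(x)
  u <- colSums(Z[cur, , drop = FALSE])
  pair_sum <- (sum(u^2) - sum(ok[cur])) / 2
  repeat {
    k <- length(cur)
    if (k >= params$max_genes) break
    cand <- setdiff(ids, cur)
    if (!length(cand)) break
    gain <- as.vector(Z[cand, , drop = FALSE] %*% u)
    new_avg <- (pair_sum + gain) / choose(k + 1, 2)
    compatible <- gain / k >= params$pcc_threshold
    new_avg[!compatible] <- -Inf
    best <- order(-new_avg, cand)[1]
    if (new_avg[best] < params$pcc_threshold) break
    g <- cand[best]
    pair_sum <- pair_sum + gain[best]
    u <- u + Z[g, ]
    cur <- c(cur, g)
  }
  sort(cur)
}

#' Greedy sample-direction expansion of a seed
#'
#' Over the seed's fixed gene set, repeatedly adds the sample whose
#' inclusion yields the highest resulting average PCC while that average
#' stays at or above `pcc_threshold`.  There is no cap on samples, so a
#' pattern holding across many disease classes can spread across all of
#' them.  Ties are broken by lexicographic sample id.
#'
#' @inheritParams expand_genes
#' @return Character vector of sample ids, a superset of the seed samples.
#' @export
expand_samples <- function(x, seed, params = biclic_params()) {
  stopifnot_coex(x)
  genes <- sort(seed$genes)
  cur <- sort(seed$samples)
  if (length(genes) < 2) abort("Seed has fewer than 2 genes.")
  if (length(cur) < params$min_samples) {
    abort("Seed has fewer than `min_samples` samples.")
  }
  vals <- x$values[genes, , drop = FALSE]
  k <- length(genes)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  in_cur <- colnames(vals) %in% cur
  m <- sum(in_cur)
  s1 <- rowSums(vals[, in_cur, drop = FALSE])
  s2 <- rowSums(vals[, in_cur, drop = FALSE]^2)
  P <- tcrossprod(vals[, in_cur, drop = FALSE])
  repeat {
    cand <- setdiff(colnames(vals), cur)
    if (!length(cand)) break
    W <- vals[, cand, drop = FALSE]
    mp <- m + 1
    # per-candidate running sums after adding that sample
    t1 <- s1 + W
    den <- mp * (s2 + W^2) - t1^2          # k x C variance terms
    den[den < 0] <- 0
    avg <- numeric(length(cand))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      num <- mp * (P[i, j] + W[i, ] * W[j, ]) - t1[i, ] * t1[j, ]
      d <- sqrt(den[i, ] * den[j, ])
      rho <- ifelse(d > 0, num / d, 0)
      avg <- avg + rho
    }
    avg <- avg / nrow(pairs)
    best <- order(-avg, cand)[1]
    if (avg[best] < params$pcc_threshold) break
    v <- W[, best]
    cur <- c(cur, cand[best])
    m <- mp; s1 <- s1 + v; s2 <- s2 + v^2; P <- P + tcrossprod(v)
  }
  sort(cur)
}

#' Trim a search space to an optimal bicluster
#'
#' Starting from the full gene-space x sample-space block spanned by the
#' two expansions of one seed, elements are removed greedily until the
#' average PCC first reaches the threshold: at each step the single gene
#' whose removal raises the average most is dropped; only when no gene
#' removal raises it is a sample dropped instead.  Preferring gene
#' removals operationalizes keeping as many samples as possible.  If no
#' state at or above the threshold is reachable before hitting the minimum
#' dimensions, the seed is discarded.
#'
#' @param x A [coex_matrix()].
#' @param gene_space,sample_space Character vectors delimiting the search
#'   space.
#' @param params A [biclic_params()].
#' @return One-row tibble (`genes`, `samples` list-columns, `avg_pcc`) or
#'   `NULL` when discarded.
#' @export
optimize_bicluster <- function(x, gene_space, sample_space,
                               params = biclic_params()) {
  stopifnot_coex(x)
  genes <- sort(gene_space)
  samples <- sort(sample_space)
  if (length(genes) < params$min_genes ||
      length(samples) < params$min_samples) return(NULL)
  C <- safe_cor(x$values[genes, samples, drop = FALSE])
  cur <- mean_upper(C)
  repeat {
    if (cur >= params$pcc_threshold) {
      return(tibble(genes = list(genes), samples = list(samples),
                    avg_pcc = cur))
    }
    k <- length(genes)
    step <- NULL
    if (k > params$min_genes) {
      off <- rowSums(C) - diag(C)
      total <- sum(off) / 2
      drop_avg <- unname((total - off) / choose(k - 1, 2))
      best <- order(-drop_avg, genes)[1]
      if (drop_avg[best] > cur) {
        step <- list(kind = "gene", idx = best, avg = drop_avg[best])
      }
    }
    if (is.null(step) && length(samples) > params$min_samples) {
      drop_avg <- vapply(seq_along(samples), function(j) {
        mean_upper(safe_cor(x$values[genes, samples[-j], drop = FALSE]))
      }, 0)
      best <- order(-drop_avg, samples)[1]
      if (drop_avg[best] > cur) {
        step <- list(kind = "sample", idx = best, avg = drop_avg[best])
      }
    }
    if (is.null(step)) return(NULL)  # stalled below threshold
    if (step$kind == "gene") {
      genes <- genes[-step$idx]
      C <- C[-step$idx, -step$idx, drop = FALSE]
    } else {
      samples <- samples[-step$idx]
      C <- safe_cor(x$values[genes, samples, drop = FALSE])
    }
    cur <- step$avg
  }
}

#' Run the full bicluster search
#'
#' Seeds (window-identity seeds plus, by default, within-class correlation
#' seeds) are expanded in the gene and sample directions separately; each
#' pair of expansions spans a search space that is trimmed by
#' [optimize_bicluster()]; results are deduplicated (identical blocks
#' merged, blocks strictly contained in another emitted block dropped).
#' Deterministic for fixed input and parameters.
#'
#' @param x A [coex_matrix()].
#' @param params A [biclic_params()].
#' @return A tibble of class `coex_biclusters` with list-columns `genes`
#'   and `samples` plus `n_genes`, `n_samples` and `avg_pcc`, sorted by
#'   decreasing `avg_pcc`.  Zero rows when nothing reaches the threshold.
#' @export
run_biclic <- function(x, params = biclic_params()) {
  stopifnot_coex(x)
  clusters <- lapply(setNames(nm = sample_ids(x)), function(s) {
    sample_seed_clusters(x, s, params)
  })
  seeds <- find_seeds(clusters, params)
  if (params$cor_seeds) {
    seeds <- dplyr::bind_rows(seeds, correlation_seeds(x, params))
  }
  if (!nrow(seeds)) return(empty_biclusters())
  key <- vapply(seq_len(nrow(seeds)), function(i) {
    paste(set_key(seeds$genes[[i]]), set_key(seeds$samples[[i]]), sep = "\n")
  }, "")
  seeds <- seeds[order(key), ][!duplicated(sort(key)), ]

  found <- list()
  for (i in seq_len(nrow(seeds))) {
    seed <- list(genes = seeds$genes[[i]], samples = seeds$samples[[i]])
    gene_space <- expand_genes(x, seed, params)
    sample_space <- expand_samples(x, seed, params)
    bc <- optimize_bicluster(x, gene_space, sample_space, params)
    if (!is.null(bc)) found[[length(found) + 1L]] <- bc
  }
  if (!length(found)) return(empty_biclusters())
  out <- dplyr::bind_rows(found)
  out <- dedup_biclusters(out)
  out$n_genes <- lengths(out$genes)
  out$n_samples <- lengths(out$samples)
  out <- out[order(-out$avg_pcc,
                   vapply(out$genes, set_key, "")),
             c("genes", "samples", "n_genes", "n_samples", "avg_pcc")]
  class(out) <- c("coex_biclusters", class(out))
  out
}

empty_biclusters <- function() {
  out <- tibble(genes = list(), samples = list(),
                n_genes = integer(), n_samples = integer(),
                avg_pcc = numeric())
  class(out) <- c("coex_biclusters", class(out))
  out
}

# merge identical blocks, drop blocks strictly contained in another
dedup_biclusters <- function(tbl) {
  key <- vapply(seq_len(nrow(tbl)), function(i) {
    paste(set_key(tbl$genes[[i]]), set_key(tbl$samples[[i]]), sep = "\n")
  }, "")
  tbl <- tbl[!duplicated(key), ]
  n <- nrow(tbl)
  if (n <= 1) return(tbl)
  sz <- lengths(tbl$genes) + lengths(tbl$samples)
  o <- order(-sz)
  tbl <- tbl[o, ]
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j || !keep[j]) next
      if (all(tbl$genes[[j]] %in% tbl$genes[[i]]) &&
          all(tbl$samples[[j]] %in% tbl$samples[[i]]) &&
          (length(tbl$genes[[j]]) < length(tbl$genes[[i]]) ||
           length(tbl$samples[[j]]) < length(tbl$samples[[i]]))) {
        keep[j] <- FALSE
      }
    }
  }
  tbl[keep, ]
}

#' Write biclusters to JSON
#'
#' @param biclusters A `coex_biclusters` tibble from [run_biclic()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biclusters_json <- function(biclusters, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(biclusters)), function(i) {
      list(genes = biclusters$genes[[i]],
           samples = biclusters$samples[[i]],
           avg_pcc = biclusters$avg_pcc[i])
    }),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
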