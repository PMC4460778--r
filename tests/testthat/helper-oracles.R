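# Independent oracles and small fixture builders shared across tests.
# Each oracle is a deliberately naive re-derivation, kept free of the
# package's own code paths.

# quick genes x samples container; one batch, all-control unless given
make_cm <- function(values, classes = NULL, batches = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  coex_matrix(values, data.frame(
    sample_id = colnames(values),
    batch = batches %||% rep("b1", ncol(values)),
    class = classes %||% rep("CTRL", ncol(values))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# mean pairwise Pearson correlation by explicit pair loop
oracle_avg_pcc <- function(values, genes, samples) {
  sub <- values[genes, samples, drop = FALSE]
  pairs <- utils::combn(seq_along(genes), 2)
  mean(apply(pairs, 2, function(ij) {
    a <- sub[ij[1], ]; b <- sub[ij[2], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }))
}

# textbook BH step-up: q_(i) = min_{j >= i} m p_(j) / j, input order kept
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

# exact hypergeometric upper tail by term-by-term summation
oracle_hyper_tail <- function(k, n_univ, n_term, n_set) {
  js <- seq(k, min(n_term, n_set))
  if (!length(js)) return(1)
  sum(choose(n_term, js) * choose(n_univ - n_term, n_set - js)) /
    choose(n_univ, n_set)
}

# all (gene subset >= min_g) x (sample subset >= min_s) blocks meeting the
# threshold, by full enumeration; returns list of list(genes, samples, avg)
oracle_all_blocks <- function(cm, threshold, min_g = 2, min_s = 3) {
  g <- rownames(cm$values); s <- colnames(cm$values)
  out <- list()
  for (kg in min_g:length(g)) {
    for (gi in utils::combn(length(g), kg, simplify = FALSE)) {
      for (ks in min_s:length(s)) {
        for (si in utils::combn(length(s), ks, simplify = FALSE)) {
          avg <- oracle_avg_pcc(cm$values, g[gi], s[si])
          if (avg >= threshold) {
            out[[length(out) + 1]] <- list(genes = g[gi], samples = s[si],
                                           avg = avg)
          }
        }
      }
    }
  }
  out
}

# among enumerated blocks, the ones maximizing samples (then genes)
oracle_best_block <- function(cm, threshold, min_g = 2, min_s = 3) {
  blocks <- oracle_all_blocks(cm, threshold, min_g, min_s)
  if (!length(blocks)) return(NULL)
  ns <- vapply(blocks, function(b) length(b$samples), 0L)
  ng <- vapply(blocks, function(b) length(b$genes), 0L)
  blocks[[order(-ns, -ng)[1]]]
}

# brute-force identity-seed enumeration over all (gene-set, sample) window
# incidences
oracle_find_seeds <- function(cluster_lists, min_samples) {
  inc <- list()
  for (s in names(cluster_lists)) {
    for (g in cluster_lists[[s]]) {
      key <- paste(sort(g), collapse = "|")
      inc[[key]] <- union(inc[[key]], s)
    }
  }
  keep <- sort(names(inc)[lengths(inc) >= min_samples])
  lapply(keep, function(k) {
    list(genes = strsplit(k, "|", fixed = TRUE)[[1]],
         samples = sort(inc[[k]]))
  })
}

# matrix with a perfectly colinear gene block over chosen samples and
# noise elsewhere
planted_block_matrix <- function(n_genes, n_samples, block_genes,
                                 block_samples, seed = 1, noise_sd = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, sd = noise_sd), n_genes,
                n_samples,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    f <- rnorm(length(block_samples))
    for (g in block_genes) m[g, block_samples] <- f
    m
  })
}
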