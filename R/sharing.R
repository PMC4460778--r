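#' Partition gene sets into shared and disease-specific
#'
#' Shared sets are coexpressed in at least two diseases (two or more
#' combination flags); specific sets carry exactly one.
#'
#' @param sets Tibble with a `combination` list-column, e.g.
#'   `tidy(refined)` or `refined$sets`.
#' @return Named list with tibbles `shared` and `specific`.
#' @export
partition_shared <- function(sets) {
  n_flags <- lengths(sets$combination)
  list(shared = sets[n_flags >= 2, , drop = FALSE],
       specific = sets[n_flags == 1, , drop = FALSE])
}

#' Pairwise disease sharing counts
#'
#' Entry (i, j) counts the gene sets whose combination includes both
#' disease i and disease j; the diagonal counts sets including the
#' disease at all.  The inclusive reading ("combination includes both")
#' is used, so a set spanning three diseases contributes to all three
#' pairs.
#'
#' @inheritParams partition_shared
#' @return Symmetric 8 x 8 integer matrix over [disease_classes()].
#' @export
pairwise_counts <- function(sets) {
  dz <- disease_classes()
  m <- matrix(0L, length(dz), length(dz), dimnames = list(dz, dz))
  for (cmb in sets$combination) {
    cmb <- intersect(dz, cmb)
    m[cmb, cmb] <- m[cmb, cmb] + 1L
  }
  m
}

#' Most frequent genes in a group of sets
#'
#' Ranks genes by how many gene sets of the chosen group contain them
#' (the reference analysis reports the top 30 for shared and for
#' disease-specific sets).  Ties are broken lexicographically.
#'
#' @inheritParams partition_shared
#' @param group `"shared"`, `"specific"`, or `"all"`.
#' @param k Number of genes to return.
#' @return Tibble with columns `gene` and `n_sets`, at most `k` rows.
#' @export
top_genes <- function(sets, group = c("all", "shared", "specific"),
                      k = 30L) {
  group <- match.arg(group)
  if (k < 1) abort("`k` must be >= 1.")
  if (group != "all") sets <- partition_shared(sets)[[group]]
  counts <- table(unlist(sets$genes))
  if (!length(counts)) return(tibble(gene = character(), n_sets = integer()))
  out <- tibble(gene = names(counts), n_sets = as.integer(counts))
  out <- out[order(-out$n_sets, out$gene), ]
  head(out, k)
}

#' Overlap with known disease genes, direct and first-order
#'
#' Annotates every gene occurring in the gene sets with the diseases
#' whose known-gene lists contain it directly, and with the diseases
#' reachable through one protein-interaction edge (a first-order
#' interactor of a known disease gene).
#'
#' @inheritParams partition_shared
#' @param disease_genes Named list mapping disease labels to known
#'   gene-id vectors.
#' @param network Data frame of undirected edges with columns `geneA`,
#'   `geneB` (self-loops ignored), or `NULL` for no network.
#' @return Tibble with columns `gene`, `direct` (list of diseases),
#'   `first_order` (list of diseases).
#' @export
disease_gene_overlap <- function(sets, disease_genes, network = NULL) {
  bad <- setdiff(names(disease_genes), disease_classes())
  if (length(bad)) {
    abort(paste("Unknown disease label(s):", paste(bad, collapse = ", ")))
  }
  genes <- sort(unique(unlist(sets$genes)))
  nbrs <- neighbor_map(network, genes)
  tibble(
    gene = genes,
    direct = lapply(genes, function(g) {
      sort(names(disease_genes)[vapply(disease_genes, function(dg) {
        g %in% dg
      }, TRUE)])
    }),
    first_order = lapply(genes, function(g) {
      nb <- nbrs[[g]]
      if (is.null(nb)) return(character(0))
      sort(names(disease_genes)[vapply(disease_genes, function(dg) {
        length(intersect(nb, dg)) > 0
      }, TRUE)])
    }))
}

neighbor_map <- function(network, genes) {
  if (is.null(network) || !nrow(network)) return(list())
  edges <- as_tibble(network)
  if (!all(c("geneA", "geneB") %in% names(edges))) {
    abort("`network` needs columns geneA and geneB.")
  }
  edges <- edges[edges$geneA != edges$geneB, ]
  both <- rbind(data.frame(g = edges$geneA, nb = edges$geneB),
                data.frame(g = edges$geneB, nb = edges$geneA))
  both <- both[both$g %in% genes, ]
  lapply(split(both$nb, both$g), unique)
}

#' Summarize sharing across disease combinations
#'
#' One call producing the sharing views of a refined result: the
#' shared/specific split, the pairwise disease count matrix and the
#' top-gene tables.
#'
#' @param refined A `coex_refined` object (or a tibble of sets).
#' @param k Top-gene list length.
#' @return List with `counts` (tibble: n_sets, n_shared, n_specific),
#'   `pairwise` (matrix), `top_shared`, `top_specific` (tibbles).
#' @export
sharing_summary <- function(refined, k = 30L) {
  sets <- if (inherits(refined, "coex_refined")) refined$sets else refined
  parts <- partition_shared(sets)
  list(counts = tibble(n_sets = nrow(sets),
                       n_shared = nrow(parts$shared),
                       n_specific = nrow(parts$specific)),
       pairwise = pairwise_counts(sets),
       top_shared = top_genes(sets, "shared", k),
       top_specific = top_genes(sets, "specific", k))
}
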