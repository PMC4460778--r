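#' Read a GMT annotation file
#'
#' Standard tab-delimited gene-set format: one term per line as
#' `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @param background Optional gene universe; defaults to the union of all
#'   term genes.  Term genes outside the background are dropped.
#' @return An `annotation_set`: list with `terms` (named list of gene-id
#'   vectors), `term_names` (named character) and `background`.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1)
  annotation_set(
    terms = setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids),
    term_names = setNames(vapply(parts, `[[`, "", 2), ids),
    background = background)
}

#' Build an annotation set in memory
#'
#' @param terms Named list: term id -> character vector of member genes.
#' @param term_names Optional named character vector of display names.
#' @param background Gene universe; defaults to the union of term genes.
#'   Every term is clipped to the background.
#' @return An `annotation_set` list.
#' @export
annotation_set <- function(terms, term_names = NULL, background = NULL) {
  if (is.null(names(terms))) abort("`terms` must be a named list.")
  background <- background %||% sort(unique(unlist(terms)))
  if (!length(background)) abort("Empty background universe.")
  terms <- lapply(terms, intersect, background)
  structure(list(terms = terms,
                 term_names = term_names %||% setNames(names(terms),
                                                       names(terms)),
                 background = background),
            class = "annotation_set")
}

#' Hypergeometric term enrichment of one gene set
#'
#' For each annotation term, the upper-tail hypergeometric probability of
#' seeing at least the observed number of term genes in the set, given
#' the background universe; BH adjustment across terms; terms passing
#' `q <= alpha` are returned.  Genes outside the background are ignored
#' (the universe should be the measured genes, not the genome).
#'
#' @param gene_set Character vector of gene ids.
#' @param annotation An [annotation_set()].
#' @param alpha FDR threshold (the reference analysis used corrected
#'   0.005 for term reporting and 0.01 for the category comparison).
#' @return Tibble with columns `term`, `term_name`, `k` (overlap), `p`,
#'   `q`, sorted by `p`; attribute `"all_terms"` holds the unfiltered
#'   table.
#' @export
hypergeom_enrich <- function(gene_set, annotation, alpha = 0.005) {
  if (!inherits(annotation, "annotation_set")) {
    abort("`annotation` must be an annotation_set.")
  }
  set <- intersect(unique(gene_set), annotation$background)
  if (!length(set)) abort("Gene set does not intersect the background.")
  n_univ <- length(annotation$background)
  n_set <- length(set)
  term_ids <- names(annotation$terms)
  k <- vapply(annotation$terms, function(tg) length(intersect(tg, set)), 0L)
  m <- lengths(annotation$terms)
  # P(X >= k) for X ~ Hypergeom(universe n_univ, term m, draws n_set)
  p <- phyper(k - 1, m, n_univ - m, n_set, lower.tail = FALSE)
  tab <- tibble(term = term_ids,
                term_name = unname(annotation$term_names[term_ids]),
                k = unname(as.integer(k)), p = unname(pmin(p, 1)))
  tab$q <- bh_correct(tab$p)
  tab <- tab[order(tab$p, tab$term), ]
  out <- tab[tab$q <= alpha, , drop = FALSE]
  attr(out, "all_terms") <- tab
  out
}

#' Category profile of enriched gene sets
#'
#' Maps each gene set's enriched terms to representative categories and
#' counts, per category, the sets hitting it at least once; the
#' normalized fraction divides by the number of sets with any enriched
#' term, so a set enriched in several terms of one category still counts
#' once there (fractions can sum past 1 across categories).
#'
#' @param enrichments List of enrichment tibbles from
#'   [hypergeom_enrich()], one per gene set.
#' @param category_map Data frame with columns `term`, `category`.
#' @return Tibble with columns `category`, `count`, `fraction`.
#' @export
category_profile <- function(enrichments, category_map) {
  cm <- as_tibble(category_map)
  if (!all(c("term", "category") %in% names(cm))) {
    abort("`category_map` needs columns term and category.")
  }
  with_terms <- Filter(function(e) nrow(e) > 0, enrichments)
  n_enriched <- length(with_terms)
  cats <- sort(unique(cm$category))
  counts <- setNames(integer(length(cats)), cats)
  for (e in with_terms) {
    hit <- sort(unique(cm$category[cm$term %in% e$term]))
    counts[hit] <- counts[hit] + 1L
  }
  tibble(category = cats, count = as.integer(counts),
         fraction = if (n_enriched) as.numeric(counts) / n_enriched
                    else rep(NA_real_, length(cats)))
}

#' Fold comparison of category profiles
#'
#' Ratio of each category's normalized fraction in the shared profile
#' over the specific profile -- the "how much more often do shared sets
#' hit this category" view.  Categories absent from the specific profile
#' get an infinite fold and sort last.
#'
#' @param shared_profile,specific_profile Tibbles from
#'   [category_profile()] over the same categories.
#' @return Tibble with `category`, `shared_fraction`,
#'   `specific_fraction`, `fold`, sorted by decreasing finite fold.
#' @export
fold_comparison <- function(shared_profile, specific_profile) {
  if (!setequal(shared_profile$category, specific_profile$category)) {
    abort("Profiles must cover the same categories.")
  }
  sp <- specific_profile[match(shared_profile$category,
                               specific_profile$category), ]
  out <- tibble(category = shared_profile$category,
                shared_fraction = shared_profile$fraction,
                specific_fraction = sp$fraction,
                fold = shared_profile$fraction / sp$fraction)
  out$fold[sp$fraction == 0 & shared_profile$fraction > 0] <- Inf
  out$fold[sp$fraction == 0 & shared_profile$fraction == 0] <- NaN
  out[order(is.infinite(out$fold), -out$fold, out$category), ]
}

#' Compare shared vs specific gene sets by category enrichment
#'
#' Runs [hypergeom_enrich()] on every refined set, splits sets into
#' shared and disease-specific, profiles both groups by category and
#' returns the fold comparison.
#'
#' @param refined A `coex_refined` object or tibble of sets.
#' @param annotation An [annotation_set()].
#' @param category_map Data frame with columns `term`, `category`.
#' @param alpha FDR threshold per set (0.01 in the reference category
#'   comparison).
#' @return List with `shared_profile`, `specific_profile`, `fold`.
#' @export
enrichment_comparison <- function(refined, annotation, category_map,
                                  alpha = 0.01) {
  sets <- if (inherits(refined, "coex_refined")) refined$sets else refined
  parts <- partition_shared(sets)
  enrich_group <- function(group) {
    lapply(group$genes, function(g) {
      hypergeom_enrich(g, annotation, alpha = alpha)
    })
  }
  shared_profile <- category_profile(enrich_group(parts$shared),
                                     category_map)
  specific_profile <- category_profile(enrich_group(parts$specific),
                                       category_map)
  list(shared_profile = shared_profile,
       specific_profile = specific_profile,
       fold = fold_comparison(shared_profile, specific_profile))
}
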