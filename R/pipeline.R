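#' Configure an end-to-end run
#'
#' Collects everything [run_pipeline()] needs: where to write, the master
#' seed, the input cohort (either TSV paths or a [synthetic_config()] to
#' generate one), stage parameters and optional sharing/enrichment
#' inputs.  Per-stage seeds are derived deterministically from the master
#' seed by stage-name hashing, so any stage can be reproduced alone.
#'
#' @param out_dir Output directory.
#' @param seed Master integer seed (mandatory).
#' @param expr_path,meta_path Expression/metadata TSVs ([read_coex_tsv()]
#'   layout), or `NULL` to use `synthetic`.
#' @param synthetic A [synthetic_config()] generating the cohort when no
#'   paths are given (its own seed is overridden by the derived stage
#'   seed).
#' @param biclic A [biclic_params()].
#' @param alpha FDR threshold of the refinement stage.
#' @param n_draws Null draws per size/combination.
#' @param disease_genes Optional named list of known disease genes.
#' @param network Optional protein-interaction edge data frame
#'   (`geneA`, `geneB`).
#' @param annotation Optional [annotation_set()] (or GMT path) enabling
#'   the enrichment stage.
#' @param category_map Optional data frame `term`/`category` for the
#'   category comparison.
#' @param enrich_alpha Per-set FDR threshold of the enrichment stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed,
                            expr_path = NULL, meta_path = NULL,
                            synthetic = synthetic_config(),
                            biclic = biclic_params(),
                            alpha = 0.005, n_draws = 100000L,
                            disease_genes = NULL, network = NULL,
                            annotation = NULL, category_map = NULL,
                            enrich_alpha = 0.01) {
  if (missing(seed)) abort("A master `seed` is mandatory.")
  if (!is.null(expr_path) && !file.exists(expr_path)) {
    abort(paste("Configuration error: expression path not found:",
                expr_path))
  }
  if (!is.null(expr_path) &&
      (is.null(meta_path) || !file.exists(meta_path))) {
    abort("Configuration error: metadata path missing or not found.")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 expr_path = expr_path, meta_path = meta_path,
                 synthetic = synthetic, biclic = biclic,
                 alpha = alpha, n_draws = as.integer(n_draws),
                 disease_genes = disease_genes, network = network,
                 annotation = annotation, category_map = category_map,
                 enrich_alpha = enrich_alpha),
            class = "pipeline_config")
}

#' Run the whole analysis end to end
#'
#' Executes, in order: cohort acquisition (synthetic generation or TSV
#' load), integration (per-batch quantile normalization + batch
#' adjustment), bicluster search, refinement with the permutation null,
#' sharing summaries and -- when an annotation is configured -- the
#' enrichment comparison.  Every stage writes its outputs under the
#' configured directory; a JSON manifest records outputs, counts,
#' parameters, seeds and per-stage runtimes.  A failing stage aborts
#' with its name; files of the failed stage keep a `.partial` suffix.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly, as a list; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    info <- tryCatch(fun(), error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    info$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    manifest$stages[[name]] <<- info
  }

  run_stage("input", function() {
    if (!is.null(config$expr_path)) {
      state$raw <- read_coex_tsv(config$expr_path, config$meta_path)
      list(source = config$expr_path,
           n_genes = nrow(state$raw$values),
           n_samples = ncol(state$raw$values))
    } else {
      cfg <- config$synthetic
      cfg$seed <- derive_seed(config$seed, "synth")
      gen <- generate_dataset(cfg)
      state$raw <- gen$expr
      state$truth <- gen$truth
      paths <- write_synthetic_dataset(gen, config$out_dir)
      list(source = "synthetic", seed = cfg$seed,
           outputs = as.list(paths),
           n_genes = nrow(state$raw$values),
           n_samples = ncol(state$raw$values),
           n_modules = nrow(gen$truth))
    }
  })

  run_stage("integration", function() {
    state$merged <- integrate_cohort(state$raw)
    paths <- write_coex_tsv(state$merged, config$out_dir,
                            prefix = "merged")
    list(outputs = as.list(paths), n_genes = nrow(state$merged$values),
         n_samples = ncol(state$merged$values))
  })

  run_stage("biclic", function() {
    state$biclusters <- run_biclic(state$merged, config$biclic)
    path <- file.path(config$out_dir, "biclusters.json")
    partial_write(path, function(p) write_biclusters_json(state$biclusters, p))
    list(outputs = path, n_biclusters = nrow(state$biclusters),
         params = unclass(config$biclic))
  })

  run_stage("refinement", function() {
    state$refined <- refine_all(state$biclusters, state$merged,
                                alpha = config$alpha,
                                n_draws = config$n_draws,
                                seed = derive_seed(config$seed, "refine"))
    path <- file.path(config$out_dir, "refined.tsv")
    partial_write(path, function(p) write_refined_tsv(state$refined, p))
    list(outputs = path, alpha = config$alpha,
         n_draws = config$n_draws,
         seed = derive_seed(config$seed, "refine"),
         n_tested = nrow(state$refined$tested),
         n_significant = nrow(state$refined$sets))
  })

  run_stage("sharing", function() {
    summ <- sharing_summary(state$refined)
    state$sharing <- summ
    pc_path <- file.path(config$out_dir, "pairwise_counts.tsv")
    utils::write.table(summ$pairwise, pc_path, sep = "\t", quote = FALSE)
    tg_path <- file.path(config$out_dir, "top_genes_shared.tsv")
    utils::write.table(summ$top_shared, tg_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ts_path <- file.path(config$out_dir, "top_genes_specific.tsv")
    utils::write.table(summ$top_specific, ts_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    info <- list(outputs = c(pc_path, tg_path, ts_path),
                 counts = as.list(summ$counts))
    if (!is.null(config$disease_genes)) {
      ov <- disease_gene_overlap(state$refined$sets, config$disease_genes,
                                 config$network)
      ov_path <- file.path(config$out_dir, "disease_gene_overlap.tsv")
      flat <- tibble(gene = ov$gene,
                     direct = vapply(ov$direct, paste, "", collapse = ","),
                     first_order = vapply(ov$first_order, paste, "",
                                          collapse = ","))
      utils::write.table(flat, ov_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      info$outputs <- c(info$outputs, ov_path)
    }
    info
  })

  if (!is.null(config$annotation)) {
    run_stage("enrichment", function() {
      ann <- config$annotation
      if (is.character(ann)) ann <- read_gmt(ann)
      cmp <- enrichment_comparison(state$refined, ann,
                                   config$category_map,
                                   alpha = config$enrich_alpha)
      path <- file.path(config$out_dir, "category_fold.tsv")
      utils::write.table(cmp$fold, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      list(outputs = path, alpha = config$enrich_alpha,
           n_categories = nrow(cmp$fold))
    })
  }

  manifest$params <- list(alpha = config$alpha, n_draws = config$n_draws,
                          biclic = unclass(config$biclic))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  res <- list(manifest = manifest,
              merged = state$merged, biclusters = state$biclusters,
              refined = state$refined, sharing = state$sharing,
              truth = state$truth)
  invisible(res)
}

# write through a .partial file so an interrupted stage never leaves a
# complete-looking output behind
partial_write <- function(path, writer) {
  tmp <- paste0(path, ".partial")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
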