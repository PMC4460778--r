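#' Describe one synthetic batch
#'
#' @param batch_id Batch label.
#' @param class_counts Named non-negative integer vector: samples per class.
#'   Names must come from [disease_classes()] / [control_class()] and at
#'   least one class needs 3 or more samples.
#' @return A `batch_spec` list.
#' @export
batch_spec <- function(batch_id, class_counts) {
  if (is.null(names(class_counts)) ||
      !all(names(class_counts) %in% all_classes())) {
    abort("`class_counts` must be named with known class labels.")
  }
  counts <- as.integer(class_counts)
  if (any(counts < 0)) abort("Class counts must be non-negative.")
  if (!any(counts >= 3)) abort("At least one class needs >= 3 samples.")
  structure(list(batch_id = as.character(batch_id),
                 class_counts = setNames(counts, names(class_counts))),
            class = "batch_spec")
}

#' Describe a planted coexpression module
#'
#' A planted module is a block of genes generated from a shared latent
#' factor on the samples of its member classes, so that the expected
#' pairwise Pearson correlation there equals `within_pcc`; elsewhere the
#' genes behave like background noise (or follow a weaker factor when
#' `outside_pcc > 0`).  Under the unit-loading factor model
#' `x = (f + e) / sqrt(1 + s^2)` with `e ~ N(0, s)`, the expected pairwise
#' correlation is `1 / (1 + s^2)`, so `s` is solved from the requested
#' correlation in closed form.
#'
#' @param module_id Module label (used to name the genes).
#' @param n_genes Number of member genes (>= 2).
#' @param member_classes Character vector of class labels whose samples
#'   carry the correlation.
#' @param within_pcc Target average pairwise correlation on member-class
#'   samples, in (0, 1].
#' @param outside_pcc Target correlation on all other samples, in
#'   [0, within_pcc); 0 means independent noise.
#' @return A `planted_module` list.
#' @export
planted_module <- function(module_id, n_genes, member_classes,
                           within_pcc, outside_pcc = 0) {
  if (n_genes < 2) abort("A module needs at least 2 genes.")
  if (!length(member_classes) ||
      !all(member_classes %in% all_classes())) {
    abort("`member_classes` must be known class labels.")
  }
  if (!(outside_pcc >= 0 && outside_pcc < within_pcc && within_pcc <= 1)) {
    abort("Require 0 <= outside_pcc < within_pcc <= 1.")
  }
  structure(list(module_id = as.character(module_id),
                 n_genes = as.integer(n_genes),
                 member_classes = unique(member_classes),
                 within_pcc = within_pcc,
                 outside_pcc = outside_pcc),
            class = "planted_module")
}

#' The three-batch brain-cohort layout
#'
#' Batch specifications mirroring the sample layout of the three-cohort
#' brain study the package emulates: one entorhinal-cortex batch with six
#' neurodegenerative/psychiatric classes plus controls (11 AD, 10 ALS,
#' 10 HD, 10 MS, 12 PD, 10 SCH, 55 CTRL), one bipolar-disorder batch
#' (30 BD, 31 CTRL) and one autism batch (29 AUT, 29 CTRL) -- 237 samples
#' in total.
#'
#' @return A list of three [batch_spec()] objects.
#' @export
brain_cohort_batches <- function() {
  list(
    batch_spec("B1", c(AD = 11, ALS = 10, HD = 10, MS = 10, PD = 12,
                       SCH = 10, CTRL = 55)),
    batch_spec("B2", c(BD = 30, CTRL = 31)),
    batch_spec("B3", c(AUT = 29, CTRL = 29))
  )
}

#' Configure a synthetic multi-batch cohort
#'
#' Defaults describe the desk-scale stand-in for the study's merged cohort:
#' ~500 background genes over the 237-sample, three-batch layout of
#' [brain_cohort_batches()], with gene-wise additive (sd 1) and
#' multiplicative (log-sd 0.25) batch effects and unit-variance background
#' noise.
#'
#' @param n_background_genes Number of uncorrelated background genes.
#' @param batches List of [batch_spec()] objects.
#' @param modules List of [planted_module()] objects.
#' @param batch_additive_sd SD of the per-(gene, batch) additive shift.
#' @param batch_multiplicative_sd Log-scale SD of the per-(gene, batch)
#'   multiplicative factor (lognormal with log-mean 0).
#' @param noise_sd SD of background gene noise.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_background_genes = 500,
                             batches = brain_cohort_batches(),
                             modules = list(),
                             batch_additive_sd = 1,
                             batch_multiplicative_sd = 0.25,
                             noise_sd = 1,
                             seed = 1L) {
  if (batch_additive_sd < 0 || batch_multiplicative_sd < 0 || noise_sd < 0) {
    abort("Spread parameters must be non-negative.")
  }
  if (!length(batches)) abort("Need at least one batch.")
  cfg <- structure(list(n_background_genes = as.integer(n_background_genes),
                        batches = batches, modules = modules,
                        batch_additive_sd = batch_additive_sd,
                        batch_multiplicative_sd = batch_multiplicative_sd,
                        noise_sd = noise_sd, seed = as.integer(seed)),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  present <- unique(unlist(lapply(cfg$batches, function(b) {
    names(b$class_counts)[b$class_counts > 0]
  })))
  counts <- class_totals(cfg)
  for (m in cfg$modules) {
    missing <- setdiff(m$member_classes, present)
    if (length(missing)) {
      abort(paste0("Module ", m$module_id, ": member class(es) ",
                   paste(missing, collapse = ", "),
                   " absent from every batch."))
    }
    if (sum(counts[m$member_classes]) < 3) {
      abort(paste0("Module ", m$module_id,
                   ": fewer than 3 member-class samples."))
    }
  }
  ids <- vapply(cfg$modules, `[[`, "", "module_id")
  if (anyDuplicated(ids)) abort("Duplicate module ids.")
  invisible(cfg)
}

class_totals <- function(cfg) {
  tot <- setNames(integer(length(all_classes())), all_classes())
  for (b in cfg$batches) {
    tot[names(b$class_counts)] <- tot[names(b$class_counts)] +
      b$class_counts
  }
  tot
}

# sigma of the factor-model noise giving expected pairwise PCC = rho
pcc_to_sigma <- function(rho) sqrt(1 / rho - 1)

#' Generate a synthetic cohort with planted modules
#'
#' Draws a genes x samples matrix under the configured world: background
#' genes are independent noise; each planted module's genes follow a
#' unit-loading single-factor model on the member-class samples (expected
#' pairwise correlation `within_pcc`, values rescaled to unit variance) and
#' background-like behaviour elsewhere; finally a per-(gene, batch)
#' additive shift and multiplicative scale emulate batch effects.  The same
#' config and seed always reproduce the matrix bit for bit.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `expr` (a [coex_matrix()]) and `truth`
#'   (tibble: `module_id`, list-columns `genes` and `samples` naming each
#'   module's members and the samples of its member classes).
#' @examples
#' cfg <- synthetic_config(
#'   n_background_genes = 50,
#'   batches = list(batch_spec("b", c(AD = 10, CTRL = 10))),
#'   modules = list(planted_module("m1", 5, "AD", within_pcc = 0.9)),
#'   seed = 7)
#' gen <- generate_dataset(cfg)
#' gen$truth
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must come from synthetic_config().")
  }
  meta <- do.call(rbind, lapply(config$batches, function(b) {
    cls <- rep(names(b$class_counts), b$class_counts)
    data.frame(
      sample_id = sprintf("%s_%s_%02d", b$batch_id, cls,
                          unlist(lapply(b$class_counts, seq_len))),
      batch = b$batch_id, class = cls, stringsAsFactors = FALSE)
  }))
  n_samp <- nrow(meta)
  mod_genes <- lapply(config$modules, function(m) {
    sprintf("%s_g%02d", m$module_id, seq_len(m$n_genes))
  })
  n_mod <- sum(vapply(mod_genes, length, 0L))
  genes <- c(unlist(mod_genes),
             sprintf("BG%04d", seq_len(config$n_background_genes)))
  if (!length(genes)) abort("Configuration yields zero genes.")

  withr::with_seed(config$seed, {
    values <- matrix(rnorm(length(genes) * n_samp, sd = config$noise_sd),
                     nrow = length(genes), ncol = n_samp,
                     dimnames = list(genes, meta$sample_id))
    for (i in seq_along(config$modules)) {
      m <- config$modules[[i]]
      rows <- mod_genes[[i]]
      member <- meta$class %in% m$member_classes
      values[rows, member] <-
        factor_block(length(rows), sum(member), m$within_pcc)
      if (m$outside_pcc > 0 && any(!member)) {
        values[rows, !member] <-
          factor_block(length(rows), sum(!member), m$outside_pcc)
      }
    }
    for (b in unique(meta$batch)) {
      cols <- meta$batch == b
      shift <- rnorm(length(genes), sd = config$batch_additive_sd)
      scale <- rlnorm(length(genes), sdlog = config$batch_multiplicative_sd)
      values[, cols] <- values[, cols] * scale + shift
    }
  })

  truth <- tibble(
    module_id = vapply(config$modules, `[[`, "", "module_id"),
    genes = mod_genes,
    samples = lapply(config$modules, function(m) {
      meta$sample_id[meta$class %in% m$member_classes]
    }))
  list(expr = coex_matrix(values, meta), truth = truth)
}

# k x n block from a single-factor model with expected pairwise PCC rho,
# rescaled to unit variance: x = (f + e) / sqrt(1 + sigma^2)
factor_block <- function(k, n, rho) {
  sigma <- pcc_to_sigma(rho)
  f <- rnorm(n)
  eps <- matrix(rnorm(k * n, sd = sigma), k, n)
  sweep(eps, 2, f, `+`) / sqrt(1 + sigma^2)
}

#' Write a synthetic dataset to disk
#'
#' Expression and metadata TSVs via [write_coex_tsv()] plus a
#' `truth.json` with the planted module membership.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  paths <- write_coex_tsv(dataset$expr, dir, prefix = "expression")
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    lapply(seq_len(nrow(dataset$truth)), function(i) {
      list(module_id = dataset$truth$module_id[i],
           genes = dataset$truth$genes[[i]],
           samples = dataset$truth$samples[[i]])
    }),
    truth_path, auto_unbox = TRUE)
  invisible(c(paths, truth = truth_path))
}
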