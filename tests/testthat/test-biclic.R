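test_that("avg_pcc agrees with direct pairwise computation", {
  m <- make_cm(matrix(c(1, 2, 3,
                        2, 4, 6,
                        3, 2, 1,
                        1, 3, 2,
                        2, 1, 3), 5, 3, byrow = TRUE))
  s <- colnames(m$values)
  expect_equal(avg_pcc(m, c("g01", "g02"), s), 1.0)
  expect_equal(avg_pcc(m, c("g01", "g03"), s), -1.0)
  # (0.5 + 0.5 - 0.5) / 3 = 1/6 for the mixed trio
  expect_equal(avg_pcc(m, c("g01", "g04", "g05"), s), 1 / 6)

  # random matrices against the pair-loop oracle
  withr::with_seed(31, {
    for (rep in 1:5) {
      r <- make_cm(matrix(rnorm(80), 8, 10))
      genes <- sample(rownames(r$values), 4)
      samples <- sample(colnames(r$values), 6)
      expect_equal(avg_pcc(r, genes, samples),
                   oracle_avg_pcc(r$values, genes, samples))
    }
  })
})

test_that("avg_pcc handles degenerate inputs per contract", {
  vals <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE)
  m <- make_cm(vals)
  # zero-variance member makes the pair contribute 0
  expect_equal(avg_pcc(m, c("g01", "g02"), colnames(m$values)), 0)
  expect_error(avg_pcc(m, "g01", colnames(m$values)), "2 genes")
  expect_error(avg_pcc(m, rownames(m$values), c("s01", "s02")), "3 samples")
})

test_that("sample_seed_clusters windows the within-sample ranking", {
  withr::with_seed(7, m <- make_cm(matrix(rnorm(30), 10, 3)))
  p <- biclic_params(seed_window = 5)
  w <- sample_seed_clusters(m, "s01", p)
  expect_length(w, 2)
  expect_true(all(lengths(w) == 5))
  # windows tile the ranking: bottom 5 then top 5
  o <- rownames(m$values)[order(m$values[, "s01"], rownames(m$values))]
  expect_setequal(w[[1]], o[1:5])
  expect_setequal(w[[2]], o[6:10])

  # 11 genes: trailing singleton dropped (< min_genes)
  withr::with_seed(8, m11 <- make_cm(matrix(rnorm(33), 11, 3)))
  w11 <- sample_seed_clusters(m11, "s01", p)
  expect_equal(lengths(w11), c(5L, 5L))

  # grouping depends only on within-sample ranks
  m_mono <- m
  m_mono$values[, "s01"] <- exp(m$values[, "s01"]) * 3 + 100
  expect_identical(sample_seed_clusters(m_mono, "s01", p), w)
})

test_that("find_seeds collects identical windows across enough samples", {
  p <- biclic_params(min_samples = 3)
  clusters <- list(
    s1 = list(c("a", "b"), c("c", "d")),
    s2 = list(c("b", "a"), c("d", "e")),
    s3 = list(c("a", "b"), c("c", "e")),
    s4 = list(c("x", "y"), c("a", "b")))
  seeds <- find_seeds(clusters, p)
  expect_equal(nrow(seeds), 1)
  expect_setequal(seeds$genes[[1]], c("a", "b"))
  expect_setequal(seeds$samples[[1]], c("s1", "s2", "s3", "s4"))

  # a set recurring in only 2 samples is gated out
  seeds2 <- find_seeds(clusters[c("s1", "s2")], p)
  expect_equal(nrow(seeds2), 0)

  # random fixture against exhaustive incidence enumeration
  withr::with_seed(19, m <- make_cm(matrix(rnorm(200), 20, 10)))
  cl <- lapply(setNames(nm = colnames(m$values)), function(s) {
    sample_seed_clusters(m, s, p)
  })
  got <- find_seeds(cl, p)
  want <- oracle_find_seeds(cl, p$min_samples)
  expect_equal(nrow(got), length(want))
  if (length(want)) {
    for (i in seq_along(want)) {
      expect_setequal(got$genes[[i]], want[[i]]$genes)
      expect_setequal(got$samples[[i]], want[[i]]$samples)
    }
  }
})

test_that("expand_genes grows greedily under the PCC constraint", {
  # 8 colinear genes: all join and the average stays 1
  f <- c(0.3, -1.2, 0.8, 2.1, -0.5, 0.1)
  vals <- t(sapply(1:8, function(i) i * f))
  vals <- rbind(vals, anti = -f, noise = c(1, -1, 1, -1, 1, -1))
  rownames(vals) <- c(paste0("lin", 1:8), "anti", "noise")
  m <- make_cm(vals)
  seed <- list(genes = c("lin1", "lin2"), samples = colnames(m$values))
  p <- biclic_params(pcc_threshold = 0.7)
  got <- expand_genes(m, seed, p)
  # all colinear genes join and the average stays 1; the anti-correlated
  # and incompatible genes never do
  expect_setequal(got, paste0("lin", 1:8))
  expect_equal(avg_pcc(m, got, colnames(m$values)), 1)
})

test_that("expand_genes stops at the gene cap", {
  f <- rnorm(8)
  vals <- t(sapply(1:60, function(i) i * f + i))
  rownames(vals) <- sprintf("c%02d", 1:60)
  m <- make_cm(vals)
  p <- biclic_params(max_genes = 50)
  got <- expand_genes(m, list(genes = c("c01", "c02"),
                              samples = colnames(m$values)), p)
  expect_length(got, 50)
})

test_that("expand_samples adds pattern-consistent samples without a cap", {
  withr::with_seed(41, {
    f <- rnorm(12)
    vals <- rbind(a = 2 * f + 1, b = -0.5 + f, c = 3 * f)
    vals <- vals + matrix(rnorm(36, sd = 0.01), 3, 12)
  })
  colnames(vals) <- sprintf("s%02d", 1:12)
  m <- make_cm(vals)
  p <- biclic_params()
  got <- expand_samples(m, list(genes = c("a", "b", "c"),
                                samples = c("s01", "s02", "s03")), p)
  expect_setequal(got, colnames(vals))  # all consistent => all added

  # a sample breaking the correlation is rejected
  vals2 <- vals
  vals2[, "s12"] <- c(5, -9, 2)
  m2 <- make_cm(vals2)
  got2 <- expand_samples(m2, list(genes = c("a", "b", "c"),
                                  samples = c("s01", "s02", "s03")), p)
  expect_false("s12" %in% got2)
})

test_that("optimize_bicluster stops at the first compliant state", {
  withr::with_seed(51, {
    vals <- planted_block_matrix(5, 6, paste0("g0", 1:5),
                                 sprintf("s%02d", 1:6), seed = 51,
                                 noise_sd = 1)
  })
  m <- make_cm(vals)
  p <- biclic_params()
  # space already above threshold: returned unchanged
  out <- optimize_bicluster(m, rownames(vals), colnames(vals), p)
  expect_setequal(out$genes[[1]], rownames(vals))
  expect_setequal(out$samples[[1]], colnames(vals))
  expect_gte(out$avg_pcc, p$pcc_threshold)
})

test_that("optimize_bicluster removes a poisoning gene, matching the
           exhaustive oracle", {
  for (s in c(61, 62, 63)) {
    # 5 perfectly coherent genes plus one anti-correlated poison gene:
    # the search space starts well below threshold
    withr::with_seed(s, {
      f <- rnorm(6)
      vals <- rbind(t(sapply(1:5, function(i) f)),
                    -f + rnorm(6, sd = 0.2))
    })
    dimnames(vals) <- list(paste0("g0", 1:6), sprintf("s%02d", 1:6))
    m <- make_cm(vals)
    p <- biclic_params()
    expect_lt(avg_pcc(m, rownames(vals), colnames(vals)), p$pcc_threshold)
    got <- optimize_bicluster(m, rownames(vals), colnames(vals), p)
    best <- oracle_best_block(m, p$pcc_threshold)
    expect_setequal(got$genes[[1]], paste0("g0", 1:5))
    expect_setequal(got$samples[[1]], sprintf("s%02d", 1:6))
    expect_equal(length(got$samples[[1]]), length(best$samples))
  }
})

test_that("optimize_bicluster keeps at least as many samples as the
           exhaustive optimum on small random spaces", {
  deviations <- 0
  withr::with_seed(71, {
    for (rep in 1:6) {
      vals <- matrix(rnorm(30), 5, 6)
      m <- make_cm(vals)
      p <- biclic_params(pcc_threshold = 0.6)
      got <- optimize_bicluster(m, rownames(m$values), colnames(m$values), p)
      best <- oracle_best_block(m, p$pcc_threshold)
      if (is.null(best)) {
        expect_null(got)
      } else if (!is.null(got)) {
        expect_gte(got$avg_pcc, p$pcc_threshold)
        if (length(got$samples[[1]]) < length(best$samples)) {
          deviations <- deviations + 1
        }
      }
    }
  })
  # greedy may fall short of the exhaustive optimum; log, never hide
  if (deviations > 0) {
    message(sprintf("optimize_bicluster: %d greedy shortfall(s) vs oracle",
                    deviations))
  }
  expect_lte(deviations, 6)
})

test_that("run_biclic recovers a noiseless planted module", {
  cfg <- synthetic_config(
    n_background_genes = 120,
    batches = list(batch_spec("b1", c(AD = 10, CTRL = 10))),
    modules = list(planted_module("mod", 10, c("AD", "CTRL"),
                                  within_pcc = 1)),
    batch_additive_sd = 0, batch_multiplicative_sd = 0, seed = 77)
  gen <- generate_dataset(cfg)
  bc <- run_biclic(gen$expr)
  expect_gt(nrow(bc), 0)
  jg <- vapply(bc$genes, jaccard, 0, gen$truth$genes[[1]])
  js <- vapply(bc$samples, jaccard, 0, gen$truth$samples[[1]])
  best <- which.max(jg * js)
  expect_gte(jg[best], 0.9)
  expect_gte(js[best], 0.9)
})

test_that("every emitted bicluster meets the output contract", {
  cfg <- synthetic_config(
    n_background_genes = 150,
    batches = list(batch_spec("b1", c(AD = 8, ALS = 8, CTRL = 20))),
    modules = list(planted_module("mod", 6, "ALS", within_pcc = 0.9)),
    seed = 83)
  gen <- generate_dataset(cfg)
  p <- biclic_params()
  bc <- run_biclic(gen$expr, p)
  expect_gt(nrow(bc), 0)
  for (i in seq_len(nrow(bc))) {
    expect_gte(bc$avg_pcc[i], p$pcc_threshold)
    expect_gte(length(bc$genes[[i]]), p$min_genes)
    expect_lte(length(bc$genes[[i]]), p$max_genes)
    expect_gte(length(bc$samples[[i]]), p$min_samples)
    # stored average equals recomputation from the matrix
    expect_equal(bc$avg_pcc[i],
                 avg_pcc(gen$expr, bc$genes[[i]], bc$samples[[i]]),
                 tolerance = 1e-9)
  }
})

test_that("run_biclic is invariant to sample order", {
  cfg <- synthetic_config(
    n_background_genes = 80,
    batches = list(batch_spec("b1", c(MS = 8, CTRL = 12))),
    modules = list(planted_module("mod", 5, "MS", within_pcc = 0.95)),
    seed = 97)
  gen <- generate_dataset(cfg)
  bc1 <- run_biclic(gen$expr)
  perm <- withr::with_seed(5, sample(ncol(gen$expr$values)))
  shuffled <- coex_matrix(gen$expr$values[, perm],
                          gen$expr$meta[perm, ])
  bc2 <- run_biclic(shuffled)
  key <- function(b) sort(vapply(seq_len(nrow(b)), function(i) {
    paste(paste(b$genes[[i]], collapse = ","),
          paste(b$samples[[i]], collapse = ","))
  }, ""))
  expect_identical(key(bc1), key(bc2))
})

test_that("the exhaustively optimal block is matched on a tiny matrix", {
  # a noiseless 4-gene block spanning all 7 samples, planted among noise
  # genes; the enumeration oracle finds the sample-maximal compliant
  # block and the search must essentially agree with it
  vals <- planted_block_matrix(7, 7, paste0("g0", 1:4),
                               sprintf("s%02d", 1:7), seed = 101,
                               noise_sd = 1.5)
  m <- make_cm(vals, classes = c(rep("AD", 4), rep("CTRL", 3)))
  p <- biclic_params(pcc_threshold = 0.9)
  bc <- run_biclic(m, p)
  expect_gt(nrow(bc), 0)
  best <- oracle_best_block(m, p$pcc_threshold)
  overlap <- vapply(seq_len(nrow(bc)), function(i) {
    min(jaccard(bc$genes[[i]], best$genes),
        jaccard(bc$samples[[i]], best$samples))
  }, 0)
  expect_gte(max(overlap), 0.8)
})
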