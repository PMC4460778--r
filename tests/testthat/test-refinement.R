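# a small class map used throughout: 2 diseases + controls
toy_cmap <- function() {
  list(AD = paste0("ad", 1:4), MS = paste0("ms", 1:3),
       CTRL = paste0("ct", 1:5))
}

test_that("select_and_trim keeps complete classes and trims partial ones", {
  cmap <- toy_cmap()
  # all MS samples plus part of AD: combination {MS}, AD trimmed
  bc <- list(genes = c("g1", "g2"),
             samples = c(paste0("ms", 1:3), "ad1", "ad2"))
  out <- select_and_trim(bc, cmap)
  expect_equal(out$combination, "MS")
  expect_setequal(out$samples, paste0("ms", 1:3))

  # nothing complete: rejected
  bc2 <- list(genes = "g1", samples = c("ad1", "ms1", "ct1"))
  expect_null(select_and_trim(bc2, cmap))

  # AD and MS complete plus 3 of 5 controls: both flagged, controls trimmed
  bc3 <- list(genes = c("g1", "g2"),
              samples = c(paste0("ad", 1:4), paste0("ms", 1:3),
                          paste0("ct", 1:3)))
  out3 <- select_and_trim(bc3, cmap)
  expect_setequal(out3$combination, c("AD", "MS"))
  expect_setequal(out3$samples, c(paste0("ad", 1:4), paste0("ms", 1:3)))

  # only CTRL complete: kept, but with an empty disease combination
  bc4 <- list(genes = c("g1", "g2"),
              samples = c(paste0("ct", 1:5), "ad1"))
  out4 <- select_and_trim(bc4, cmap)
  expect_length(out4$combination, 0)
  expect_setequal(out4$samples, paste0("ct", 1:5))
})

test_that("coexpression_delta contrasts disease and control coexpression", {
  cmap <- list(AD = paste0("ad", 1:4), MS = paste0("ms", 1:3),
               CTRL = paste0("ct", 1:12))
  f <- c(1.2, -0.4, 0.9, 2.0, -1.1, 0.3, 1.7)
  withr::with_seed(3, {
    vals <- rbind(g1 = c(f, rnorm(12)), g2 = c(2 * f, rnorm(12)),
                  g3 = rnorm(19))
  })
  classes <- c(rep("AD", 4), rep("MS", 3), rep("CTRL", 12))
  colnames(vals) <- c(paste0("ad", 1:4), paste0("ms", 1:3),
                      paste0("ct", 1:12))
  cm <- make_cm(vals, classes = classes)
  out <- coexpression_delta(cm, c("g1", "g2"), c("AD", "MS"), cmap)
  expect_equal(out$pcc_disease, 1.0)
  expect_lt(abs(out$pcc_normal), 0.6)
  expect_equal(out$delta, out$pcc_disease - out$pcc_normal)

  # identical behaviour everywhere: delta exactly 0
  same_vals <- rbind(g1 = 1:19, g2 = 2 * (1:19), g3 = 1:19 + 5)
  colnames(same_vals) <- colnames(vals)
  same <- make_cm(same_vals, classes = classes)
  out2 <- coexpression_delta(same, c("g1", "g2"), "AD", cmap)
  expect_equal(out2$delta, 0)

  expect_error(coexpression_delta(cm, "g1", "AD", cmap), "2 genes")
})

test_that("build_null is deterministic and centred under the null", {
  withr::with_seed(5, vals <- matrix(rnorm(60 * 20), 60, 20))
  cm <- make_cm(vals, classes = rep(c("AD", "CTRL"), each = 10))
  cmap <- class_map(cm)
  null <- build_null(cm, set_size = 3, combination = "AD", cmap,
                     n_draws = 3000, seed = 11)
  expect_length(null$deltas, 3000)
  expect_lt(abs(mean(null$deltas)),
            3 * stats::sd(null$deltas) / sqrt(3000))
  null2 <- build_null(cm, 3, "AD", cmap, n_draws = 3000, seed = 11)
  expect_identical(null$deltas, null2$deltas)
  one <- build_null(cm, 3, "AD", cmap, n_draws = 1, seed = 2)
  expect_length(one$deltas, 1)
  expect_error(build_null(cm, 1000, "AD", cmap, 10, 1), "exceeds")
})

test_that("build_null deltas equal direct coexpression_delta evaluation", {
  withr::with_seed(15, vals <- matrix(rnorm(30 * 16), 30, 16))
  cm <- make_cm(vals, classes = rep(c("MS", "CTRL"), each = 8))
  cmap <- class_map(cm)
  null <- build_null(cm, 4, "MS", cmap, n_draws = 5, seed = 21)
  # reproduce the draws with the same generator and compare against the
  # scalar path
  withr::with_seed(21, {
    for (i in 1:5) {
      idx <- sample.int(30, 4)
      direct <- coexpression_delta(cm, rownames(cm$values)[idx], "MS",
                                   cmap)
      expect_equal(null$deltas[i], direct$delta, tolerance = 1e-9)
    }
  })
})

test_that("empirical_p follows the add-one two-sided estimator", {
  null <- structure(list(deltas = seq(-0.5, 0.5, length.out = 100),
                         n_draws = 100L), class = "null_distribution")
  expect_equal(empirical_p(9, null), 1 / 101)
  expect_equal(empirical_p(0, null), 1)       # every |d| >= 0
  expect_equal(empirical_p(0.5, null), 3 / 101) # ties at both extremes
})

test_that("bh_correct matches the textbook step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_correct(p), rep(0.04, 4))
  expect_equal(bh_correct(0.37), 0.37)
  expect_equal(bh_correct(rep(1, 5)), rep(1, 5))
  withr::with_seed(9, p_rand <- runif(50)^2)
  expect_equal(bh_correct(p_rand), oracle_bh(p_rand))
  expect_error(bh_correct(c(0.5, 0)), "0, 1")
  expect_error(bh_correct(c(0.5, 1.2)), "0, 1")
})

test_that("refine_all keeps a disease-only module and drops a global one", {
  # module A: correlated only in AD+MS; module B: correlated everywhere
  n_ad <- 10; n_ms <- 10; n_ct <- 20
  classes <- c(rep("AD", n_ad), rep("MS", n_ms), rep("CTRL", n_ct))
  withr::with_seed(23, {
    vals <- matrix(rnorm(60 * 40), 60, 40)
    fA <- rnorm(n_ad + n_ms); fB <- rnorm(40)
    for (i in 1:4) vals[i, 1:20] <- fA + rnorm(20, sd = 0.2)
    for (i in 5:8) vals[i, ] <- fB + rnorm(40, sd = 0.2)
  })
  rownames(vals) <- sprintf("g%02d", 1:60)
  cm <- make_cm(vals, classes = classes)
  bcs <- tibble::tibble(
    genes = list(rownames(vals)[1:4], rownames(vals)[5:8]),
    samples = list(colnames(cm$values)[1:20], colnames(cm$values)))
  ref <- refine_all(bcs, cm, alpha = 0.005, n_draws = 2000, seed = 31)
  expect_equal(nrow(ref$tested), 2)
  td <- tidy(ref)
  expect_equal(nrow(td), 1)
  expect_equal(td$combination, "AD+MS")
  expect_equal(td$direction, "gain")
  expect_setequal(td$genes[[1]], rownames(vals)[1:4])

  # an impossible threshold empties the result but not the tested table
  ref0 <- refine_all(bcs, cm, alpha = 0, n_draws = 500, seed = 31)
  expect_equal(nrow(ref0$sets), 0)
  expect_equal(nrow(ref0$tested), 2)

  # input order does not matter
  ref_rev <- refine_all(bcs[2:1, ], cm, alpha = 0.005, n_draws = 2000,
                        seed = 31)
  expect_equal(tidy(ref_rev), td)
})

test_that("null cache reuses identical distributions", {
  withr::with_seed(43, vals <- matrix(rnorm(50 * 20), 50, 20))
  cm <- make_cm(vals, classes = rep(c("HD", "CTRL"), each = 10))
  cmap <- class_map(cm)
  # two biclusters with the same size and combination share one null:
  # their p-values must equal a fresh scalar computation with the same
  # derived seed
  bcs <- tibble::tibble(
    genes = list(rownames(cm$values)[1:3], rownames(cm$values)[11:13]),
    samples = list(colnames(cm$values), colnames(cm$values)))
  ref <- refine_all(bcs, cm, alpha = 1, n_draws = 1500, seed = 77)
  key <- paste(3, "HD")
  null <- build_null(cm, 3, "HD", cmap, n_draws = 1500,
                     seed = transcoex:::derive_seed(77, key))
  for (i in 1:2) {
    d <- ref$tested$delta[i]
    expect_equal(ref$tested$p_value[i], empirical_p(d, null))
  }
})

test_that("glance summarizes a refinement run", {
  withr::with_seed(47, vals <- matrix(rnorm(40 * 30), 40, 30))
  cm <- make_cm(vals, classes = c(rep("BD", 10), rep("CTRL", 20)))
  bcs <- tibble::tibble(genes = list(rownames(cm$values)[1:3]),
                        samples = list(colnames(cm$values)[1:10]))
  ref <- refine_all(bcs, cm, alpha = 0.5, n_draws = 500, seed = 3)
  g <- glance(ref)
  expect_equal(g$n_input, 1)
  expect_equal(g$n_tested, 1)
  expect_equal(g$n_significant + (g$n_tested - g$n_significant), 1)
  expect_equal(g$alpha, 0.5)
})
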