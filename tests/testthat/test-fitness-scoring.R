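test_that("median-ratio normalization satisfies its stated identities", {
  set.seed(1)
  a <- rpois(200, 100) + 1L
  m <- cbind(s1 = a, s2 = a)
  rownames(m) <- paste0("g", seq_len(200))
  n1 <- normalize_counts(m)
  expect_equal(unname(n1$size_factors), c(1, 1))
  expect_equal(n1$normalized, m + 0)

  # doubled column: factors in ratio 1:2 (geometric mean 1 by the
  # median-of-ratios construction), normalized columns identical
  m2 <- cbind(s1 = a, s2 = 2L * a)
  rownames(m2) <- rownames(m)
  n2 <- normalize_counts(m2)
  expect_equal(unname(n2$size_factors[2] / n2$size_factors[1]), 2,
               tolerance = 1e-12)
  expect_equal(unname(prod(n2$size_factors)), 1, tolerance = 1e-12)
  expect_equal(n2$normalized[, 1], n2$normalized[, 2])
})

test_that("guides with a zero count are excluded from the geometric-mean set", {
  set.seed(2)
  a <- rpois(300, 50) + 1L
  m <- cbind(s1 = a, s2 = a)
  rownames(m) <- paste0("g", seq_len(300))
  # zeroing one guide in one sample must not perturb the size factors
  # beyond the median's robustness (it is simply dropped from the set)
  m[1, 2] <- 0L
  sf <- normalize_counts(m)$size_factors
  geo <- exp(rowMeans(log(m[-1, ])))
  expect_equal(unname(sf),
               unname(apply(m[-1, ], 2, function(col) median(col / geo))))
})

test_that("median-ratio agrees with the DESeq size-factor estimator", {
  skip_if_not_installed("DESeq2")
  s <- sim_small_screen(n_genes = 50, seed = 61)
  sf <- normalize_counts(s$counts)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(s$counts$counts)
  # same estimator up to the all-positive-guide filtering convention
  expect_equal(unname(sf), unname(ref), tolerance = 0.02)
})

test_that("median-ratio falls back to total_count on sparse matrices", {
  set.seed(3)
  m <- matrix(rpois(50 * 4, 2), 50, 4,
              dimnames = list(paste0("g", 1:50),
                              paste0("s", 1:4)))
  m[seq(1, 50, 2), 1] <- 0L
  expect_warning(res <- normalize_counts(m), "falling back")
  expect_equal(res$method, "total_count")
  expect_equal(unname(res$size_factors),
               unname(colSums(m) / mean(colSums(m))))
  m0 <- m; m0[, 2] <- 0L
  expect_error(normalize_counts(m0), "all-zero")
})

test_that("guide log2fc pairs replicates and averages over pairs", {
  m <- rbind(g1 = c(a1 = 19, a2 = 39, b1 = 9, b2 = 19),
             g2 = c(10, 10, 10, 10))
  lfc <- guide_log2fc(m, c("a1", "a2"), c("b1", "b2"), pseudocount = 1)
  expect_equal(unname(lfc["g1"]), 1.0)  # log2(20/10), log2(40/20)
  expect_equal(unname(lfc["g2"]), 0.0)
  # pseudocount -> 0 limit of 20 vs 10
  m2 <- rbind(g1 = c(a1 = 20, b1 = 10))
  expect_equal(unname(guide_log2fc(m2, "a1", "b1", 1e-12)["g1"]), 1.0,
               tolerance = 1e-9)
  expect_error(guide_log2fc(m, c("a1", "a2"), "b1"), "mismatch")
})

test_that("z-score transform matches the (x - mean)/SD convention", {
  expect_equal(as.numeric(zscore_transform(c(2, 4, 6))), c(-1, 0, 1))
  z <- zscore_transform(rnorm(100, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  zc <- zscore_transform(rep(3, 5))
  expect_true(attr(zc, "degenerate"))
  expect_equal(as.numeric(zc), rep(0, 5))
  expect_error(zscore_transform(1), ">= 2")
})

test_that("gene fitness score is the median of guide z-scores", {
  lib <- data.frame(
    guide_id = c("a1", "a2", "a3", "b1", "b2", "c1", "n1"),
    gene = c("GA", "GA", "GA", "GB", "GB", "GC", "NTC"),
    spacer = c("AAAAAAAAAAGGGGGGGGGG", "CAAAAAAAAAGGGGGGGGGG",
               "GAAAAAAAAAGGGGGGGGGG", "TAAAAAAAAAGGGGGGGGGG",
               "ACAAAAAAAAGGGGGGGGGG", "AGAAAAAAAAGGGGGGGGGG",
               "ATAAAAAAAAGGGGGGGGGG"))
  class(lib) <- c("guide_library", "data.frame")
  z <- c(a1 = -2, a2 = -1, a3 = 0, b1 = -2, b2 = 0, c1 = 0.7, n1 = 5)
  gs <- gene_fitness_scores(z, lib)
  expect_equal(gs$fitness_score[match(c("GA", "GB", "GC"), gs$gene)],
               c(-1, -1, 0.7))
  expect_equal(gs$n_guides[match("GA", gs$gene)], 3L)
  expect_false("NTC" %in% gs$gene)
  # fitness score bounded by guide extremes
  expect_true(all(gs$fitness_score >= tapply(z[1:6], lib$gene[1:6], min) &
                  gs$fitness_score <= tapply(z[1:6], lib$gene[1:6], max)))
})

test_that("pipeline fitness scores equal the brute-force recomputation", {
  for (seed in c(101, 202)) {
    s <- sim_small_screen(n_genes = 90,
                          fractions = c(neutral = 0.8, core_essential = 0.1,
                                        resensitizer = 0.1),
                          n_ntc = 100, seed = seed)
    sc <- score_screen(s$counts, s$lib)
    oracle <- brute_fitness(s$counts$counts, s$lib)
    got <- setNames(sc$genes$fitness_score, sc$genes$gene)[names(oracle)]
    expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
  }
})

test_that("scaling one sample leaves median-ratio log2fc unchanged", {
  s <- sim_small_screen(n_genes = 50, seed = 71)
  m <- s$counts$counts
  m2 <- m
  m2[, "treatment_T24_rep1"] <- 3L * m2[, "treatment_T24_rep1"]
  pc <- 1e-9
  lfc <- function(mm) {
    n <- normalize_counts(mm)$normalized
    guide_log2fc(n, sprintf("treatment_T24_rep%d", 1:3),
                 sprintf("treatment_T0_rep%d", 1:3), pc)
  }
  expect_equal(lfc(m), lfc(m2), tolerance = 1e-6)
})

test_that("lowering a treatment T24 count never raises that guide's z", {
  s <- sim_small_screen(n_genes = 40, seed = 81)
  base <- score_screen(s$counts, s$lib)
  gid <- s$lib$guide_id[5]
  for (drop_to in c(0.5, 0.1, 0)) {
    m <- s$counts$counts
    cols <- sprintf("treatment_T24_rep%d", 1:3)
    m[gid, cols] <- as.integer(floor(m[gid, cols] * drop_to))
    alt <- score_screen(screen_counts(m), s$lib)
    i <- match(gid, alt$guides$guide_id)
    expect_lte(alt$guides$z_treatment[i],
               base$guides$z_treatment[match(gid, base$guides$guide_id)] +
                 1e-10)
  }
})

test_that("per-arm selection scores recover arm-specific selection", {
  s <- sim_small_screen(
    n_genes = 100,
    fractions = c(neutral = 0.9, resensitizer = 0.1),
    effects = list(neutral = c(0, 0), resensitizer = c(0, -0.3)),
    seed = 91)
  sel <- arm_selection_scores(s$counts, s$lib)
  res <- s$truth$gene[s$truth$effect_class == "resensitizer"]
  is_res <- sel$gene %in% res
  expect_true(all(sel$treatment_score[is_res] < -2))
  expect_true(mean(abs(sel$control_score[is_res]) < 1) > 0.9)

  neutral <- sim_small_screen(n_genes = 100, seed = 92)
  seln <- arm_selection_scores(neutral$counts, neutral$lib)
  expect_gt(mean(abs(seln$control_score) < 1 &
                 abs(seln$treatment_score) < 1), 0.95)

  # missing treatment T0 samples
  m <- s$counts$counts
  m <- m[, !grepl("treatment_T0", colnames(m))]
  expect_error(score_screen(screen_counts(m), s$lib), "no treatment T0")
})

test_that("the direct T24 contrast and NTC centering are available", {
  s <- sim_small_screen(n_genes = 30, seed = 95)
  direct <- score_screen(s$counts, s$lib, contrast = "t24")
  expect_equal(direct$contrast, "t24")
  centered <- score_screen(s$counts, s$lib, ntc_center = TRUE)
  expect_equal(median(centered$ntc_z), 0, tolerance = 1e-12)
})
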