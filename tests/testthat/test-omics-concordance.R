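test_that("interval overlap uses half-open semantics", {
  a <- data.frame(chrom = "chr1", start = 0, end = 10)
  b <- data.frame(chrom = "chr1", start = 10, end = 20)
  expect_equal(nrow(find_overlaps(a, b)), 0)   # abutting

  b2 <- data.frame(chrom = "chr1", start = 5, end = 15)
  ov <- find_overlaps(a, b2)
  expect_equal(ov, data.frame(index_a = 1L, index_b = 1L))

  # different chromosomes never overlap
  b3 <- data.frame(chrom = "chr2", start = 0, end = 10)
  expect_equal(nrow(find_overlaps(a, b3)), 0)

  expect_error(find_overlaps(data.frame(chrom = "chr1", start = 5, end = 5),
                             b2), "malformed")
})

test_that("interval overlap matches brute-force enumeration", {
  for (seed in c(31, 32, 33)) {
    set.seed(seed)
    a <- random_intervals(200)
    b <- random_intervals(200)
    got <- find_overlaps(a, b)
    exp <- brute_overlaps(a, b)
    rownames(exp) <- NULL
    expect_equal(got, exp)
    # symmetry up to transposition (as unordered pair sets)
    rev <- find_overlaps(b, a)
    expect_setequal(paste(got$index_a, got$index_b),
                    paste(rev$index_b, rev$index_a))
  }
})

test_that("peak classification applies the log2FC and p rules", {
  peaks <- data.frame(peak_id = paste0("p", 1:4), chrom = "chr1",
                      start = c(0, 100, 200, 300),
                      end = c(50, 150, 250, 350),
                      log2fc = c(0.8, 0.8, -1.2, 0.1),
                      p = c(0.01, 0.20, 0.001, 0.001))
  cl <- classify_peaks(peaks, lfc_threshold = 0.5)
  expect_equal(as.character(cl$class),
               c("gained", "retained", "lost", "retained"))
  cl2 <- classify_peaks(peaks, lfc_threshold = 1.0)
  expect_equal(as.character(cl2$class[3]), "lost")
  expect_equal(as.character(cl2$class[1]), "retained")

  # partition + threshold monotonicity over random tables
  set.seed(41)
  rnd <- data.frame(peak_id = paste0("p", 1:300), chrom = "chr1",
                    start = 1:300, end = 2:301,
                    log2fc = rnorm(300), p = runif(300))
  loose <- classify_peaks(rnd, 0.5)
  tight <- classify_peaks(rnd, 1.0)
  expect_equal(sum(table(loose$class)), 300)
  expect_lte(sum(tight$class == "gained"), sum(loose$class == "gained"))
  expect_lte(sum(tight$class == "lost"), sum(loose$class == "lost"))
  expect_error(classify_peaks(rnd[, -5], 0.5), "log2fc")
})

test_that("peaks assign to genes through promoters and links, strand-aware", {
  tss <- data.frame(gene = c("PLUS", "MINUS"), chrom = "chr1",
                    pos = c(10000, 50000), strand = c("+", "-"))
  links <- data.frame(chrom = "chr1", start = 70000, end = 71000,
                      gene = "PLUS")
  peaks <- data.frame(
    peak_id = c("prom_plus", "up_minus", "enh", "nowhere"),
    chrom = "chr1",
    # MINUS upstream window is mirrored downstream in genome coordinates
    start = c(9000, 50600, 70200, 30000),
    end = c(9500, 50900, 70400, 30200))
  asg <- assign_peaks_to_genes(peaks, tss, c(2000, 500), links)
  expect_setequal(paste(asg$peak_id, asg$gene, asg$source),
                  c("prom_plus PLUS promoter", "up_minus MINUS promoter",
                    "enh PLUS link"))

  # a + strand peak upstream beyond the window does not assign
  none <- assign_peaks_to_genes(
    data.frame(peak_id = "far", chrom = "chr1", start = 7000, end = 7500),
    tss, c(2000, 500))
  expect_equal(nrow(none), 0)

  expect_warning(assign_peaks_to_genes(
    data.frame(peak_id = "x", chrom = "chrUn", start = 1, end = 10),
    tss, c(2000, 500)), "absent")
})

test_that("concordance counts directional gene-peak agreement", {
  de <- data.frame(gene = c("u1", "u2", "u3", "d1", "d2"),
                   direction = c("up", "up", "up", "down", "down"))
  asg <- data.frame(peak_id = c("p1", "p2", "p3"),
                    gene = c("u1", "d1", "u2"),
                    source = "promoter",
                    class = factor(c("gained", "lost", "lost"),
                                   c("gained", "lost", "retained")))
  rep <- concordance(de, asg)
  expect_equal(rep$n_concordant_up, 1)
  expect_equal(rep$n_concordant_down, 1)
  expect_equal(rep$fraction_all, 2 / 5)
  expect_equal(rep$fraction_linked, 2 / 3)
  expect_gte(rep$fraction_linked, rep$fraction_all)

  all_conc <- concordance(de[1:2, ],
                          data.frame(peak_id = c("a", "b"),
                                     gene = c("u1", "u2"),
                                     class = factor(c("gained", "gained"),
                                                    c("gained", "lost",
                                                      "retained"))))
  expect_equal(all_conc$fraction_all, 1)
  expect_error(concordance(de[0, ], asg), "empty")
})

test_that("the generator's concordance target is recovered end to end", {
  sat <- simulate_omics_tables(300, 400, 1.0, seed = 51)
  expect_equal(concordance_pipeline(sat)$fraction_all, 1.0)

  nul <- simulate_omics_tables(300, 400, 0.0, seed = 52)
  expect_equal(concordance_pipeline(nul)$fraction_all, 0.0)

  mid <- simulate_omics_tables(2000, 2600, 0.45, seed = 53)
  got <- concordance_pipeline(mid)$fraction_all
  expect_lt(abs(got - 0.45), 0.02)
})

test_that("TSS profiles average signal with strand flipping", {
  tss <- data.frame(gene = c("gp", "gm"), chrom = "chr1",
                    pos = c(5000, 20000), strand = c("+", "-"))
  flat <- data.frame(chrom = "chr1", start = 0, end = 30000, value = 2.5)
  prof <- tss_profile(flat, tss, window = 1000, n_bins = 10)
  expect_equal(unname(prof["all", ]), rep(2.5, 10))

  # delta at each TSS, explicit zero elsewhere -> peak h at the center bin
  h <- 7
  delta <- rbind(
    data.frame(chrom = "chr1", start = c(5000, 20000),
               end = c(5001, 20001), value = h))
  prof2 <- tss_profile(delta, tss, window = 1000, n_bins = 10)
  expect_equal(unname(prof2["all", 6]), h)  # bin [0, 200) holds the TSS
  expect_equal(unname(prof2["all", -6]), rep(0, 9))

  # asymmetric signal flips for the - strand gene
  asym <- data.frame(chrom = "chr1",
                     start = c(5000, 19000), end = c(6000, 20000),
                     value = 1)   # downstream of gp, downstream of gm
  prof3 <- tss_profile(asym, tss, window = 1000, n_bins = 2,
                       groups = c(gp = "A", gm = "B"))
  expect_equal(unname(prof3["A", ]), c(0, 1))
  expect_equal(unname(prof3["B", ]), c(0, 1))
  expect_equal(nrow(prof3), 2)

  # gene with no coverage is skipped with a count
  far <- data.frame(chrom = "chr1", start = 0, end = 6001, value = 1)
  prof4 <- tss_profile(far, tss, window = 1000, n_bins = 4)
  expect_equal(attr(prof4, "n_skipped"), 1)
  expect_error(tss_profile(flat, tss, window = 1000, n_bins = 7), "evenly")
})

test_that("peak BED round-trips bit-exact on 0-based coordinates", {
  peaks <- data.frame(peak_id = c("p1", "p2"), chrom = c("chr1", "chr2"),
                      start = c(0L, 250L), end = c(100L, 900L),
                      strand = c(".", "."),
                      log2fc = c(1.25, -0.5), p = c(0.001, 0.2))
  path <- withr::local_tempfile(fileext = ".bed")
  write_peak_bed(peaks, path)
  back <- read_peak_bed(path)
  expect_equal(back[c("peak_id", "chrom", "start", "end", "log2fc", "p")],
               peaks[c("peak_id", "chrom", "start", "end", "log2fc", "p")])
})
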