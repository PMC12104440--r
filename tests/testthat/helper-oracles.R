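# Independent brute-force oracles; deliberately plain loops, no reuse of
# package internals beyond exported entry points under test.

# one-pass recomputation of the gene fitness score from a raw count
# matrix: median-ratio normalize -> replicate-paired log2fc -> delta ->
# z (n-1 SD) -> per-gene median
brute_fitness <- function(counts, lib, pseudocount = 1) {
  m <- counts
  pos <- apply(m, 1, function(r) all(r > 0))
  geo <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  sf <- apply(m[pos, , drop = FALSE], 2, function(col) median(col / geo))
  norm <- sweep(m, 2, sf, "/")

  lfc_arm <- function(arm) {
    reps <- sort(unique(as.integer(sub(".*_rep", "", colnames(m)))))
    per <- sapply(reps, function(k) {
      num <- norm[, sprintf("%s_T24_rep%d", arm, k)]
      den <- norm[, sprintf("%s_T0_rep%d", arm, k)]
      log2((num + pseudocount) / (den + pseudocount))
    })
    rowMeans(per)
  }
  delta <- lfc_arm("treatment") - lfc_arm("control")
  z <- (delta - mean(delta)) / sd(delta)
  z <- z[lib$guide_id]
  genes <- unique(lib$gene[lib$gene != "NTC"])
  out <- sapply(genes, function(g) median(z[lib$guide_id[lib$gene == g]]))
  sort_by_name <- order(names(out))
  out[sort_by_name]
}

# exhaustive ordered-pair AUC with half credit for ties;
# depleted (more negative) essential = correctly ordered
brute_auc <- function(ess_scores, non_scores) {
  total <- 0
  for (e in ess_scores) for (n in non_scores) {
    if (e < n) total <- total + 1
    else if (e == n) total <- total + 0.5
  }
  total / (length(ess_scores) * length(non_scores))
}

# O(n^2) half-open interval overlap enumeration
brute_overlaps <- function(a, b) {
  pairs <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) >= 1) {
      pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  if (!length(pairs))
    return(data.frame(index_a = integer(0), index_b = integer(0)))
  m <- do.call(rbind, pairs)
  df <- data.frame(index_a = m[, 1], index_b = m[, 2])
  df[order(a$chrom[df$index_a], a$start[df$index_a], b$start[df$index_b],
           df$index_a, df$index_b), , drop = FALSE]
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             span = 1000L) {
  start <- sample.int(span, n, replace = TRUE) - 1L
  width <- sample.int(50L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width)
}

# small standard screen used across tests
sim_small_screen <- function(n_genes = 100, fractions = c(neutral = 1),
                             effects = default_effect_params(),
                             n_ntc = 100, design = sim_design(),
                             seed = 11) {
  lib <- build_library(n_genes, 10, n_ntc, seed = seed)
  tt <- assign_truth(lib, fractions, effects, seed = seed + 1)
  list(lib = lib, truth = tt,
       counts = simulate_screen_counts(lib, tt, design, seed = seed + 2))
}
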