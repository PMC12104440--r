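#' Simulate paired differential-accessibility / expression tables
#'
#' Builds a synthetic single-chromosome gene annotation (genes spaced
#' 100 kb apart, alternating strand), a DE gene table where every gene is
#' significantly up- or down-regulated, a peak table with per-peak log2FC
#' and p-value, and an enhancer-link table, such that the expected
#' fraction of DE genes carrying a concordant significant peak (gained
#' for up genes, lost for down genes, under the given thresholds) equals
#' \code{concordance_target}: the number of concordant genes is the
#' rounded target count (which genes is randomized), so every target is
#' recovered to within half a gene. Concordant peaks sit in
#' the gene's promoter or in a distal linked enhancer (50/50); the
#' remaining peak budget produces discordant or sub-threshold promoter
#' peaks and unassigned background peaks, none of which can create
#' concordance.
#'
#' @param n_genes number of DE genes (>= 1).
#' @param n_peaks total number of peaks; must cover the concordant
#'   assignments drawn.
#' @param concordance_target fraction in [0, 1].
#' @param lfc_threshold,p_threshold the significance thresholds the peak
#'   statistics are generated around.
#' @param seed integer seed.
#' @return list of class \code{omics_bundle}: \code{peaks}, \code{de},
#'   \code{tss}, \code{links}, \code{concordance_target},
#'   \code{concordant_genes}, \code{lfc_threshold}, \code{p_threshold}.
#' @export
simulate_omics_tables <- function(n_genes, n_peaks,
                                  concordance_target = 0.4,
                                  lfc_threshold = 0.5, p_threshold = 0.05,
                                  seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes", min = 1L)
  n_peaks <- assert_count(n_peaks, "n_peaks", min = 0L)
  concordance_target <- assert_number(concordance_target,
                                      "concordance_target", min = 0, max = 1)
  lfc_threshold <- assert_number(lfc_threshold, "lfc_threshold", min = 0,
                                 strict_min = TRUE)
  p_threshold <- assert_number(p_threshold, "p_threshold", min = 0,
                               strict_min = TRUE)

  withr::with_seed(seed, {
    gene <- sprintf("G%06d", seq_len(n_genes))
    pos <- 50000 + (seq_len(n_genes) - 1) * 100000
    strand <- rep(c("+", "-"), length.out = n_genes)
    tss <- data.frame(gene = gene, chrom = "chr1", pos = pos,
                      strand = strand, stringsAsFactors = FALSE)

    up <- runif(n_genes) < 0.5
    de <- data.frame(gene = gene,
                     log2fc = ifelse(up, 1, -1) * runif(n_genes, 1, 3),
                     padj = runif(n_genes, 0, 0.009),
                     direction = ifelse(up, "up", "down"),
                     stringsAsFactors = FALSE)

    # rounded deterministic allocation: the recovered fraction equals the
    # target to within 1/(2 n_genes); gene identity is still randomized
    n_conc <- round(concordance_target * n_genes)
    conc <- rep(FALSE, n_genes)
    conc[sample.int(n_genes, n_conc)] <- TRUE
    if (n_peaks < n_conc)
      abort("n_peaks = %d < %d concordant assignments required",
            n_peaks, n_conc)

    sig_lfc <- function(n, sign)
      sign * (lfc_threshold + runif(n, 0.3, 1.5))
    weak_lfc <- function(n, sign) sign * runif(n, 0, lfc_threshold * 0.8)
    sig_p <- function(n) runif(n, 0, p_threshold * 0.8)
    null_p <- function(n) runif(n, p_threshold * 1.5,
                                min(1, p_threshold * 20))

    peaks <- list(); links <- list(); k <- 0L
    add_peak <- function(start, end, lfc, p) {
      k <<- k + 1L
      peaks[[k]] <<- data.frame(peak_id = sprintf("peak_%05d", k),
                                chrom = "chr1", start = start, end = end,
                                log2fc = lfc, p = p,
                                stringsAsFactors = FALSE)
    }

    # concordant genes: matching-direction significant peak,
    # promoter or linked enhancer
    sgn <- ifelse(up, 1, -1)
    via_link <- runif(n_genes) < 0.5
    for (i in which(conc)) {
      if (via_link[i]) {
        estart <- pos[i] + 20000
        add_peak(estart + 200, estart + 600, sig_lfc(1, sgn[i]), sig_p(1))
        links[[length(links) + 1L]] <-
          data.frame(chrom = "chr1", start = estart, end = estart + 1000,
                     gene = gene[i], stringsAsFactors = FALSE)
      } else {
        add_peak(pos[i] - 200, pos[i] + 200, sig_lfc(1, sgn[i]), sig_p(1))
      }
    }

    # non-concordant genes: discordant-significant or retained promoter
    # peaks while the budget lasts, then background peaks in gene deserts
    budget <- n_peaks - n_conc
    nc <- which(!conc)
    take <- nc[seq_len(min(length(nc), budget))]
    for (i in take) {
      if (runif(1) < 0.5) add_peak(pos[i] - 200, pos[i] + 200,
                                   sig_lfc(1, -sgn[i]), sig_p(1))
      else add_peak(pos[i] - 200, pos[i] + 200,
                    weak_lfc(1, sgn[i]), null_p(1))
    }
    budget <- budget - length(take)
    if (budget > 0) {
      for (j in seq_len(budget)) {
        # gene deserts: offsets 5000.. within a block stay clear of the
        # promoter (block + 48000..52500) and enhancers (block + 70000..)
        block <- (j - 1) %% n_genes
        off <- 5000 + (((j - 1) %/% n_genes) * 400) %% 40000
        start <- block * 100000 + off
        add_peak(start, start + 300, weak_lfc(1, 1), null_p(1))
      }
    }

    peaks <- if (k > 0) do.call(rbind, peaks)
             else data.frame(peak_id = character(0), chrom = character(0),
                             start = integer(0), end = integer(0),
                             log2fc = numeric(0), p = numeric(0))
    links <- if (length(links)) do.call(rbind, links)
             else data.frame(chrom = character(0), start = integer(0),
                             end = integer(0), gene = character(0))
    structure(list(peaks = peaks, de = de, tss = tss, links = links,
                   concordance_target = concordance_target,
                   concordant_genes = gene[conc],
                   lfc_threshold = lfc_threshold,
                   p_threshold = p_threshold),
              class = "omics_bundle")
  })
}

#' Run the full peak-classification / assignment / concordance path
#'
#' Convenience wrapper: classify peaks at the bundle's (or supplied)
#' thresholds, assign them to genes via promoter windows and links, and
#' compute the concordance report.
#'
#' @param bundle an \code{omics_bundle} (or a list with \code{peaks},
#'   \code{de}, \code{tss}, \code{links}).
#' @param lfc_threshold,p_threshold thresholds; default to the bundle's.
#' @param promoter_window passed to \code{\link{assign_peaks_to_genes}}.
#' @return a \code{concordance_report}.
#' @export
concordance_pipeline <- function(bundle, lfc_threshold = NULL,
                                 p_threshold = NULL,
                                 promoter_window = c(2000, 500)) {
  lfc <- if (is.null(lfc_threshold)) bundle$lfc_threshold else lfc_threshold
  p <- if (is.null(p_threshold)) bundle$p_threshold else p_threshold
  classified <- classify_peaks(bundle$peaks, lfc, p)
  asg <- assign_peaks_to_genes(classified, bundle$tss, promoter_window,
                               bundle$links)
  concordance(bundle$de, asg)
}
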