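SF_STRANDS <- c("+", "-", ".")

# data.frame(chrom, start, end) in 0-based half-open coordinates -> GRanges;
# `levels` fixes a common seqlevel universe across interval sets
as_granges0 <- function(df, what = "interval", levels = NULL) {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(df)))
    abort("%s table needs columns %s", what, paste(req, collapse = ", "))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    abort("malformed %s at record %d: start %s, end %s", what, bad[1],
          format(df$start[bad[1]]), format(df$end[bad[1]]))
  if (is.null(levels)) levels <- unique(as.character(df$chrom))
  GenomicRanges::GRanges(factor(df$chrom, levels = levels),
                         IRanges::IRanges(df$start + 1L, df$end))
}

#' Overlapping interval pairs (0-based half-open)
#'
#' Reports every pair (i, j) whose intervals share at least one base on
#' the same chromosome under BED half-open semantics — abutting intervals
#' do not overlap. Pairs are sorted by (chrom, start in A, start in B).
#'
#' @param a,b data.frames with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @return data.frame with columns \code{index_a}, \code{index_b} (row
#'   indices into \code{a} and \code{b}).
#' @export
find_overlaps <- function(a, b) {
  lv <- union(unique(as.character(a$chrom)), unique(as.character(b$chrom)))
  ga <- as_granges0(a, "query", levels = lv)
  gb <- as_granges0(b, "subject", levels = lv)
  h <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L)
  ia <- S4Vectors::queryHits(h)
  ib <- S4Vectors::subjectHits(h)
  ord <- order(a$chrom[ia], a$start[ia], b$start[ib], ia, ib)
  data.frame(index_a = ia[ord], index_b = ib[ord])
}

#' Classify differential-accessibility peaks
#'
#' A peak is \code{gained} when \code{log2fc > +lfc_threshold} with
#' \code{p < p_threshold}, \code{lost} when \code{log2fc < -lfc_threshold}
#' with \code{p < p_threshold}, and \code{retained} otherwise. p-values
#' are used raw by default; \code{adjust = "BH"} applies
#' Benjamini-Hochberg before thresholding.
#'
#' @param peaks data.frame with at least \code{log2fc} and \code{p}
#'   (typically also \code{peak_id}, \code{chrom}, \code{start},
#'   \code{end}).
#' @param lfc_threshold absolute log2FC cutoff (> 0); 0.5 and 1 are the
#'   conventional choices.
#' @param p_threshold p-value cutoff (> 0).
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return the input with an added \code{class} factor
#'   (gained/lost/retained); attribute \code{"proportions"} holds the
#'   class proportions.
#' @export
classify_peaks <- function(peaks, lfc_threshold = 0.5, p_threshold = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  lfc_threshold <- assert_number(lfc_threshold, "lfc_threshold", min = 0,
                                 strict_min = TRUE)
  p_threshold <- assert_number(p_threshold, "p_threshold", min = 0,
                               strict_min = TRUE)
  for (col in c("log2fc", "p")) {
    if (is.null(peaks[[col]])) abort("peak table lacks column '%s'", col)
    bad <- which(!is.finite(peaks[[col]]))
    if (length(bad)) abort("missing %s at peak record %d", col, bad[1])
  }
  p <- if (adjust == "BH") stats::p.adjust(peaks$p, "BH") else peaks$p
  sig <- p < p_threshold
  cls <- ifelse(sig & peaks$log2fc > lfc_threshold, "gained",
                ifelse(sig & peaks$log2fc < -lfc_threshold, "lost",
                       "retained"))
  peaks$class <- factor(cls, levels = c("gained", "lost", "retained"))
  attr(peaks, "proportions") <- prop.table(table(peaks$class))
  peaks
}

#' Assign peaks to genes via promoter windows and enhancer links
#'
#' A peak is assigned to a gene with source \code{"promoter"} when it
#' overlaps the strand-aware promoter window around the gene's TSS
#' (\code{[tss - upstream, tss + downstream)} on the + strand, mirrored on
#' the - strand), and with source \code{"link"} when it overlaps an
#' element linked to the gene. A peak may map to several genes; duplicate
#' (peak, gene) pairs keep the promoter source.
#'
#' @param peaks data.frame with \code{peak_id}, \code{chrom},
#'   \code{start}, \code{end} and (if present) \code{class}.
#' @param tss data.frame with \code{gene}, \code{chrom}, \code{pos}
#'   (0-based TSS position), \code{strand} (+/-).
#' @param promoter_window numeric \code{c(upstream, downstream)} in bases.
#' @param links optional data.frame of linked elements: \code{chrom},
#'   \code{start}, \code{end}, \code{gene} (0-based half-open).
#' @return data.frame with columns \code{peak_id}, \code{gene},
#'   \code{source} and, when \code{peaks} carries one, \code{class}.
#' @export
assign_peaks_to_genes <- function(peaks, tss,
                                  promoter_window = c(2000, 500),
                                  links = NULL) {
  up <- assert_number(promoter_window[1], "upstream", min = 0)
  down <- assert_number(promoter_window[2], "downstream", min = 0)
  if (!all(tss$strand %in% c("+", "-")))
    abort("tss strand must be '+' or '-'")
  unk <- setdiff(unique(peaks$chrom), unique(tss$chrom))
  if (length(unk))
    warning(sprintf("%d peak chromosome(s) absent from the TSS table",
                    length(unk)), call. = FALSE)

  plus <- tss$strand == "+"
  prom <- data.frame(chrom = tss$chrom,
                     start = pmax(0, ifelse(plus, tss$pos - up,
                                            tss$pos - down)),
                     end = ifelse(plus, tss$pos + down, tss$pos + up))
  hits <- find_overlaps(peaks, prom)
  out <- data.frame(peak_id = peaks$peak_id[hits$index_a],
                    gene = tss$gene[hits$index_b],
                    source = rep("promoter", nrow(hits)),
                    stringsAsFactors = FALSE)
  if (!is.null(links) && nrow(links)) {
    lh <- find_overlaps(peaks, links)
    out <- rbind(out,
                 data.frame(peak_id = peaks$peak_id[lh$index_a],
                            gene = links$gene[lh$index_b],
                            source = rep("link", nrow(lh)),
                            stringsAsFactors = FALSE))
  }
  out <- out[!duplicated(out[c("peak_id", "gene")]), , drop = FALSE]
  if (!is.null(peaks$class))
    out$class <- peaks$class[match(out$peak_id, peaks$peak_id)]
  rownames(out) <- NULL
  out
}

#' DE-gene / differential-peak concordance
#'
#' An up-regulated DE gene is concordant when at least one peak assigned
#' to it is gained; a down-regulated gene when at least one assigned peak
#' is lost. Two denominators are reported: all DE genes, and DE genes with
#' at least one assigned peak.
#'
#' @param de data.frame with columns \code{gene} and \code{direction}
#'   (\code{"up"}/\code{"down"}) or \code{log2fc} (sign used).
#' @param assignments peak-gene pairs with a \code{class} column, as from
#'   \code{\link{assign_peaks_to_genes}} on classified peaks.
#' @return list of class \code{concordance_report}: \code{n_de_up},
#'   \code{n_de_down}, \code{n_concordant_up}, \code{n_concordant_down},
#'   \code{n_de_linked}, \code{fraction_all} and \code{fraction_linked}
#'   (overall concordant fractions over the two denominators), plus the
#'   per-direction fractions \code{fraction_up}, \code{fraction_down}.
#' @export
concordance <- function(de, assignments) {
  if (nrow(de) == 0L) abort("DE table is empty")
  dir <- de$direction
  if (is.null(dir)) {
    if (is.null(de$log2fc)) abort("DE table needs 'direction' or 'log2fc'")
    dir <- ifelse(de$log2fc >= 0, "up", "down")
  }
  if (is.null(assignments$class))
    abort("assignments need a peak 'class' column")
  gained <- unique(assignments$gene[assignments$class == "gained"])
  lost <- unique(assignments$gene[assignments$class == "lost"])
  linked <- unique(assignments$gene)

  up <- de$gene[dir == "up"]; down <- de$gene[dir == "down"]
  conc_up <- sum(up %in% gained)
  conc_down <- sum(down %in% lost)
  n_de <- length(up) + length(down)
  n_linked <- sum(de$gene %in% linked)
  structure(list(
    n_de_up = length(up), n_de_down = length(down),
    n_concordant_up = conc_up, n_concordant_down = conc_down,
    n_de_linked = n_linked,
    fraction_all = (conc_up + conc_down) / n_de,
    fraction_linked = if (n_linked > 0)
      (conc_up + conc_down) / n_linked else NA_real_,
    fraction_up = if (length(up)) conc_up / length(up) else NA_real_,
    fraction_down = if (length(down)) conc_down / length(down) else NA_real_),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: %d/%d DE genes concordant (%.1f%% of all DE, %.1f%% of linked DE)\n",
              x$n_concordant_up + x$n_concordant_down,
              x$n_de_up + x$n_de_down,
              100 * x$fraction_all, 100 * x$fraction_linked))
  invisible(x)
}

#' Mean signal profile around TSSs, by gene group
#'
#' Averages a binned coverage track over \code{[tss - window,
#' tss + window)} for each gene, flipping the orientation of - strand
#' genes, and returns the per-bin mean within each gene group. Bin values
#' are coverage-weighted means over the bases the track covers; bins with
#' no covered base contribute 0. Genes whose window has no coverage at all
#' are skipped (count reported).
#'
#' @param signal bedGraph-like data.frame: \code{chrom}, \code{start},
#'   \code{end}, \code{value} (0-based half-open).
#' @param tss data.frame as in \code{\link{assign_peaks_to_genes}}.
#' @param window half-width in bases (> 0).
#' @param n_bins number of bins; must divide \code{2 * window} evenly.
#' @param groups optional named character vector gene -> group; ungrouped
#'   genes fall into \code{"all"}.
#' @return matrix (groups x bins) of mean signal; attribute
#'   \code{"n_skipped"} counts genes without coverage, attribute
#'   \code{"bin_centers"} gives bin midpoints relative to the TSS.
#' @export
tss_profile <- function(signal, tss, window = 2000L, n_bins = 40L,
                        groups = NULL) {
  window <- assert_count(window, "window", min = 1L)
  n_bins <- assert_count(n_bins, "n_bins", min = 1L)
  if ((2 * window) %% n_bins != 0)
    abort("n_bins must divide 2*window evenly")
  bw <- 2 * window / n_bins
  grp <- if (is.null(groups)) setNames(rep("all", nrow(tss)), tss$gene)
         else groups
  lv <- union(unique(as.character(signal$chrom)),
              unique(as.character(tss$chrom)))
  gsig <- as_granges0(signal, "signal", levels = lv)

  # - strand windows shift by one base so that after flipping the TSS base
  # occupies the mirror image of the bin it occupies on the + strand
  shift <- ifelse(tss$strand == "-", 1L, 0L)
  starts <- rep(tss$pos + shift, each = n_bins) - window +
    rep(seq_len(n_bins) - 1L, times = nrow(tss)) * bw
  bins <- data.frame(chrom = rep(tss$chrom, each = n_bins),
                     start = pmax(0, starts),
                     end = pmax(starts + bw, pmax(0, starts)))
  gb <- GenomicRanges::GRanges(factor(bins$chrom, levels = lv),
                               IRanges::IRanges(bins$start + 1L, bins$end))
  h <- GenomicRanges::findOverlaps(gb, gsig)
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  ov <- pmin(bins$end[qi], signal$end[si]) -
    pmax(bins$start[qi], signal$start[si])
  wsum <- numeric(nrow(bins)); vsum <- numeric(nrow(bins))
  agg_w <- tapply(ov, qi, sum)
  agg_v <- tapply(ov * signal$value[si], qi, sum)
  idx <- as.integer(names(agg_w))
  wsum[idx] <- agg_w; vsum[idx] <- agg_v

  binval <- ifelse(wsum > 0, vsum / pmax(wsum, 1), 0)
  m <- matrix(binval, nrow = nrow(tss), ncol = n_bins, byrow = TRUE)
  m[tss$strand == "-", ] <- m[tss$strand == "-", n_bins:1, drop = FALSE]

  covered <- rowSums(matrix(wsum, nrow = nrow(tss), byrow = TRUE)) > 0
  n_skipped <- sum(!covered)
  m <- m[covered, , drop = FALSE]
  gg <- unname(grp[tss$gene[covered]])
  gg[is.na(gg)] <- "all"
  prof <- do.call(rbind, lapply(split(seq_len(nrow(m)), gg), function(i)
    colMeans(m[i, , drop = FALSE])))
  attr(prof, "n_skipped") <- n_skipped
  attr(prof, "bin_centers") <- seq(-window + bw / 2, window - bw / 2, by = bw)
  prof
}

#' Read a BED6+ peak file with log2fc and p extra columns
#'
#' Columns: chrom, start, end, name, score, strand, log2fc, p
#' (tab-delimited, no header, 0-based half-open).
#'
#' @param path file path.
#' @return peak data.frame with columns \code{peak_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{log2fc}, \code{p}.
#' @export
read_peak_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 8L) abort("expected BED6+2 (chrom start end name score strand log2fc p)")
  out <- data.frame(peak_id = df[[4]], chrom = df[[1]], start = df[[2]],
                    end = df[[3]], strand = df[[6]], log2fc = df[[7]],
                    p = df[[8]], stringsAsFactors = FALSE)
  as_granges0(out, "peak")  # validates coordinates
  out
}

#' @rdname read_peak_bed
#' @param peaks a peak data.frame.
#' @export
write_peak_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                   0L, if (is.null(peaks$strand)) "." else peaks$strand,
                   peaks$log2fc, peaks$p)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
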