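#' Read a reference gene list
#'
#' One gene symbol per line; blank lines and \code{#} comments ignored.
#'
#' @param path file path.
#' @return character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Essentiality ROC quality control
#'
#' Ranks genes by score and measures how well reference core-essential
#' genes separate from nonessential genes. With
#' \code{direction = "depleted_is_positive"} (the knockout-screen
#' convention) more negative scores rank as more essential. The AUC uses
#' the rank (Mann-Whitney) formulation with midrank tie handling; the
#' curve steps through the score-sorted genes. Genes absent from the score
#' table are ignored (their count is reported).
#'
#' @param gene_scores named numeric vector (names = gene symbols) or a
#'   data.frame with columns \code{gene} and a score column (default
#'   \code{fitness_score}).
#' @param essential,nonessential character vectors of reference symbols
#'   (disjoint, non-empty).
#' @param direction \code{"depleted_is_positive"} (only option; stated
#'   explicitly rather than inferred).
#' @param score_col score column when \code{gene_scores} is a data.frame.
#' @return list of class \code{roc_result}: \code{auc}, \code{curve}
#'   (data.frame \code{fpr}, \code{tpr} from (0,0) to (1,1)),
#'   \code{n_essential}, \code{n_nonessential}, \code{n_unscored}.
#' @export
roc_essentiality <- function(gene_scores, essential, nonessential,
                             direction = "depleted_is_positive",
                             score_col = "fitness_score") {
  direction <- match.arg(direction, "depleted_is_positive")
  if (length(intersect(essential, nonessential)))
    abort("essential and nonessential sets overlap")
  if (is.data.frame(gene_scores))
    gene_scores <- setNames(gene_scores[[score_col]], gene_scores$gene)
  ess <- gene_scores[names(gene_scores) %in% essential]
  non <- gene_scores[names(gene_scores) %in% nonessential]
  if (length(ess) == 0L || length(non) == 0L)
    abort("no scored genes in one of the reference sets")
  n_unscored <- sum(!c(essential, nonessential) %in% names(gene_scores))

  # depleted (negative) = positive class: larger -score = more essential
  pred <- -c(ess, non)
  lab <- rep(c(TRUE, FALSE), c(length(ess), length(non)))
  r <- rank(pred)  # midranks
  auc <- (sum(r[lab]) - length(ess) * (length(ess) + 1) / 2) /
    (length(ess) * length(non))

  # ROC curve: sweep threshold over decreasing predictor, tie groups merged
  ord <- order(pred, decreasing = TRUE)
  lab_s <- lab[ord]
  pred_s <- pred[ord]
  keep <- c(pred_s[-length(pred_s)] != pred_s[-1], TRUE)
  tpr <- c(0, cumsum(lab_s)[keep] / length(ess))
  fpr <- c(0, cumsum(!lab_s)[keep] / length(non))
  structure(list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr),
                 n_essential = length(ess), n_nonessential = length(non),
                 n_unscored = n_unscored),
            class = "roc_result")
}

#' Pearson correlation between condition-level gene log2FC vectors
#'
#' @param x,y numeric vectors aligned by gene, length >= 3.
#' @return Pearson product-moment correlation coefficient.
#' @export
condition_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must be aligned by gene")
  if (length(x) < 3L) abort("need >= 3 genes")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in a score vector")
  cor(x, y, method = "pearson")
}

#' Replicate correlation over log-normalized counts
#'
#' Pearson correlation of \code{log2(normalized + 1)} for every pair of
#' samples sharing an arm and timepoint.
#'
#' @param x a \code{screen_counts}.
#' @param normalization passed to \code{\link{normalize_counts}}.
#' @return data.frame with columns \code{arm}, \code{timepoint},
#'   \code{sample_a}, \code{sample_b}, \code{r}.
#' @export
replicate_correlation <- function(x, normalization = "median_ratio") {
  if (!inherits(x, "screen_counts")) x <- screen_counts(x)
  lm2 <- log2(normalize_counts(x, normalization)$normalized + 1)
  smp <- x$samples
  cond <- split(smp$sample, paste(smp$arm, smp$timepoint))
  if (!any(vapply(cond, length, integer(1)) >= 2L))
    abort("no condition has >= 2 replicates")
  out <- do.call(rbind, lapply(names(cond), function(cn) {
    ss <- cond[[cn]]
    if (length(ss) < 2L) return(NULL)
    pairs <- utils::combn(ss, 2)
    data.frame(arm = smp$arm[match(pairs[1, ], smp$sample)],
               timepoint = smp$timepoint[match(pairs[1, ], smp$sample)],
               sample_a = pairs[1, ], sample_b = pairs[2, ],
               r = apply(pairs, 2, function(p) cor(lm2[, p[1]], lm2[, p[2]])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cells required to maintain fold coverage of a library
#'
#' @param n_guides library size (> 0).
#' @param fold_coverage cells per guide (> 0).
#' @return list with \code{cells} (= \code{n_guides * fold_coverage}) and
#'   \code{cells_millions} (rounded to the nearest million).
#' @examples
#' coverage_report(40820, 600)  # 24,492,000 cells ~ 24 million
#' @export
coverage_report <- function(n_guides, fold_coverage) {
  n_guides <- assert_count(n_guides, "n_guides", min = 1L)
  fold_coverage <- assert_count(fold_coverage, "fold_coverage", min = 1L)
  cells <- as.numeric(n_guides) * fold_coverage
  list(cells = cells, cells_millions = round(cells / 1e6))
}
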