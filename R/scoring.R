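#' Normalize a screen count matrix
#'
#' \code{median_ratio}: per-sample size factor = median, over guides with
#' strictly positive counts in every sample, of count / geometric mean
#' across samples (the standard median-of-ratios estimator). When fewer
#' than 100 guides are all-positive the method falls back to
#' \code{total_count} with a warning. \code{total_count}: size factor =
#' column sum / mean column sum. Normalized counts are counts divided by
#' the sample's size factor.
#'
#' @param x a \code{screen_counts} or a count matrix.
#' @param method \code{"median_ratio"} (default) or \code{"total_count"}.
#' @return list with \code{normalized} (numeric matrix),
#'   \code{size_factors} (named vector) and \code{method} (method actually
#'   used).
#' @export
normalize_counts <- function(x, method = c("median_ratio", "total_count")) {
  method <- match.arg(method)
  m <- if (inherits(x, "screen_counts")) x$counts else as.matrix(x)
  if (ncol(m) < 2L) abort("need >= 2 samples to normalize")
  if (any(m < 0)) abort("counts must be non-negative")
  cs <- colSums(m)
  if (any(cs == 0)) abort("all-zero sample column: %s",
                          paste(colnames(m)[cs == 0], collapse = ", "))
  if (method == "median_ratio") {
    pos <- rowSums(m > 0) == ncol(m)
    if (sum(pos) < 100L) {
      warning(sprintf(
        "only %d guides with all-positive counts; falling back to total_count",
        sum(pos)), call. = FALSE)
      method <- "total_count"
    } else {
      loggeo <- rowMeans(log(m[pos, , drop = FALSE]))
      sf <- apply(m[pos, , drop = FALSE], 2,
                  function(col) median(exp(log(col) - loggeo)))
    }
  }
  if (method == "total_count") sf <- cs / mean(cs)
  names(sf) <- colnames(m)
  list(normalized = sweep(m, 2, sf, "/"), size_factors = sf,
       method = method)
}

#' Per-guide log2 fold change between sample groups
#'
#' Replicates are paired by position: the k-th numerator sample is compared
#' with the k-th denominator sample, \code{log2((num + pc)/(den + pc))},
#' and the per-guide value is the mean over replicate pairs.
#'
#' @param norm normalized count matrix (or the list from
#'   \code{\link{normalize_counts}}).
#' @param numerator,denominator equal-length character vectors of sample
#'   (column) names, ordered by replicate.
#' @param pseudocount added to both sides before the ratio (> 0).
#' @return named numeric vector of per-guide log2 fold changes.
#' @export
guide_log2fc <- function(norm, numerator, denominator, pseudocount = 1) {
  if (is.list(norm) && !is.null(norm$normalized)) norm <- norm$normalized
  pseudocount <- assert_number(pseudocount, "pseudocount", min = 0,
                               strict_min = TRUE)
  if (length(numerator) != length(denominator))
    abort("numerator and denominator replicate structure mismatch (%d vs %d)",
          length(numerator), length(denominator))
  miss <- setdiff(c(numerator, denominator), colnames(norm))
  if (length(miss)) abort("sample(s) not in matrix: %s",
                          paste(miss, collapse = ", "))
  lfc <- vapply(seq_along(numerator), function(k)
    log2((norm[, numerator[k]] + pseudocount) /
         (norm[, denominator[k]] + pseudocount)),
    numeric(nrow(norm)))
  rowMeans(matrix(lfc, nrow = nrow(norm),
                  dimnames = list(rownames(norm), NULL)))
}

#' z-score transform of guide log2 fold changes
#'
#' \code{z = (x - mean(x)) / sd(x)} with the sample (n-1 denominator)
#' standard deviation, taken across all guides in the comparison. A
#' zero-variance input returns all zeros with attribute
#' \code{degenerate = TRUE}.
#'
#' @param values numeric vector, length >= 2.
#' @return z vector (names preserved) with attribute \code{degenerate}.
#' @export
zscore_transform <- function(values) {
  if (length(values) < 2L) abort("need >= 2 values to z-score")
  s <- sd(values)
  if (s == 0) {
    z <- values * 0
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  z <- (values - mean(values)) / s
  attr(z, "degenerate") <- FALSE
  z
}

#' Aggregate guide z-scores to per-gene fitness scores
#'
#' The per-gene CRISPR fitness score is the median of the z-scored guide
#' log2 fold changes of the guides targeting the gene (midpoint of the two
#' central values for even guide counts). NTC guides are excluded.
#'
#' @param guide_z named numeric vector of guide z-scores (names =
#'   guide_ids).
#' @param library a \code{guide_library} mapping guides to genes.
#' @return data.frame with columns \code{gene}, \code{n_guides},
#'   \code{fitness_score}, ordered by gene.
#' @export
gene_fitness_scores <- function(guide_z, library) {
  validate_library(library)
  idx <- match(library$guide_id, names(guide_z))
  keep <- !is.na(idx) & library$gene != "NTC"
  dropped <- setdiff(unique(library$gene[library$gene != "NTC"]),
                     unique(library$gene[keep]))
  if (length(dropped))
    warning(sprintf("%d gene(s) with zero scored guides excluded",
                    length(dropped)), call. = FALSE)
  z <- as.numeric(guide_z)[idx[keep]]
  gene <- library$gene[keep]
  med <- tapply(z, gene, median)
  data.frame(gene = names(med),
             n_guides = as.integer(tapply(z, gene, length)),
             fitness_score = as.numeric(med),
             row.names = NULL, stringsAsFactors = FALSE)
}

# sample names of one arm/timepoint, ordered by replicate
arm_samples <- function(samples, arm, timepoint) {
  s <- samples[samples$arm == arm & samples$timepoint == timepoint, ]
  if (nrow(s) == 0L) abort("no %s %s samples in matrix", arm, timepoint)
  s$sample[order(s$replicate)]
}

#' Per-arm selection scores (median z of T24-vs-T0 log2FC)
#'
#' Within each arm, per-guide log2 fold changes T24 vs T0 are z-scored
#' across all guides of that arm and summarized per gene by the median.
#' These per-arm scores are the axes of the nine-square selection plot.
#'
#' @param x a \code{screen_counts} containing T0 and T24 for both arms.
#' @param library a \code{guide_library}.
#' @param pseudocount passed to \code{\link{guide_log2fc}}.
#' @param normalization passed to \code{\link{normalize_counts}}.
#' @return data.frame with columns \code{gene}, \code{n_guides},
#'   \code{control_score}, \code{treatment_score}.
#' @export
arm_selection_scores <- function(x, library, pseudocount = 1,
                                 normalization = "median_ratio") {
  sc <- score_screen(x, library, pseudocount = pseudocount,
                     normalization = normalization)
  sc$genes[c("gene", "n_guides", "control_score", "treatment_score")]
}

#' Score a two-arm screen end to end
#'
#' Runs the full pipeline: normalization, per-arm T24-vs-T0 log2 fold
#' changes, the treatment-minus-control contrast, z-score transforms, and
#' per-gene medians. The default \code{contrast = "delta"} computes, per
#' guide, \code{log2fc(treatment T24/T0) - log2fc(control T24/T0)} before
#' z-scoring, which cancels arm-independent fitness effects;
#' \code{contrast = "t24"} compares treatment T24 with control T24
#' directly. Optionally the guide z-scores are centred on the NTC median.
#'
#' @param x a \code{screen_counts}.
#' @param library a \code{guide_library}.
#' @param contrast \code{"delta"} (default) or \code{"t24"}.
#' @param normalization passed to \code{\link{normalize_counts}}.
#' @param pseudocount passed to \code{\link{guide_log2fc}}.
#' @param ntc_center if \code{TRUE}, subtract the median NTC z from all
#'   guide z-scores before gene aggregation (off by default).
#' @return list of class \code{screen_scores} with elements
#'   \code{guides} (per-guide data.frame: guide_id, gene, lfc_control,
#'   lfc_treatment, delta, z, z_control, z_treatment), \code{genes}
#'   (per-gene data.frame: gene, n_guides, control_score, treatment_score,
#'   fitness_score), \code{ntc_z} (z of NTC guides on the fitness
#'   contrast), \code{size_factors}, and \code{contrast}.
#' @export
score_screen <- function(x, library, contrast = c("delta", "t24"),
                         normalization = "median_ratio", pseudocount = 1,
                         ntc_center = FALSE) {
  contrast <- match.arg(contrast)
  validate_library(library)
  if (!inherits(x, "screen_counts")) x <- screen_counts(x)
  idx <- match(library$guide_id, rownames(x$counts))
  if (anyNA(idx)) abort("library guide(s) missing from counts: %s",
                        library$guide_id[which(is.na(idx))[1]])
  norm <- normalize_counts(x, method = normalization)
  m <- norm$normalized[idx, , drop = FALSE]
  smp <- x$samples

  lfc_ctrl <- guide_log2fc(m, arm_samples(smp, "control", "T24"),
                           arm_samples(smp, "control", "T0"), pseudocount)
  lfc_trt <- guide_log2fc(m, arm_samples(smp, "treatment", "T24"),
                          arm_samples(smp, "treatment", "T0"), pseudocount)
  fit_lfc <- if (contrast == "delta") {
    lfc_trt - lfc_ctrl
  } else {
    guide_log2fc(m, arm_samples(smp, "treatment", "T24"),
                 arm_samples(smp, "control", "T24"), pseudocount)
  }

  z <- zscore_transform(fit_lfc)
  z_ctrl <- zscore_transform(lfc_ctrl)
  z_trt <- zscore_transform(lfc_trt)
  if (ntc_center) {
    ntc <- library$gene == "NTC"
    if (!any(ntc)) abort("ntc_center requested but library has no NTC guides")
    z <- z - median(z[ntc])
  }

  guides <- data.frame(guide_id = library$guide_id, gene = library$gene,
                       lfc_control = unname(lfc_ctrl),
                       lfc_treatment = unname(lfc_trt),
                       delta = unname(fit_lfc), z = as.numeric(z),
                       z_control = as.numeric(z_ctrl),
                       z_treatment = as.numeric(z_trt),
                       stringsAsFactors = FALSE)

  fit <- gene_fitness_scores(setNames(guides$z, guides$guide_id), library)
  ctl <- gene_fitness_scores(setNames(guides$z_control, guides$guide_id),
                             library)
  trt <- gene_fitness_scores(setNames(guides$z_treatment, guides$guide_id),
                             library)
  genes <- data.frame(gene = fit$gene, n_guides = fit$n_guides,
                      control_score = ctl$fitness_score[match(fit$gene, ctl$gene)],
                      treatment_score = trt$fitness_score[match(fit$gene, trt$gene)],
                      fitness_score = fit$fitness_score,
                      stringsAsFactors = FALSE)
  structure(list(guides = guides, genes = genes,
                 ntc_z = guides$z[guides$gene == "NTC"],
                 size_factors = norm$size_factors, contrast = contrast),
            class = "screen_scores")
}

#' @export
print.screen_scores <- function(x, ...) {
  cat(sprintf("screen_scores: %d genes, %d guides (%d NTC), contrast '%s'\n",
              nrow(x$genes), nrow(x$guides), length(x$ntc_z), x$contrast))
  invisible(x)
}
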