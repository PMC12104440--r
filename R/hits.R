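#' NTC-derived null distribution of pseudo-gene medians
#'
#' Resamples non-targeting-control guide z-scores (with replacement across
#' resamples) into pseudo-genes of \code{group_size} guides and records the
#' median of each, building an empirical null for per-gene median z-scores.
#'
#' @param ntc_z numeric vector of NTC guide z-scores.
#' @param group_size guides per pseudo-gene; defaults should match the
#'   modal guides-per-gene of the library.
#' @param n_groups number of pseudo-genes drawn.
#' @param seed integer seed.
#' @return list of class \code{ntc_null}: \code{medians}, \code{mean},
#'   \code{sd}, \code{degenerate} (TRUE when the null has zero spread).
#' @export
ntc_null <- function(ntc_z, group_size = 10L, n_groups = 1000L, seed = 1L) {
  group_size <- assert_count(group_size, "group_size", min = 1L)
  n_groups <- assert_count(n_groups, "n_groups", min = 1L)
  if (length(ntc_z) < group_size)
    abort("only %d NTC guides for group_size %d", length(ntc_z), group_size)
  med <- withr::with_seed(seed, {
    vapply(seq_len(n_groups), function(i)
      median(ntc_z[sample.int(length(ntc_z), group_size)]), numeric(1))
  })
  s <- sd(med)
  structure(list(medians = med, mean = mean(med), sd = s,
                 degenerate = s == 0),
            class = "ntc_null")
}

NINE_SQUARE_GROUPS <- c("purple", "green", "blue", "orange", "center",
                        "strong_both_negative", "strong_both_positive",
                        "discordant_neg_pos", "discordant_pos_neg")

#' Nine-square selection classification
#'
#' Trichotomizes the control-arm and treatment-arm selection scores at
#' \code{±threshold} (boundaries closed: |score| = threshold counts as
#' strong) and names the cells after the screen-figure convention:
#' \itemize{
#'   \item \code{purple}: strong negative control, weak treatment —
#'     essential regardless of drug;
#'   \item \code{green}: weak control, strong positive treatment —
#'     knockout enriches under drug (resistance enhancer);
#'   \item \code{blue}: strong positive control, weak treatment;
#'   \item \code{orange}: weak control, strong negative treatment —
#'     potential synthetic-lethal / resensitizer candidates;
#'   \item \code{center}: weak in both arms;
#'   \item remaining corner cells get descriptive labels.
#' }
#'
#' @param scores data.frame with columns \code{gene},
#'   \code{control_score}, \code{treatment_score} (e.g. from
#'   \code{\link{arm_selection_scores}}).
#' @param threshold positive cutoff on the score scale (default 1.0 on the
#'   z scale; an NTC-null quantile is a principled alternative).
#' @return the input with an added factor column \code{group}.
#' @export
nine_square_classify <- function(scores, threshold = 1) {
  threshold <- assert_number(threshold, "threshold", min = 0,
                             strict_min = TRUE)
  miss <- !is.finite(scores$control_score) | !is.finite(scores$treatment_score)
  if (any(miss)) {
    warning(sprintf("%d gene(s) with missing scores excluded", sum(miss)),
            call. = FALSE)
    scores <- scores[!miss, , drop = FALSE]
  }
  tri <- function(v) ifelse(v <= -threshold, -1L, ifelse(v >= threshold, 1L, 0L))
  cx <- tri(scores$control_score)
  cy <- tri(scores$treatment_score)
  key <- paste(cx, cy)
  map <- c("-1 0" = "purple", "0 1" = "green", "1 0" = "blue",
           "0 -1" = "orange", "0 0" = "center",
           "-1 -1" = "strong_both_negative", "1 1" = "strong_both_positive",
           "-1 1" = "discordant_neg_pos", "1 -1" = "discordant_pos_neg")
  scores$group <- factor(unname(map[key]), levels = NINE_SQUARE_GROUPS)
  scores
}

#' Rank hits against the NTC null
#'
#' Sorts genes by fitness score in the requested direction and attaches a
#' one-sided empirical p-value from the NTC pseudo-gene null,
#' \code{p = (1 + #null medians at least as extreme) / (1 + n_null)}, so p
#' is never 0. Genes are called in the direction's class
#' (\code{resensitizer} for negative, \code{resistance_enhancer} for
#' positive) when \code{p <= p_cutoff}.
#'
#' @param genes data.frame with columns \code{gene} and
#'   \code{fitness_score} (e.g. \code{score_screen(...)$genes}).
#' @param null an \code{\link{ntc_null}}; a degenerate null yields ranks
#'   only (p and calls NA, with a warning).
#' @param direction \code{"negative"} (depletion/resensitizer, default) or
#'   \code{"positive"} (enrichment/resistance enhancer).
#' @param p_cutoff empirical-p call threshold.
#' @return data.frame sorted by rank with columns \code{gene},
#'   \code{fitness_score}, \code{rank}, \code{empirical_p}, \code{call}.
#' @export
rank_hits <- function(genes, null, direction = c("negative", "positive"),
                      p_cutoff = 0.05) {
  direction <- match.arg(direction)
  if (nrow(genes) == 0L) abort("gene table is empty")
  s <- genes$fitness_score
  ord <- if (direction == "negative") order(s, genes$gene)
         else order(-s, genes$gene)
  out <- genes[ord, c("gene", "fitness_score"), drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (null$degenerate) {
    warning("degenerate NTC null: ranks only, no p-values", call. = FALSE)
    out$empirical_p <- NA_real_
    out$call <- NA_character_
  } else {
    nm <- null$medians
    out$empirical_p <- if (direction == "negative") {
      vapply(out$fitness_score, function(v) (1 + sum(nm <= v)) / (1 + length(nm)),
             numeric(1))
    } else {
      vapply(out$fitness_score, function(v) (1 + sum(nm >= v)) / (1 + length(nm)),
             numeric(1))
    }
    cls <- if (direction == "negative") "resensitizer" else "resistance_enhancer"
    out$call <- ifelse(out$empirical_p <= p_cutoff, cls, "none")
  }
  rownames(out) <- NULL
  out
}
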