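TRUTH_CLASSES <- c("neutral", "core_essential", "resensitizer",
                   "resistance_enhancer")

#' Default per-generation selection coefficients by effect class
#'
#' Selection coefficients are per-generation relative-fitness offsets: a
#' knockout clone with coefficient \code{s} changes in expected frequency by
#' a factor \code{(1+s)} per population doubling. Core-essential knockouts
#' deplete in both arms; resensitizers deplete only under drug; resistance
#' enhancers enrich under drug.
#'
#' @return named list of \code{c(s_control, s_treatment)} pairs.
#' @export
default_effect_params <- function() {
  list(neutral             = c(s_control = 0,    s_treatment = 0),
       core_essential      = c(s_control = -0.3, s_treatment = -0.3),
       resensitizer        = c(s_control = 0,    s_treatment = -0.3),
       resistance_enhancer = c(s_control = 0,    s_treatment = 0.3))
}

# largest-remainder (Hamilton) apportionment of n among fractions;
# remainder ties broken by class order for determinism
largest_remainder <- function(fractions, n) {
  quota <- fractions * n
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Assign ground-truth effect classes to library genes
#'
#' Partitions the targeted genes of a library into effect classes
#' (\code{neutral}, \code{core_essential}, \code{resensitizer},
#' \code{resistance_enhancer}) by largest-remainder allocation of the
#' requested fractions, shuffling gene-to-class assignment with the seed.
#' NTC guides are excluded: they are not genes and always evolve neutrally.
#'
#' @param library a \code{guide_library}.
#' @param class_fractions named numeric vector/list of class fractions,
#'   summing to 1 (within 1e-9). Unlisted classes get fraction 0.
#' @param effect_params named list mapping class to
#'   \code{c(s_control, s_treatment)}; defaults to
#'   \code{\link{default_effect_params}}.
#' @param seed integer seed for the gene shuffle.
#' @return data.frame (class \code{truth_table}) with columns \code{gene},
#'   \code{effect_class}, \code{s_control}, \code{s_treatment}.
#' @export
assign_truth <- function(library, class_fractions = c(neutral = 1),
                         effect_params = default_effect_params(), seed = 1L) {
  validate_library(library)
  fr <- unlist(class_fractions)
  if (is.null(names(fr)) || any(names(fr) == ""))
    abort("class_fractions must be named")
  unknown <- setdiff(names(fr), TRUTH_CLASSES)
  if (length(unknown))
    abort("unknown effect class: %s", paste(unknown, collapse = ", "))
  if (any(fr < 0)) abort("class fractions must be >= 0")
  if (abs(sum(fr) - 1) > 1e-9)
    abort("class fractions sum to %.10g, not 1", sum(fr))
  fr_full <- setNames(numeric(length(TRUTH_CLASSES)), TRUTH_CLASSES)
  fr_full[names(fr)] <- fr

  for (cl in TRUTH_CLASSES) {
    if (fr_full[[cl]] > 0 && is.null(effect_params[[cl]]))
      abort("effect_params missing class '%s'", cl)
  }
  check_effect <- function(cl, s) {
    sc <- s[[1]]; st <- s[[2]]
    ok <- switch(cl,
      neutral             = sc == 0 && st == 0,
      core_essential      = sc < 0 && st < 0,
      resensitizer        = st < 0,
      resistance_enhancer = st > 0)
    if (!ok) abort("effect_params for '%s' violate the class invariant", cl)
  }
  for (cl in names(effect_params))
    if (cl %in% TRUTH_CLASSES && fr_full[[cl]] > 0)
      check_effect(cl, effect_params[[cl]])

  genes <- unique(library$gene[library$gene != "NTC"])
  n <- length(genes)
  counts <- largest_remainder(fr_full, n)
  classes <- rep(TRUTH_CLASSES, times = counts)
  perm <- withr::with_seed(seed, sample.int(n))
  classes <- classes[order(perm)]  # random gene <-> class pairing

  sc <- vapply(classes, function(cl) effect_params[[cl]][[1]], numeric(1))
  st <- vapply(classes, function(cl) effect_params[[cl]][[2]], numeric(1))
  tt <- data.frame(gene = genes, effect_class = classes,
                   s_control = unname(sc), s_treatment = unname(st),
                   stringsAsFactors = FALSE)
  class(tt) <- c("truth_table", "data.frame")
  tt
}
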