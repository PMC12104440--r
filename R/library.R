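#' Build a synthetic guide library
#'
#' Generates a guide library with a fixed number of guides per gene plus a
#' block of non-targeting control (NTC) guides, mirroring the composition of
#' a focused knockout library (~10 guides/gene plus 100 NTCs). Gene symbols
#' are synthesized as \code{"G000001"} onward; NTC guides carry the reserved
#' gene token \code{"NTC"}. All spacers are distinct random DNA sequences of
#' a fixed length.
#'
#' @param n_genes number of targeted genes (>= 1).
#' @param guides_per_gene guides designed against each gene.
#' @param n_ntc number of non-targeting control guides.
#' @param spacer_length spacer length in nucleotides (>= 8).
#' @param seed integer seed; the library is a deterministic function of the
#'   arguments and the seed.
#' @return A \code{data.frame} of class \code{guide_library} with columns
#'   \code{guide_id}, \code{gene}, \code{spacer}.
#' @examples
#' lib <- build_library(n_genes = 10, guides_per_gene = 5, n_ntc = 3, seed = 1)
#' nrow(lib)  # 53
#' @export
build_library <- function(n_genes, guides_per_gene, n_ntc = 100L,
                          spacer_length = 20L, seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes", min = 1L)
  guides_per_gene <- assert_count(guides_per_gene, "guides_per_gene", min = 0L)
  n_ntc <- assert_count(n_ntc, "n_ntc", min = 0L)
  spacer_length <- assert_count(spacer_length, "spacer_length", min = 8L)
  n_total <- n_genes * guides_per_gene + n_ntc
  if (n_total < 1L) abort("library would contain zero guides")
  # with rejection sampling, require the spacer space to dominate the draw
  if (4^spacer_length < 4 * n_total)
    abort("spacer space 4^%d too small to guarantee %d unique spacers",
          spacer_length, n_total)

  spacers <- withr::with_seed(seed, {
    out <- character(0)
    while (length(out) < n_total) {
      need <- n_total - length(out)
      draw <- vapply(seq_len(need * 2L), function(i)
        paste(sample(DNA_BASES, spacer_length, replace = TRUE), collapse = ""),
        character(1))
      out <- unique(c(out, draw))
    }
    out[seq_len(n_total)]
  })

  genes <- sprintf("G%06d", seq_len(n_genes))
  gene_col <- c(rep(genes, each = guides_per_gene), rep("NTC", n_ntc))
  id_col <- c(
    if (guides_per_gene > 0)
      paste0(rep(genes, each = guides_per_gene), "_g",
             rep(seq_len(guides_per_gene), times = n_genes)),
    if (n_ntc > 0) sprintf("NTC_g%d", seq_len(n_ntc))
  )
  lib <- data.frame(guide_id = id_col, gene = gene_col, spacer = spacers,
                    stringsAsFactors = FALSE)
  class(lib) <- c("guide_library", "data.frame")
  validate_library(lib)
}

validate_library <- function(lib) {
  req <- c("guide_id", "gene", "spacer")
  if (!all(req %in% names(lib)))
    abort("guide library must have columns %s", paste(req, collapse = ", "))
  if (anyDuplicated(lib$guide_id)) abort("guide_ids are not unique")
  if (anyDuplicated(lib$spacer)) abort("spacers are not unique")
  if (length(unique(nchar(lib$spacer))) > 1L)
    abort("spacers must all have the same length")
  if (!all(grepl("^[ACGT]+$", lib$spacer)))
    abort("spacers must be DNA over {A,C,G,T}")
  lib
}

#' Read / write a guide library TSV
#'
#' Tab-delimited with header columns \code{guide_id}, \code{gene},
#' \code{spacer}; NTC guides carry gene \code{"NTC"}.
#'
#' @param path file path.
#' @return \code{read_library} returns a validated \code{guide_library}
#'   data.frame; \code{write_library} returns \code{path} invisibly.
#' @export
read_library <- function(path) {
  lib <- read.delim(path, stringsAsFactors = FALSE)
  class(lib) <- c("guide_library", "data.frame")
  validate_library(lib)
}

#' @rdname read_library
#' @param lib a guide library.
#' @export
write_library <- function(lib, path) {
  validate_library(lib)
  write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
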