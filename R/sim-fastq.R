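#' Vector flanking sequences around the spacer
#'
#' The 5' flank ends in \code{CACCG}: the G is the vector base completing
#' the U6 transcription start, and \code{CACCG} doubles as the default
#' anchor for spacer extraction.
#' @name flanks
#' @export
FLANK5_DEFAULT <- "TATCTTGTGGAAAGGACGAAACACCG"

#' @rdname flanks
#' @export
FLANK3_DEFAULT <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAAT"

#' Emit synthetic screen reads as FASTQ
#'
#' Writes \code{sum(counts)} single-end reads. Each read is
#' \code{flank5 + spacer + flank3}, truncated to \code{read_length}, with
#' i.i.d. per-base substitution errors at \code{error_rate} and a constant
#' Phred+33 quality string. Read order is shuffled so file order carries no
#' information about the guide; each read name records the emitting guide
#' (\code{<guide_id>|read_<i>}), the conventional way simulators expose
#' per-read ground truth for benchmarking.
#'
#' @param counts named integer vector of reads per guide (names =
#'   guide_ids present in \code{library}).
#' @param library a \code{guide_library}.
#' @param path output FASTQ path (".gz" suffix compresses).
#' @param flank5,flank3 flanking vector sequence around the spacer.
#' @param read_length read length; must cover \code{flank5} plus the full
#'   spacer.
#' @param error_rate per-base substitution probability in [0, 1).
#' @param seed integer seed.
#' @return \code{path}, invisibly. Attribute \code{"n_reads"} holds the
#'   number of reads written.
#' @export
emit_fastq <- function(counts, library, path,
                       flank5 = FLANK5_DEFAULT, flank3 = FLANK3_DEFAULT,
                       read_length = 60L, error_rate = 0, seed = 1L) {
  validate_library(library)
  read_length <- assert_count(read_length, "read_length", min = 1L)
  error_rate <- assert_number(error_rate, "error_rate", min = 0)
  if (error_rate >= 1) abort("error_rate must be < 1")
  L <- nchar(library$spacer[1])
  if (read_length < nchar(flank5) + L)
    abort("read_length %d too short for %d-nt flank + %d-nt spacer",
          read_length, nchar(flank5), L)
  if (is.null(names(counts))) abort("counts must be named by guide_id")
  unknown <- setdiff(names(counts), library$guide_id)
  if (length(unknown)) abort("counts name not in library: %s", unknown[1])
  counts <- counts[counts > 0]
  n_reads <- sum(counts)

  spacer <- setNames(library$spacer, library$guide_id)
  templates <- substr(paste0(flank5, spacer[names(counts)], flank3),
                      1L, read_length)
  reads <- rep(templates, times = counts)
  origin <- rep(names(counts), times = counts)

  out <- withr::with_seed(seed, {
    perm <- sample.int(length(reads))
    reads <- reads[perm]
    origin <- origin[perm]
    if (error_rate > 0 && length(reads)) {
      m <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(reads), byrow = TRUE)
      hit <- which(matrix(runif(length(m)) < error_rate, nrow = nrow(m)))
      if (length(hit)) {
        # substitute with one of the three other bases, uniformly
        old <- m[hit]
        pick <- function(b) DNA_BASES[DNA_BASES != b]
        alt <- matrix(c(pick("A"), pick("C"), pick("G"), pick("T")), nrow = 3)
        m[hit] <- alt[cbind(sample.int(3, length(hit), replace = TRUE),
                            match(old, DNA_BASES))]
      }
      reads <- apply(m, 1, paste, collapse = "")
    }
    list(reads = reads, origin = origin)
  })

  dna <- Biostrings::DNAStringSet(out$reads)
  names(dna) <- sprintf("%s|read_%d", out$origin, seq_along(out$reads))
  qual <- Biostrings::BStringSet(rep(strrep("I", read_length),
                                     length(dna)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(structure(path, n_reads = n_reads))
}
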