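#' Count library spacers in FASTQ reads
#'
#' For each read, the first occurrence of \code{anchor} (default
#' \code{"CACCG"}, the terminal 5 nt of the 5' vector flank) is located and
#' the spacer-length bases following it are extracted. The extracted
#' sequence is assigned to a guide on exact spacer match; with
#' \code{max_mismatches = 1} an unmatched sequence is additionally assigned
#' when it lies at Hamming distance 1 from exactly one library spacer
#' (ambiguous multi-guide matches are discarded). Reads without the anchor,
#' without room for a full spacer after it, or without an assignment are
#' tallied but not counted. No quality filtering is applied.
#'
#' @param reads path(s) to FASTQ file(s), optionally gzip-compressed.
#' @param library a \code{guide_library}; spacers must share one length.
#' @param anchor non-empty DNA string searched in each read.
#' @param max_mismatches 0 (exact only) or 1.
#' @param detail if \code{TRUE}, also return the per-read assignment table
#'   (read name, assigned guide or NA), e.g. to benchmark against the
#'   ground truth that \code{\link{emit_fastq}} stores in read names.
#' @return list with \code{counts} (named integer vector covering every
#'   library guide, zeros included), \code{qc} (a \code{counting_qc}
#'   list: \code{reads_total}, \code{reads_with_anchor},
#'   \code{reads_perfectly_matched}, \code{reads_assigned},
#'   \code{guides_undetected}, \code{skew_ratio}, \code{skew_undefined})
#'   and, with \code{detail}, \code{assignments}.
#' @export
count_spacers <- function(reads, library, anchor = "CACCG",
                          max_mismatches = 0L, detail = FALSE) {
  validate_library(library)
  if (nrow(library) == 0L) abort("library is empty")
  if (!nzchar(anchor)) abort("anchor must be non-empty")
  max_mismatches <- assert_count(max_mismatches, "max_mismatches")
  if (!max_mismatches %in% c(0L, 1L)) abort("max_mismatches must be 0 or 1")
  L <- nchar(library$spacer[1])

  fq <- lapply(reads, function(f)
    Biostrings::readDNAStringSet(f, format = "fastq"))
  seqs <- unlist(lapply(fq, as.character), use.names = FALSE)
  read_names <- unlist(lapply(fq, names), use.names = FALSE)
  n_total <- length(seqs)

  pos <- regexpr(anchor, seqs, fixed = TRUE)
  has_anchor <- pos > 0L
  start <- pos + nchar(anchor)
  cand <- substr(seqs, start, start + L - 1L)
  full <- has_anchor & nchar(cand) == L

  hit <- rep(NA_integer_, n_total)
  hit[full] <- match(cand[full], library$spacer)
  n_perfect <- sum(!is.na(hit))

  if (max_mismatches == 1L) {
    todo <- which(full & is.na(hit))
    if (length(todo)) {
      nb <- mismatch_index(library$spacer)
      j <- match(cand[todo], nb$variant)
      hit[todo] <- nb$guide[j]  # NA when absent or ambiguous
    }
  }

  counts <- tabulate(hit, nbins = nrow(library))
  names(counts) <- library$guide_id
  qc <- c(list(reads_total = n_total,
               reads_with_anchor = sum(has_anchor),
               reads_perfectly_matched = n_perfect,
               reads_assigned = sum(!is.na(hit))),
          counting_stats(counts))
  class(qc) <- "counting_qc"
  out <- list(counts = counts, qc = qc)
  if (detail)
    out$assignments <- data.frame(read = read_names,
                                  guide_id = library$guide_id[hit],
                                  stringsAsFactors = FALSE)
  out
}

# all Hamming-distance-1 variants of each spacer -> guide index;
# variants reachable from >1 guide are marked ambiguous (NA)
mismatch_index <- function(spacers) {
  L <- nchar(spacers[1])
  n <- length(spacers)
  variants <- character(0)
  guide <- integer(0)
  for (p in seq_len(L)) {
    base_at <- substr(spacers, p, p)
    for (b in DNA_BASES) {
      keep <- base_at != b
      v <- spacers[keep]
      substr(v, p, p) <- b
      variants <- c(variants, v)
      guide <- c(guide, which(keep))
    }
  }
  dup <- variants[duplicated(variants)]
  guide[variants %in% dup] <- NA_integer_
  # a variant equal to another guide's exact spacer is also ambiguous
  guide[variants %in% spacers] <- NA_integer_
  list(variant = variants, guide = guide)
}

#' Count-distribution QC
#'
#' @param counts named numeric vector of per-guide counts covering the
#'   full library.
#' @return list with \code{guides_undetected} (zero-count guides),
#'   \code{skew_ratio} (90th / 10th percentile of counts; \code{NA} with
#'   \code{skew_undefined = TRUE} when the 10th percentile is 0).
#' @export
counting_stats <- function(counts) {
  if (length(counts) == 0L) abort("counts are empty")
  q <- quantile(counts, c(0.1, 0.9), names = FALSE, type = 7)
  undef <- q[1] == 0
  list(guides_undetected = sum(counts == 0),
       skew_ratio = if (undef) NA_real_ else q[2] / q[1],
       skew_undefined = undef)
}
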