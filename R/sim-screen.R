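#' Screen simulation design
#'
#' Describes a two-arm (control vs treatment) screen with T0 and T24
#' timepoints, replicate structure, number of population doublings between
#' the timepoints, sequencing depth, negative-binomial dispersion and the
#' lognormal spread of initial guide abundances.
#'
#' @param replicates replicates per arm (>= 1).
#' @param generations population doublings between T0 and T24 (> 0). The
#'   default 12 corresponds to a ~24-day culture at roughly one doubling
#'   every two days.
#' @param depth target reads per sample. \code{NULL} (default) means
#'   500 reads per guide, resolved when the library size is known.
#' @param dispersion negative-binomial dispersion (variance
#'   \code{mu + dispersion * mu^2}); 0 degrades to Poisson.
#' @param t0_lognormal_sigma sdlog of the lognormal initial guide
#'   abundances (library skew).
#' @return list of class \code{sim_design}.
#' @export
sim_design <- function(replicates = 3L, generations = 12, depth = NULL,
                       dispersion = 0.1, t0_lognormal_sigma = 0.5) {
  replicates <- assert_count(replicates, "replicates", min = 1L)
  generations <- assert_number(generations, "generations", min = 0,
                               strict_min = TRUE)
  if (!is.null(depth)) depth <- assert_number(depth, "depth", min = 0,
                                              strict_min = TRUE)
  dispersion <- assert_number(dispersion, "dispersion", min = 0)
  t0_lognormal_sigma <- assert_number(t0_lognormal_sigma,
                                      "t0_lognormal_sigma", min = 0)
  structure(list(timepoints = c("T0", "T24"),
                 arms = c("control", "treatment"),
                 replicates = replicates, generations = generations,
                 depth = depth, dispersion = dispersion,
                 t0_lognormal_sigma = t0_lognormal_sigma),
            class = "sim_design")
}

#' Guide-by-sample screen count matrix
#'
#' Wraps an integer count matrix (rows = guides, columns = samples) with
#' sample metadata parsed from column names of the form
#' \code{<arm>_<timepoint>_rep<k>}, e.g. \code{control_T0_rep1}.
#'
#' @param counts integer matrix with rownames = guide_ids and the column
#'   naming above.
#' @param samples optional data.frame with columns \code{sample},
#'   \code{arm}, \code{timepoint}, \code{replicate}; parsed from column
#'   names when omitted.
#' @return object of class \code{screen_counts}: list with elements
#'   \code{counts} and \code{samples}.
#' @export
screen_counts <- function(counts, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) abort("counts must have guide_id rownames")
  if (any(counts < 0) || any(counts != floor(counts)))
    abort("counts must be non-negative integers")
  if (is.null(samples)) samples <- parse_sample_names(colnames(counts))
  structure(list(counts = counts, samples = samples),
            class = "screen_counts")
}

parse_sample_names <- function(nm) {
  if (is.null(nm)) abort("count matrix must have sample column names")
  m <- regmatches(nm, regexec("^([A-Za-z]+)_(T[0-9]+)_rep([0-9]+)$", nm))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    abort("sample name(s) not of form <arm>_<timepoint>_rep<k>: %s",
          paste(nm[bad], collapse = ", "))
  data.frame(sample = nm,
             arm = vapply(m, `[`, character(1), 2L),
             timepoint = vapply(m, `[`, character(1), 3L),
             replicate = as.integer(vapply(m, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("screen_counts: %d guides x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("samples:", paste(x$samples$sample, collapse = " "), "\n")
  invisible(x)
}

#' Simulate screen counts under known selection
#'
#' Draws initial guide abundances from a lognormal, propagates them through
#' a geometric growth model — a guide targeting a gene with per-generation
#' selection coefficient \code{s} changes expected frequency by
#' \code{(1+s)^generations}, with per-sample renormalization so frequencies
#' sum to 1 — and samples counts from a negative binomial with mean
#' \code{depth * frequency}. NTC guides evolve with \code{s = 0}. The same
#' T0 expected frequencies are used for every T0 sample of both arms;
#' replicates are independent draws.
#'
#' @param library a \code{guide_library}.
#' @param truth a \code{truth_table} covering every non-NTC gene.
#' @param design a \code{sim_design}.
#' @param seed integer seed; identical inputs and seed give identical counts.
#' @return a \code{screen_counts} object with
#'   \code{2 * 2 * replicates} columns named \code{<arm>_<timepoint>_rep<k>}.
#' @export
simulate_screen_counts <- function(library, truth, design = sim_design(),
                                   seed = 1L) {
  validate_library(library)
  if (!inherits(design, "sim_design")) abort("design must be a sim_design")
  genes <- unique(library$gene[library$gene != "NTC"])
  missing <- setdiff(genes, truth$gene)
  if (length(missing))
    abort("truth table missing %d gene(s), e.g. %s", length(missing),
          missing[1])
  s_ctrl <- setNames(truth$s_control, truth$gene)
  s_trt <- setNames(truth$s_treatment, truth$gene)
  if (any(1 + c(s_ctrl, s_trt) < 0))
    abort("selection coefficients must satisfy 1 + s >= 0")

  n <- nrow(library)
  depth <- if (is.null(design$depth)) 500 * n else design$depth
  is_ntc <- library$gene == "NTC"
  g_ctrl <- ifelse(is_ntc, 0, s_ctrl[library$gene])
  g_trt <- ifelse(is_ntc, 0, s_trt[library$gene])

  samples <- expand.grid(replicate = seq_len(design$replicates),
                         timepoint = design$timepoints, arm = design$arms,
                         stringsAsFactors = FALSE)
  samples <- samples[c("arm", "timepoint", "replicate")]
  samples$sample <- sprintf("%s_%s_rep%d", samples$arm, samples$timepoint,
                            samples$replicate)

  counts <- withr::with_seed(seed, {
    a <- rlnorm(n, meanlog = 0, sdlog = design$t0_lognormal_sigma)
    f0 <- a / sum(a)
    freq_for <- function(arm, timepoint) {
      if (timepoint == "T0") return(f0)
      s <- if (arm == "control") g_ctrl else g_trt
      w <- a * (1 + s)^design$generations
      w / sum(w)
    }
    draw <- function(mu) {
      if (design$dispersion == 0) rpois(n, mu)
      else rnbinom(n, mu = mu, size = 1 / design$dispersion)
    }
    m <- vapply(seq_len(nrow(samples)), function(j) {
      draw(depth * freq_for(samples$arm[j], samples$timepoint[j]))
    }, numeric(n))
    storage.mode(m) <- "integer"
    m
  })
  rownames(counts) <- library$guide_id
  colnames(counts) <- samples$sample
  screen_counts(counts, samples[c("sample", "arm", "timepoint", "replicate")])
}

#' Read / write a counts TSV
#'
#' First column \code{guide_id}, one column per sample named
#' \code{<arm>_<timepoint>_rep<k>}.
#'
#' @param path file path.
#' @return \code{read_counts} returns a \code{screen_counts};
#'   \code{write_counts} returns \code{path} invisibly.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "guide_id") abort("first column must be guide_id")
  m <- as.matrix(df[-1])
  rownames(m) <- df$guide_id
  screen_counts(m)
}

#' @rdname read_counts
#' @param x a \code{screen_counts}.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(guide_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
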