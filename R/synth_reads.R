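#' Simulate bisulfite amplicon reads for one donor
#'
#' Generative model for the deep-bisulfite-sequencing input. Each read is
#' drawn from one rDNA copy: with probability `active_fraction` an active
#' copy whose CpGs are methylated independently with probability `p_active`,
#' otherwise an inactive copy with per-CpG probability `p_inactive`.
#' Bisulfite chemistry is then applied: methylated CpG cytosines stay C;
#' unmethylated cytosines (CpG and non-CpG alike) read as T except with
#' probability `conversion_failure_rate`, in which case they stay C.
#' A fraction `minor_allele_fraction` of reads carries the minor A allele at
#' the variant site. Finally each base is replaced by a uniformly chosen
#' different base with probability `seq_error_rate`. Per-read ground truth
#' (copy class, methylated-CpG count, allele) is returned as a sidecar
#' table.
#'
#' @param n_reads Number of reads (template molecules).
#' @param ref An [amplicon_reference()].
#' @param active_fraction Fraction of active copies in the donor, between
#'   0 and 1.
#' @param p_active,p_inactive Per-CpG methylation probability of active and
#'   inactive copies.
#' @param conversion_failure_rate Probability an unmethylated C escapes
#'   conversion (default 0.005).
#' @param seq_error_rate Per-base substitution error rate (default 0.001).
#' @param minor_allele_fraction Fraction of reads from the minor A variant
#'   (default 0.02).
#' @param paired If TRUE, emit two 150-nt overlapping mates fully covering
#'   the amplicon (mate 2 reverse-complemented); otherwise one full-length
#'   read per molecule.
#' @param read_length Mate length in paired mode (default 150).
#' @param sample_id Used in read ids.
#' @param seed Optional RNG seed.
#' @return List: `reads` (data frame `read_id`, `sequence`; in paired mode
#'   `mate1`/`mate2` instead of `sequence`) and `truth` (sidecar data frame
#'   `read_id`, `copy_class`, `true_n_methylated`, `allele`).
#' @export
simulate_reads <- function(n_reads, ref, active_fraction, p_active = 0.02,
                           p_inactive = 0.22, conversion_failure_rate = 0.005,
                           seq_error_rate = 0.001,
                           minor_allele_fraction = 0.02, paired = FALSE,
                           read_length = 150L, sample_id = "S", seed = NULL) {
  stopifnot(inherits(ref, "amplicon_reference"), n_reads > 0)
  rates <- c(active_fraction, p_active, p_inactive, conversion_failure_rate,
             seq_error_rate, minor_allele_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (paired && (read_length < 50L || read_length > ref$length ||
                 2L * read_length < ref$length))
    stop("paired mates must overlap and cover the amplicon")
  with_seed(seed, {
    n <- as.integer(n_reads)
    L <- ref$length
    active <- stats::runif(n) < active_fraction
    p_cpg <- ifelse(active, p_active, p_inactive)
    meth <- matrix(stats::runif(n * ref$n_cpg) < rep(p_cpg, ref$n_cpg),
                   nrow = n)
    minor <- stats::runif(n) < minor_allele_fraction

    mat <- matrix(rep(ref$chars, each = n), nrow = n)
    # bisulfite conversion of unmethylated cytosines
    cf <- conversion_failure_rate
    for (j in seq_along(ref$non_cpg_c_positions)) {
      pos <- ref$non_cpg_c_positions[j]
      conv <- stats::runif(n) >= cf
      mat[conv, pos] <- "T"
    }
    for (j in seq_along(ref$cpg_positions)) {
      pos <- ref$cpg_positions[j]
      conv <- !meth[, j] & stats::runif(n) >= cf
      mat[conv, pos] <- "T"
    }
    mat[minor, ref$variant_pos] <- "A"
    if (seq_error_rate > 0) {
      err <- which(stats::runif(n * L) < seq_error_rate)
      if (length(err)) {
        bases <- c("A", "C", "G", "T")
        cur <- mat[err]
        repl <- vapply(cur, function(b)
          sample(setdiff(bases, b), 1L), character(1))
        mat[err] <- repl
      }
    }
    seqs <- apply(mat, 1, paste, collapse = "")
    ids <- sprintf("%s_read%06d", sample_id, seq_len(n))
    truth <- data.frame(
      read_id = ids,
      copy_class = ifelse(active, "active", "inactive"),
      true_n_methylated = rowSums(meth),
      allele = ifelse(minor, "A", "G"),
      stringsAsFactors = FALSE)
    if (paired) {
      m1 <- substr(seqs, 1L, read_length)
      m2 <- reverse_complement(substr(seqs, L - read_length + 1L, L))
      reads <- data.frame(read_id = ids, mate1 = m1, mate2 = m2,
                          stringsAsFactors = FALSE)
    } else {
      reads <- data.frame(read_id = ids, sequence = seqs,
                          stringsAsFactors = FALSE)
    }
    list(reads = reads, truth = truth)
  })
}

#' Write simulated reads as FASTQ
#'
#' Phred+33 FASTQ with uniform quality (the caller does not use qualities).
#' In paired mode two files are written (`_R1`/`_R2` inserted before the
#' extension).
#'
#' @param reads Reads data frame from [simulate_reads()].
#' @param path Output FASTQ path (plain text).
#' @return The file path(s), invisibly.
#' @export
write_fastq <- function(reads, path) {
  emit <- function(ids, seqs, p) {
    qual <- vapply(nchar(seqs), function(k)
      paste(rep("I", k), collapse = ""), character(1))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), p)
    p
  }
  if ("sequence" %in% names(reads)) {
    invisible(emit(reads$read_id, reads$sequence, path))
  } else {
    p1 <- sub("(\\.[^.]+)$", "_R1\\1", path)
    p2 <- sub("(\\.[^.]+)$", "_R2\\1", path)
    if (identical(p1, path)) { p1 <- paste0(path, "_R1"); p2 <- paste0(path, "_R2") }
    emit(paste0(reads$read_id, "/1"), reads$mate1, p1)
    emit(paste0(reads$read_id, "/2"), reads$mate2, p2)
    invisible(c(p1, p2))
  }
}

#' Expected hypomethylated-read fraction under the two-mode mixture
#'
#' Closed-form oracle for the generative model of [simulate_reads()]: the
#' probability that a read has at most `floor(threshold * n_cpg)` methylated
#' CpGs, under the binomial mixture of active and inactive copies. Used as
#' the ground truth for the "presumably active" read fraction.
#'
#' @param active_fraction,p_active,p_inactive Mixture parameters.
#' @param n_cpg CpGs per read (default 25).
#' @param threshold Methylation fraction defining "hypomethylated"
#'   (default 0.10, i.e. at most 2 of 25 CpGs).
#' @param conversion_failure_rate Optional conversion-failure rate; failures
#'   read unmethylated cytosines as methylated, shifting the effective
#'   per-CpG probability to `p + (1 - p) * rate`.
#' @return Expected fraction of reads with methylation <= threshold.
#' @export
expected_hypomethylated_fraction <- function(active_fraction, p_active = 0.02,
                                             p_inactive = 0.22, n_cpg = 25L,
                                             threshold = 0.10,
                                             conversion_failure_rate = 0) {
  k <- floor(threshold * n_cpg)
  eff <- function(p) p + (1 - p) * conversion_failure_rate
  active_fraction * stats::pbinom(k, n_cpg, eff(p_active)) +
    (1 - active_fraction) * stats::pbinom(k, n_cpg, eff(p_inactive))
}
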