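# Deep bisulfite sequencing: per-read alignment, QC and methylation calling.

#' Read a FASTQ file into a data frame
#'
#' Plain or gzip-compressed FASTQ (Phred+33); qualities are not used by the
#' caller and are dropped.
#'
#' @param path FASTQ path.
#' @return Data frame with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(dna)),
             sequence = as.character(dna),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Best ungapped offset of a read against the reference in bisulfite space
# (both sequences with C collapsed to T, so converted bases score as
# matches). Returns offset = NA when no placement reaches the identity floor.
.align_offsets <- function(seqs, ref, identity_floor = 0.8, min_length = 50L) {
  ref_bs <- Biostrings::DNAString(chartr("C", "T", ref$sequence))
  lens <- nchar(seqs)
  offset <- rep(NA_integer_, length(seqs))
  identity <- rep(NA_real_, length(seqs))
  ok <- lens >= min_length & lens <= ref$length
  for (i in which(ok)) {
    pat <- Biostrings::DNAString(chartr("C", "T", seqs[i]))
    starts <- seq_len(ref$length - lens[i] + 1L)
    mm <- Biostrings::neditStartingAt(pat, ref_bs, starting.at = starts,
                                      with.indels = FALSE)
    best <- which.min(mm)
    id <- 1 - mm[best] / lens[i]
    if (id >= identity_floor) {
      offset[i] <- starts[best]
      identity[i] <- id
    } else {
      identity[i] <- id
    }
  }
  list(offset = offset, identity = identity, length = lens,
       too_short = lens < min_length | lens > ref$length)
}

#' Align one read to the amplicon reference
#'
#' Ungapped, bisulfite-aware placement: both read and reference are collapsed
#' to "bisulfite space" (C treated as T), so a converted T opposite a
#' reference C scores as a match, and the best offset is the one minimising
#' mismatches on the remaining (non C/T-ambiguous) columns. Reads below the
#' identity floor, shorter than `min_length`, or longer than the reference
#' are rejected as non-amplicon (`mapped = FALSE`, reason `"unmapped"`).
#' Indels are not modelled: the assay is a single short amplicon.
#'
#' @param read Character scalar, read sequence (A/C/G/T/N).
#' @param ref An [amplicon_reference()].
#' @param identity_floor Minimum identity in bisulfite space (default 0.8).
#' @param min_length Minimum read length (default 50).
#' @return List: `mapped`, `offset` (1-based), `identity`.
#' @export
align_to_amplicon <- function(read, ref, identity_floor = 0.8,
                              min_length = 50L) {
  stopifnot(inherits(ref, "amplicon_reference"), is.character(read),
            length(read) == 1L)
  al <- .align_offsets(toupper(read), ref, identity_floor, min_length)
  list(mapped = !is.na(al$offset), offset = al$offset, identity = al$identity)
}

# Extract the read base over each reference position in `positions`
# (1-based on the reference) for reads placed at `offset`. Positions not
# covered by a read yield NA.
.bases_at <- function(seqs, offset, lens, positions) {
  n <- length(seqs)
  out <- matrix(NA_character_, n, length(positions))
  for (j in seq_along(positions)) {
    rel <- positions[j] - offset + 1L
    inside <- !is.na(rel) & rel >= 1L & rel <= lens
    out[inside, j] <- substring(seqs[inside], rel[inside], rel[inside])
  }
  out
}

#' Call alignment, conversion, allele and methylation for a set of reads
#'
#' The workhorse of the DBS stage. Each read is placed on the amplicon
#' (bisulfite-aware, ungapped), then:
#' \itemize{
#'   \item conversion rate = converted / (converted + unconverted) over the
#'     non-CpG reference cytosines the read covers, where a read T is
#'     converted, a read C unconverted, and any other base is excluded;
#'   \item the A/G variant base is called (G, A, or ambiguous);
#'   \item each covered CpG cytosine is called methylated (read C),
#'     unmethylated (read T) or ambiguous (anything else);
#'   \item per-read methylation percent = 100 x methylated / analyzable CpGs.
#' }
#' Filters (applied in this order, each read assigned exactly one reason):
#' `unmapped`; `qc_insufficient` (fewer than `min_non_cpg_c` covered non-CpG
#' reference cytosines with C/T evidence); `low_conversion` (conversion rate
#' not strictly greater than `min_conversion`); `allele` (variant not the
#' major allele, including uncovered/ambiguous); `cpg_missing` (fewer than
#' `min_cpgs` analyzable CpG states); otherwise `retained`.
#'
#' @param reads Data frame with `read_id` and `sequence` (see
#'   [read_fastq()]), or a character vector of sequences.
#' @param ref An [amplicon_reference()].
#' @param min_conversion Strict lower bound on the bisulfite conversion rate
#'   (default 0.95; a read at exactly 0.95 fails).
#' @param min_cpgs Minimum analyzable CpGs per read (default 20).
#' @param min_non_cpg_c Minimum covered non-CpG reference cytosines with C/T
#'   evidence (default 10).
#' @param identity_floor,min_length Passed to the aligner.
#' @return Data frame, one row per read: `read_id`, `offset`, `identity`,
#'   `conversion_rate`, `allele`, `n_methylated`, `n_analyzable`,
#'   `methylation_pct`, `bin`, `pass`, `reason`.
#' @export
call_reads <- function(reads, ref, min_conversion = 0.95, min_cpgs = 20L,
                       min_non_cpg_c = 10L, identity_floor = 0.8,
                       min_length = 50L) {
  stopifnot(inherits(ref, "amplicon_reference"))
  if (is.character(reads))
    reads <- data.frame(read_id = paste0("read", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) stop("no reads supplied")
  seqs <- toupper(reads$sequence)
  al <- .align_offsets(seqs, ref, identity_floor, min_length)
  n <- length(seqs)

  conv <- rep(NA_real_, n)
  allele <- rep(NA_character_, n)
  n_meth <- rep(NA_integer_, n); n_anal <- rep(NA_integer_, n)
  n_conv_cov <- rep(0L, n)

  mapped <- !is.na(al$offset)
  if (any(mapped)) {
    idx <- which(mapped)
    off <- al$offset[idx]; lens <- al$length[idx]
    cb <- .bases_at(seqs[idx], off, lens, ref$non_cpg_c_positions)
    conv_t <- rowSums(cb == "T", na.rm = TRUE)
    conv_c <- rowSums(cb == "C", na.rm = TRUE)
    n_conv_cov[idx] <- conv_t + conv_c
    conv[idx] <- ifelse(n_conv_cov[idx] > 0, conv_t / (conv_t + conv_c), NA)
    vb <- .bases_at(seqs[idx], off, lens, ref$variant_pos)[, 1]
    allele[idx] <- ifelse(is.na(vb), "uncovered",
                          ifelse(vb %in% c("G", "A"), vb, "ambiguous"))
    mb <- .bases_at(seqs[idx], off, lens, ref$cpg_positions)
    n_meth[idx] <- as.integer(rowSums(mb == "C", na.rm = TRUE))
    n_anal[idx] <- as.integer(rowSums(mb == "C" | mb == "T", na.rm = TRUE))
  }

  reason <- rep("retained", n)
  reason[!is.na(n_anal) & n_anal < min_cpgs] <- "cpg_missing"
  reason[!is.na(allele) & allele != ref$major_allele] <- "allele"
  reason[!is.na(conv) & conv <= min_conversion] <- "low_conversion"
  reason[mapped & n_conv_cov < min_non_cpg_c] <- "qc_insufficient"
  reason[!mapped] <- "unmapped"
  pass <- reason == "retained"

  pct <- ifelse(!is.na(n_anal) & n_anal > 0, 100 * n_meth / n_anal, NA_real_)
  data.frame(read_id = reads$read_id, offset = al$offset,
             identity = al$identity, conversion_rate = conv,
             allele = ifelse(is.na(allele), "unmapped", allele),
             n_methylated = n_meth, n_analyzable = n_anal,
             methylation_pct = pct, bin = methylation_bin(pct),
             pass = pass, reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bisulfite conversion rate of one mapped read
#'
#' Fraction of non-CpG reference cytosines read as T among those read as T
#' or C (other bases are excluded from both counts).
#'
#' @inheritParams align_to_amplicon
#' @param min_non_cpg_c Minimum C/T-informative positions required.
#' @return List: `rate`, `n_converted`, `n_informative`, `ok` (FALSE with
#'   reason `"qc_insufficient"` when too few informative positions).
#' @export
conversion_rate <- function(read, ref, min_non_cpg_c = 10L,
                            identity_floor = 0.8, min_length = 50L) {
  cc <- call_reads(read, ref, min_non_cpg_c = min_non_cpg_c,
                   identity_floor = identity_floor, min_length = min_length)
  ok <- cc$reason[1] != "qc_insufficient" && cc$reason[1] != "unmapped"
  list(rate = cc$conversion_rate[1], ok = ok,
       reason = if (ok) NA_character_ else cc$reason[1])
}

#' Call the A/G variant allele of one read
#'
#' @inheritParams align_to_amplicon
#' @return `"G"`, `"A"`, or `"ambiguous"` (uncovered variant or non-A/G
#'   base).
#' @export
call_allele <- function(read, ref, identity_floor = 0.8, min_length = 50L) {
  cc <- call_reads(read, ref, identity_floor = identity_floor,
                   min_length = min_length)
  a <- cc$allele[1]
  if (a %in% c("G", "A")) a else "ambiguous"
}

#' Methylation bin of a per-read methylation percentage
#'
#' Ten bins: `[0, 10]`, `(10, 20]`, ..., `(90, 100]`. The first bin is
#' closed at 10 so that bin membership coincides with the "presumably
#' active" definition (methylation <= 10 percent).
#'
#' @param pct Numeric vector of methylation percentages (0..100).
#' @return Integer bin indices 1..10 (NA preserved).
#' @export
methylation_bin <- function(pct) {
  bin <- ifelse(pct <= 10, 1L, as.integer(ceiling(pct / 10)))
  bin[!is.na(pct) & (pct < 0 | pct > 100)] <- NA_integer_
  as.integer(bin)
}

#' Per-read methylation summary from CpG states
#'
#' @param cpg_states Character vector of states in
#'   `c("methylated", "unmethylated", "ambiguous")`.
#' @param min_cpgs Minimum analyzable (non-ambiguous) CpGs.
#' @return List: `n_methylated`, `n_analyzable`, `methylation_pct`, `bin`,
#'   `active` (methylation <= 10 percent), `ok` (FALSE with reason
#'   `"cpg_missing"` below the minimum).
#' @export
read_methylation <- function(cpg_states, min_cpgs = 20L) {
  stopifnot(all(cpg_states %in% c("methylated", "unmethylated", "ambiguous")))
  n_meth <- sum(cpg_states == "methylated")
  n_anal <- sum(cpg_states != "ambiguous")
  if (n_anal < min_cpgs)
    return(list(n_methylated = n_meth, n_analyzable = n_anal,
                methylation_pct = NA_real_, bin = NA_integer_,
                active = NA, ok = FALSE, reason = "cpg_missing"))
  pct <- 100 * n_meth / n_anal
  list(n_methylated = n_meth, n_analyzable = n_anal, methylation_pct = pct,
       bin = methylation_bin(pct), active = pct <= 10, ok = TRUE,
       reason = NA_character_)
}

#' Merge overlapping paired-end mates into one amplicon read
#'
#' Both mates are placed on the reference independently (the second mate is
#' supplied as sequenced and reverse-complemented here); the merged read
#' spans the union of the two placements, with per-column consensus:
#' positions covered by one mate take that mate's base, agreeing overlaps
#' keep the base, conflicting overlaps become `N` (ambiguous), and interior
#' positions covered by neither become `N`.
#'
#' @param mate1,mate2 Character scalars; `mate2` in sequencing orientation.
#' @param ref An [amplicon_reference()].
#' @param identity_floor,min_length Passed to the aligner.
#' @return List: `merged` (sequence or NA), `offset`, `mapped`.
#' @export
merge_mates <- function(mate1, mate2, ref, identity_floor = 0.8,
                        min_length = 50L) {
  m2 <- reverse_complement(toupper(mate2))
  a1 <- align_to_amplicon(mate1, ref, identity_floor, min_length)
  a2 <- align_to_amplicon(m2, ref, identity_floor, min_length)
  if (!a1$mapped || !a2$mapped)
    return(list(merged = NA_character_, offset = NA_integer_, mapped = FALSE))
  s1 <- strsplit(toupper(mate1), "")[[1]]
  s2 <- strsplit(m2, "")[[1]]
  lo <- min(a1$offset, a2$offset)
  hi <- max(a1$offset + length(s1), a2$offset + length(s2)) - 1L
  cons <- rep("N", hi - lo + 1L)
  i1 <- (a1$offset - lo + 1L):(a1$offset - lo + length(s1))
  cons[i1] <- s1
  i2 <- (a2$offset - lo + 1L):(a2$offset - lo + length(s2))
  clash <- cons[i2] != "N" & cons[i2] != s2
  cons[i2] <- ifelse(cons[i2] == "N", s2, ifelse(clash, "N", s2))
  list(merged = paste(cons, collapse = ""), offset = lo, mapped = TRUE)
}

#' Per-sample methylation profile
#'
#' Aggregates retained per-read calls into the sample-level quantities the
#' downstream integration uses: the fraction of retained reads in each of
#' the ten 10-percent methylation bins, the pooled mean promoter methylation
#' (total methylated CpG calls over total analyzable CpG calls), and the
#' hypomethylated (<= 10 percent, "presumably active") read fraction, which
#' by construction equals the first bin's fraction. The retention-reason
#' histogram accounts for every input read exactly once.
#'
#' @param calls Data frame from [call_reads()].
#' @param sample_id Sample identifier attached to the profile.
#' @param min_depth Minimum retained reads; below it the profile is flagged
#'   `no_data` and carries NA fractions (default 1; a realistic floor for
#'   clinical data is 100).
#' @param mean_method `"pooled"` (default: pooled CpG-call fraction) or
#'   `"per_read"` (mean of per-read percentages); identical for complete
#'   reads.
#' @return Object of class `methylation_profile`.
#' @export
profile_sample <- function(calls, sample_id = "sample", min_depth = 1L,
                           mean_method = c("pooled", "per_read")) {
  mean_method <- match.arg(mean_method)
  reasons <- c("unmapped", "qc_insufficient", "low_conversion", "allele",
               "cpg_missing")
  hist <- vapply(reasons, function(r) sum(calls$reason == r), integer(1))
  kept <- calls[calls$pass, , drop = FALSE]
  n_ret <- nrow(kept)
  no_data <- n_ret < max(1L, min_depth)
  if (no_data) {
    bins <- rep(NA_real_, 10)
    meanm <- NA_real_; hypo <- NA_real_
  } else {
    bins <- tabulate(kept$bin, nbins = 10) / n_ret
    meanm <- if (mean_method == "pooled")
      100 * sum(kept$n_methylated) / sum(kept$n_analyzable)
    else mean(kept$methylation_pct)
    hypo <- bins[1]
  }
  structure(list(
    sample_id = sample_id, n_reads_total = nrow(calls),
    n_reads_retained = n_ret, rejection_reasons = hist,
    bin_fractions = bins, mean_methylation_pct = meanm,
    hypomethylated_fraction = hypo, no_data = no_data,
    mean_method = mean_method
  ), class = "methylation_profile")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("Methylation profile %s: %d/%d reads retained%s\n",
              x$sample_id, x$n_reads_retained, x$n_reads_total,
              if (x$no_data) " [no_data]" else ""))
  if (!x$no_data)
    cat(sprintf("  mean methylation %.2f%%, hypomethylated fraction %.3f\n",
                x$mean_methylation_pct, x$hypomethylated_fraction))
  invisible(x)
}

#' Profile table for many samples
#'
#' @param profiles List of `methylation_profile` objects.
#' @return Data frame with one row per sample: retained counts, mean
#'   methylation, hypomethylated fraction and the ten bin fractions.
#' @export
profiles_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    row <- data.frame(sample_id = p$sample_id,
                      n_reads_total = p$n_reads_total,
                      n_reads_retained = p$n_reads_retained,
                      mean_methylation_pct = p$mean_methylation_pct,
                      hypomethylated_fraction = p$hypomethylated_fraction,
                      no_data = p$no_data, stringsAsFactors = FALSE)
    bf <- as.list(p$bin_fractions)
    names(bf) <- paste0("bin_frac_", 1:10)
    cbind(row, as.data.frame(bf))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
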