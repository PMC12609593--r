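#' Amplicon reference for the rDNA promoter bisulfite assay
#'
#' Describes the bisulfite amplicon against which reads are called: the
#' genomic (unconverted) sequence, the 1-based positions of the cytosines of
#' each CpG dinucleotide, and the position and major allele of the single
#' A/G variant used to restrict analysis to the major sequence variant.
#'
#' Invariants enforced: CpG positions are strictly increasing and each points
#' at a `CG` in the sequence; the sequence contains no `CG` outside the
#' annotated set; the variant position does not fall inside an annotated CpG;
#' and at least `min_non_cpg_c` cytosines lie outside CpG context (these are
#' the substrate of the per-read bisulfite conversion-rate QC).
#'
#' @param sequence Character scalar, unconverted DNA (A/C/G/T).
#' @param cpg_positions Integer vector, 1-based offsets of CpG cytosines.
#' @param variant_pos 1-based offset of the A/G variant site.
#' @param major_allele Major allele at the variant site, `"G"` or `"A"`.
#' @param min_non_cpg_c Minimum number of non-CpG cytosines required.
#' @return An object of class `amplicon_reference`.
#' @seealso [default_amplicon()] for the packaged 25-CpG promoter amplicon.
#' @export
amplicon_reference <- function(sequence, cpg_positions, variant_pos,
                               major_allele = "G", min_non_cpg_c = 20L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("amplicon sequence must contain only A/C/G/T")
  cpg_positions <- as.integer(cpg_positions)
  if (length(cpg_positions) < 1L || is.unsorted(cpg_positions, strictly = TRUE))
    stop("cpg_positions must be non-empty and strictly increasing")
  hits <- gregexpr("CG", sequence)[[1]]
  hits <- as.integer(hits[hits > 0])
  if (!identical(hits, cpg_positions))
    stop("cpg_positions must list exactly the CG dinucleotides in the sequence")
  variant_pos <- as.integer(variant_pos)
  if (variant_pos < 1L || variant_pos > length(chars))
    stop("variant_pos outside the sequence")
  if (any(variant_pos == cpg_positions | variant_pos == cpg_positions + 1L))
    stop("variant_pos must not fall inside a CpG dinucleotide")
  major_allele <- match.arg(major_allele, c("G", "A"))
  if (chars[variant_pos] != major_allele)
    stop("sequence base at variant_pos must equal the major allele")
  non_cpg_c <- setdiff(which(chars == "C"), cpg_positions)
  if (length(non_cpg_c) < min_non_cpg_c)
    stop(sprintf("amplicon has %d non-CpG cytosines; >= %d required for conversion QC",
                 length(non_cpg_c), min_non_cpg_c))
  structure(list(
    sequence = sequence,
    chars = chars,
    length = length(chars),
    cpg_positions = cpg_positions,
    n_cpg = length(cpg_positions),
    non_cpg_c_positions = non_cpg_c,
    variant_pos = variant_pos,
    major_allele = major_allele
  ), class = "amplicon_reference")
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("Amplicon reference: %d nt, %d CpGs, %s/%s variant at %d (major %s)\n",
              x$length, x$n_cpg, "G", "A", x$variant_pos, x$major_allele))
  invisible(x)
}

# Synthetic stand-in for the rDNA upstream control element / core promoter
# amplicon: 280 nt, 25 CpGs, one A/G variant (major G), 48 non-CpG cytosines.
# Constructed de novo (no genomic sequence is reproduced here).
.default_amplicon_seq <- paste0(
  "TGGTTAAAAATCAGACCAGTAAGACTTTCACTATCAGCACCGAGTCGGGGCGCCACGGTG",
  "TGACTAAGCGTAGCACCCGACCCCTCGTGCACGCAAAGGTCCGAGGTACGTACTGGCGTA",
  "ACGGCACCGCTACGGAGCTGGCTGGGTCGCACAGTCGAGACTGTCAGTCGAGCCGGTGCT",
  "TGCAGCACATACACGAATGTTAACGGACCAAGAGTCGTAGTTAGCGAGGGCCCGGGCAAG",
  "CAAAGCGTTCGATTAATATAAGAGGATCTAGGTCACATCA"
)

.default_amplicon_cpg <- c(41L, 46L, 51L, 56L, 69L, 78L, 86L, 92L, 102L,
                           109L, 117L, 122L, 128L, 133L, 148L, 156L, 169L,
                           174L, 194L, 204L, 216L, 225L, 233L, 246L, 250L)

#' Packaged synthetic rDNA promoter amplicon
#'
#' A synthetic 280-nt amplicon emulating the structure of the rDNA upstream
#' control element / core promoter bisulfite assay: 25 CpG dinucleotides and
#' a single A/G variant (major allele G). The sequence is an in-silico
#' construct, not a genomic sequence; only its structural properties (CpG
#' count, variant, non-CpG cytosine content) matter to the pipeline.
#'
#' @return An `amplicon_reference`.
#' @export
default_amplicon <- function() {
  amplicon_reference(.default_amplicon_seq, .default_amplicon_cpg,
                     variant_pos = 140L, major_allele = "G")
}

#' Write / read an amplicon reference as FASTA plus annotation TSV
#'
#' The FASTA holds the unconverted sequence; the sidecar TSV holds the CpG
#' offsets, variant offset and major allele so a reference round-trips
#' through plain-text files.
#'
#' @param ref An `amplicon_reference`.
#' @param fasta_path,annot_path Output (or input) file paths.
#' @param name Sequence name used in the FASTA header.
#' @return `write_amplicon()` returns the paths invisibly; `read_amplicon()`
#'   returns an `amplicon_reference`.
#' @export
write_amplicon <- function(ref, fasta_path, annot_path,
                           name = "rDNA_promoter_amplicon") {
  stopifnot(inherits(ref, "amplicon_reference"))
  dna <- Biostrings::DNAStringSet(ref$sequence)
  names(dna) <- name
  Biostrings::writeXStringSet(dna, fasta_path)
  annot <- data.frame(
    key = c(rep("cpg_position", ref$n_cpg), "variant_pos", "major_allele"),
    value = c(ref$cpg_positions, ref$variant_pos, ref$major_allele),
    stringsAsFactors = FALSE
  )
  utils::write.table(annot, annot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta_path, annot = annot_path))
}

#' @rdname write_amplicon
#' @export
read_amplicon <- function(fasta_path, annot_path) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1L) stop("amplicon FASTA must contain exactly one sequence")
  annot <- utils::read.table(annot_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, colClasses = "character")
  cpg <- as.integer(annot$value[annot$key == "cpg_position"])
  vp <- as.integer(annot$value[annot$key == "variant_pos"])
  major <- annot$value[annot$key == "major_allele"]
  amplicon_reference(as.character(dna[[1]]), cpg, vp, major)
}
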