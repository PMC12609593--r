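# Integration of absolute copy number with methylation bins, and the
# WHO 5th-edition semen classifier.

#' Copy numbers per methylation bin and the presumably active copy number
#'
#' Distributes the absolute copy number over the ten 10-percent methylation
#' bins in proportion to the read fractions, so that
#' `bin_cns[i] = absolute_cn * bin_fractions[i]`. The presumably active copy
#' number is the first bin (promoter methylation at most 10 percent).
#' Unrounded values are returned for statistics (they conserve the absolute
#' copy number exactly); half-up integer roundings are provided for
#' reporting.
#'
#' @param absolute_cn Absolute copy number (>= 0).
#' @param bin_fractions Ten bin fractions summing to 1.
#' @param tol Tolerance on the bin-fraction sum.
#' @return List: `bin_cns`, `active_cn`, `bin_cns_rounded`,
#'   `active_cn_rounded`.
#' @export
binned_copy_numbers <- function(absolute_cn, bin_fractions, tol = 1e-6) {
  if (absolute_cn < 0) stop("absolute_cn must be >= 0")
  if (length(bin_fractions) != 10L)
    stop("bin_fractions must have 10 elements")
  if (any(bin_fractions < -tol)) stop("bin fractions must be >= 0")
  if (abs(sum(bin_fractions) - 1) > tol)
    stop("bin fractions must sum to 1")
  cns <- absolute_cn * bin_fractions
  list(bin_cns = cns, active_cn = cns[1],
       bin_cns_rounded = round_half_up(cns),
       active_cn_rounded = round_half_up(cns[1]))
}

#' WHO 5th-edition semen reference thresholds
#'
#' Lower reference limits used by [classify_semen()]: semen volume 1.5 mL,
#' sperm concentration 15 x 10^6/mL, total motility 40 percent, normal
#' morphology 4 percent; cryptozoospermia below 0.1 x 10^6/mL. The
#' `"progressive_motility"` preset replaces the motility limit by 32
#' percent, for laboratories classifying on progressive rather than total
#' motility.
#'
#' @param preset `"total_motility"` (default) or `"progressive_motility"`.
#' @return Named list of thresholds.
#' @export
who5_thresholds <- function(preset = c("total_motility",
                                       "progressive_motility")) {
  preset <- match.arg(preset)
  list(volume_ml = 1.5, conc_mio_per_ml = 15,
       motility_pct = if (preset == "total_motility") 40 else 32,
       morphology_pct = 4, crypto_conc = 0.1)
}

#' Classify semen status under WHO-5 reference values
#'
#' A sample has normal semen parameters (NSP) iff volume, concentration,
#' motility and morphology all meet their thresholds; otherwise it has
#' abnormal semen parameters (ASP) with subtype labels: oligozoospermia
#' (low concentration), asthenozoospermia (low motility), teratozoospermia
#' (low morphology), OAT when all three are low, and cryptozoospermia when
#' concentration falls below the crypto threshold. A missing parameter
#' yields class `"unknown"`. Vectorised over samples; a pure threshold
#' function of its inputs.
#'
#' @param volume_ml,conc_mio_per_ml,motility_pct,morphology_pct Semen
#'   parameters (>= 0).
#' @param thresholds See [who5_thresholds()].
#' @return Data frame: `semen_class` (`NSP`/`ASP`/`unknown`) and `subtypes`
#'   (comma-separated labels, empty for NSP).
#' @export
classify_semen <- function(volume_ml, conc_mio_per_ml, motility_pct,
                           morphology_pct, thresholds = who5_thresholds()) {
  n <- length(volume_ml)
  stopifnot(length(conc_mio_per_ml) == n, length(motility_pct) == n,
            length(morphology_pct) == n)
  num_ok <- function(x) !is.na(x) & x >= 0
  complete <- num_ok(volume_ml) & num_ok(conc_mio_per_ml) &
    num_ok(motility_pct) & num_ok(morphology_pct)
  oligo <- conc_mio_per_ml < thresholds$conc_mio_per_ml
  astheno <- motility_pct < thresholds$motility_pct
  terato <- morphology_pct < thresholds$morphology_pct
  lowvol <- volume_ml < thresholds$volume_ml
  crypto <- conc_mio_per_ml < thresholds$crypto_conc
  asp <- oligo | astheno | terato | lowvol
  subtypes <- vapply(seq_len(n), function(i) {
    if (!complete[i] || !asp[i]) return("")
    labs <- c(if (oligo[i]) "oligozoospermia",
              if (astheno[i]) "asthenozoospermia",
              if (terato[i]) "teratozoospermia",
              if (oligo[i] && astheno[i] && terato[i]) "OAT",
              if (crypto[i]) "cryptozoospermia")
    paste(labs, collapse = ",")
  }, character(1))
  cls <- ifelse(!complete, "unknown", ifelse(asp, "ASP", "NSP"))
  data.frame(semen_class = cls, subtypes = subtypes, stringsAsFactors = FALSE)
}

#' Join ddPCR, methylation profiles and the sample sheet into sample records
#'
#' Produces the master per-sample table on which all cohort statistics run:
#' absolute copy number (ddPCR), mean promoter methylation and bin
#' fractions (DBS), the per-bin and presumably active copy numbers, the
#' WHO-5 classification recomputed from the sheet's semen parameters, and
#' the pregnancy outcome. Samples flagged `no_data` in the profile stage
#' are dropped with a message.
#'
#' @param sheet Sample sheet data frame (see [read_sample_sheet()]).
#' @param ddpcr Data frame from [ddpcr_table()].
#' @param profiles Data frame from [profiles_table()].
#' @param thresholds WHO-5 thresholds for the classifier.
#' @return Master data frame, one row per sample, with unrounded
#'   `absolute_cn`, `active_cn`, `bin_cn_1` .. `bin_cn_10`, and
#'   `active_cn_rounded`.
#' @export
integrate_samples <- function(sheet, ddpcr, profiles,
                              thresholds = who5_thresholds()) {
  ids <- Reduce(intersect, list(sheet$sample_id, ddpcr$sample_id,
                                profiles$sample_id))
  dropped <- setdiff(sheet$sample_id, ids)
  if (length(dropped))
    message("dropping ", length(dropped), " sample(s) without both assays")
  m <- merge(merge(sheet, ddpcr, by = "sample_id"), profiles,
             by = "sample_id")
  nod <- m$no_data
  if (any(nod)) {
    message("dropping ", sum(nod), " sample(s) flagged no_data")
    m <- m[!nod, , drop = FALSE]
  }
  cls <- classify_semen(m$volume_ml, m$conc_mio_per_ml, m$motility_pct,
                        m$morphology_pct, thresholds)
  m$semen_class <- cls$semen_class
  m$subtypes <- cls$subtypes
  binmat <- as.matrix(m[, paste0("bin_frac_", 1:10)])
  cn_bins <- binmat * m$absolute_cn
  colnames(cn_bins) <- paste0("bin_cn_", 1:10)
  m$methylation_pct <- m$mean_methylation_pct
  m$active_cn <- cn_bins[, 1]
  m$active_cn_rounded <- round_half_up(m$active_cn)
  out <- cbind(m, as.data.frame(cn_bins))
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
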