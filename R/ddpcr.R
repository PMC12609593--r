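#' Droplet well container
#'
#' One ddPCR well for one assay (target rDNA or single-copy reference gene),
#' summarised as total droplets and positive droplets. The dilution factor
#' records any pre-partition dilution of the template relative to the
#' reference well, so that concentrations are comparable after correction.
#'
#' @param well_id Character well identifier.
#' @param assay `"target"` or `"reference"`.
#' @param n_droplets Total accepted droplets (> 0).
#' @param n_positive Positive droplets (0..n_droplets).
#' @param dilution Dilution factor >= 1 applied to the template in this well.
#' @param saturated Logical; flags wells where the positive fraction is at
#'   (or numerically indistinguishable from) 1, making the Poisson estimate
#'   unbounded.
#' @return An object of class `droplet_well`.
#' @export
droplet_well <- function(well_id, assay = c("target", "reference"),
                         n_droplets, n_positive, dilution = 1,
                         saturated = FALSE) {
  assay <- match.arg(assay)
  n_droplets <- as.integer(n_droplets)
  n_positive <- as.integer(n_positive)
  if (is.na(n_droplets) || n_droplets <= 0L) stop("n_droplets must be > 0")
  if (is.na(n_positive) || n_positive < 0L || n_positive > n_droplets)
    stop("n_positive must be in [0, n_droplets]")
  if (!is.numeric(dilution) || dilution < 1) stop("dilution must be >= 1")
  structure(list(well_id = as.character(well_id), assay = assay,
                 n_droplets = n_droplets, n_positive = n_positive,
                 dilution = dilution, saturated = isTRUE(saturated)),
            class = "droplet_well")
}

#' @export
print.droplet_well <- function(x, ...) {
  cat(sprintf("ddPCR well %s [%s]: %d/%d positive, dilution %g%s\n",
              x$well_id, x$assay, x$n_positive, x$n_droplets, x$dilution,
              if (x$saturated) " (SATURATED)" else ""))
  invisible(x)
}

#' Classify droplets from two-channel amplitudes
#'
#' Applies fixed per-channel thresholds to droplet fluorescence amplitudes
#' (channel 1 = FAM/reference gene, channel 2 = HEX/rDNA target, following
#' the assay's label convention). A droplet is positive on a channel iff its
#' amplitude strictly exceeds that channel's threshold. Thresholds are user
#' inputs, mirroring manual threshold adjustment in the instrument software.
#'
#' @param amplitudes Data frame with columns `ch1_amplitude` and
#'   `ch2_amplitude` (one row per droplet); a `well_id` column is carried
#'   through if present.
#' @param thresholds Named list/vector with elements `ch1` and `ch2`.
#' @return A one-row data frame of counts: `n_droplets`, `ch1_positive`,
#'   `ch2_positive`, `double_positive`, `double_negative`.
#' @export
classify_droplets <- function(amplitudes, thresholds) {
  if (!is.data.frame(amplitudes) || nrow(amplitudes) == 0L)
    stop("amplitudes must be a non-empty data frame")
  for (col in c("ch1_amplitude", "ch2_amplitude"))
    if (!col %in% names(amplitudes)) stop("missing channel column: ", col)
  thr <- as.list(thresholds)
  if (is.null(thr$ch1) || is.null(thr$ch2) ||
      !is.finite(thr$ch1) || !is.finite(thr$ch2))
    stop("thresholds must provide finite ch1 and ch2 cutoffs")
  p1 <- amplitudes$ch1_amplitude > thr$ch1
  p2 <- amplitudes$ch2_amplitude > thr$ch2
  out <- data.frame(
    n_droplets = nrow(amplitudes),
    ch1_positive = sum(p1),
    ch2_positive = sum(p2),
    double_positive = sum(p1 & p2),
    double_negative = sum(!p1 & !p2)
  )
  if (!is.null(amplitudes$well_id))
    out <- cbind(well_id = amplitudes$well_id[1], out)
  out
}

#' Poisson occupancy estimate for one well
#'
#' Converts a positive-droplet fraction into the mean template copies per
#' droplet via the Poisson occupancy relation `lambda = -ln(1 - p)`,
#' corrected for the well's dilution factor, and into a concentration in
#' copies/microlitre given the droplet volume. The confidence interval is a
#' Wilson score interval on the positive fraction propagated through the
#' same transform (monotone, so endpoints map directly).
#'
#' @param n_positive,n_droplets Positive and total droplet counts.
#' @param droplet_volume_nl Droplet volume in nanolitres (default 0.85,
#'   the QX200 convention); affects only the concentration scale, never
#'   ratios of wells measured with the same volume.
#' @param dilution Dilution factor >= 1.
#' @param conf_level Confidence level for the interval.
#' @return List with `lambda` (dilution-corrected copies/droplet),
#'   `concentration` (copies/uL, dilution-corrected), `p_hat`, and
#'   `lambda_ci`, `concentration_ci` (2-vectors).
#' @export
estimate_lambda <- function(n_positive, n_droplets, droplet_volume_nl = 0.85,
                            dilution = 1, conf_level = 0.95) {
  n_positive <- as.integer(n_positive); n_droplets <- as.integer(n_droplets)
  if (n_droplets <= 0L) stop("n_droplets must be > 0")
  if (n_positive < 0L || n_positive > n_droplets)
    stop("n_positive must be in [0, n_droplets]")
  if (n_positive == n_droplets)
    stop("well is saturated (all droplets positive): lambda is unbounded")
  if (droplet_volume_nl <= 0) stop("droplet_volume_nl must be > 0")
  if (dilution < 1) stop("dilution must be >= 1")
  p <- n_positive / n_droplets
  lam <- -log1p(-p) * dilution
  ci_p <- wilson_interval(n_positive, n_droplets, conf_level)
  ci_lam <- -log1p(-ci_p) * dilution
  vol_ul <- droplet_volume_nl * 1e-3
  list(lambda = lam, concentration = lam / vol_ul, p_hat = p,
       lambda_ci = unname(ci_lam), concentration_ci = unname(ci_lam / vol_ul),
       n_positive = n_positive, n_droplets = n_droplets, dilution = dilution)
}

#' Absolute copy number from a target and a reference well
#'
#' Copy number is the ratio of the dilution-corrected target concentration to
#' the reference concentration, multiplied by the copy number of the
#' reference gene, `m_ref`. For a single-copy autosomal reference gene,
#' `m_ref = 1` expresses the result per haploid genome (the convention for
#' sperm) and `m_ref = 2` per diploid genome. The confidence interval
#' combines the two wells' Wilson intervals by the delta method on the log
#' ratio.
#'
#' @param target,reference `droplet_well` objects (or lists with the same
#'   fields).
#' @param m_ref Copy number of the reference gene in the genome of interest
#'   (default 1: haploid mode).
#' @param droplet_volume_nl Droplet volume in nanolitres.
#' @param conf_level Confidence level.
#' @return An object of class `copy_number_estimate`: lambdas,
#'   concentrations, `ratio`, `m_ref`, `absolute_cn`, `ci_low`, `ci_high`.
#' @export
copy_number <- function(target, reference, m_ref = 1,
                        droplet_volume_nl = 0.85, conf_level = 0.95) {
  if (isTRUE(target$saturated) || target$n_positive == target$n_droplets)
    stop("target well is saturated; copy number is unbounded")
  if (m_ref <= 0) stop("m_ref must be > 0")
  et <- estimate_lambda(target$n_positive, target$n_droplets,
                        droplet_volume_nl, target$dilution %||% 1, conf_level)
  er <- estimate_lambda(reference$n_positive, reference$n_droplets,
                        droplet_volume_nl, reference$dilution %||% 1, conf_level)
  if (er$lambda <= 0)
    stop("reference well has no positive droplets: ratio undefined")
  ratio <- et$lambda / er$lambda
  cn <- ratio * m_ref
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  # delta method on log lambda, using the Wilson half-width as a z*se proxy
  se_log <- function(e) {
    if (e$lambda <= 0) return(NA_real_)
    diff(log(e$lambda_ci)) / (2 * z)
  }
  st <- se_log(et); sr <- se_log(er)
  if (et$lambda > 0 && is.finite(st) && is.finite(sr)) {
    se <- sqrt(st^2 + sr^2)
    ci <- cn * exp(c(-1, 1) * z * se)
  } else {
    # zero target positives: lower bound 0, upper from the interval endpoints
    ci <- c(0, m_ref * et$lambda_ci[2] / er$lambda_ci[1])
  }
  structure(list(
    lambda_target = et$lambda, lambda_reference = er$lambda,
    concentration_target = et$concentration,
    concentration_reference = er$concentration,
    ratio = ratio, m_ref = m_ref, absolute_cn = cn,
    ci_low = ci[1], ci_high = ci[2], conf_level = conf_level
  ), class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("Absolute CN: %.1f copies (%.0f%% CI %.1f-%.1f); ratio %.3f x m_ref %g\n",
              x$absolute_cn, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$ratio, x$m_ref))
  invisible(x)
}

#' Read droplet count tables
#'
#' Reads the simplified counts schema: a CSV with header
#' `sample_id,well_id,assay,n_droplets,n_positive,dilution`.
#'
#' @param path CSV path.
#' @return Data frame of validated well rows.
#' @export
read_droplet_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "well_id", "assay", "n_droplets", "n_positive", "dilution")
  missing <- setdiff(req, names(df))
  if (length(missing)) stop("droplet counts CSV missing column(s): ",
                            paste(missing, collapse = ", "))
  if (!all(df$assay %in% c("target", "reference")))
    stop("assay must be 'target' or 'reference'")
  bad <- df$n_positive < 0 | df$n_positive > df$n_droplets | df$n_droplets <= 0
  if (any(bad)) stop("invalid droplet counts in row(s): ",
                     paste(which(bad), collapse = ", "))
  df
}

#' Per-sample absolute copy number from a wells table
#'
#' Pairs each sample's target and reference wells and computes the absolute
#' copy number estimate for each sample.
#'
#' @param wells Data frame as returned by [read_droplet_counts()] (or built
#'   in code with the same columns).
#' @inheritParams copy_number
#' @return Data frame: `sample_id`, `absolute_cn`, `ci_low`, `ci_high`,
#'   `ratio`, `lambda_target`, `lambda_reference`.
#' @export
ddpcr_table <- function(wells, m_ref = 1, droplet_volume_nl = 0.85,
                        conf_level = 0.95) {
  out <- lapply(split(wells, wells$sample_id), function(w) {
    tg <- w[w$assay == "target", , drop = FALSE]
    rf <- w[w$assay == "reference", , drop = FALSE]
    if (nrow(tg) != 1L || nrow(rf) != 1L)
      stop("sample ", w$sample_id[1],
           ": need exactly one target and one reference well")
    est <- copy_number(
      droplet_well(tg$well_id, "target", tg$n_droplets, tg$n_positive, tg$dilution),
      droplet_well(rf$well_id, "reference", rf$n_droplets, rf$n_positive, rf$dilution),
      m_ref = m_ref, droplet_volume_nl = droplet_volume_nl,
      conf_level = conf_level)
    data.frame(sample_id = w$sample_id[1], absolute_cn = est$absolute_cn,
               ci_low = est$ci_low, ci_high = est$ci_high, ratio = est$ratio,
               lambda_target = est$lambda_target,
               lambda_reference = est$lambda_reference)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample_id), , drop = FALSE]
}
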