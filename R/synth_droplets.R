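#' Simulate a ddPCR target/reference well pair
#'
#' Droplet-level generative model for the copy-number assay. Template
#' molecules partition independently into droplets, so the number of
#' positive droplets is binomial with the Poisson occupancy probability:
#' reference well `p = 1 - exp(-ref_lambda)`, target well
#' `p = 1 - exp(-true_cn * ref_lambda / dilution_target)`. The target is
#' run in a separate, diluted well (default 10x) because a several-hundred
#' copy target would saturate an undiluted well at a reference loading that
#' keeps the single-copy gene countable.
#'
#' @param true_cn True copies of the target per haploid genome (>= 0).
#' @param n_droplets Droplets per well (default 20000).
#' @param ref_lambda Mean reference-gene copies per droplet (default 0.0305).
#' @param dilution_target Dilution factor of the target well (>= 1,
#'   default 10).
#' @param well_id Prefix for the two well ids.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return List with `target` and `reference` [droplet_well()] objects.
#'   Wells whose expected positive fraction is numerically 1 carry
#'   `saturated = TRUE` instead of failing, so a saturation can be detected
#'   downstream.
#' @export
simulate_droplets <- function(true_cn, n_droplets = 20000L,
                              ref_lambda = 0.0305, dilution_target = 10,
                              well_id = "W", seed = NULL) {
  stopifnot(true_cn >= 0, n_droplets > 0, ref_lambda > 0, dilution_target >= 1)
  with_seed(seed, {
    p_ref <- -expm1(-ref_lambda)
    p_tgt <- -expm1(-true_cn * ref_lambda / dilution_target)
    sat_ref <- p_ref >= 1 - 1e-12
    sat_tgt <- p_tgt >= 1 - 1e-12
    if (sat_ref) warning("reference well saturated")
    if (sat_tgt) warning("target well saturated")
    k_tgt <- stats::rbinom(1, n_droplets, min(p_tgt, 1))
    k_ref <- stats::rbinom(1, n_droplets, min(p_ref, 1))
    list(
      target = droplet_well(paste0(well_id, "_T"), "target", n_droplets,
                            k_tgt, dilution_target, saturated = sat_tgt),
      reference = droplet_well(paste0(well_id, "_R"), "reference", n_droplets,
                               k_ref, 1, saturated = sat_ref)
    )
  })
}

#' Simulated droplet wells for a whole cohort
#'
#' @param donors Donor truth table from [simulate_cohort()] (needs
#'   `sample_id` and `true_abs_cn`).
#' @inheritParams simulate_droplets
#' @param seed RNG seed for the whole table.
#' @return Wells data frame in the counts schema accepted by
#'   [ddpcr_table()].
#' @export
simulate_droplet_table <- function(donors, n_droplets = 20000L,
                                   ref_lambda = 0.0305, dilution_target = 10,
                                   seed = NULL) {
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(donors)), function(i) {
      w <- simulate_droplets(donors$true_abs_cn[i], n_droplets, ref_lambda,
                             dilution_target,
                             well_id = donors$sample_id[i])
      data.frame(
        sample_id = donors$sample_id[i],
        well_id = c(w$target$well_id, w$reference$well_id),
        assay = c("target", "reference"),
        n_droplets = c(w$target$n_droplets, w$reference$n_droplets),
        n_positive = c(w$target$n_positive, w$reference$n_positive),
        dilution = c(w$target$dilution, w$reference$dilution),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
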