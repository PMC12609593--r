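# Synthetic cohort generator: ground-truth donors with the statistical
# structure the analysis pipeline assumes.

#' Cohort specification for the synthetic generator
#'
#' Bundles the calibration of the generator: group sizes, age/BMI and
#' absolute-copy-number distributions, the methylation model (baseline mean
#' promoter methylation of the normal-semen group, the abnormal-group
#' offset in percentage points, an age slope, residual donor scatter), the
#' two per-copy methylation modes, and the logistic pregnancy model.
#' Defaults emulate a 94 + 96 clinical cohort: absolute CN truncated-normal
#' (mean 236, SD 58, bounds 100-420 copies/haploid genome), NSP mean
#' methylation 12.1 percent with a +1.8 point ASP offset, an age slope
#' calibrated so that Spearman correlation between age and active CN is
#' about -0.54 over the cohort, and pregnancy coefficients calibrated so
#' that samples with pregnancy average about 24 more absolute copies.
#'
#' @param n_nsp,n_asp Group sizes (> 0).
#' @param age_mean_sd,age_bounds Age distribution (years).
#' @param bmi_mean_sd,bmi_bounds BMI distribution (kg/m^2).
#' @param abs_cn_mean_sd,abs_cn_bounds Absolute copy-number distribution
#'   (copies per haploid genome; truncated normal).
#' @param meth_base Mean promoter methylation (percent) of NSP donors at the
#'   mean age.
#' @param asp_methylation_offset ASP minus NSP expected methylation,
#'   percentage points.
#' @param age_methylation_slope Percentage points of methylation per year of
#'   age.
#' @param meth_noise_sd Residual donor-level methylation SD (percentage
#'   points).
#' @param active_mode_mean,active_mode_conc Beta distribution (mean,
#'   concentration) of the per-CpG methylation probability of active copies
#'   across donors.
#' @param inactive_mode_mean,inactive_mode_conc Same for inactive copies.
#' @param pregnancy_model Named coefficients of the logistic model on
#'   z-standardised covariates: `intercept`, `active_cn`, `concentration`,
#'   `motility`, `morphology`, `age`.
#' @param asp_subtype_weights Named weights for ASP subtypes
#'   (asthenozoospermia, OAT, oligozoospermia, teratozoospermia,
#'   cryptozoospermia).
#' @param n_pregnancy_missing Donors with unknown pregnancy outcome
#'   (default 1, as in a cohort with one unrecorded outcome).
#' @param seed Default RNG seed for [simulate_cohort()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_nsp = 94L, n_asp = 96L,
                        age_mean_sd = c(39, 7), age_bounds = c(25, 57),
                        bmi_mean_sd = c(26.5, 4.5), bmi_bounds = c(17.5, 52),
                        abs_cn_mean_sd = c(236, 58),
                        abs_cn_bounds = c(100, 420),
                        meth_base = 12.1, asp_methylation_offset = 1.8,
                        age_methylation_slope = 0.35, meth_noise_sd = 1.9,
                        active_mode_mean = 0.02, active_mode_conc = 150,
                        inactive_mode_mean = 0.22, inactive_mode_conc = 400,
                        pregnancy_model = c(intercept = 0.18,
                                            active_cn = 1.00,
                                            concentration = 0.25,
                                            motility = 0.15,
                                            morphology = 0.40,
                                            age = -0.10),
                        asp_subtype_weights = c(asthenozoospermia = 49,
                                                OAT = 37,
                                                oligozoospermia = 4,
                                                teratozoospermia = 4,
                                                cryptozoospermia = 2),
                        n_pregnancy_missing = 1L, seed = 1L) {
  if (n_nsp <= 0L || n_asp <= 0L) stop("group sizes must be > 0")
  if (any(c(age_mean_sd[2], bmi_mean_sd[2], abs_cn_mean_sd[2],
            meth_noise_sd) < 0)) stop("all SDs must be >= 0")
  if (abs_cn_bounds[1] <= 0 || abs_cn_bounds[1] >= abs_cn_bounds[2])
    stop("abs_cn_bounds must be positive with lower < upper")
  if (abs_cn_mean_sd[2] == 0 &&
      (abs_cn_mean_sd[1] < abs_cn_bounds[1] ||
       abs_cn_mean_sd[1] > abs_cn_bounds[2]))
    stop("degenerate CN spec: zero variance with mean outside bounds")
  req <- c("intercept", "active_cn", "concentration", "motility",
           "morphology", "age")
  if (!all(req %in% names(pregnancy_model)))
    stop("pregnancy_model must name coefficients: ",
         paste(req, collapse = ", "))
  if (active_mode_mean >= inactive_mode_mean)
    stop("active-mode methylation must be below the inactive mode")
  structure(as.list(environment()), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d NSP + %d ASP donors; abs CN ~ TN(%g, %g) in [%g, %g]\n",
              x$n_nsp, x$n_asp, x$abs_cn_mean_sd[1], x$abs_cn_mean_sd[2],
              x$abs_cn_bounds[1], x$abs_cn_bounds[2]))
  cat(sprintf("  methylation: NSP base %.1f%%, ASP offset +%.1f pp, age slope %.2f pp/yr\n",
              x$meth_base, x$asp_methylation_offset, x$age_methylation_slope))
  invisible(x)
}

# Semen parameter draws. NSP donors are guaranteed to satisfy the WHO-5
# thresholds (after reporting-precision rounding); ASP donors fail in the
# parameter(s) of their assigned subtype.
.draw_semen <- function(n, subtype) {
  vol <- round(pmin(pmax(exp(stats::rnorm(n, log(3.1), 0.35)), 1.5), 8), 1)
  conc <- round(pmin(pmax(exp(stats::rnorm(n, log(70), 0.5)), 16), 250))
  mot <- round(rtruncnorm(n, 58, 11, 40, 85))
  morph <- round(rtruncnorm(n, 8.5, 3.5, 4, 18))
  low_conc <- round(pmin(pmax(exp(stats::rnorm(n, log(7), 0.7)), 0.5), 14.4))
  low_mot <- round(rtruncnorm(n, 28, 10, 1, 39.4))
  low_morph <- round(rtruncnorm(n, 1.8, 1.1, 0, 3.4))
  crypto_conc <- round(stats::runif(n, 0.02, 0.09), 2)
  conc[subtype %in% c("oligozoospermia", "OAT")] <-
    low_conc[subtype %in% c("oligozoospermia", "OAT")]
  conc[subtype == "cryptozoospermia"] <- crypto_conc[subtype == "cryptozoospermia"]
  mot[subtype %in% c("asthenozoospermia", "OAT", "cryptozoospermia")] <-
    low_mot[subtype %in% c("asthenozoospermia", "OAT", "cryptozoospermia")]
  morph[subtype %in% c("teratozoospermia", "OAT")] <-
    low_morph[subtype %in% c("teratozoospermia", "OAT")]
  data.frame(volume_ml = vol, conc_mio_per_ml = conc, motility_pct = mot,
             morphology_pct = morph)
}

# Allocate ASP subtypes by largest-remainder apportionment of the weights.
.allocate_subtypes <- function(n, weights) {
  q <- n * weights / sum(weights)
  k <- floor(q)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(q - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  rep(names(weights), k)
}

#' Simulate a ground-truth donor cohort
#'
#' Draws donors according to a [cohort_spec()]. Each donor receives an
#' absolute copy number, a donor-level expected promoter methylation (linear
#' in group and age plus residual scatter), the two per-copy methylation
#' modes, and the active-copy fraction solving the mixture identity
#' `methylation = f * p_active + (1 - f) * p_inactive`. From these the
#' expected hypomethylated-read fraction and expected active copy number
#' follow in closed form. Semen parameters are drawn so that every NSP
#' donor satisfies the WHO-5 classifier and every ASP donor fails it in the
#' parameter(s) of its subtype. Pregnancy is Bernoulli under the spec's
#' logistic model on z-standardised covariates.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed (defaults to `spec$seed`). Identical seeds give
#'   identical cohorts.
#' @return Data frame (one row per donor) with identifiers, group and
#'   subtype, clinical covariates, pregnancy outcome, and the ground-truth
#'   columns `true_abs_cn`, `p_active_mode`, `p_inactive_mode`,
#'   `true_active_fraction` (copy-level), `true_meth_pct`,
#'   `true_hypo_fraction` (expected read fraction at or below 10 percent
#'   methylation) and `true_active_cn`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n_nsp + spec$n_asp
    group <- c(rep("NSP", spec$n_nsp), rep("ASP", spec$n_asp))
    subtype <- c(rep("", spec$n_nsp),
                 .allocate_subtypes(spec$n_asp, spec$asp_subtype_weights))
    age <- round(rtruncnorm(n, spec$age_mean_sd[1], spec$age_mean_sd[2],
                            spec$age_bounds[1], spec$age_bounds[2]), 1)
    bmi <- round(rtruncnorm(n, spec$bmi_mean_sd[1], spec$bmi_mean_sd[2],
                            spec$bmi_bounds[1], spec$bmi_bounds[2]), 1)
    abs_cn <- rtruncnorm(n, spec$abs_cn_mean_sd[1], spec$abs_cn_mean_sd[2],
                         spec$abs_cn_bounds[1], spec$abs_cn_bounds[2])
    p_act <- rbeta_ms(n, spec$active_mode_mean, spec$active_mode_conc)
    p_inact <- rbeta_ms(n, spec$inactive_mode_mean, spec$inactive_mode_conc)
    meth <- spec$meth_base +
      spec$age_methylation_slope * (age - spec$age_mean_sd[1]) +
      spec$asp_methylation_offset * (group == "ASP") +
      stats::rnorm(n, 0, spec$meth_noise_sd)
    meth <- pmin(pmax(meth, 100 * p_act + 0.2), 100 * p_inact - 0.2)
    f <- (p_inact - meth / 100) / (p_inact - p_act)
    hypo <- expected_hypomethylated_fraction(f, p_act, p_inact)
    active_cn <- abs_cn * hypo

    semen <- .draw_semen(n, subtype)
    z <- function(x) (x - mean(x)) / stats::sd(x)
    b <- spec$pregnancy_model
    eta <- b[["intercept"]] + b[["active_cn"]] * z(active_cn) +
      b[["concentration"]] * z(semen$conc_mio_per_ml) +
      b[["motility"]] * z(semen$motility_pct) +
      b[["morphology"]] * z(semen$morphology_pct) +
      b[["age"]] * z(age)
    preg <- ifelse(stats::runif(n) < stats::plogis(eta), "yes", "no")
    if (spec$n_pregnancy_missing > 0L) {
      miss <- sample(n, min(spec$n_pregnancy_missing, n))
      preg[miss] <- "unknown"
    }
    donors <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      group = group, subtype = subtype,
      age = age, bmi = bmi,
      semen,
      pregnancy = preg,
      true_abs_cn = abs_cn,
      p_active_mode = p_act, p_inactive_mode = p_inact,
      true_active_fraction = f,
      true_meth_pct = meth,
      true_hypo_fraction = hypo,
      true_active_cn = active_cn,
      stringsAsFactors = FALSE)
    attr(donors, "cohort_spec") <- spec
    donors
  })
}

#' Ground-truth view of a cohort as analysis-ready sample records
#'
#' Renames the truth columns of a [simulate_cohort()] table to the names
#' the statistics layer expects (`absolute_cn`, `active_cn`,
#' `methylation_pct`), with the WHO-5 classification recomputed from the
#' semen parameters. Useful for separating generator calibration checks
#' from measurement error: statistics run on these records see the truth
#' without ddPCR or sequencing noise.
#'
#' @param donors Donor table from [simulate_cohort()].
#' @param thresholds WHO-5 thresholds for the classifier.
#' @return Data frame shaped like the master table of
#'   [integrate_samples()].
#' @export
truth_records <- function(donors, thresholds = who5_thresholds()) {
  cls <- classify_semen(donors$volume_ml, donors$conc_mio_per_ml,
                        donors$motility_pct, donors$morphology_pct,
                        thresholds)
  data.frame(
    sample_id = donors$sample_id,
    absolute_cn = donors$true_abs_cn,
    active_cn = donors$true_active_cn,
    methylation_pct = donors$true_meth_pct,
    age = donors$age, bmi = donors$bmi,
    volume_ml = donors$volume_ml,
    conc_mio_per_ml = donors$conc_mio_per_ml,
    motility_pct = donors$motility_pct,
    morphology_pct = donors$morphology_pct,
    semen_class = cls$semen_class, subtypes = cls$subtypes,
    pregnancy = donors$pregnancy,
    stringsAsFactors = FALSE)
}

#' Write / read the cohort sample sheet
#'
#' The sample sheet is the clinical-facing view of the cohort (no ground
#' truth): CSV with header `sample_id,group,age,bmi,volume_ml,
#' conc_mio_per_ml,motility_pct,morphology_pct,pregnancy`.
#'
#' @param donors Donor table from [simulate_cohort()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_sample_sheet <- function(donors, path) {
  cols <- c("sample_id", "group", "age", "bmi", "volume_ml",
            "conc_mio_per_ml", "motility_pct", "morphology_pct", "pregnancy")
  sheet <- donors[, cols]
  sheet$pregnancy[sheet$pregnancy == "unknown"] <- ""
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the ground-truth sidecar for a cohort
#'
#' @param donors Donor table from [simulate_cohort()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort_truth <- function(donors, path) {
  cols <- c("sample_id", "true_abs_cn", "p_active_mode", "p_inactive_mode",
            "true_active_fraction", "true_meth_pct", "true_hypo_fraction",
            "true_active_cn")
  utils::write.csv(donors[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
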