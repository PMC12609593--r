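# Formats, configuration, orchestration and reporting.

#' Read and validate a cohort sample sheet
#'
#' CSV with required header `sample_id,group,age,bmi,volume_ml,
#' conc_mio_per_ml,motility_pct,morphology_pct,pregnancy`. Pregnancy values
#' other than yes/no (including blanks) map to `"unknown"`; duplicate
#' sample ids and non-numeric clinical fields are errors.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) stop("sample sheet is empty")
  req <- c("sample_id", "group", "age", "bmi", "volume_ml",
           "conc_mio_per_ml", "motility_pct", "morphology_pct", "pregnancy")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  num_cols <- c("age", "bmi", "volume_ml", "conc_mio_per_ml",
                "motility_pct", "morphology_pct")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- !is.na(df[[col]]) & df[[col]] != "" & is.na(v)
    if (any(bad))
      stop("non-numeric values in column ", col, " (row ",
           paste(which(bad), collapse = ", "), ")")
    df[[col]] <- v
  }
  df$pregnancy <- ifelse(df$pregnancy %in% c("yes", "no"), df$pregnancy,
                         "unknown")
  df
}

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run with validated defaults.
#' Unknown keys are rejected. The resolved configuration is echoed into
#' every run report and manifest.
#'
#' @param ... Overrides of the defaults, by name.
#' @return Object of class `run_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_reads = 300L,
    paired = FALSE,
    n_droplets = 20000L,
    ref_lambda = 0.0305,
    dilution_target = 10,
    droplet_volume_nl = 0.85,
    m_ref = 1,
    min_conversion = 0.95,
    min_cpgs = 20L,
    min_non_cpg_c = 10L,
    min_depth = 1L,
    identity_floor = 0.8,
    conversion_failure_rate = 0.005,
    seq_error_rate = 0.001,
    minor_allele_fraction = 0.02,
    who5_preset = "total_motility",
    alpha = 0.05,
    min_k = 5L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    if (min_conversion < 0 || min_conversion > 1)
      stop("min_conversion must lie in [0, 1]")
    if (identity_floor < 0 || identity_floor > 1)
      stop("identity_floor must lie in [0, 1]")
    if (n_reads <= 0 || n_droplets <= 0) stop("counts must be > 0")
    if (dilution_target < 1) stop("dilution_target must be >= 1")
    if (!who5_preset %in% c("total_motility", "progressive_motility"))
      stop("unknown who5_preset")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  })
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [pipeline_config()] defaults.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the whole synthetic-study pipeline
#'
#' Executes simulate -> ddPCR -> DBS -> integrate -> statistics against a
#' synthetic cohort and writes every intermediate and final artefact under
#' `outdir`: sample sheet and truth sidecar, droplet counts CSV, per-sample
#' FASTQ (round-tripped through disk before calling), ddPCR and profile
#' tables, the master per-sample TSV, and a JSON run report with a manifest
#' (parameters, seed, input hashes, package version). Reruns with the same
#' config are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param spec Optional [cohort_spec()]; defaults to `cohort_spec(seed =
#'   config$seed)`.
#' @param ref Amplicon reference (default [default_amplicon()]).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `donors`, `master`, `stats`, `report_path`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run"),
                         spec = NULL, ref = default_amplicon(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  if (is.null(spec)) spec <- cohort_spec(seed = config$seed)

  say("stage 1/5: simulating cohort")
  donors <- simulate_cohort(spec, seed = config$seed)
  sheet_path <- file.path(outdir, "sample_sheet.csv")
  write_sample_sheet(donors, sheet_path)
  write_cohort_truth(donors, file.path(outdir, "cohort_truth.csv"))

  say("stage 2/5: ddPCR wells and copy-number estimation")
  wells <- simulate_droplet_table(donors, config$n_droplets,
                                  config$ref_lambda, config$dilution_target,
                                  seed = config$seed + 1L)
  wells_path <- file.path(outdir, "droplet_counts.csv")
  utils::write.csv(wells, wells_path, row.names = FALSE, quote = FALSE)
  cn_tbl <- ddpcr_table(read_droplet_counts(wells_path), m_ref = config$m_ref,
                        droplet_volume_nl = config$droplet_volume_nl)

  say("stage 3/5: bisulfite reads and methylation profiles")
  fq_dir <- file.path(outdir, "fastq")
  dir.create(fq_dir, showWarnings = FALSE)
  profiles <- vector("list", nrow(donors))
  for (i in seq_len(nrow(donors))) {
    sim <- simulate_reads(
      config$n_reads, ref,
      active_fraction = donors$true_active_fraction[i],
      p_active = donors$p_active_mode[i],
      p_inactive = donors$p_inactive_mode[i],
      conversion_failure_rate = config$conversion_failure_rate,
      seq_error_rate = config$seq_error_rate,
      minor_allele_fraction = config$minor_allele_fraction,
      paired = config$paired, sample_id = donors$sample_id[i],
      seed = config$seed + 1000L + i)
    fq <- file.path(fq_dir, paste0(donors$sample_id[i], ".fastq"))
    write_fastq(sim$reads, fq)
    reads <- if (config$paired) {
      p1 <- sub("(\\.[^.]+)$", "_R1\\1", fq)
      p2 <- sub("(\\.[^.]+)$", "_R2\\1", fq)
      r1 <- read_fastq(p1); r2 <- read_fastq(p2)
      merged <- mapply(function(m1, m2)
        merge_mates(m1, m2, ref, config$identity_floor)$merged,
        r1$sequence, r2$sequence)
      data.frame(read_id = sub("/1$", "", r1$read_id),
                 sequence = unname(merged), stringsAsFactors = FALSE)
    } else read_fastq(fq)
    reads <- reads[!is.na(reads$sequence), , drop = FALSE]
    calls <- call_reads(reads, ref, config$min_conversion, config$min_cpgs,
                        config$min_non_cpg_c, config$identity_floor)
    profiles[[i]] <- profile_sample(calls, donors$sample_id[i],
                                    config$min_depth)
  }
  prof_tbl <- profiles_table(profiles)

  say("stage 4/5: integration")
  sheet <- read_sample_sheet(sheet_path)
  master <- integrate_samples(sheet, cn_tbl, prof_tbl,
                              who5_thresholds(config$who5_preset))
  master_path <- file.path(outdir, "master_table.tsv")
  utils::write.table(master, master_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  say("stage 5/5: cohort statistics")
  stats_res <- cohort_statistics(master, k = config$min_k)

  manifest <- list(
    package_version = as.character(utils::packageVersion("rdnactive")),
    seed = config$seed,
    config = unclass(config),
    n_samples = nrow(master),
    input_hashes = as.list(tools::md5sum(c(sheet_path, wells_path)))
  )
  report_path <- file.path(outdir, "run_report.json")
  write_report(stats_res, report_path, manifest = manifest)
  invisible(list(donors = donors, master = master, stats = stats_res,
                 master_path = master_path, report_path = report_path))
}

#' All cohort statistics for a master table
#'
#' Group summaries and Mann-Whitney comparisons for the semen-status and
#' pregnancy groupings, the key Spearman correlations, normality checks,
#' the confounder-adjusted pregnancy regressions (absolute and active CN),
#' and the minimum active-CN analysis.
#'
#' @param master Master table from [integrate_samples()].
#' @param k Minima per stratum for the minimum-CN analysis.
#' @return Named list of results.
#' @export
cohort_statistics <- function(master, k = 5L) {
  known_preg <- master[master$pregnancy %in% c("yes", "no"), , drop = FALSE]
  corr_vars <- c(age = "age", bmi = "bmi", concentration = "conc_mio_per_ml",
                 motility = "motility_pct", morphology = "morphology_pct")
  correlations <- do.call(rbind, lapply(names(corr_vars), function(v) {
    t <- spearman_rho(master[[corr_vars[v]]], master$active_cn)
    data.frame(variable = v, rho = t$statistic, p_value = t$p_value,
               n = t$n, stringsAsFactors = FALSE)
  }))
  # stages that have sample-size preconditions degrade to NULL (the report
  # is then marked incomplete) instead of aborting a small run
  try_or_null <- function(expr) tryCatch(expr, error = function(e) {
    message("statistics stage skipped: ", conditionMessage(e))
    NULL
  })
  list(
    summary_semen = group_summary(master, "semen_class"),
    summary_pregnancy = try_or_null(group_summary(known_preg, "pregnancy")),
    comparison_semen = compare_groups(master, "semen_class",
                                      c("NSP", "ASP")),
    comparison_pregnancy = try_or_null(
      compare_groups(known_preg, "pregnancy", c("yes", "no"))),
    correlations_active_cn = correlations,
    normality_active_cn = normality_tests(master$active_cn),
    regression_absolute = try_or_null(pregnancy_regression(master, "absolute")),
    regression_active = try_or_null(pregnancy_regression(master, "active")),
    minimum_cn = try_or_null(minimum_cn_analysis(master, k = k))
  )
}

#' Write a machine-readable run report
#'
#' JSON bundle mirroring every computed statistic (group summaries,
#' comparisons, correlations, regression tables, minimum-CN analysis) plus
#' the manifest. Partial results are marked incomplete.
#'
#' @param results List from [cohort_statistics()] (possibly partial).
#' @param path Output JSON path.
#' @param manifest Provenance list (config, seed, hashes, version).
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, manifest = list()) {
  expected <- c("summary_semen", "summary_pregnancy", "comparison_semen",
                "comparison_pregnancy", "correlations_active_cn",
                "regression_absolute", "regression_active", "minimum_cn")
  incomplete <- !all(expected %in% names(results)) ||
    any(vapply(results[intersect(expected, names(results))], is.null,
               logical(1)))
  ser <- function(x) {
    if (inherits(x, "rdna_test")) x$test <- x$test  # keep list as is
    if (inherits(x, "pregnancy_model"))
      return(list(coefficients = x$coefficients, converged = x$converged,
                  separation = x$separation, n = x$n,
                  cn_variable = x$cn_variable))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, ser))
    x
  }
  payload <- list(incomplete = incomplete, manifest = manifest,
                  results = lapply(results, ser))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
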