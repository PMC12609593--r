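test_that("cohort spec validates its inputs", {
  expect_error(cohort_spec(n_nsp = 0), "group sizes")
  expect_error(cohort_spec(abs_cn_bounds = c(400, 100)), "lower < upper")
  expect_error(cohort_spec(abs_cn_mean_sd = c(500, 0),
                           abs_cn_bounds = c(100, 420)), "degenerate")
  expect_error(cohort_spec(meth_noise_sd = -1), "SDs")
  expect_error(cohort_spec(pregnancy_model = c(intercept = 0)),
               "pregnancy_model")
})

test_that("default cohort has the study's group structure", {
  donors <- simulate_cohort(cohort_spec(), seed = 5)
  expect_equal(nrow(donors), 190L)
  expect_equal(sum(donors$group == "NSP"), 94L)
  expect_equal(sum(donors$group == "ASP"), 96L)
  cls <- classify_semen(donors$volume_ml, donors$conc_mio_per_ml,
                        donors$motility_pct, donors$morphology_pct)
  # every NSP donor passes the WHO-5 classifier; every ASP donor fails it
  expect_true(all(cls$semen_class[donors$group == "NSP"] == "NSP"))
  expect_true(all(cls$semen_class[donors$group == "ASP"] == "ASP"))
  # ground-truth invariants
  expect_true(all(donors$true_active_fraction >= 0 &
                    donors$true_active_fraction <= 1))
  expect_true(all(donors$true_abs_cn >= 100 & donors$true_abs_cn <= 420))
  expect_true(all(donors$true_active_cn <= donors$true_abs_cn))
  expect_equal(sum(donors$pregnancy == "unknown"), 1L)
})

test_that("zero offset with identical distributions equalises the groups", {
  spec <- cohort_spec(asp_methylation_offset = 0, n_nsp = 300, n_asp = 300,
                      n_pregnancy_missing = 0)
  d <- simulate_cohort(spec, seed = 17)
  diff <- mean(d$true_meth_pct[d$group == "ASP"]) -
    mean(d$true_meth_pct[d$group == "NSP"])
  se <- sqrt(var(d$true_meth_pct[d$group == "ASP"]) / 300 +
               var(d$true_meth_pct[d$group == "NSP"]) / 300)
  expect_lt(abs(diff), 3 * se)
})

test_that("configured offset appears in expected group methylation", {
  d <- simulate_cohort(cohort_spec(n_nsp = 400, n_asp = 400,
                                   n_pregnancy_missing = 0), seed = 23)
  diff <- mean(d$true_meth_pct[d$group == "ASP"]) -
    mean(d$true_meth_pct[d$group == "NSP"])
  expect_equal(diff, 1.8, tolerance = 0.25)
  # age acts negatively on active copies
  expect_lt(cor(rank(d$age), rank(d$true_active_cn)), 0)
})

test_that("generation is deterministic given the seed", {
  spec <- cohort_spec(n_nsp = 8, n_asp = 8, n_pregnancy_missing = 0)
  d1 <- simulate_cohort(spec, seed = 7)
  d2 <- simulate_cohort(spec, seed = 7)
  expect_identical(d1, d2)
  p1 <- tempfile(); p2 <- tempfile()
  write_sample_sheet(d1, p1); write_sample_sheet(d2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  w1 <- simulate_droplet_table(d1, seed = 9)
  w2 <- simulate_droplet_table(d2, seed = 9)
  expect_identical(w1, w2)
  ref <- default_amplicon()
  r1 <- simulate_reads(40, ref, 0.5, seed = 3)
  r2 <- simulate_reads(40, ref, 0.5, seed = 3)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(r1$reads, f1); write_fastq(r2$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("read mixture converges to the binomial-mixture oracle", {
  ref <- default_amplicon()
  # the two-mode case with well-separated modes: hypo fraction ~ active frac
  sim <- simulate_reads(20000, ref, active_fraction = 0.5, p_active = 0.02,
                        p_inactive = 0.6, conversion_failure_rate = 0,
                        seq_error_rate = 0, minor_allele_fraction = 0,
                        seed = 31)
  calls <- call_reads(sim$reads, ref)
  prof <- profile_sample(calls, "x")
  p_expect <- expected_hypomethylated_fraction(0.5, 0.02, 0.6)
  expect_equal(p_expect, 0.5 * pbinom(2, 25, 0.02) + 0.5 * pbinom(2, 25, 0.6))
  se <- sqrt(p_expect * (1 - p_expect) / 20000)
  expect_lt(abs(prof$hypomethylated_fraction - p_expect), 4 * se)
  # overlapping modes: the oracle still predicts the bin-1 mass
  sim2 <- simulate_reads(20000, ref, active_fraction = 0.45, p_active = 0.02,
                         p_inactive = 0.22, conversion_failure_rate = 0,
                         seq_error_rate = 0, minor_allele_fraction = 0,
                         seed = 32)
  prof2 <- profile_sample(call_reads(sim2$reads, ref), "y")
  p2 <- expected_hypomethylated_fraction(0.45, 0.02, 0.22)
  expect_lt(abs(prof2$hypomethylated_fraction - p2),
            4 * sqrt(p2 * (1 - p2) / 20000))
})

test_that("minor-allele reads appear at the configured fraction", {
  ref <- default_amplicon()
  sim <- simulate_reads(10000, ref, 0.5, minor_allele_fraction = 0.03,
                        conversion_failure_rate = 0, seq_error_rate = 0,
                        seed = 41)
  frac_a <- mean(sim$truth$allele == "A")
  expect_lt(abs(frac_a - 0.03), 4 * sqrt(0.03 * 0.97 / 10000))
  # so that > 95% of reads carry the major G allele
  expect_gt(mean(sim$truth$allele == "G"), 0.95)
  calls <- call_reads(sim$reads, ref)
  expect_equal(mean(calls$allele == "A"), frac_a)
})

test_that("zero-methylation donors emit fully unmethylated clean reads", {
  ref <- default_amplicon()
  sim <- simulate_reads(200, ref, active_fraction = 1, p_active = 0,
                        conversion_failure_rate = 0, seq_error_rate = 0,
                        minor_allele_fraction = 0, seed = 2)
  calls <- call_reads(sim$reads, ref)
  expect_true(all(calls$n_methylated == 0L))
  expect_true(all(calls$conversion_rate == 1))
  expect_true(all(calls$pass))
})

test_that("rate and count preconditions are enforced", {
  ref <- default_amplicon()
  expect_error(simulate_reads(0, ref, 0.5), "n_reads")
  expect_error(simulate_reads(10, ref, 1.5), "rates")
  expect_error(simulate_droplets(-1, 100))
  expect_error(simulate_droplets(100, 100, ref_lambda = 0))
})
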