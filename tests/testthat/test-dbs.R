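test_that("fully converted and unconverted reference reads call cleanly", {
  ref <- default_amplicon()
  conv <- make_read(ref)               # all Cs converted, no methylation
  unconv <- ref$sequence               # nothing converted
  cc <- call_reads(c(conv, unconv), ref)
  expect_equal(cc$offset, c(1L, 1L))
  expect_equal(cc$conversion_rate, c(1, 0))
  expect_equal(cc$n_methylated, c(0L, 25L))
  expect_equal(cc$n_analyzable, c(25L, 25L))
  expect_equal(cc$methylation_pct, c(0, 100))
  expect_equal(cc$reason, c("retained", "low_conversion"))
})

test_that("alignment agrees with a brute-force oracle on a toy reference", {
  ref <- toy_ref()
  set.seed(9)
  # mapped: converted fragments of the reference at random offsets
  full <- make_read(ref, methylated = c(1, 3))
  for (i in 1:10) {
    o <- sample(1:8, 1); len <- sample(50:(60 - o + 1), 1)
    frag <- substr(full, o, o + len - 1)
    got <- align_to_amplicon(frag, ref)
    oracle <- bf_align(frag, ref)
    expect_true(got$mapped)
    expect_equal(got$offset, oracle$offset)
    expect_equal(got$identity, oracle$identity)
  }
  # random non-amplicon sequence is rejected as unmapped
  for (i in 1:5) {
    junk <- paste(sample(c("A", "C", "G", "T"), 55, replace = TRUE),
                  collapse = "")
    oracle <- bf_align(junk, ref)
    got <- align_to_amplicon(junk, ref)
    if (oracle$identity < 0.8) expect_false(got$mapped)
    cc <- call_reads(junk, ref)
    if (oracle$identity < 0.8) expect_equal(cc$reason, "unmapped")
  }
  # too short / too long
  expect_false(align_to_amplicon("ACGTACGT", ref)$mapped)
  expect_false(align_to_amplicon(strrep("A", 100), ref)$mapped)
})

test_that("conversion rate uses C/T evidence with a strict > 0.95 filter", {
  ref <- default_amplicon()
  nc <- ref$non_cpg_c_positions      # 48 non-CpG cytosines
  # blank out all but 40 informative positions
  blank <- nc[41:48]
  ow <- as.list(rep("A", length(blank))); names(ow) <- blank
  informative <- nc[1:40]
  # 38 of 40 converted -> exactly 0.95 -> fails the strict filter
  r38 <- make_read(ref, unconverted = informative[1:2], overwrite = ow)
  # 39 of 40 -> 0.975 -> passes
  r39 <- make_read(ref, unconverted = informative[1], overwrite = ow)
  r40 <- make_read(ref, overwrite = ow)
  cc <- call_reads(c(r38, r39, r40), ref)
  expect_equal(cc$conversion_rate, c(38 / 40, 39 / 40, 1))
  expect_equal(cc$reason, c("low_conversion", "retained", "retained"))
  # fewer informative positions than the minimum -> qc_insufficient
  ow_all <- as.list(rep("A", 44)); names(ow_all) <- nc[1:44]
  r_few <- make_read(ref, overwrite = ow_all)
  expect_equal(call_reads(r_few, ref)$reason, "qc_insufficient")
  cr <- conversion_rate(r39, ref)
  expect_equal(cr$rate, 0.975)
  expect_true(cr$ok)
})

test_that("allele calls gate reads on the major variant", {
  ref <- default_amplicon()
  rG <- make_read(ref); rA <- make_read(ref, allele = "A")
  rN <- make_read(ref, allele = "N")
  expect_equal(call_allele(rG, ref), "G")
  expect_equal(call_allele(rA, ref), "A")
  expect_equal(call_allele(rN, ref), "ambiguous")
  cc <- call_reads(c(rG, rA, rN), ref)
  expect_equal(cc$pass, c(TRUE, FALSE, FALSE))
  expect_equal(cc$reason[2:3], c("allele", "allele"))
  # variant not covered: fragment ending before the variant site
  frag <- substr(rG, 1, ref$variant_pos - 10)
  cf <- call_reads(frag, ref, min_cpgs = 5L)
  expect_equal(cf$allele, "uncovered")
  expect_equal(cf$reason, "allele")
})

test_that("methylation percent and bins follow the <=10% active rule", {
  s <- function(k) c(rep("methylated", k), rep("unmethylated", 25 - k))
  m2 <- read_methylation(s(2))
  expect_equal(m2$methylation_pct, 8)
  expect_equal(m2$bin, 1L)
  expect_true(m2$active)
  m3 <- read_methylation(s(3))
  expect_equal(m3$methylation_pct, 12)
  expect_equal(m3$bin, 2L)
  expect_false(m3$active)
  m25 <- read_methylation(s(25))
  expect_equal(m25$bin, 10L)
  # partial reads below the analyzable minimum are rejected
  part <- c(s(2)[1:15], rep("ambiguous", 10))
  expect_false(read_methylation(part)$ok)
  expect_equal(read_methylation(part)$reason, "cpg_missing")
  expect_equal(methylation_bin(c(10, 10.5, 100)), c(1L, 2L, 10L))
})

test_that("profile aggregates reads with exact hand-computed values", {
  ref <- default_amplicon()
  reads <- c(replicate(4, make_read(ref)),
             replicate(4, make_read(ref, methylated = 1:2)),
             replicate(2, make_read(ref, methylated = 1:15)))
  calls <- call_reads(reads, ref)
  prof <- profile_sample(calls, "toy")
  expect_equal(prof$n_reads_retained, 10L)
  expect_equal(prof$hypomethylated_fraction, 0.8)
  # pooled mean: (0*4 + 8*4 + 60*2) / 10 reads of 25 CpGs = 15.2%
  expect_equal(prof$mean_methylation_pct, 15.2)
  expect_equal(prof$bin_fractions[c(1, 6)], c(0.8, 0.2))
  expect_equal(sum(prof$bin_fractions), 1)
  # per-read mean coincides for complete reads
  expect_equal(profile_sample(calls, "toy",
                              mean_method = "per_read")$mean_methylation_pct,
               15.2)
})

test_that("every read is accounted for exactly once across filters", {
  ref <- default_amplicon()
  sim <- simulate_reads(400, ref, active_fraction = 0.5,
                        conversion_failure_rate = 0.05,
                        seq_error_rate = 0.01, minor_allele_fraction = 0.1,
                        seed = 21)
  calls <- call_reads(sim$reads, ref)
  prof <- profile_sample(calls, "x")
  expect_equal(prof$n_reads_retained + sum(prof$rejection_reasons),
               prof$n_reads_total)
  expect_equal(prof$n_reads_total, 400L)
  expect_equal(sum(prof$bin_fractions), 1, tolerance = 1e-9)
})

test_that("raising the conversion threshold never increases retention", {
  ref <- default_amplicon()
  sim <- simulate_reads(300, ref, active_fraction = 0.5,
                        conversion_failure_rate = 0.04, seed = 33)
  kept <- vapply(c(0.90, 0.95, 0.97, 0.99), function(thr) {
    calls <- call_reads(sim$reads, ref, min_conversion = thr)
    sum(calls$pass)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("paired mates merge into the full amplicon read", {
  ref <- default_amplicon()
  sim <- simulate_reads(30, ref, active_fraction = 0.5,
                        conversion_failure_rate = 0, seq_error_rate = 0,
                        minor_allele_fraction = 0, paired = TRUE, seed = 8)
  sim_single <- simulate_reads(30, ref, active_fraction = 0.5,
                               conversion_failure_rate = 0,
                               seq_error_rate = 0,
                               minor_allele_fraction = 0, seed = 8)
  merged <- mapply(function(m1, m2) merge_mates(m1, m2, ref)$merged,
                   sim$reads$mate1, sim$reads$mate2)
  expect_equal(unname(merged), sim_single$reads$sequence)
  # conflicting overlap becomes ambiguous N
  m1 <- sim$reads$mate1[1]
  m2bad <- sim$reads$mate2[1]
  # flip a base near the end of mate2: after reverse-complementing it lands
  # at the start of mate2's placement, inside the overlap with mate1
  pos <- nchar(m2bad) - 5L
  base <- substr(m2bad, pos, pos)
  substr(m2bad, pos, pos) <- setdiff(c("A", "C", "G", "T"), base)[1]
  mg <- merge_mates(m1, m2bad, ref)
  expect_true(grepl("N", mg$merged))
})

test_that("zero-error reads reproduce the generator sidecar exactly", {
  ref <- default_amplicon()
  sim <- simulate_reads(500, ref, active_fraction = 0.4, p_active = 0.02,
                        p_inactive = 0.6, conversion_failure_rate = 0,
                        seq_error_rate = 0, minor_allele_fraction = 0.1,
                        seed = 14)
  calls <- call_reads(sim$reads, ref)
  expect_equal(calls$n_methylated, sim$truth$true_n_methylated)
  expect_equal(calls$allele, sim$truth$allele)
  expect_true(all(calls$conversion_rate == 1))
  expect_equal(calls$reason[sim$truth$allele == "A"] == "allele",
               rep(TRUE, sum(sim$truth$allele == "A")))
})

test_that("FASTQ round-trip preserves reads", {
  ref <- default_amplicon()
  sim <- simulate_reads(50, ref, 0.5, seed = 2)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$read_id, sim$reads$read_id)
  expect_equal(back$sequence, sim$reads$sequence)
})
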