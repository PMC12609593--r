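# Shared fixtures, built in code at test time.

# 60-nt toy reference (prefix of the packaged amplicon): 4 CpGs, A variant.
toy_ref <- function() {
  amplicon_reference(substr(rdnactive:::.default_amplicon_seq, 1, 60),
                     c(41L, 46L, 51L, 56L), variant_pos = 10L,
                     major_allele = "A", min_non_cpg_c = 5L)
}

# Build a bisulfite read straight from a reference: methylated CpGs keep C,
# everything else converts; selected non-CpG Cs can be left unconverted and
# arbitrary positions overwritten.
make_read <- function(ref, methylated = integer(0), unconverted = integer(0),
                      allele = ref$major_allele, overwrite = list()) {
  chars <- ref$chars
  chars[setdiff(ref$non_cpg_c_positions, unconverted)] <- "T"
  unmeth <- setdiff(seq_len(ref$n_cpg), methylated)
  chars[ref$cpg_positions[unmeth]] <- "T"
  chars[ref$variant_pos] <- allele
  for (pos in names(overwrite)) chars[as.integer(pos)] <- overwrite[[pos]]
  paste(chars, collapse = "")
}

# Brute-force two-sided Mann-Whitney p by full enumeration (oracle).
bf_mw_p <- function(a, b) {
  r <- rank(c(a, b))
  n1 <- length(a); N <- length(r)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(N, n1)
  w <- colSums(matrix(r[combos], nrow = n1))
  mu <- n1 * (N + 1) / 2
  mean(abs(w - mu) >= abs(w_obs - mu) - 1e-9)
}

# Brute-force bisulfite-space alignment oracle (pure R).
bf_align <- function(read, ref) {
  rb <- strsplit(chartr("C", "T", read), "")[[1]]
  fb <- strsplit(chartr("C", "T", ref$sequence), "")[[1]]
  K <- length(fb) - length(rb) + 1
  if (K < 1) return(list(offset = NA, identity = NA))
  mm <- vapply(seq_len(K), function(o)
    sum(rb != fb[o:(o + length(rb) - 1)]), integer(1))
  best <- which.min(mm)
  list(offset = best, identity = 1 - mm[best] / length(rb))
}

# A small deterministic master-table fixture for integration tests.
tiny_cohort <- function(n_nsp = 10, n_asp = 10, seed = 11) {
  spec <- cohort_spec(n_nsp = n_nsp, n_asp = n_asp,
                      asp_subtype_weights = c(asthenozoospermia = 5, OAT = 3,
                                              oligozoospermia = 1,
                                              teratozoospermia = 1,
                                              cryptozoospermia = 0),
                      n_pregnancy_missing = 1)
  simulate_cohort(spec, seed = seed)
}
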