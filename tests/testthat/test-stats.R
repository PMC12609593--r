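test_that("descriptive summary follows the mean/SD/median/range conventions", {
  s <- descriptive_summary(c(43, 47, 50, 55, 56))
  expect_equal(s$mean, 50.2)
  expect_equal(s$median, 50)
  expect_equal(c(s$min, s$max), c(43, 56))
  expect_equal(s$sd, sd(c(43, 47, 50, 55, 56)))
  # even-n midpoint convention
  expect_equal(descriptive_summary(c(1, 2, 3, 4))$median, 2.5)
  # single value: SD reported as 0 with the degenerate flag
  s1 <- descriptive_summary(7)
  expect_true(s1$degenerate)
  expect_equal(c(s1$mean, s1$median, s1$min, s1$max, s1$sd), c(7, 7, 7, 7, 0))
  expect_error(descriptive_summary(numeric(0)), "empty")
})

test_that("Mann-Whitney matches closed-form and enumeration on the minima lists", {
  a <- c(43, 47, 50, 55, 56); b <- c(61, 65, 67, 69, 69)
  asym <- mann_whitney_u(a, b, method = "asymptotic")
  expect_equal(asym$statistic, 0)
  # tie-corrected variance, no continuity correction:
  # z = -12.5 / sqrt(25/12 * (11 - 6/90))
  z_oracle <- -12.5 / sqrt(25 / 12 * (11 - 6 / 90))
  expect_equal(asym$z, z_oracle, tolerance = 1e-12)
  expect_equal(asym$p_value, 2 * pnorm(z_oracle), tolerance = 1e-12)
  ex <- mann_whitney_u(a, b, method = "exact")
  expect_equal(ex$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(ex$p_value, bf_mw_p(a, b), tolerance = 1e-12)
})

test_that("Mann-Whitney handles symmetry, ties and degeneracy", {
  t1 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t1$p_value, 1)
  # constant data across both groups
  t2 <- mann_whitney_u(c(5, 5), c(5, 5, 5))
  expect_true(t2$degenerate)
  expect_equal(t2$p_value, 1)
  # U(a,b) + U(b,a) = n_a * n_b
  set.seed(6)
  for (i in 1:20) {
    a <- sample(1:10, sample(2:8, 1), replace = TRUE)
    b <- sample(1:10, sample(2:8, 1), replace = TRUE)
    ua <- mann_whitney_u(a, b)$statistic
    ub <- mann_whitney_u(b, a)$statistic
    expect_equal(ua + ub, length(a) * length(b))
  }
})

test_that("exact enumeration agrees with brute force on small tied data", {
  set.seed(7)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(1:6, n1, replace = TRUE)
    b <- sample(1:6, n2, replace = TRUE)
    expect_equal(mann_whitney_u(a, b, method = "exact")$p_value,
                 bf_mw_p(a, b), tolerance = 1e-12,
                 info = paste(c(a, "|", b), collapse = " "))
  }
  # tie-free exact agrees with wilcox.test's exact p
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(6)
    expect_equal(mann_whitney_u(a, b, method = "exact")$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-10)
  }
})

test_that("asymptotic Mann-Whitney matches the normal approximation oracle", {
  set.seed(8)
  # tie-free: equals wilcox.test with correct = FALSE
  a <- rnorm(40); b <- rnorm(35, 0.3)
  ours <- mann_whitney_u(a, b, method = "asymptotic")
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  # with ties: tie-corrected variance, still matching wilcox.test
  at <- sample(1:8, 50, replace = TRUE); bt <- sample(1:8, 45, replace = TRUE)
  expect_equal(mann_whitney_u(at, bt, method = "asymptotic")$p_value,
               wilcox.test(at, bt, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("Spearman correlation matches the rank-formula oracle", {
  expect_equal(spearman_rho(1:10, 1:10)$statistic, 1)
  expect_equal(spearman_rho(1:10, 10:1)$statistic, -1)
  # oracle: rho = 1 - 6*sum(d^2)/(n^3 - n), d = (-1, 1, -1, 1, 0)
  t <- spearman_rho(1:5, c(2, 1, 4, 3, 5))
  expect_equal(t$statistic, 1 - 6 * 4 / (125 - 5))
  expect_equal(t$statistic, 0.8)
  ref <- suppressWarnings(cor.test(1:5, c(2, 1, 4, 3, 5),
                                   method = "spearman"))
  expect_equal(t$statistic, unname(ref$estimate))
  # invariance under strictly monotone transforms
  set.seed(9)
  x <- rnorm(40); y <- x + rnorm(40)
  r0 <- spearman_rho(x, y)$statistic
  expect_equal(spearman_rho(exp(x), y)$statistic, r0)
  expect_equal(spearman_rho(x, y^3 + 5 * y)$statistic, r0)
  # degenerate input
  expect_true(spearman_rho(rep(1, 5), 1:5)$degenerate)
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("normality tests reject uniforms and hold their size on normals", {
  set.seed(10)
  u <- runif(500)
  nt <- normality_tests(u)
  expect_lt(nt$shapiro$p_value, 0.05)
  expect_lt(nt$ks$p_value, 0.05)
  expect_error(normality_tests(c(1, 2)), "n >= 3")
  expect_true(normality_tests(rep(3, 10))$shapiro$degenerate)
  # type-I error of Shapiro-Wilk near alpha on normal data
  rej <- mean(replicate(400, normality_tests(rnorm(50))$shapiro$p_value < 0.05))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("logistic pregnancy model recovers generator coefficients", {
  spec <- cohort_spec(n_nsp = 1500, n_asp = 1500, n_pregnancy_missing = 0)
  donors <- simulate_cohort(spec, seed = 19)
  rec <- truth_records(donors)
  fit <- pregnancy_regression(rec, "active")
  expect_true(fit$converged)
  expect_false(fit$separation)
  co <- fit$coefficients
  est <- function(term) co$estimate[co$term == term]
  # true standardized log-odds slopes from the spec
  expect_equal(est("active_cn"), 1.0, tolerance = 0.2)
  expect_equal(est("morphology_pct"), 0.40, tolerance = 0.15)
  # BMI has no effect at generation: estimate near zero
  expect_lt(abs(est("bmi")), 0.1)
  expect_lt(co$p_value[co$term == "active_cn"], 1e-6)
})

test_that("regression preconditions are enforced", {
  donors <- tiny_cohort(30, 30, seed = 3)
  rec <- truth_records(donors)
  rec$pregnancy <- "yes"
  expect_error(pregnancy_regression(rec, "active"), "single class")
  expect_error(pregnancy_regression(rec[1:5, ], "active"), "at least")
})

test_that("minimum-CN analysis reports the pregnancy floor and its test", {
  rec <- data.frame(
    active_cn = c(43, 47, 50, 55, 56, 61, 65, 67, 69, 69, rep(150, 20)),
    pregnancy = c(rep("no", 5), rep("yes", 15), rep("no", 10)))
  res <- minimum_cn_analysis(rec, k = 5)
  expect_equal(res$overall_minima, c(43, 47, 50, 55, 56))
  expect_equal(res$pregnancy_minima, c(61, 65, 67, 69, 69))
  expect_equal(res$floor, 61)
  expect_equal(round(res$comparison$p_value, 3), 0.009)
  # identical strata
  rec2 <- data.frame(active_cn = rep(c(10, 20, 30, 40, 50), 2),
                     pregnancy = rep("yes", 10))
  expect_equal(minimum_cn_analysis(rec2, k = 5)$comparison$p_value, 1)
  # degenerate k = 1: floor only, no test
  r1 <- minimum_cn_analysis(rec, k = 1)
  expect_equal(r1$floor, 61)
  expect_null(r1$comparison)
  expect_error(minimum_cn_analysis(rec[1:3, ], k = 5), "at least")
})

test_that("group summaries cover all variables for each group", {
  rec <- truth_records(tiny_cohort(12, 12, seed = 6))
  gs <- group_summary(rec, "semen_class")
  expect_equal(nrow(gs), 18L)  # 9 variables x 2 groups
  expect_true(all(gs$min <= gs$median & gs$median <= gs$max))
  expect_true(all(gs$sd >= 0))
  cmp <- compare_groups(rec, "semen_class", c("NSP", "ASP"))
  expect_equal(nrow(cmp), 3L)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
})
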