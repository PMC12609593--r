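# Cohort statistics: descriptive summaries, rank tests, correlations,
# normality checks, the pregnancy regression and the minimum-CN analysis.

#' Descriptive summary of one variable
#'
#' Mean, sample SD (n - 1 denominator), median (midpoint convention for
#' even n), minimum and maximum — the row structure of a
#' "Mean +/- SD | Median | Range" cohort table.
#'
#' @param values Numeric vector (NAs dropped).
#' @return One-row data frame: `n`, `mean`, `sd`, `median`, `min`, `max`,
#'   `degenerate` (TRUE when n = 1, where the SD is reported as 0).
#' @export
descriptive_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty input")
  degenerate <- length(values) == 1L
  data.frame(n = length(values), mean = mean(values),
             sd = if (degenerate) 0 else stats::sd(values),
             median = stats::median(values),
             min = min(values), max = max(values),
             degenerate = degenerate)
}

# Exact null distribution of the first group's rank sum, with midrank ties,
# by dynamic programming over doubled ranks (integers even under midranks).
# Returns P(|W - mu| >= |w_obs - mu|); the distribution is symmetric.
.mw_exact_p <- function(r2, n1, w_obs) {
  N <- length(r2)
  maxs <- sum(r2)
  # dp[k + 1, s + 1] = number of k-subsets with doubled-rank sum s
  dp <- matrix(0, n1 + 1L, maxs + 1L)
  dp[1L, 1L] <- 1
  for (v in r2) {
    kmax <- min(n1, N)  # iterate k downward to avoid reuse
    for (k in seq(from = kmax, to = 1L)) {
      src <- dp[k, seq_len(maxs + 1L - v)]
      idx <- (v + 1L):(maxs + 1L)
      dp[k + 1L, idx] <- dp[k + 1L, idx] + src
    }
  }
  counts <- dp[n1 + 1L, ]
  total <- sum(counts)
  s_vals <- 0:maxs
  mu <- n1 * (N + 1)  # doubled-rank scale
  extreme <- abs(s_vals - mu) >= abs(w_obs - mu) - 1e-9
  sum(counts[extreme]) / total
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The asymptotic method uses the
#' normal approximation with tie-corrected variance and no continuity
#' correction (the convention of common clinical statistics software); the
#' exact method computes the full permutation null distribution by dynamic
#' programming (correct under ties) and is used automatically when the
#' combined sample size is at most `exact_cap`. The reported statistic is
#' `U` for the first group; `u_min = min(U, n1*n2 - U)` is also returned.
#'
#' @param group_a,group_b Numeric vectors (NAs dropped).
#' @param method `"auto"`, `"exact"` or `"asymptotic"`.
#' @param exact_cap Largest combined n for which `"auto"` picks the exact
#'   method (default 25).
#' @return Object of class `rdna_test`: `statistic` (U), `u_min`, `z`,
#'   `p_value`, `method`, `n`, `tie_corrected`, `degenerate`.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           method = c("auto", "exact", "asymptotic"),
                           exact_cap = 25L) {
  method <- match.arg(method)
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  N <- n1 + n2
  r <- rank(c(a, b))
  w1 <- sum(r[seq_len(n1)])
  u1 <- w1 - n1 * (n1 + 1) / 2
  ties <- table(r)
  tie_corrected <- any(ties > 1)
  degenerate <- length(ties) == 1L
  if (method == "auto") method <- if (N <= exact_cap) "exact" else "asymptotic"
  if (degenerate) {
    p <- 1; z <- 0
  } else if (method == "exact") {
    r2 <- as.integer(round(2 * r))
    p <- .mw_exact_p(r2, n1, as.integer(round(2 * w1)))
    z <- NA_real_
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- (u1 - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(test = "Mann-Whitney U", statistic = u1,
                 u_min = min(u1, n1 * n2 - u1), z = z,
                 p_value = min(p, 1), method = method, n = c(n1, n2),
                 tie_corrected = tie_corrected, degenerate = degenerate),
            class = "rdna_test")
}

#' @export
print.rdna_test <- function(x, ...) {
  stat <- if (!is.null(x$statistic) && !is.na(x$statistic))
    sprintf("%s = %.4g", x$stat_name %||% "U", x$statistic) else ""
  cat(sprintf("%s (%s): %s, p = %.4g (n = %s)%s\n", x$test, x$method, stat,
              x$p_value, paste(x$n, collapse = "/"),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks; the two-sided p-value uses
#' the t-distribution approximation with n - 2 degrees of freedom.
#' Pairwise-complete observations only.
#'
#' @param x,y Paired numeric vectors.
#' @return Object of class `rdna_test` with `statistic` = rho.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(test = "Spearman correlation", stat_name = "rho",
                          statistic = NA_real_, p_value = NA_real_,
                          method = "t-approximation", n = n,
                          degenerate = TRUE), class = "rdna_test"))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  structure(list(test = "Spearman correlation", stat_name = "rho",
                 statistic = rho, p_value = p, method = "t-approximation",
                 n = n, degenerate = FALSE), class = "rdna_test")
}

#' Normality checks (Lilliefors-corrected Kolmogorov-Smirnov, Shapiro-Wilk)
#'
#' Reported for distribution QC only; group comparisons in this package are
#' always rank-based regardless of the outcome. The KS test uses the
#' Lilliefors correction since the normal parameters are estimated from the
#' data; a plain KS against a fully specified normal is available.
#'
#' @param values Numeric vector.
#' @param lilliefors Use the Lilliefors correction (default TRUE).
#' @return List with `ks` and `shapiro`, each an `rdna_test`; constant
#'   input yields degenerate results.
#' @export
normality_tests <- function(values, lilliefors = TRUE) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n >= 3L && stats::sd(values) == 0) {
    deg <- structure(list(test = "normality", statistic = NA_real_,
                          p_value = NA_real_, method = "degenerate", n = n,
                          degenerate = TRUE), class = "rdna_test")
    return(list(ks = deg, shapiro = deg))
  }
  ks <- if (n >= 5L && lilliefors) {
    t <- nortest::lillie.test(values)
    structure(list(test = "Kolmogorov-Smirnov (Lilliefors)",
                   stat_name = "D", statistic = unname(t$statistic),
                   p_value = t$p.value, method = "lilliefors", n = n,
                   degenerate = FALSE), class = "rdna_test")
  } else {
    t <- stats::ks.test(values, "pnorm", mean(values), stats::sd(values))
    structure(list(test = "Kolmogorov-Smirnov", stat_name = "D",
                   statistic = unname(t$statistic), p_value = t$p.value,
                   method = "plain (estimated parameters)", n = n,
                   degenerate = FALSE), class = "rdna_test")
  }
  if (n < 3L) stop("Shapiro-Wilk requires n >= 3")
  sw <- stats::shapiro.test(values)
  shapiro <- structure(list(test = "Shapiro-Wilk", stat_name = "W",
                            statistic = unname(sw$statistic),
                            p_value = sw$p.value, method = "exact", n = n,
                            degenerate = FALSE), class = "rdna_test")
  list(ks = ks, shapiro = shapiro)
}

#' Confounder-adjusted logistic regression on pregnancy outcome
#'
#' Binary logistic model
#' `pregnancy ~ CN + concentration + motility + morphology + age + BMI`,
#' fitted by maximum likelihood (IRLS), with Wald two-sided p-values.
#' Continuous covariates can be z-standardised. Perfect separation and
#' non-convergence are flagged; with separation no p-values are reported.
#'
#' @param records Master table with columns `pregnancy` (yes/no/unknown),
#'   `conc_mio_per_ml`, `motility_pct`, `morphology_pct`, `age`, `bmi`, and
#'   the chosen CN column.
#' @param cn_variable `"active"` (uses `active_cn`) or `"absolute"`
#'   (`absolute_cn`).
#' @param standardize z-standardise continuous covariates (default TRUE).
#' @param min_n Minimum complete records (default 20).
#' @return Object of class `pregnancy_model`: coefficient table
#'   (`estimate`, `se`, `z`, `p_value`), `converged`, `separation`, `n`,
#'   `cn_variable`, and the fitted `glm`.
#' @export
pregnancy_regression <- function(records,
                                 cn_variable = c("active", "absolute"),
                                 standardize = TRUE, min_n = 20L) {
  cn_variable <- match.arg(cn_variable)
  cn_col <- if (cn_variable == "active") "active_cn" else "absolute_cn"
  covars <- c(cn_col, "conc_mio_per_ml", "motility_pct", "morphology_pct",
              "age", "bmi")
  d <- records[records$pregnancy %in% c("yes", "no"),
               c("pregnancy", covars), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < min_n) stop("need at least ", min_n, " complete records")
  y <- as.integer(d$pregnancy == "yes")
  if (length(unique(y)) < 2L) stop("pregnancy outcome has a single class")
  X <- d[, covars, drop = FALSE]
  if (standardize) X[] <- lapply(X, function(v) (v - mean(v)) / stats::sd(v))
  fit <- stats::glm(y ~ ., data = cbind(y = y, X), family = stats::binomial())
  separation <- any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8) ||
    any(abs(stats::coef(fit)[-1]) > 15)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3],
                      p_value = if (separation) NA_real_ else sm[, 4],
                      row.names = NULL)
  structure(list(coefficients = coefs, converged = fit$converged,
                 separation = separation, n = nrow(d),
                 cn_variable = cn_variable, fit = fit),
            class = "pregnancy_model")
}

#' @export
print.pregnancy_model <- function(x, ...) {
  cat(sprintf("Logistic pregnancy model (%s CN, n = %d)%s%s\n",
              x$cn_variable, x$n,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$separation) " [SEPARATION]" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Minimum active copy number analysis
#'
#' Extracts the k smallest presumably active copy numbers over all samples
#' and within the pregnancy group, compares the two minima lists by
#' Mann-Whitney U, and reports the pregnancy-group minimum as the empirical
#' floor of "sufficient" active copies.
#'
#' @param records Master table with `active_cn` and `pregnancy`.
#' @param k Number of minima per stratum (default 5).
#' @param use_rounded Compare half-up-rounded integer copy numbers, the
#'   reporting convention (default TRUE).
#' @param method Mann-Whitney method for the comparison.
#' @return List: `overall_minima`, `pregnancy_minima`, `floor`
#'   (pregnancy-group minimum), `comparison` (an `rdna_test`, NULL when
#'   k = 1).
#' @export
minimum_cn_analysis <- function(records, k = 5L, use_rounded = TRUE,
                                method = "asymptotic") {
  cn <- if (use_rounded) round_half_up(records$active_cn) else records$active_cn
  preg <- cn[records$pregnancy == "yes"]
  if (length(cn) < k || length(preg) < k)
    stop("each stratum needs at least k = ", k, " samples")
  overall <- sort(cn)[seq_len(k)]
  preg_min <- sort(preg)[seq_len(k)]
  cmp <- if (k >= 2L) mann_whitney_u(overall, preg_min, method = method)
  else NULL
  list(overall_minima = overall, pregnancy_minima = preg_min,
       floor = preg_min[1], k = k, comparison = cmp)
}

#' Group summary table for the cohort variables
#'
#' One [descriptive_summary()] row per variable per group — the shape of a
#' clinical cohort characteristics table (absolute CN, active CN,
#' methylation, age, BMI, volume, concentration, morphology, motility).
#'
#' @param records Master table.
#' @param group_col Grouping column (e.g. `"semen_class"` or
#'   `"pregnancy"`).
#' @param variables Named character vector mapping display names to columns.
#' @return Data frame of summaries with `group` and `variable` columns.
#' @export
group_summary <- function(records, group_col = "semen_class",
                          variables = c(
                            "Absolute Copy Number" = "absolute_cn",
                            "Presumably Active Copy Number" = "active_cn",
                            "Methylation (%)" = "methylation_pct",
                            "Age" = "age",
                            "BMI (kg/m2)" = "bmi",
                            "Volume (mL)" = "volume_ml",
                            "Concentration (x10^6/mL)" = "conc_mio_per_ml",
                            "Morphology (% normal)" = "morphology_pct",
                            "Motility (% motile)" = "motility_pct")) {
  groups <- split(records, records[[group_col]])
  rows <- lapply(names(groups), function(g) {
    do.call(rbind, lapply(names(variables), function(v) {
      cbind(group = g, variable = v,
            descriptive_summary(groups[[g]][[variables[v]]]))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank-based group comparisons over several variables
#'
#' @param records Master table.
#' @param group_col Grouping column with exactly two levels to compare.
#' @param levels The two group labels (first vs second).
#' @param variables Columns to compare.
#' @param method Mann-Whitney method.
#' @return Data frame: variable, group ns, U, z, p_value, method.
#' @export
compare_groups <- function(records, group_col, levels,
                           variables = c("absolute_cn", "active_cn",
                                         "methylation_pct"),
                           method = "asymptotic") {
  a <- records[records[[group_col]] == levels[1], , drop = FALSE]
  b <- records[records[[group_col]] == levels[2], , drop = FALSE]
  rows <- lapply(variables, function(v) {
    t <- mann_whitney_u(a[[v]], b[[v]], method = method)
    data.frame(variable = v, n_a = t$n[1], n_b = t$n[2], U = t$statistic,
               z = if (is.null(t$z)) NA_real_ else t$z, p_value = t$p_value,
               method = t$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
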