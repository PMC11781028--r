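#' Two-tailed unpaired Student t-test
#'
#' Classical equal-variance t statistic with `n_a + n_b - 2` degrees of
#' freedom, the test used to compare replicate probabilities at paired time
#' points (the pipeline gates on Levene homoscedasticity first, which is
#' why the pooled-variance form is the default). Set `var_equal = FALSE`
#' for Welch's unequal-variance variant.
#'
#' @param a,b Numeric replicate vectors (e.g. probabilities in %), each of
#'   length >= 2.
#' @param var_equal Pooled-variance Student test (default) or Welch.
#' @return List: `t`, `df`, `p` (two-tailed). Zero pooled variance with
#'   equal means gives `t = 0, p = 1`; with different means, `t = +-Inf,
#'   p = 0`.
#' @export
unpaired_t_two_tailed <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    .fail("each group needs at least 2 replicates")
  }
  if (var(a) == 0 && var(b) == 0) {
    df <- length(a) + length(b) - 2L
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Levene's test for equality of variances
#'
#' Classical Levene W (group-mean centring by default; `center = "median"`
#' gives the Brown-Forsythe variant), with p from the F distribution. Used
#' as the homoscedasticity gate before the pooled-variance t-test. Fully
#' degenerate input (all absolute deviations equal) returns `W = 0, p = 1`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param center `"mean"` (default) or `"median"`.
#' @return List: `W`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(a) < 2L || length(b) < 2L) {
    .fail("each group needs at least 2 values")
  }
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  cfun <- if (center == "mean") mean else median
  z <- abs(y - ave(y, g, FUN = cfun))
  df1 <- 1L
  df2 <- length(y) - 2L
  # degenerate: no within-group spread of deviations, or no spread at all
  within_ss <- sum((z - ave(z, g, FUN = mean))^2)
  between_equal <- isTRUE(all.equal(mean(z[g == "a"]), mean(z[g == "b"])))
  if (within_ss == 0 && between_equal) {
    return(list(W = 0, df1 = df1, df2 = df2, p = 1))
  }
  lt <- car::leveneTest(y, g, center = cfun)
  W <- lt[["F value"]][1]
  p <- lt[["Pr(>F)"]][1]
  if (!is.finite(W)) { W <- 0; p <- 1 }
  list(W = W, df1 = df1, df2 = df2, p = p)
}

#' Significance code for a p-value
#'
#' `ns` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.005 and `****` for
#' p < 0.0001 (the most extreme applicable tier; no `***` tier is defined
#' in this scheme).
#'
#' @param p p-value(s) in \[0, 1\]. Vectorised.
#' @return Character code(s).
#' @export
significance_code <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) .fail("p must lie in [0, 1]")
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi < 1e-4) "****"
    else if (pi < 0.005) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, "")
}

#' Compare replicate probabilities at two time points
#'
#' Builds one row of the replicate comparison table (typically minute 1
#' versus minute 30): group means with SEM, the two-tailed unpaired t-test,
#' Levene's homoscedasticity check, and the significance code.
#'
#' @param a,b Replicate probabilities (%) at the two time points.
#' @param label_a,label_b Group labels, default `"1 min"` / `"30 min"`.
#' @param condition Optional condition label for the row.
#' @return One-row data.frame: `condition`, `group_a`, `n_a`, `mean_a`,
#'   `sem_a`, `group_b`, `n_b`, `mean_b`, `sem_b`, `t`, `df`, `p`,
#'   `levene_W`, `levene_p`, `code`.
#' @export
compare_timepoints <- function(a, b, label_a = "1 min", label_b = "30 min",
                               condition = NA_character_) {
  tt <- unpaired_t_two_tailed(a, b)
  lv <- levene_test(a, b)
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  data.frame(condition = condition,
             group_a = label_a, n_a = length(a),
             mean_a = mean(a), sem_a = sem(a),
             group_b = label_b, n_b = length(b),
             mean_b = mean(b), sem_b = sem(b),
             t = tt$t, df = tt$df, p = tt$p,
             levene_W = lv$W, levene_p = lv$p,
             code = significance_code(tt$p),
             stringsAsFactors = FALSE)
}
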