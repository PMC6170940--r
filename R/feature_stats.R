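#' Descriptive summary of a feature sample
#'
#' Mean, standard deviation (n-1 denominator), minimum, quartiles (linear
#' interpolation between order statistics, quantile type 7), interquartile
#' range, maximum and semi-interquartile deviation (`IQR / 2`).
#'
#' @param x Numeric sample, at least one value.
#' @return Named list with `mean`, `sd`, `min`, `q1`, `q2`, `q3`, `iqr`,
#'   `max`, `sid`.
#' @export
descriptive_summary <- function(x) {
  if (length(x) < 1L || !is.numeric(x))
    stop("descriptive_summary needs a non-empty numeric sample")
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  s <- if (length(x) > 1L) stats::sd(x) else 0
  iqr <- q[3] - q[1]
  list(mean = mean(x), sd = s, min = min(x), q1 = q[1], q2 = q[2],
       q3 = q[3], iqr = iqr, max = max(x), sid = iqr / 2)
}

# exact two-sided rank-sum p by full enumeration of rank assignments
# (tie-free samples only)
ranksum_exact_p <- function(w, n1, n2) {
  combs <- utils::combn(n1 + n2, n1)
  ws <- colSums(combs)
  p_lo <- mean(ws <= w)
  p_hi <- mean(ws >= w)
  min(1, 2 * min(p_lo, p_hi))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mid-ranks are used for ties. The z score always comes from the normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction; its sign is positive when sample `a` tends to rank higher.
#' The p value is computed by exact enumeration of all rank assignments
#' when `min(n1, n2) <= 8` and the pooled sample is tie-free (or when
#' `exact = TRUE` is forced), otherwise from the normal approximation.
#'
#' @param a,b Numeric samples, both non-empty.
#' @param exact `"auto"` (default), `TRUE` or `FALSE`.
#' @return List with `p_value`, `z_score`, `n1`, `n2`, `statistic` (rank
#'   sum of `a`) and `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(a, b, exact = "auto") {
  if (length(a) < 1L || length(b) < 1L)
    stop("rank_sum_test needs two non-empty samples")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  rk <- rank(pooled)
  w <- sum(rk[seq_len(n1)])
  ties <- table(pooled)
  has_ties <- any(ties > 1)

  mu <- n1 * (n1 + 1 + n2) / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  d <- w - mu
  z <- if (sigma2 <= 0) 0 else (d - sign(d) * 0.5) / sqrt(sigma2)
  p_normal <- min(1, 2 * stats::pnorm(-abs(z)))

  use_exact <- if (isTRUE(exact)) TRUE
  else if (identical(exact, FALSE) || identical(exact, "no")) FALSE
  else min(n1, n2) <= 8L && !has_ties
  if (use_exact && has_ties)
    stop("exact enumeration requires a tie-free pooled sample")
  if (use_exact && choose(n, n1) > 2e6)
    stop("exact enumeration infeasible at this sample size")
  p <- if (use_exact) ranksum_exact_p(w, n1, n2) else p_normal
  list(p_value = p, z_score = z, n1 = n1, n2 = n2, statistic = w,
       method = if (use_exact) "exact" else "normal")
}

#' Feature-validation report
#'
#' For every feature column, computes the per-class descriptive summaries
#' and the two-sided rank-sum test between the normal (label 0) and ictal
#' (label 1) rows — the screening step that checks the features actually
#' separate the classes before any classifier is trained.
#'
#' @param features Feature data frame from [extract_features()].
#' @param feature_cols Feature column names (default the four standard
#'   features).
#' @return List with one entry per feature: `normal` and `epileptic`
#'   summaries plus `rank_sum` (the test result).
#' @export
feature_stats_report <- function(features,
                                 feature_cols = c("psd_max", "shannon_H",
                                                  "renyi_H", "teager")) {
  stopifnot(all(feature_cols %in% names(features)),
            "label" %in% names(features))
  lab <- features$label
  if (!any(lab == 0) || !any(lab == 1))
    stop("need both normal and epileptic rows")
  out <- lapply(feature_cols, function(fc) {
    x0 <- features[[fc]][lab == 0]
    x1 <- features[[fc]][lab == 1]
    list(normal = descriptive_summary(x0),
         epileptic = descriptive_summary(x1),
         rank_sum = rank_sum_test(x0, x1, exact = FALSE))
  })
  names(out) <- feature_cols
  out
}
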