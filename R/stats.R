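# Cohort-level statistics: descriptives, pooled two-sample t-tests with
# Cohen's d, two-tailed Pearson correlations, a Kolmogorov-Smirnov normality
# diagnostic, and the cohort x subset x feature x outcome correlation table.

#' Descriptive statistics
#'
#' @param values Numeric vector; non-finite values are dropped.
#' @return A list with \code{n}, \code{mean}, \code{sd} (sample SD, n-1).
#' @export
descriptives <- function(values) {
  v <- values[is.finite(values)]
  .assert(length(v) >= 2L, "descriptives needs at least 2 finite values")
  list(n = length(v), mean = mean(v), sd = stats::sd(v))
}

t_from_summaries <- function(m1, s1, n1, m2, s2, n2,
                             d_denominator = c("total", "df")) {
  d_denominator <- match.arg(d_denominator)
  df <- n1 + n2 - 2
  ss <- (n1 - 1) * s1^2 + (n2 - 1) * s2^2
  .assert(ss > 0 || m1 == m2,
          "degenerate: zero pooled variance with unequal means")
  sp2 <- ss / df
  t <- if (ss == 0) 0 else
    (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  # Cohen's d with the total-sample pooled SD (denominator n1+n2) by default;
  # "df" switches to the n1+n2-2 convention
  sd_d2 <- ss / if (d_denominator == "total") (n1 + n2) else df
  d <- if (ss == 0) 0 else (m1 - m2) / sqrt(sd_d2)
  list(t = t, df = df, p_two_tailed = 2 * stats::pt(-abs(t), df),
       cohen_d = d, n1 = n1, n2 = n2)
}

#' Pooled-variance two-sample t-test with Cohen's d
#'
#' Student's t with pooled variance (df = n1 + n2 - 2), two-tailed p, and
#' Cohen's d computed with the total-sample pooled SD (denominator n1 + n2;
#' switchable to n1 + n2 - 2).
#'
#' @param a,b Numeric vectors (non-finite values dropped).
#' @param d_denominator \code{"total"} (n1+n2) or \code{"df"} (n1+n2-2) for
#'   the pooled SD entering Cohen's d.
#' @return A list with \code{t}, \code{df}, \code{p_two_tailed},
#'   \code{cohen_d}, \code{n1}, \code{n2}.
#' @export
pooled_t_test <- function(a, b, d_denominator = c("total", "df")) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  .assert(length(a) >= 2L && length(b) >= 2L,
          "each group needs at least 2 finite values")
  t_from_summaries(mean(a), stats::sd(a), length(a),
                   mean(b), stats::sd(b), length(b),
                   d_denominator = match.arg(d_denominator))
}

#' Pooled t-test from summary statistics
#'
#' Identical formulas to \code{\link{pooled_t_test}} applied to group
#' summaries, so published descriptive tables can drive the test without raw
#' data.
#'
#' @param d1,d2 \code{\link{descriptives}}-shaped lists (\code{n},
#'   \code{mean}, \code{sd}).
#' @param d_denominator As in \code{\link{pooled_t_test}}.
#' @return As \code{\link{pooled_t_test}}.
#' @export
summary_t_test <- function(d1, d2, d_denominator = c("total", "df")) {
  .assert(d1$n >= 2L && d2$n >= 2L && d1$sd >= 0 && d2$sd >= 0,
          "invalid summary statistics")
  t_from_summaries(d1$mean, d1$sd, d1$n, d2$mean, d2$sd, d2$n,
                   d_denominator = match.arg(d_denominator))
}

#' Two-tailed Pearson correlation
#'
#' Product-moment r with the two-tailed p-value from
#' t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom. Pairs with a missing
#' member are dropped pairwise.
#'
#' @param x,y Paired numeric vectors.
#' @return A list with \code{r}, \code{p_two_tailed}, \code{n}.
#' @export
pearson <- function(x, y) {
  .assert(length(x) == length(y), "x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  .assert(n >= 3L, "pearson needs at least 3 complete pairs")
  .assert(stats::var(x) > 0 && stats::var(y) > 0,
          "correlation undefined for a zero-variance vector")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, p_two_tailed = p, n = n)
}

#' One-sample Kolmogorov-Smirnov normality diagnostic
#'
#' KS statistic of the sample against a normal distribution with the
#' sample's own mean and SD. Reported for diagnostics only; no analysis is
#' gated on it.
#'
#' @param values Numeric vector, at least 5 finite values.
#' @return A list with \code{statistic} and \code{p}.
#' @export
ks_normality <- function(values) {
  v <- values[is.finite(values)]
  .assert(length(v) >= 5L, "ks_normality needs at least 5 finite values")
  .assert(stats::sd(v) > 0, "ks_normality undefined for a constant vector")
  res <- suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v)))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Cohort correlation table
#'
#' Two-tailed Pearson correlations between the cry features (F0, F0var) and
#' the attention outcomes (orienting latency, dwell index) for each cohort
#' and subset: all participants, the beginning-of-bout subset (Tampere), and
#' the SSRI-unexposed subset (Cape Town). Missing outcomes are dropped
#' pairwise per cell; cells with fewer than 3 complete pairs are marked
#' not computable. Alpha is 0.05 with no multiple-comparison correction.
#'
#' @param records Data.frame with columns \code{participant_id},
#'   \code{cohort} (\code{tampere} / \code{cape_town}), \code{f0_hz},
#'   \code{f0var_hz}, \code{orienting_latency_ms}, \code{dwell_index},
#'   \code{bout_start_captured}, \code{ssri_exposed}.
#' @param alpha Significance threshold recorded per cell.
#' @return A data.frame with one row per cohort x subset x feature x outcome
#'   cell: \code{cohort}, \code{subset}, \code{feature}, \code{outcome},
#'   \code{r}, \code{p}, \code{n}, \code{significant}, \code{computable}.
#' @export
run_correlation_table <- function(records, alpha = 0.05) {
  features <- c(F0 = "f0_hz", F0var = "f0var_hz")
  outcomes <- c(orienting = "orienting_latency_ms",
                disengagement = "dwell_index")
  subsets <- list(
    list(cohort = "tampere", subset = "all",
         filter = function(d) d),
    list(cohort = "tampere", subset = "bout_start",
         filter = function(d) d[d$bout_start_captured %in% TRUE, ]),
    list(cohort = "cape_town", subset = "all",
         filter = function(d) d),
    list(cohort = "cape_town", subset = "ssri_excluded",
         filter = function(d) d[!(d$ssri_exposed %in% TRUE), ])
  )
  rows <- list()
  for (sub in subsets) {
    d <- records[records$cohort == sub$cohort, , drop = FALSE]
    d <- sub$filter(d)
    for (fi in seq_along(features)) {
      for (oi in seq_along(outcomes)) {
        x <- d[[features[fi]]]; y <- d[[outcomes[oi]]]
        ok <- !is.null(x) && !is.null(y) &&
          sum(is.finite(x) & is.finite(y)) >= 3L &&
          stats::var(x[is.finite(x) & is.finite(y)]) > 0 &&
          stats::var(y[is.finite(x) & is.finite(y)]) > 0
        cell <- if (ok) pearson(x, y) else
          list(r = NA_real_, p_two_tailed = NA_real_,
               n = if (is.null(x)) 0L else
                 sum(is.finite(x) & is.finite(y)))
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = sub$cohort, subset = sub$subset,
          feature = names(features)[fi], outcome = names(outcomes)[oi],
          r = cell$r, p = cell$p_two_tailed, n = cell$n,
          significant = isTRUE(cell$p_two_tailed < alpha),
          computable = ok
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort comparison t-tests
#'
#' Pooled t-tests comparing the two cohorts on each main study variable.
#'
#' @param records As in \code{\link{run_correlation_table}}.
#' @param d_denominator As in \code{\link{pooled_t_test}}.
#' @return A data.frame with one row per variable: \code{variable}, \code{t},
#'   \code{df}, \code{p}, \code{cohen_d}, \code{n_tampere},
#'   \code{n_cape_town}.
#' @export
run_cohort_t_tests <- function(records, d_denominator = "total") {
  vars <- c(F0 = "f0_hz", F0var = "f0var_hz",
            disengagement = "dwell_index",
            orienting = "orienting_latency_ms")
  rows <- lapply(seq_along(vars), function(i) {
    a <- records[[vars[i]]][records$cohort == "tampere"]
    b <- records[[vars[i]]][records$cohort == "cape_town"]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) {
      return(data.frame(variable = names(vars)[i], t = NA_real_,
                        df = NA_real_, p = NA_real_, cohen_d = NA_real_,
                        n_tampere = length(a), n_cape_town = length(b)))
    }
    tt <- pooled_t_test(a, b, d_denominator = d_denominator)
    data.frame(variable = names(vars)[i], t = tt$t, df = tt$df,
               p = tt$p_two_tailed, cohen_d = tt$cohen_d,
               n_tampere = tt$n1, n_cape_town = tt$n2)
  })
  do.call(rbind, rows)
}

#' Descriptive table for the main study variables
#'
#' @param records As in \code{\link{run_correlation_table}}.
#' @return A data.frame with one row per cohort x variable: \code{cohort},
#'   \code{variable}, \code{n}, \code{mean}, \code{sd}.
#' @export
run_descriptives_table <- function(records) {
  vars <- c(F0 = "f0_hz", F0var = "f0var_hz",
            disengagement = "dwell_index",
            orienting = "orienting_latency_ms")
  rows <- list()
  for (ch in unique(records$cohort)) {
    for (i in seq_along(vars)) {
      v <- records[[vars[i]]][records$cohort == ch]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- if (length(v) >= 2L) {
        d <- descriptives(v)
        data.frame(cohort = ch, variable = names(vars)[i], n = d$n,
                   mean = d$mean, sd = d$sd)
      } else {
        data.frame(cohort = ch, variable = names(vars)[i],
                   n = length(v), mean = NA_real_, sd = NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
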