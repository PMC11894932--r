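#' Wilcoxon rank-sum group comparison
#'
#' Two-sided rank-sum test between two groups of connectivity values. The
#' exact null distribution is used when the smaller group has at most 10
#' observations and there are no ties; otherwise the normal approximation
#' with tie (midrank) correction and continuity correction is used.
#'
#' @param a,b Numeric vectors, one value per subject (each of length >= 2).
#' @return One-row tibble: `statistic` (rank-sum W), `p_value`, `exact`.
#' @export
rank_sum <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= 10L && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 exact = exact)
}

#' Friedman test of consistency across repeated segments
#'
#' Tests, within one group, whether subjects' connectivity values differ
#' systematically across repeated segments. A non-significant result
#' (p > 0.05) supports treating the segments as repeated measures of a
#' stable quantity. Subjects with missing segments form incomplete blocks
#' and are dropped with a warning.
#'
#' @param data Tibble with one row per (subject, segment) observation.
#' @param value,subject,segment Column names (strings).
#' @return One-row tibble: `statistic` (Friedman chi-square), `df`,
#'   `p_value`, `n_subjects`.
#' @export
friedman_repeats <- function(data, value = "value", subject = "subject",
                             segment = "segment") {
  wide <- tidyr::pivot_wider(
    data[, c(subject, segment, value)],
    names_from = dplyr::all_of(segment), values_from = dplyr::all_of(value)
  )
  m <- as.matrix(wide[, -1L, drop = FALSE])
  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    warning(sprintf("%d subject(s) with missing segments dropped",
                    sum(!complete)), call. = FALSE)
    m <- m[complete, , drop = FALSE]
  }
  ht <- stats::friedman.test(m)
  stat <- unname(ht$statistic)
  p <- ht$p.value
  if (!is.finite(stat)) {
    # fully tied blocks (every subject constant across segments): no
    # evidence of a segment effect
    stat <- 0
    p <- 1
  }
  tibble::tibble(statistic = stat, df = unname(ht$parameter), p_value = p,
                 n_subjects = nrow(m))
}

#' Kruskal-Wallis consistency test for a single subject
#'
#' Assesses whether one subject's values (e.g. per-window coupling
#' strengths) differ across repeats/segments.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor-like vector assigning each observation to a repeat.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis_per_subject <- function(values, groups) {
  ht <- stats::kruskal.test(values, factor(groups))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value)
}

#' Cohen's d effect size
#'
#' Difference of group means divided by the pooled standard deviation
#' (pooled-variance convention, denominator n1 + n2 - 2). By this
#' convention d = 0.5 is a medium and d = 0.8 a large effect.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return Scalar d (positive when `mean(a) > mean(b)`); `NA` with a warning
#'   when the pooled standard deviation is zero.
#' @export
cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values", call. = FALSE)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2))
  if (sp == 0) {
    warning("zero pooled standard deviation; effect size undefined", call. = FALSE)
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sp
}

#' Shuffled-segment repeatability test
#'
#' Guards against the recording time acting as a confounder: per shuffle,
#' one segment is drawn uniformly at random for every subject, the rank-sum
#' test compares the groups on the drawn values, and the percentage of
#' shuffles reaching significance is reported.
#'
#' @param data Tibble with columns `subject`, `group` (two levels),
#'   `segment`, `value`.
#' @param n_shuffles Number of shuffles (default 1000).
#' @param alpha Significance threshold (default 0.05).
#' @param seed Optional integer seed; fixing it makes the result
#'   bit-reproducible.
#' @return One-row tibble: `percent_significant`, `n_shuffles`, `alpha`.
#' @export
shuffled_segment_test <- function(data, n_shuffles = 1000, alpha = 0.05,
                                  seed = NULL) {
  stopifnot(all(c("subject", "group", "segment", "value") %in% names(data)))
  if (!is.null(seed)) set.seed(seed)
  split_by_subj <- split(data, data$subject)
  n_seg <- vapply(split_by_subj, nrow, 1L)
  if (any(n_seg == 0L)) {
    warning("subject(s) with no segments excluded", call. = FALSE)
    split_by_subj <- split_by_subj[n_seg > 0L]
  }
  if (any(vapply(split_by_subj, nrow, 1L) < 2L)) {
    warning("subject(s) with a single segment contribute the same value to every shuffle",
            call. = FALSE)
  }
  subj_group <- vapply(split_by_subj, function(d) as.character(d$group[1L]), "")
  glev <- unique(subj_group)
  if (length(glev) != 2L) stop("`group` must have exactly two levels", call. = FALSE)
  vals <- lapply(split_by_subj, function(d) d$value)
  sig <- logical(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    drawn <- vapply(vals, function(v) v[sample.int(length(v), 1L)], 1.0)
    p <- rank_sum(drawn[subj_group == glev[1L]],
                  drawn[subj_group == glev[2L]])$p_value
    sig[s] <- p < alpha
  }
  tibble::tibble(percent_significant = 100 * mean(sig),
                 n_shuffles = n_shuffles, alpha = alpha)
}

#' Minimum detectable effect size (sensitivity analysis)
#'
#' Smallest Cohen's d that a two-sided two-sample Wilcoxon rank-sum
#' comparison detects with the requested power, computed by noncentral-t
#' root finding with the asymptotic-relative-efficiency (A.R.E.) sample-size
#' correction: each group size is multiplied by the A.R.E. of the rank-sum
#' test relative to the t-test under the assumed parent distribution, and
#' the noncentral-t power equation is solved for d. The default parent,
#' `"min_are"`, uses the distribution-free lower bound A.R.E. = 0.864; the
#' normal parent gives 3/pi, Laplace 3/2, logistic pi^2/9.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level in (0, 1).
#' @param power Target power in (alpha, 1).
#' @param parent Parent-distribution assumption for the A.R.E. correction;
#'   `"uniform_are"` applies no correction (A.R.E. = 1, the plain t-test).
#' @return Scalar minimum detectable d.
#' @examples
#' sensitivity_mdes(13, 9, alpha = 0.05, power = 0.80)
#' @export
sensitivity_mdes <- function(n1, n2, alpha = 0.05, power = 0.80,
                             parent = c("min_are", "normal", "laplace",
                                        "logistic", "uniform_are")) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (!(power > alpha && power < 1)) {
    stop("`power` must lie in (alpha, 1)", call. = FALSE)
  }
  are <- switch(match.arg(parent),
                min_are = 0.864, normal = 3 / pi, laplace = 1.5,
                logistic = pi^2 / 9, uniform_are = 1)
  m1 <- n1 * are
  m2 <- n2 * are
  df <- m1 + m2 - 2
  mult <- sqrt(m1 * m2 / (m1 + m2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  pow <- function(d) {
    ncp <- d * mult
    1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
  }
  f <- function(d) pow(d) - power
  lo <- 1e-4; hi <- 10
  if (f(lo) > 0 || f(hi) < 0) {
    stop("power equation has no root in [1e-4, 10]", call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Multiple-comparison adjustment for pair-wise group statistics
#'
#' Optional reporting mode: adjusts the per-pair p-value columns of a
#' [run_pipeline()] statistics table for the number of probe pairs tested
#' (within each measure, when both coherence and coupling statistics are
#' present). With four frontal pairs, Bonferroni turns the 0.05 threshold
#' into 0.0125; equivalently the p-values reported here are multiplied by
#' the pair count and capped at 1. Not applied by default anywhere.
#'
#' @param stats Statistics tibble from `run_pipeline()$stats`.
#' @param method Adjustment method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return The table with `min_p` and `median_p` replaced by adjusted
#'   values and the raw columns kept as `min_p_raw`, `median_p_raw`.
#' @export
adjust_group_stats <- function(stats, method = "bonferroni") {
  grp <- if ("measure" %in% names(stats)) stats$measure else rep(1L, nrow(stats))
  stats$min_p_raw <- stats$min_p
  stats$median_p_raw <- stats$median_p
  for (g in unique(grp)) {
    i <- grp == g
    stats$min_p[i] <- stats::p.adjust(stats$min_p_raw[i], method = method)
    stats$median_p[i] <- stats::p.adjust(stats$median_p_raw[i], method = method)
  }
  stats
}

#' Association of connectivity with age
#'
#' Ordinary least-squares regression of connectivity values on age, with the
#' Pearson correlation and its two-sided p-value.
#'
#' @param values Numeric connectivity values, one per subject.
#' @param ages Numeric ages, same length.
#' @return One-row tibble: `slope`, `r`, `p_value`, `n`.
#' @export
age_regression <- function(values, ages) {
  stopifnot(length(values) == length(ages), length(values) >= 3L)
  fit <- stats::lm(values ~ ages)
  if (stats::sd(values) == 0) {
    return(tibble::tibble(slope = 0, r = 0, p_value = 1, n = length(values)))
  }
  ct <- stats::cor.test(ages, values)
  tibble::tibble(slope = unname(stats::coef(fit)[2L]),
                 r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(values))
}
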