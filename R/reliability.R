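#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Royston-algorithm implementation, with
#' the input checks used throughout the reliability pipeline.
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return List with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L || length(x) > 5000L)
    .vm_stop("vm_invalid_sample", "Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0)
    .vm_stop("vm_zero_variance", "Shapiro-Wilk undefined for a constant sample")
  ht <- stats::shapiro.test(x)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Paired t test
#'
#' Two-sided paired t test on differences `d = x - y`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 2).
#' @return List with `statistic` (t), `p_value`, `df`.
#' @export
paired_t <- function(x, y) {
  d <- .vm_paired_diff(x, y)
  n <- length(d)
  if (stats::sd(d) == 0)
    .vm_stop("vm_degenerate_differences",
             "identical measurements: paired differences have zero variance")
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1)
}

.vm_paired_diff <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2L)
    .vm_stop("vm_invalid_sample", "paired samples must have equal length >= 2")
  x - y
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped; tied absolute differences receive
#' mid-ranks. For `m <= exact_max` remaining pairs the two-sided p-value is
#' exact, computed from the full distribution of the positive-rank sum `W+`
#' over all `2^m` sign assignments (`p = min(1, 2 * min(P(W+ <= w),
#' P(W+ >= w)))`). For larger m a normal approximation with continuity
#' correction and the usual tie correction is used.
#'
#' @param x,y Equal-length numeric vectors.
#' @param exact_max Largest m for which the exact enumeration is used.
#' @return List with `statistic` (W+, the positive-rank sum), `p_value`,
#'   `m` (pairs after zero-drop), and `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12L) {
  d <- .vm_paired_diff(x, y)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L)
    .vm_stop("vm_degenerate_differences", "all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (m <= exact_max) {
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)  # all 2^m subset rank sums
    tol <- 1e-9
    p <- min(1, 2 * min(mean(sums <= W + tol), mean(sums >= W - tol)))
    list(statistic = W, p_value = p, m = m, exact = TRUE)
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
    list(statistic = W, p_value = 2 * stats::pnorm(-abs(z)), m = m, exact = FALSE)
  }
}

#' Normality-routed paired comparison
#'
#' Applies the Shapiro-Wilk test to the paired differences; if its p-value
#' is at least `normality_alpha` the paired t test is used, otherwise the
#' Wilcoxon matched-pairs signed-rank test.
#'
#' @param x,y Equal-length numeric vectors.
#' @param alpha Significance level for the comparison itself.
#' @param normality_alpha Threshold for the Shapiro-Wilk routing.
#' @param exact_max Passed to [wilcoxon_signed_rank()].
#' @return A `vm_comparison`: list with `test_used` (`"paired_t"`,
#'   `"wilcoxon"`, or `"degenerate"`), `statistic`, `p_value`,
#'   `significant`, `shapiro_p`, `degenerate`.
#' @export
compare_paired <- function(x, y, alpha = 0.05, normality_alpha = 0.05,
                           exact_max = 12L) {
  d <- .vm_paired_diff(x, y)
  if (stats::sd(d) == 0) {
    return(structure(list(test_used = "degenerate", statistic = NA_real_,
                          p_value = NA_real_, significant = NA,
                          shapiro_p = NA_real_, degenerate = TRUE),
                     class = "vm_comparison"))
  }
  sw <- shapiro_wilk(d)
  res <- if (sw$p_value >= normality_alpha) {
    c(paired_t(x, y)[c("statistic", "p_value")], test_used = "paired_t")
  } else {
    c(wilcoxon_signed_rank(x, y, exact_max)[c("statistic", "p_value")],
      test_used = "wilcoxon")
  }
  structure(list(test_used = res$test_used, statistic = res$statistic,
                 p_value = res$p_value, significant = res$p_value < alpha,
                 shapiro_p = sw$p_value, degenerate = FALSE),
            class = "vm_comparison")
}

#' @export
print.vm_comparison <- function(x, ...) {
  if (x$degenerate) cat("Paired comparison: degenerate (identical measurements)\n")
  else cat(sprintf("Paired comparison: %s, statistic %.4f, p = %.4g%s\n",
                   x$test_used, x$statistic, x$p_value,
                   if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Intraclass correlation coefficient
#'
#' Computed from the two-way ANOVA mean squares of a complete
#' subjects-by-raters matrix: `MSR` (rows/subjects), `MSC` (columns/raters),
#' `MSE` (residual). The default form is the two-way random-effects,
#' absolute-agreement, single-measure coefficient
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' `ICC(3,1)` (consistency) and `ICC(1,1)` (one-way) are available.
#'
#' @param mat n x k numeric matrix, n >= 2 subjects, k >= 2 raters/sessions,
#'   no missing cells.
#' @param form One of `"icc2_1"`, `"icc1_1"`, `"icc3_1"`.
#' @return The ICC (scalar, <= 1, possibly negative).
#' @examples
#' icc(matrix(1:8, ncol = 2, byrow = TRUE))  # 0.9302
#' @export
icc <- function(mat, form = c("icc2_1", "icc1_1", "icc3_1")) {
  form <- match.arg(form)
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L || anyNA(mat))
    .vm_stop("vm_invalid_ratings", "need a complete matrix with n >= 2 subjects, k >= 2 raters")
  gm <- mean(mat)
  sst <- sum((mat - gm)^2)
  if (sst == 0)
    .vm_stop("vm_degenerate_ratings", "ratings have zero total variance")
  rm <- rowMeans(mat); cm <- colMeans(mat)
  ssr <- k * sum((rm - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  switch(form,
         icc2_1 = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
         icc3_1 = (msr - mse) / (msr + (k - 1) * mse),
         icc1_1 = {
           msw <- (ssc + sse) / (n * (k - 1))
           (msr - msw) / (msr + (k - 1) * msw)
         })
}

#' Classify an ICC value
#'
#' Reliability above 0.75 (strictly) is labelled excellent.
#'
#' @param value ICC value(s).
#' @return `"excellent"` or `"below_excellent"` per value.
#' @export
icc_class <- function(value) ifelse(value > 0.75, "excellent", "below_excellent")

#' Intra-/inter-observer reliability report
#'
#' For every combination of vertebral level and measurement dimension,
#' computes the normality-routed paired comparison and the ICC for the
#' intra-observer pair of sessions (default observer one's two sessions,
#' O1a vs O1b) and the inter-observer pair (default O1a vs O2).
#'
#' @param data Long-format data frame with columns `specimen_id`, `level`,
#'   `dimension`, `session`, `value_mm` (complete design over the sessions
#'   used).
#' @param icc_form Passed to [icc()].
#' @param intra_sessions,inter_sessions Length-2 character vectors of
#'   session labels to compare.
#' @param alpha Significance level.
#' @return A `vm_reliability_table` data frame with one row per
#'   level x dimension and columns `intra_p`, `intra_test`, `intra_icc`,
#'   `intra_icc_class` and the `inter_*` counterparts.
#' @export
reliability_report <- function(data, icc_form = "icc2_1",
                               intra_sessions = c("O1a", "O1b"),
                               inter_sessions = c("O1a", "O2"),
                               alpha = 0.05) {
  req <- c("specimen_id", "level", "dimension", "session", "value_mm")
  if (!all(req %in% names(data)))
    .vm_stop("vm_incomplete_design", "missing columns: %s",
             paste(setdiff(req, names(data)), collapse = ", "))
  need <- unique(c(intra_sessions, inter_sessions))
  if (!all(need %in% data$session))
    .vm_stop("vm_incomplete_design", "missing sessions: %s",
             paste(setdiff(need, unique(data$session)), collapse = ", "))
  levels_ <- unique(data$level)
  dims_ <- unique(data$dimension)
  pair_stats <- function(sub, sessions) {
    w <- stats::reshape(sub[sub$session %in% sessions,
                            c("specimen_id", "session", "value_mm")],
                        idvar = "specimen_id", timevar = "session",
                        direction = "wide")
    cols <- paste0("value_mm.", sessions)
    if (!all(cols %in% names(w)) || anyNA(w[cols]))
      .vm_stop("vm_incomplete_design", "incomplete design for sessions %s",
               paste(sessions, collapse = "/"))
    x <- w[[cols[1]]]; y <- w[[cols[2]]]
    cmp <- compare_paired(x, y, alpha = alpha)
    ic <- tryCatch(icc(cbind(x, y), form = icc_form),
                   vm_degenerate_ratings = function(e) NA_real_)
    list(p = cmp$p_value, test = cmp$test_used, icc = ic)
  }
  rows <- list()
  for (lv in levels_) for (dm in dims_) {
    sub <- data[data$level == lv & data$dimension == dm, , drop = FALSE]
    if (!nrow(sub)) next
    intra <- pair_stats(sub, intra_sessions)
    inter <- pair_stats(sub, inter_sessions)
    rows[[length(rows) + 1L]] <- data.frame(
      level = lv, dimension = dm,
      intra_p = intra$p, intra_test = intra$test,
      intra_icc = intra$icc, intra_icc_class = icc_class(intra$icc),
      inter_p = inter$p, inter_test = inter$test,
      inter_icc = inter$icc, inter_icc_class = icc_class(inter$icc),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("vm_reliability_table", "data.frame")
  out
}

#' @export
print.vm_reliability_table <- function(x, ...) {
  cat(sprintf("Reliability table: %d level x dimension cells\n", nrow(x)))
  NextMethod()
}
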