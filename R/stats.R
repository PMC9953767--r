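#' Significance of a correlation coefficient
#'
#' Tests a fit correlation against the null hypothesis rho = 0 with
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, referred to a one-tailed Student
#' t distribution with n - 2 degrees of freedom.
#'
#' @param r correlation coefficient, |r| <= 1.
#' @param n number of paired observations, >= 3.
#' @return An object of class `"htest"` with the statistic, df, one-tailed
#'   p-value and `r`. For |r| = 1 the statistic is infinite and p = 0, with
#'   a `note` element flagging the degenerate case.
#' @examples
#' correlationTTest(0.2977, 37)$p.value   # < 0.05
#' correlationTTest(0.1965, 37)$p.value   # > 0.05
#' @export
correlationTTest <- function(r, n) {
  stopifnot(length(r) == 1L, length(n) == 1L)
  if (!is.finite(r) || abs(r) > 1) stop("r must lie in [-1, 1]")
  if (n < 3) stop("need n >= 3")
  note <- NULL
  if (abs(r) == 1) {
    t <- sign(r) * Inf
    p <- 0
    note <- "perfect correlation: t is infinite, p reported as 0"
  } else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- pt(abs(t), df = n - 2, lower.tail = FALSE)
  }
  out <- list(statistic = c(t = t), parameter = c(df = n - 2),
              p.value = p, estimate = c(r = r),
              method = "one-tailed t test of a correlation coefficient",
              alternative = "one.sided", note = note)
  class(out) <- "htest"
  out
}

#' Paired comparison of symmetric regions with a normality gate
#'
#' Compares matched left/right regional values. Normality of the paired
#' differences is assessed by the Kolmogorov-Smirnov test in its
#' Lilliefors-corrected form (mean and SD are estimated from the sample);
#' differences passing the gate at alpha are compared by the paired Student
#' t test, otherwise by the Wilcoxon signed-rank test. Two-sided p-values.
#'
#' @param left,right numeric vectors of equal length >= 5.
#' @param alpha significance level of the normality gate (default 0.05).
#' @return List with elements `test` (`"paired t"`, `"wilcoxon signed-rank"`
#'   or `"degenerate"`), `statistic`, `p.value`, `normality.p`, and
#'   `degenerate`.
#' @export
pairedCompare <- function(left, right, alpha = 0.05) {
  stopifnot(length(left) == length(right))
  if (length(left) < 5) stop("need at least 5 pairs")
  if (any(!is.finite(left)) || any(!is.finite(right)))
    stop("non-finite values in input")
  d <- left - right
  if (all(d == 0))
    return(list(test = "degenerate", statistic = NA_real_, p.value = NA_real_,
                normality.p = NA_real_, degenerate = TRUE,
                note = "all paired differences are zero; no test run"))
  if (sd(d) == 0)
    return(list(test = "degenerate", statistic = NA_real_, p.value = 0,
                normality.p = NA_real_, degenerate = TRUE,
                note = "constant nonzero difference: exact shift, p reported as 0"))
  normP <- nortest::lillie.test(d)$p.value
  if (normP >= alpha) {
    ht <- t.test(left, right, paired = TRUE)
    list(test = "paired t", statistic = unname(ht$statistic),
         p.value = ht$p.value, normality.p = normP, degenerate = FALSE)
  } else {
    ht <- suppressWarnings(wilcox.test(left, right, paired = TRUE,
                                       exact = FALSE, correct = TRUE))
    list(test = "wilcoxon signed-rank", statistic = unname(ht$statistic),
         p.value = ht$p.value, normality.p = normP, degenerate = FALSE)
  }
}

#' Test-retest reliability of qEEG features
#'
#' Pearson correlation per feature across subjects measured in two sessions.
#'
#' @param session1,session2 lists of [SubjectFeatures-class], matched by
#'   position (same subjects, same order).
#' @param features optional character vector restricting the feature set.
#' @return Named numeric vector of Pearson r per feature (NA for features
#'   with zero variance in either session).
#' @export
testRetest <- function(session1, session2, features = NULL) {
  if (length(session1) != length(session2))
    stop("sessions must contain the same subjects")
  if (length(session1) < 3) stop("need at least 3 matched subjects")
  t1 <- featureTable(session1)
  t2 <- featureTable(session2)
  cols <- setdiff(colnames(t1), c("subject", "age"))
  if (!is.null(features)) cols <- intersect(cols, features)
  r <- vapply(cols, function(f) {
    x <- t1[[f]]; y <- t2[[f]]
    if (sd(x) < 1e-12 || sd(y) < 1e-12) return(NA_real_)
    cor(x, y)
  }, 0)
  r
}
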