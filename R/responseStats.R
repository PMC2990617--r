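# Treatment-response statistics: percent/fold changes and the exact
# Mann-Whitney rank-sum test used for all group comparisons.

#' Percent change from baseline
#'
#' 100 * (baseline - followup) / baseline; positive for decreases, matching
#' the convention "a 49\% decrease".
#'
#' @param baseline baseline value, > 0.
#' @param followup follow-up value.
#' @param digits if non-NULL, round the result (reports use integer
#'   percents).
#' @return Percent change (unrounded unless \code{digits} given).
#' @examples
#' percentChange(0.075, 0.038)  # ~49
#' @export
percentChange <- function(baseline, followup, digits = NULL) {
  if (baseline <= 0) stop("baseline must be > 0")
  out <- 100 * (baseline - followup) / baseline
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Fold change from baseline
#'
#' @param baseline baseline value, > 0.
#' @param followup follow-up value.
#' @return followup / baseline.
#' @examples
#' foldChange(0.017, 0.090)  # ~5.3
#' @export
foldChange <- function(baseline, followup) {
  if (baseline <= 0) stop("baseline must be > 0")
  followup / baseline
}

.mwU <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' For combined sample sizes up to \code{exactLimit} the null distribution
#' of U is obtained by full enumeration of all group assignments of the
#' pooled (mid-ranked) values, so the test is exact even with ties; above
#' the limit a tie-corrected normal approximation with continuity
#' correction is used. Two-sided p-value is twice the smaller tail,
#' capped at 1.
#'
#' @param a,b numeric vectors of per-sample values, or
#'   \linkS4class{GroupSummary} objects; both n >= 2.
#' @param exactLimit largest pooled size for enumeration (default 12, which
#'   covers all group sizes used here).
#' @param alpha significance level for the reported flag (default 0.05).
#' @return List with \code{p.value}, \code{U} (for the first group),
#'   \code{significant}, and \code{method}.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
rankSumTest <- function(a, b, exactLimit = 12L, alpha = 0.05) {
  if (is(a, "GroupSummary")) a <- a@values
  if (is(b, "GroupSummary")) b <- b@values
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  if (N <= exactLimit) {
    sets <- utils::combn(N, n1)
    uAll <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    pLo <- mean(uAll <= u + eps)
    pHi <- mean(uAll >= u - eps)
    p <- min(1, 2 * min(pLo, pHi))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    tie <- table(pooled)
    sigma2 <- n1 * n2 / 12 * (N + 1 - sum(tie^3 - tie) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(p.value = 1, U = u, significant = FALSE,
                                 method = "normal approximation"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p.value = p, U = u, significant = p < alpha, method = method)
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors, length >= 3, with non-zero variance in both.
#' @return R^2, the squared Pearson correlation coefficient.
#' @examples
#' linearR2(1:5, 2 * (1:5) + 1)  # 1
#' @export
linearR2 <- function(x, y) {
  if (length(x) < 3 || length(y) != length(x)) stop("need n >= 3 paired values")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance")
  stats::cor(x, y)^2
}
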