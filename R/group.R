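# Group-level statistics and study-level tables.

#' Paired t-test with Cohen's d
#'
#' Dependent t-test on the paired differences \code{a - b}, with
#' d = mean(diff) / sd(diff) (the convention under which a reported
#' (M, sd, t, d) quadruple satisfies t = M/(sd/sqrt(n)) and d = M/sd).
#'
#' @param a,b equal-length numeric vectors (n >= 2).
#' @return list with \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{d}, \code{meanDiff}, \code{sdDiff}.
#' @export
pairedTCohensD <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("a and b must have equal length >= 2")
  d <- a - b
  # relative tolerance: catches differences constant up to rounding noise
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d))))
    stop("zero-variance differences")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = mean(d) / stats::sd(d),
       meanDiff = mean(d), sdDiff = stats::sd(d))
}

#' Cochran Q test with pairwise McNemar post hocs
#'
#' Tests whether the proportion of successes differs across k related
#' binary conditions measured on the same subjects. Post hoc comparisons
#' are pairwise exact McNemar tests with Bonferroni adjustment.
#'
#' @param x subjects x conditions binary (0/1 or logical) matrix.
#' @return list with \code{Q}, \code{df}, \code{p} and \code{postHoc}, a
#'   data.frame of pairwise comparisons (columns i, j, b, c, p_raw,
#'   p_bonferroni).
#' @export
cochranQ <- function(x) {
  x <- as.matrix(x) * 1
  if (ncol(x) < 2L) stop("need at least 2 conditions")
  if (!all(x %in% c(0, 1))) stop("entries must be binary")
  k <- ncol(x)
  Cj <- colSums(x)
  Ri <- rowSums(x)
  denom <- k * sum(Ri) - sum(Ri^2)
  # denominator 0 means every row is constant, i.e. the columns are
  # identical: no evidence of a difference, Q = 0 by convention
  Q <- if (denom == 0) 0 else
    k * (k - 1) * sum((Cj - mean(Cj))^2) / denom
  df <- k - 1
  p <- stats::pchisq(Q, df, lower.tail = FALSE)
  pairs <- utils::combn(k, 2)
  nPairs <- ncol(pairs)
  post <- do.call(rbind, lapply(seq_len(nPairs), function(m) {
    i <- pairs[1L, m]; j <- pairs[2L, m]
    b <- sum(x[, i] == 1 & x[, j] == 0)
    cc <- sum(x[, i] == 0 & x[, j] == 1)
    praw <- mcnemarExact(b, cc)
    data.frame(i = i, j = j, b = b, c = cc, p_raw = praw,
               p_bonferroni = min(1, praw * nPairs))
  }))
  list(Q = Q, df = df, p = p, postHoc = post)
}

#' Exact McNemar test on discordant pair counts
#'
#' Two-sided exact binomial test on the discordant pairs:
#' p = min(1, 2 * P(X <= min(b, c))) with X ~ Binomial(b + c, 1/2);
#' b = c = 0 gives p = 1 by convention.
#'
#' @param b,c discordant pair counts.
#' @return exact two-sided p-value.
#' @export
mcnemarExact <- function(b, c) {
  if (b < 0 || c < 0) stop("counts must be non-negative")
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
}

#' Sensitivity table across p-criteria
#'
#' Percentage of cases flagged significant when an effect is predicted,
#' per system x component x criterion, rounded to the nearest integer
#' percent (ties away from zero, so 15/16 prints as 94 and 14/16 as 88).
#'
#' @param caseResults data.frame of rows from \code{\link{runCaseAnalysis}}
#'   across subjects.
#' @param criteria the p-criteria whose flag columns are tabulated.
#' @return data.frame: one row per system x component, one column per
#'   criterion.
#' @export
sensitivityTable <- function(caseResults, criteria = c(0.05, 0.025, 0.01,
                                                       0.001, 0.00002)) {
  if (nrow(caseResults) == 0L) stop("caseResults must be non-empty")
  rateTable(caseResults, criteria)
}

#' Correlation between component effect magnitudes
#'
#' Product-moment correlation between per-subject EPN and LPP difference
#' values with a two-sided p, as used to explore the relation between the
#' two components' emotional-modulation magnitudes.
#'
#' @param epnDiffs,lppDiffs equal-length numeric vectors (n >= 3).
#' @return list with \code{r} and \code{p}.
#' @export
correlateComponents <- function(epnDiffs, lppDiffs) {
  if (length(epnDiffs) != length(lppDiffs) || length(epnDiffs) < 3L)
    stop("need equal-length vectors with n >= 3")
  if (stats::sd(epnDiffs) == 0 || stats::sd(lppDiffs) == 0)
    stop("zero variance")
  ct <- stats::cor.test(epnDiffs, lppDiffs)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Group statistics from per-case fixed-window scores
#'
#' Paired t / Cohen's d per system x component on the subjects'
#' fixed-window condition differences, plus the per-system EPN-LPP
#' correlation of difference magnitudes.
#'
#' @param scores data.frame with columns subject, system, component,
#'   difference (one row per subject x system x component).
#' @return list with \code{tests} (data.frame) and \code{correlations}
#'   (data.frame).
#' @export
groupStats <- function(scores) {
  strata <- unique(scores[, c("system", "component")])
  tests <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sel <- scores$system == strata$system[i] &
      scores$component == strata$component[i]
    d <- scores$difference[sel]
    r <- pairedTCohensD(d, rep(0, length(d)))
    data.frame(system = strata$system[i], component = strata$component[i],
               mean_diff = r$meanDiff, sd_diff = r$sdDiff, t = r$t,
               df = r$df, p = r$p, cohens_d = r$d,
               stringsAsFactors = FALSE)
  }))
  cors <- do.call(rbind, lapply(unique(scores$system), function(sys) {
    ep <- scores[scores$system == sys & scores$component == "EPN", ]
    lp <- scores[scores$system == sys & scores$component == "LPP", ]
    ord <- match(ep$subject, lp$subject)
    if (nrow(ep) >= 3L && !anyNA(ord)) {
      r <- correlateComponents(ep$difference, lp$difference[ord])
      data.frame(system = sys, r = r$r, p = r$p, stringsAsFactors = FALSE)
    } else NULL
  }))
  rownames(tests) <- NULL
  list(tests = tests, correlations = cors)
}
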