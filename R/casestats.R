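# Single-subject bootstrap significance testing of component differences.
#
# The resampling unit is the trial: per-trial cluster/window mean scores
# are pooled across conditions, and each replicate draws pseudo-high and
# pseudo-low samples with replacement, recording the mean difference. The
# observed difference is then located in that empirical null distribution.

#' Construct a bootstrap configuration
#'
#' @param nBoot bootstrap repetitions (study value 50000).
#' @param seed integer seed.
#' @param sidedness \code{"one"} (default) or \code{"two"}; the per-criterion
#'   significance flags always use the one-sided p in the component's
#'   predicted direction.
#' @param criteria strictly decreasing p-criteria; defaults to the graded
#'   set 0.05, 0.025, 0.01, 0.001, 0.00002 (with B = 50000 these demand
#'   fewer than 2500, 1250, 500, 50 and 0 equal-or-more-extreme replicates).
#' @param windowPolicy \code{"fixed_observed"} (default: the adaptive window
#'   chosen on the observed data is reused in every replicate) or
#'   \code{"reselect_per_replicate"} (the window search is re-run inside
#'   each replicate).
#' @return a \linkS4class{BootstrapConfig}.
#' @export
bootstrapConfig <- function(nBoot = 50000L, seed = 1L,
                            sidedness = c("one", "two"),
                            criteria = c(0.05, 0.025, 0.01, 0.001, 0.00002),
                            windowPolicy = c("fixed_observed",
                                             "reselect_per_replicate")) {
  new("BootstrapConfig", nBoot = as.integer(nBoot), seed = as.integer(seed),
      sidedness = match.arg(sidedness), criteria = criteria,
      windowPolicy = match.arg(windowPolicy))
}

#' Per-trial component scores
#'
#' For each trial, the mean amplitude over the cluster sensors and the
#' window samples (inclusive endpoints). Condition means of these scores
#' equal the corresponding ComponentScore means exactly.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param cluster sensor indices.
#' @param window length-2 ms interval.
#' @return numeric vector, one score per trial (microvolts).
#' @export
perTrialScores <- function(epochs, cluster, window) {
  idx <- windowSamples(timeAxis(epochs), window, closed = "both")
  if (length(idx) == 0L)
    stop("window [", window[1L], ", ", window[2L], "] ms contains no samples")
  apply(epochs@data[, cluster, idx, drop = FALSE], 1L, mean)
}

#' Bootstrap null distribution of the mean difference
#'
#' Pools the high and low scores; each replicate draws \code{length(high)}
#' pseudo-high and \code{length(low)} pseudo-low values with replacement
#' from the pool and records mean(pseudo-high) - mean(pseudo-low).
#'
#' @param scoresHigh,scoresLow per-trial scores of the two conditions.
#' @param nBoot number of replicates.
#' @param seed integer seed.
#' @return numeric vector of \code{nBoot} replicate differences.
#' @export
bootstrapDistribution <- function(scoresHigh, scoresLow, nBoot = 50000L,
                                  seed = 1L) {
  if (length(scoresHigh) == 0L || length(scoresLow) == 0L)
    stop("both score vectors must be non-empty")
  # sorting makes the draw depend on the pooled multiset only, so the
  # result is invariant to trial order/relabeling under a fixed seed
  pool <- sort(c(scoresHigh, scoresLow))
  nH <- length(scoresHigh); nL <- length(scoresLow)
  withSeed(seed, {
    out <- numeric(nBoot)
    chunk <- max(1L, min(nBoot, as.integer(ceiling(2e6 / (nH + nL)))))
    done <- 0L
    while (done < nBoot) {
      b <- min(chunk, nBoot - done)
      mh <- colMeans(matrix(pool[sample.int(nH + nL, b * nH, replace = TRUE)],
                            nrow = nH))
      ml <- colMeans(matrix(pool[sample.int(nH + nL, b * nL, replace = TRUE)],
                            nrow = nL))
      out[(done + 1L):(done + b)] <- mh - ml
      done <- done + b
    }
    out
  })
}

#' Bootstrap p-value
#'
#' One-sided: proportion of replicates d with
#' \code{direction*d >= direction*observed}; two-sided: proportion with
#' \code{|d| >= |observed|}. Equality counts as extreme; to avoid spurious
#' floating-point distinctions, differences from the observed value are
#' rounded to 1e-9 microvolts before the comparison. No continuity
#' correction: p = count/nBoot, so 0 extreme replicates out of 50000 give
#' p = 0 (reported as p < 0.00002).
#'
#' @param observed observed difference (microvolts).
#' @param distribution replicate differences.
#' @param direction expected effect sign (-1 or +1).
#' @param sidedness \code{"one"} or \code{"two"}.
#' @return list with \code{p} and \code{extremeCount}.
#' @export
bootstrapP <- function(observed, distribution, direction = 1,
                       sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  eps <- 1e-9
  count <- if (sidedness == "one") {
    sum(direction * distribution >= direction * observed - eps)
  } else {
    sum(abs(distribution) >= abs(observed) - eps)
  }
  list(p = count / length(distribution), extremeCount = as.integer(count))
}

#' Per-criterion significance flags
#'
#' Strict inequality: a test is significant at criterion alpha iff
#' \code{p < alpha}; p exactly equal to a criterion is not significant.
#'
#' @param p a p-value.
#' @param criteria decreasing p-criteria.
#' @return named logical vector.
#' @export
classifySignificance <- function(p, criteria = c(0.05, 0.025, 0.01, 0.001,
                                                 0.00002)) {
  stats::setNames(p < criteria, format(criteria, scientific = FALSE,
                                       trim = TRUE))
}

#' Replicate-count bound for a p-criterion
#'
#' The smallest equal-or-more-extreme replicate count that is no longer
#' significant at criterion alpha when p = count/nBoot with a strict
#' inequality: significance holds iff count < criterionCountBound. With
#' nBoot = 50000, alpha = 0.05/0.025/0.01/0.001 give 2500/1250/500/50, and
#' alpha = 0.00002 gives 1 (only a count of 0 is significant).
#'
#' @param nBoot number of bootstrap replicates.
#' @param alpha p-criterion.
#' @return integer bound.
#' @export
criterionCountBound <- function(nBoot, alpha) {
  k <- floor(alpha * nBoot)
  as.integer(if (k / nBoot < alpha) k + 1L else k)
}

#' Single-subject case analysis
#'
#' For each component: selects the scoring window (fixed window, or the
#' individually adapted window), computes per-trial scores in that window,
#' bootstraps the null distribution of the mean difference, and grades the
#' one-sided p against the criteria. Under
#' \code{windowPolicy = "fixed_observed"} the observed-data window is
#' reused in every replicate; under \code{"reselect_per_replicate"} the
#' adaptive search is repeated on each replicate's resampled trials.
#'
#' @param epochs a preprocessed, trial-equated \linkS4class{EpochSet}.
#' @param specs list of \linkS4class{ComponentSpec}s.
#' @param config a \linkS4class{BootstrapConfig}.
#' @param mode \code{"adaptive"} or \code{"fixed"} window selection.
#' @param high,low condition labels.
#' @return data.frame with one row per component: subject, system,
#'   component, mode, window bounds, observed difference, one- and
#'   two-sided p with the one-sided extreme count, per-criterion flags
#'   (columns \code{sig_<criterion>}) and bootstrap-distribution
#'   percentiles (5, 25, 50, 75, 95).
#' @export
runCaseAnalysis <- function(epochs, specs = defaultComponentSpecs(
                              nSensors(epochs)),
                            config = bootstrapConfig(),
                            mode = c("adaptive", "fixed"),
                            high = "high", low = "low") {
  mode <- match.arg(mode)
  rows <- list()
  for (spec in specs) {
    seed <- childSeed(config@seed, match(spec@name, vapply(specs, slot,
                                                           "", "name")))
    if (mode == "adaptive" &&
        config@windowPolicy == "reselect_per_replicate") {
      res <- caseReselect(epochs, spec, config, seed, high, low)
    } else {
      sc <- scoreComponent(epochs, spec, mode, high = high, low = low)
      scores <- perTrialScores(epochs, spec@cluster, sc$windowUsed)
      cond <- conditionLabels(epochs)
      dist <- bootstrapDistribution(scores[cond == high],
                                    scores[cond == low],
                                    nBoot = config@nBoot, seed = seed)
      res <- list(window = sc$windowUsed, observed = sc$difference,
                  dist = dist)
    }
    p1 <- bootstrapP(res$observed, res$dist, spec@direction, "one")
    p2 <- bootstrapP(res$observed, res$dist, spec@direction, "two")
    flags <- classifySignificance(p1$p, config@criteria)
    q <- stats::quantile(res$dist, c(0.05, 0.25, 0.5, 0.75, 0.95),
                         names = FALSE)
    row <- data.frame(subject = subjectId(epochs),
                      system = behaviorSystem(epochs),
                      component = spec@name, mode = mode,
                      window_start = res$window[1L],
                      window_end = res$window[2L],
                      observed_difference = res$observed,
                      p_one_sided = p1$p, p_two_sided = p2$p,
                      extreme_count = p1$extremeCount,
                      q05 = q[1L], q25 = q[2L], q50 = q[3L], q75 = q[4L],
                      q95 = q[5L], stringsAsFactors = FALSE)
    for (k in seq_along(config@criteria))
      row[[criterionColumn(config@criteria[k])]] <- flags[k]
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

# Adaptive case analysis with per-replicate window reselection: every
# replicate resamples whole trials, rebuilds the cluster-mean difference
# series, re-runs the window search, and scores in its own window.
caseReselect <- function(epochs, spec, config, seed, high, low) {
  time <- timeAxis(epochs)
  cond <- conditionLabels(epochs)
  # trials x samples cluster-mean series
  cm <- apply(epochs@data[, spec@cluster, , drop = FALSE], c(1L, 3L), mean)
  hIdx <- which(cond == high); lIdx <- which(cond == low)
  L <- spanSamples(spec@span, samplingRate(epochs))
  inRange <- windowSamples(time, spec@searchRange, closed = "both")
  if (length(inRange) < L)
    stop("span ", spec@span, " ms exceeds the usable search range")
  starts <- inRange[seq_len(length(inRange) - L + 1L)]

  pickDiff <- function(diffSeries) {
    means <- slidingMeans(diffSeries[inRange], L)
    k <- which.max(spec@direction * means)
    list(window = c(time[starts[k]], time[starts[k] + L - 1L]),
         value = means[k])
  }
  obs <- pickDiff(colMeans(cm[hIdx, , drop = FALSE]) -
                    colMeans(cm[lIdx, , drop = FALSE]))
  pool <- rbind(cm[hIdx, , drop = FALSE], cm[lIdx, , drop = FALSE])
  nH <- length(hIdx); nL <- length(lIdx); nP <- nH + nL
  dist <- withSeed(seed, {
    vapply(seq_len(config@nBoot), function(b) {
      ph <- pool[sample.int(nP, nH, replace = TRUE), , drop = FALSE]
      pl <- pool[sample.int(nP, nL, replace = TRUE), , drop = FALSE]
      pickDiff(colMeans(ph) - colMeans(pl))$value
    }, numeric(1L))
  })
  list(window = obs$window, observed = obs$value, dist = dist)
}

#' Split an EpochSet into first and second halves
#'
#' Splits by original trial order within each condition; an odd count gives
#' the extra trial to the first half. Used for the habituation
#' (stimulus-repetition) reanalysis.
#'
#' @param epochs an \linkS4class{EpochSet} with at least 2 trials per
#'   condition.
#' @return list with elements \code{first} and \code{second}.
#' @export
splitHalves <- function(epochs) {
  cond <- conditionLabels(epochs)
  firstIdx <- integer()
  for (lv in unique(cond)) {
    idx <- which(cond == lv)
    if (length(idx) < 2L)
      stop("need at least 2 trials per condition to split halves")
    firstIdx <- c(firstIdx, idx[seq_len(ceiling(length(idx) / 2))])
  }
  firstIdx <- sort(firstIdx)
  list(first = epochs[firstIdx],
       second = epochs[setdiff(seq_len(nTrials(epochs)), firstIdx)])
}
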