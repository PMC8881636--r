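# Specificity (false-alarm) analysis: left/right mirrored presentations of
# the same picture category are a built-in null contrast; any significant
# "effect" between them is a false alarm.

#' Split one picture category by mirror label
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param category condition label (\code{"high"} or \code{"low"}).
#' @return list with EpochSets \code{left} and \code{right}.
#' @export
mirrorSplit <- function(epochs, category) {
  idx <- which(conditionLabels(epochs) == category)
  if (length(idx) == 0L) stop("no trials with condition '", category, "'")
  sub <- epochs[idx]
  mir <- mirrorLabels(sub)
  if (!all(c("left", "right") %in% mir))
    stop("both mirror labels must be present within category '", category,
         "'")
  list(left = sub[which(mir == "left")], right = sub[which(mir == "right")])
}

# Relabel a category's trials with mirror as pseudo-condition so the main
# machinery (equate, score, bootstrap) applies unchanged.
mirrorAsCondition <- function(epochs, category) {
  idx <- which(conditionLabels(epochs) == category)
  sub <- epochs[idx]
  sub@trialData$condition <- sub@trialData$mirror
  sub
}

#' Run the specificity analysis on one EpochSet
#'
#' For each picture category (high, low) and each component, treats left
#' vs right mirrored presentations as pseudo-conditions, equates counts,
#' selects the scoring window with the same parameters as the main
#' analysis, bootstraps, and computes the one-sided p for both directions
#' (left > right and right > left, in the component's predicted sign).
#' Four tests per component x category pair of directions: 2 categories x
#' 2 directions.
#'
#' In fixed mode both directions reuse one bootstrap distribution (the
#' directional statistics are sign flips of each other); in adaptive mode
#' the window is selected per direction, so each direction has its own
#' distribution.
#'
#' @param epochs a preprocessed \linkS4class{EpochSet}.
#' @param specs list of \linkS4class{ComponentSpec}s.
#' @param config a \linkS4class{BootstrapConfig}.
#' @param mode \code{"adaptive"} or \code{"fixed"} window selection.
#' @return data.frame with one row per (category, component, direction):
#'   p-value and per-criterion flags.
#' @export
runSpecificity <- function(epochs, specs = defaultComponentSpecs(
                             nSensors(epochs)),
                           config = bootstrapConfig(),
                           mode = c("adaptive", "fixed")) {
  mode <- match.arg(mode)
  rows <- list()
  for (category in c("high", "low")) {
    pseudo <- mirrorAsCondition(epochs, category)
    pseudo <- equateTrials(pseudo, seed = childSeed(config@seed, 91L,
                                                    match(category,
                                                          c("high", "low"))))
    for (si in seq_along(specs)) {
      spec <- specs[[si]]
      for (di in 1:2) {
        dirLabel <- c("left_gt_right", "right_gt_left")[di]
        hiLab <- c("left", "right")[di]
        loLab <- c("right", "left")[di]
        seed <- childSeed(config@seed, 92L, match(category, c("high", "low")),
                          si, if (mode == "adaptive") di else 1L)
        sc <- scoreComponent(pseudo, spec, mode, high = hiLab, low = loLab)
        scores <- perTrialScores(pseudo, spec@cluster, sc$windowUsed)
        cond <- conditionLabels(pseudo)
        dist <- bootstrapDistribution(scores[cond == hiLab],
                                      scores[cond == loLab],
                                      nBoot = config@nBoot, seed = seed)
        p1 <- bootstrapP(sc$difference, dist, spec@direction, "one")
        flags <- classifySignificance(p1$p, config@criteria)
        row <- data.frame(subject = subjectId(epochs),
                          system = behaviorSystem(epochs),
                          component = spec@name, picture_category = category,
                          direction = dirLabel, mode = mode,
                          window_start = sc$windowUsed[1L],
                          window_end = sc$windowUsed[2L],
                          observed_difference = sc$difference,
                          p_one_sided = p1$p, stringsAsFactors = FALSE)
        for (k in seq_along(config@criteria))
          row[[criterionColumn(config@criteria[k])]] <- flags[k]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' False-alarm rate table across p-criteria
#'
#' Percentage of specificity tests flagged significant, per
#' component x system x criterion, rounded to the nearest integer percent.
#'
#' @param results data.frame from \code{\link{runSpecificity}} (rows from
#'   several subjects may be concatenated).
#' @param criteria the p-criteria whose flag columns are tabulated.
#' @return data.frame: one row per system x component, one column per
#'   criterion, values in percent.
#' @export
falseAlarmTable <- function(results, criteria = c(0.05, 0.025, 0.01, 0.001,
                                                  0.00002)) {
  if (nrow(results) == 0L) stop("results must be non-empty")
  rateTable(results, criteria)
}

# Shared tabulation: % of flagged rows per system x component x criterion.
rateTable <- function(results, criteria) {
  cols <- criterionColumn(criteria)
  strata <- unique(results[, c("system", "component")])
  out <- strata
  for (k in seq_along(criteria)) {
    out[[paste0("p", criteria[k])]] <- vapply(seq_len(nrow(strata)),
      function(i) {
        sel <- results$system == strata$system[i] &
          results$component == strata$component[i]
        roundPercent(mean(results[[cols[k]]][sel]))
      }, integer(1L))
  }
  rownames(out) <- NULL
  out
}
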