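# EEG signal-quality gates: (+/-)-reference noise estimate and bootstrap
# signal-to-noise-ratio confidence intervals with a 3 dB inclusion
# threshold.

#' Construct an SNR configuration
#'
#' @param nBoot bootstrap repetitions.
#' @param ciLevel central confidence level (default 0.90).
#' @param preWindow pre-stimulus (noise) interval in ms, half-open
#'   \code{[a, b)}.
#' @param postWindow post-stimulus (signal) interval in ms, half-open
#'   \code{(a, b]}; \code{c(0, NA)} means "from onset to the epoch end".
#' @param dbThreshold minimum acceptable lower CI bound (dB, default 3).
#' @param seed integer seed.
#' @return an \linkS4class{SnrConfig}.
#' @export
snrConfig <- function(nBoot = 50000L, ciLevel = 0.90,
                      preWindow = c(-100, 0), postWindow = c(0, NA),
                      dbThreshold = 3, seed = 1L) {
  new("SnrConfig", nBoot = as.integer(nBoot), ciLevel = ciLevel,
      preWindow = preWindow, postWindow = postWindow,
      dbThreshold = dbThreshold, seed = as.integer(seed))
}

#' (+/-)-reference ERP
#'
#' Averages the trials with alternating polarity (+1, -1, +1, ...) in
#' original trial order, dividing by the trial count. The evoked signal
#' cancels (exactly, for an even number of identical trials), leaving an
#' estimate of the residual noise level of the average.
#'
#' @param epochs an \linkS4class{EpochSet} with at least 2 trials.
#' @return an \linkS4class{ERPWaveform} with condition
#'   \code{"plus_minus_reference"}.
#' @export
plusMinusErp <- function(epochs) {
  n <- nTrials(epochs)
  if (n < 2L) stop("need at least 2 trials")
  signs <- rep_len(c(1, -1), n)
  d <- epochs@data * signs          # recycles along the first (trial) margin
  m <- apply(d, c(2L, 3L), sum) / n
  new("ERPWaveform", data = m, fs = samplingRate(epochs),
      time = timeAxis(epochs), nTrials = as.integer(n),
      condition = "plus_minus_reference")
}

# RMS of a cluster-mean waveform over a set of sample indices.
rmsOver <- function(series, idx) sqrt(mean(series[idx]^2))

#' Bootstrap SNR confidence interval
#'
#' Per replicate: draws n_min trials with replacement (n_min = the smaller
#' condition count, ignoring labels in the draw itself), averages them,
#' forms the cluster-mean waveform, and computes
#' \code{20*log10(RMS(post) / RMS(pre))}. The CI is the central
#' \code{ciLevel} percentile interval of the replicate dB values; the case
#' passes when the lower bound reaches \code{dbThreshold}.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param cluster sensor indices over which the waveform is averaged.
#' @param config an \linkS4class{SnrConfig}.
#' @return list with \code{lowerDb}, \code{upperDb}, \code{pass},
#'   \code{nMin} and the replicate \code{db} values.
#' @export
snrCi <- function(epochs, cluster, config = snrConfig()) {
  time <- timeAxis(epochs)
  post <- config@postWindow
  if (is.na(post[2L])) post[2L] <- max(time)
  preIdx <- windowSamples(time, config@preWindow, closed = "left")
  postIdx <- windowSamples(time, post, closed = "right")
  if (length(preIdx) == 0L || length(postIdx) == 0L)
    stop("pre- and post-stimulus windows must both contain samples")
  counts <- table(conditionLabels(epochs))
  nMin <- as.integer(min(counts))
  # trials x samples cluster-mean series
  cm <- apply(epochs@data[, cluster, , drop = FALSE], c(1L, 3L), mean)
  n <- nrow(cm)
  db <- withSeed(config@seed, {
    vapply(seq_len(config@nBoot), function(b) {
      avg <- colMeans(cm[sample.int(n, nMin, replace = TRUE), ,
                         drop = FALSE])
      pre <- rmsOver(avg, preIdx)
      if (pre == 0)
        stop("zero pre-stimulus RMS: degenerate noiseless input")
      20 * log10(rmsOver(avg, postIdx) / pre)
    }, numeric(1L))
  })
  a <- (1 - config@ciLevel) / 2
  ci <- stats::quantile(db, c(a, 1 - a), names = FALSE)
  list(lowerDb = ci[1L], upperDb = ci[2L],
       pass = ci[1L] >= config@dbThreshold, nMin = nMin, db = db)
}

#' Quality-control report for a study
#'
#' Runs \code{\link{snrCi}} on each EpochSet for each component cluster.
#'
#' @param study named list of \linkS4class{EpochSet}s.
#' @param specs list of \linkS4class{ComponentSpec}s (their clusters are
#'   used).
#' @param config an \linkS4class{SnrConfig}.
#' @return data.frame with columns subject, system, cluster, lower_db,
#'   upper_db, pass.
#' @export
qcReport <- function(study, specs, config = snrConfig(nBoot = 2000L)) {
  rows <- lapply(study, function(es) {
    do.call(rbind, lapply(specs, function(sp) {
      r <- snrCi(es, sp@cluster, config)
      data.frame(subject = subjectId(es), system = behaviorSystem(es),
                 cluster = sp@clusterName, lower_db = r$lowerDb,
                 upper_db = r$upperDb, pass = r$pass,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
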