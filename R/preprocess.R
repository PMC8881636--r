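# Preprocessing chain: Butterworth band limiting, baseline adjustment,
# average reference, artifact rejection, trial-count equating, averaging.

#' Construct a filter specification
#'
#' Defaults follow the acquisition pipeline: low-pass half-power cutoff
#' 40 Hz (Butterworth, order 19) and high-pass half-power cutoff 0.06 Hz
#' (Butterworth, order 4). High orders are realised as cascaded
#' second-order sections; the contract is the magnitude response, not a
#' coefficient layout.
#'
#' @param lowpassCutoff,lowpassOrder low-pass half-power cutoff (Hz), order.
#' @param highpassCutoff,highpassOrder high-pass half-power cutoff (Hz), order.
#' @param phaseMode \code{"zero_phase"} (forward-backward; the default, so
#'   window means are not biased by phase delay) or \code{"causal"}.
#' @return a \linkS4class{FilterSpec}.
#' @export
filterSpec <- function(lowpassCutoff = 40, lowpassOrder = 19L,
                       highpassCutoff = 0.06, highpassOrder = 4L,
                       phaseMode = c("zero_phase", "causal")) {
  new("FilterSpec",
      lowpassCutoff = lowpassCutoff, lowpassOrder = as.integer(lowpassOrder),
      highpassCutoff = highpassCutoff,
      highpassOrder = as.integer(highpassOrder),
      family = "butterworth", phaseMode = match.arg(phaseMode))
}

# Butterworth design as second-order sections via bilinear transform with
# cutoff prewarping. Analog prototype poles lie on the unit circle at
# exp(i*pi*(2k + n - 1)/(2n)); low-pass scales s by the warped cutoff,
# high-pass maps s -> wc/s. Each conjugate pole pair (plus one real pole
# for odd orders) becomes a biquad normalised to unit gain at DC
# (low-pass) or Nyquist (high-pass). Returns a list of sections, each
# list(b = length-3, a = length-3) (a[1] == 1).
butterSos <- function(n, cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  wc <- 2 * fs * tan(pi * cutoff / fs)     # prewarped analog cutoff (rad/s)
  k <- seq_len(n)
  theta <- pi * (2 * k + n - 1) / (2 * n)
  p <- exp(1i * theta)                      # prototype poles, |p| = 1
  p <- if (type == "low") wc * p else wc / p
  z <- (2 * fs + p) / (2 * fs - p)          # bilinear transform
  # pair conjugates: poles come in conjugate pairs ordered symmetrically
  sections <- list()
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (used[i]) next
    if (abs(Im(z[i])) < 1e-12) {            # real pole (odd order)
      used[i] <- TRUE
      a <- c(1, -Re(z[i]), 0)
      b <- if (type == "low") c(1, 1, 0) else c(1, -1, 0)
    } else {
      j <- which(!used & abs(Im(z) + Im(z[i])) < 1e-9 &
                   abs(Re(z) - Re(z[i])) < 1e-9)[1L]
      used[c(i, j)] <- TRUE
      a <- c(1, -2 * Re(z[i]), Mod(z[i])^2)
      b <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
    }
    ref <- if (type == "low") 1 + 0i else -1 + 0i   # z where gain must be 1
    g <- Mod(sum(a * ref^(0:-2))) / Mod(sum(b * ref^(0:-2)))
    sections[[length(sections) + 1L]] <- list(b = b * g, a = a)
  }
  sections
}

#' Magnitude response of a filter specification
#'
#' Evaluates the designed transfer-function magnitude of a single causal
#' pass at the requested frequencies. In zero-phase mode the applied
#' magnitude is this squared.
#'
#' @param spec a \linkS4class{FilterSpec}.
#' @param freq frequencies (Hz).
#' @param fs sampling rate (Hz).
#' @param which \code{"both"}, \code{"lowpass"} or \code{"highpass"}.
#' @return magnitude gain(s) of one pass.
#' @export
filterMagnitude <- function(spec, freq, fs, which = c("both", "lowpass",
                                                      "highpass")) {
  which <- match.arg(which)
  secs <- list()
  if (which %in% c("both", "lowpass"))
    secs <- c(secs, butterSos(spec@lowpassOrder, spec@lowpassCutoff, fs, "low"))
  if (which %in% c("both", "highpass"))
    secs <- c(secs, butterSos(spec@highpassOrder, spec@highpassCutoff, fs,
                              "high"))
  vapply(freq, function(f) {
    zi <- exp(-1i * 2 * pi * f / fs)
    g <- 1
    for (s in secs)
      g <- g * Mod(sum(s$b * zi^(0:2))) / Mod(sum(s$a * zi^(0:2)))
    g
  }, numeric(1L))
}

# One biquad applied causally via stats::filter (C level): FIR part with
# sides = 1, then the recursive AR part.
applyBiquad <- function(x, b, a) {
  v <- as.numeric(stats::filter(x, b, method = "convolution", sides = 1))
  v[1L] <- b[1L] * x[1L]
  if (length(x) > 1L) v[2L] <- b[1L] * x[2L] + b[2L] * x[1L]
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

# Zero-phase (forward-backward) application of one biquad with odd
# reflection padding at both ends to suppress edge transients.
filtfiltBiquad <- function(x, b, a, padlen = 9L) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  pre <- 2 * x[1L] - x[seq(padlen + 1L, 2L, by = -1L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen, by = -1L)]
  y <- c(pre, x, post)
  y <- applyBiquad(y, b, a)
  y <- rev(applyBiquad(rev(y), b, a))
  y[(padlen + 1L):(padlen + n)]
}

applySections <- function(x, sections, zeroPhase) {
  for (s in sections) {
    x <- if (zeroPhase) filtfiltBiquad(x, s$b, s$a) else applyBiquad(x, s$b, s$a)
  }
  x
}

#' Band-limit an EpochSet
#'
#' Applies the cascaded high-pass and low-pass Butterworth filters to every
#' trial and sensor time series. Output shape is unchanged.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param spec a \linkS4class{FilterSpec}.
#' @return the filtered \linkS4class{EpochSet}.
#' @export
applyFilters <- function(epochs, spec = filterSpec()) {
  fs <- samplingRate(epochs)
  if (spec@lowpassCutoff >= fs / 2)
    stop("lowpassCutoff must be below the Nyquist frequency ", fs / 2, " Hz")
  nS <- length(timeAxis(epochs))
  minLen <- 3L * max(spec@lowpassOrder, spec@highpassOrder) + 1L
  if (nS < minLen)
    stop("epoch too short for stable filtering: need at least ", minLen,
         " samples")
  secs <- c(butterSos(spec@highpassOrder, spec@highpassCutoff, fs, "high"),
            butterSos(spec@lowpassOrder, spec@lowpassCutoff, fs, "low"))
  zero <- spec@phaseMode == "zero_phase"
  d <- epochs@data
  dm <- dim(d)
  # flatten trials x sensors into columns, filter each column
  m <- matrix(aperm(d, c(3L, 1L, 2L)), nrow = dm[3L])
  for (j in seq_len(ncol(m)))
    m[, j] <- applySections(m[, j], secs, zero)
  epochs@data <- aperm(array(m, dim = c(dm[3L], dm[1L], dm[2L])),
                       c(2L, 3L, 1L))
  epochs
}

#' Baseline-adjust and average-reference an EpochSet
#'
#' Per trial, the sensor-wise mean over the baseline samples (half-open
#' interval \code{[baseline[1], baseline[2])}) is subtracted; then at every
#' sample the across-sensor mean is subtracted (average reference).
#' Baseline first, then reference: with this order the across-sensor sum is
#' exactly zero at every sample and the per-sensor baseline mean is exactly
#' zero, simultaneously.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param baseline length-2 ms interval, within the epoch and before 0 ms.
#' @return the adjusted \linkS4class{EpochSet}.
#' @export
baselineAndReference <- function(epochs, baseline = c(-100, 0)) {
  if (baseline[2L] > 0) stop("baseline interval must end at or before 0 ms")
  idx <- windowSamples(timeAxis(epochs), baseline, closed = "left")
  if (length(idx) == 0L)
    stop("baseline interval contains no samples at this sampling rate")
  d <- epochs@data
  base <- apply(d[, , idx, drop = FALSE], c(1L, 2L), mean)
  d <- sweep(d, c(1L, 2L), base, "-")
  ref <- apply(d, c(1L, 3L), mean)
  dm <- dim(d)
  d <- d - aperm(array(ref, dim = c(dm[1L], dm[3L], dm[2L])), c(1L, 3L, 2L))
  epochs@data <- d
  epochs
}

#' Reject trials exceeding an absolute amplitude threshold
#'
#' A simple amplitude-threshold rejector: trials whose absolute amplitude
#' exceeds the threshold at any sensor/sample are dropped.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param absThreshold rejection threshold in microvolts (default 100).
#' @return list with elements \code{epochs} (the retained trials) and
#'   \code{log}, a data.frame with one row per rejected trial:
#'   \code{trial_index}, \code{sensor}, \code{sample}, \code{value} of the
#'   worst excursion.
#' @export
rejectArtifacts <- function(epochs, absThreshold = 100) {
  if (absThreshold <= 0) stop("absThreshold must be positive")
  d <- epochs@data
  worst <- apply(abs(d), 1L, max)
  bad <- which(worst > absThreshold)
  log <- data.frame(trial_index = integer(), sensor = integer(),
                    sample = integer(), value = numeric())
  if (length(bad)) {
    for (tr in bad) {
      sl <- abs(d[tr, , ])
      pos <- which(sl == max(sl), arr.ind = TRUE)[1L, ]
      log <- rbind(log, data.frame(trial_index = tr,
                                   sensor = unname(pos[1L]),
                                   sample = unname(pos[2L]),
                                   value = d[tr, pos[1L], pos[2L]]))
    }
    if (length(bad) == nTrials(epochs))
      stop("all trials rejected at threshold ", absThreshold, " microvolts")
    epochs <- epochs[-bad]
  }
  list(epochs = epochs, log = log)
}

#' Equate trial counts between conditions
#'
#' Keeps min(n_high, n_low) trials per condition; the retained trials of
#' the larger condition are a seeded random subset (original order
#' preserved among kept trials), the smaller condition is untouched.
#'
#' @param epochs an \linkS4class{EpochSet} with both conditions present.
#' @param seed integer seed for the random subset.
#' @return the equated \linkS4class{EpochSet}.
#' @export
equateTrials <- function(epochs, seed = 1L) {
  cond <- conditionLabels(epochs)
  lev <- unique(cond)
  if (length(lev) < 2L) stop("both conditions must be present")
  counts <- table(cond)
  nKeep <- min(counts)
  keep <- logical(nTrials(epochs))
  withSeed(seed, {
    for (lv in lev) {
      idx <- which(cond == lv)
      if (length(idx) > nKeep)
        idx <- sort(idx[sample.int(length(idx), nKeep)])
      keep[idx] <- TRUE
    }
  })
  epochs[which(keep)]
}

#' Average trials into an ERP waveform
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param condition condition label to average, or \code{"all"} for every
#'   trial regardless of label.
#' @return an \linkS4class{ERPWaveform}.
#' @export
computeErp <- function(epochs, condition) {
  idx <- if (identical(condition, "all")) seq_len(nTrials(epochs))
         else which(conditionLabels(epochs) == condition)
  if (length(idx) == 0L) stop("no trials with condition '", condition, "'")
  m <- apply(epochs@data[idx, , , drop = FALSE], c(2L, 3L), mean)
  new("ERPWaveform", data = m, fs = samplingRate(epochs),
      time = timeAxis(epochs), nTrials = length(idx),
      condition = as.character(condition))
}

#' Condition-difference waveform (high minus low)
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param high,low the two condition labels.
#' @return an \linkS4class{ERPWaveform} with condition \code{"difference"}.
#' @export
differenceWaveform <- function(epochs, high = "high", low = "low") {
  a <- computeErp(epochs, high)
  b <- computeErp(epochs, low)
  new("ERPWaveform", data = a@data - b@data, fs = a@fs, time = a@time,
      nTrials = a@nTrials + b@nTrials, condition = "difference")
}
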