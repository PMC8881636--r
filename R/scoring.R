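# Component scoring: cluster-mean amplitudes in fixed windows (group mode)
# or individually adapted windows (case mode).

#' Construct a component specification
#'
#' @param name component label, \code{"EPN"} or \code{"LPP"} (free-form
#'   labels are allowed).
#' @param cluster sensor indices (1-based) of the scoring cluster.
#' @param fixedWindow ms interval used in fixed-window scoring
#'   (EPN 240-300, LPP 380-480).
#' @param searchRange ms interval the adaptive window may occupy
#'   (EPN 150-350, LPP 350-750).
#' @param span adaptive window length in ms (EPN 60, LPP 100).
#' @param direction expected effect sign: -1 (EPN) or +1 (LPP).
#' @param clusterName cluster label.
#' @return a \linkS4class{ComponentSpec}.
#' @export
componentSpec <- function(name, cluster, fixedWindow, searchRange, span,
                          direction, clusterName = paste0(name, "_cluster")) {
  new("ComponentSpec", name = name, clusterName = clusterName,
      cluster = as.integer(sort(unique(cluster))),
      fixedWindow = as.numeric(fixedWindow),
      searchRange = as.numeric(searchRange),
      span = as.numeric(span), direction = as.numeric(direction))
}

#' Default EPN and LPP component specifications
#'
#' EPN: occipito-parietal cluster, fixed window 240-300 ms, search range
#' 150-350 ms, 60 ms adaptive span, negative direction. LPP:
#' centro-parietal cluster, fixed window 380-480 ms, search range
#' 350-750 ms, 100 ms span, positive direction. Clusters come from
#' \code{\link{defaultClusters}} for the montage size.
#'
#' @param nSensors montage size used to pick the clusters.
#' @param clusters optional list with \code{posterior}/\code{central}
#'   sensor vectors, overriding the defaults.
#' @return named list of two \linkS4class{ComponentSpec}s.
#' @export
defaultComponentSpecs <- function(nSensors = 257L, clusters = NULL) {
  if (is.null(clusters)) clusters <- defaultClusters(nSensors)
  list(
    EPN = componentSpec("EPN", clusters$posterior,
                        fixedWindow = c(240, 300), searchRange = c(150, 350),
                        span = 60, direction = -1,
                        clusterName = "occipito_parietal"),
    LPP = componentSpec("LPP", clusters$central,
                        fixedWindow = c(380, 480), searchRange = c(350, 750),
                        span = 100, direction = +1,
                        clusterName = "centro_parietal"))
}

#' Mean cluster amplitude in a time window
#'
#' Arithmetic mean over the cluster sensors and all samples whose time t
#' satisfies \code{window[1] <= t <= window[2]} (inclusive endpoints).
#'
#' @param waveform an \linkS4class{ERPWaveform}.
#' @param cluster sensor indices.
#' @param window length-2 ms interval.
#' @return mean amplitude in microvolts.
#' @export
meanClusterAmplitude <- function(waveform, cluster, window) {
  idx <- windowSamples(waveform@time, window, closed = "both")
  if (length(idx) == 0L)
    stop("window [", window[1L], ", ", window[2L], "] ms contains no samples")
  mean(waveform@data[cluster, idx, drop = FALSE])
}

# Adaptive window length in samples: inclusive endpoints.
spanSamples <- function(span, fs) as.integer(round(span * fs / 1000)) + 1L

# Sliding-window means of a series via cumulative sums; returns a vector of
# means for windows starting at each index (length n - L + 1).
slidingMeans <- function(x, L) {
  cs <- cumsum(c(0, x))
  (cs[(L + 1L):length(cs)] - cs[1:(length(cs) - L)]) / L
}

#' Individually adapted component window
#'
#' Slides a window of the component's span (in samples:
#' \code{round(span*fs/1000) + 1} with inclusive endpoints) in 1-sample
#' steps fully inside the search range over the cluster-mean difference
#' series, and returns the window maximising
#' \code{direction x windowMean}. Ties break to the earliest start.
#'
#' @param diff an \linkS4class{ERPWaveform} holding the high-minus-low
#'   difference (sensors x samples).
#' @param spec a \linkS4class{ComponentSpec}.
#' @return length-2 ms interval (times of the first and last sample).
#' @export
adaptiveWindow <- function(diff, spec) {
  time <- diff@time
  series <- colMeans(diff@data[spec@cluster, , drop = FALSE])
  L <- spanSamples(spec@span, diff@fs)
  inRange <- windowSamples(time, spec@searchRange, closed = "both")
  if (length(inRange) < L)
    stop("span ", spec@span, " ms exceeds the usable search range")
  starts <- inRange[seq_len(length(inRange) - L + 1L)]
  means <- slidingMeans(series[inRange], L)
  best <- starts[which.max(spec@direction * means)]
  c(time[best], time[best + L - 1L])
}

#' Score a component on one EpochSet
#'
#' Computes the condition ERPs and their difference, selects the scoring
#' window (the component's fixed window, or the individually adapted
#' window), and returns the cluster-mean condition amplitudes and their
#' difference in that window.
#'
#' @param epochs a preprocessed \linkS4class{EpochSet}.
#' @param spec a \linkS4class{ComponentSpec}.
#' @param mode \code{"fixed"} or \code{"adaptive"}.
#' @param high,low condition labels.
#' @return list of class \code{"ComponentScore"} with fields
#'   \code{component}, \code{mode}, \code{windowUsed}, \code{meanHigh},
#'   \code{meanLow}, \code{difference} (high minus low, microvolts).
#' @export
scoreComponent <- function(epochs, spec, mode = c("adaptive", "fixed"),
                           high = "high", low = "low") {
  mode <- match.arg(mode)
  erpH <- computeErp(epochs, high)
  erpL <- computeErp(epochs, low)
  dif <- new("ERPWaveform", data = erpH@data - erpL@data, fs = erpH@fs,
             time = erpH@time, nTrials = erpH@nTrials + erpL@nTrials,
             condition = "difference")
  window <- if (mode == "fixed") spec@fixedWindow else adaptiveWindow(dif, spec)
  mh <- meanClusterAmplitude(erpH, spec@cluster, window)
  ml <- meanClusterAmplitude(erpL, spec@cluster, window)
  structure(list(component = spec@name, mode = mode, windowUsed = window,
                 meanHigh = mh, meanLow = ml, difference = mh - ml),
            class = "ComponentScore")
}

#' @export
print.ComponentScore <- function(x, ...) {
  cat(sprintf("%s (%s window %g-%g ms): high %.3f, low %.3f, diff %.3f microvolts\n",
              x$component, x$mode, x$windowUsed[1L], x$windowUsed[2L],
              x$meanHigh, x$meanLow, x$difference))
  invisible(x)
}
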