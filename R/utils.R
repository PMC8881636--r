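# Internal helpers: seeding, windows, effect templates, 1/f noise.

# Deterministic child seed from a root seed and integer counters, so any
# (subject, system, component) re-run reproduces the study-level run.
childSeed <- function(root, ...) {
  ids <- c(...)
  s <- as.numeric(root) %% 2147483647
  for (k in ids) {
    s <- (s * 69069 + as.numeric(k) * 12347 + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Sample indices whose time t lies in the window. closed = "both" gives
# inclusive endpoints (component scoring); "left" gives [a, b) (baseline,
# SNR pre-window); "right" gives (a, b] (SNR post-window).
windowSamples <- function(time, window, closed = c("both", "left", "right")) {
  closed <- match.arg(closed)
  eps <- 1e-9
  lo <- window[1L]; hi <- window[2L]
  keep <- switch(closed,
    both  = time >= lo - eps & time <= hi + eps,
    left  = time >= lo - eps & time <  hi - eps,
    right = time >  lo + eps & time <= hi + eps)
  which(keep)
}

# Hanning (raised-cosine) bump of full width `span` ms centered at `center`,
# evaluated on the time axis; zero outside its support, peak weight 1.
hannTemplate <- function(time, center, span) {
  rel <- (time - (center - span / 2)) / span
  w <- numeric(length(time))
  inside <- rel >= 0 & rel <= 1
  w[inside] <- 0.5 * (1 - cos(2 * pi * rel[inside]))
  w
}

# Smallest 5-smooth (2^a 3^b 5^c) integer >= n, for fast FFTs.
nextFastLen <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

# Matrix of 1/f^beta noise traces (nSamples x nTraces), each column
# normalised to zero mean and unit sample SD. Uses FFT shaping of white
# noise on a padded 5-smooth length (truncated back to nSamples); DC is
# removed. beta = 0 reduces to white noise.
oneOverFNoise <- function(nSamples, nTraces, beta, blockCols = 20000L) {
  if (nTraces == 0L) return(matrix(0, nSamples, 0L))
  if (beta == 0) {
    out <- matrix(stats::rnorm(nSamples * nTraces), nSamples, nTraces)
  } else {
    nF <- nextFastLen(nSamples)
    k <- 0:(nF - 1L)
    f <- pmin(k, nF - k)                # cycles per window; symmetric
    scale <- ifelse(f > 0, f^(-beta / 2), 0)
    out <- matrix(0, nSamples, nTraces)
    start <- 1L
    while (start <= nTraces) {
      end <- min(start + blockCols - 1L, nTraces)
      nc <- end - start + 1L
      # complex white spectrum scaled by f^(-beta/2); the real part of its
      # inverse transform is Gaussian noise with the target power spectrum
      w <- matrix(complex(real = stats::rnorm(nF * nc),
                          imaginary = stats::rnorm(nF * nc)) * scale,
                  nF, nc)
      out[, start:end] <- Re(stats::mvfft(w, inverse = TRUE)
                             )[seq_len(nSamples), , drop = FALSE] / nF
      start <- end + 1L
    }
  }
  out <- sweep(out, 2L, colMeans(out), "-")
  sds <- sqrt(colSums(out^2) / (nSamples - 1L))
  sds[sds == 0] <- 1
  sweep(out, 2L, sds, "/")
}

# Column name for a p-criterion's significance flag, formatted per element
# so 0.05 -> "sig_0.05" and 0.00002 -> "sig_0.00002".
criterionColumn <- function(alpha) {
  vapply(alpha, function(a) paste0("sig_", format(a, scientific = FALSE)),
         character(1L))
}

# Nearest-integer percentage with ties rounded away from zero, so
# 15/16 -> 94 and 14/16 -> 88.
#' Round a proportion to a whole percentage
#'
#' Converts a proportion to percent and rounds to the nearest integer with
#' ties away from zero (so 0.875 becomes 88, not 87).
#' @param p proportion(s) in \code{[0, 1]}.
#' @return integer percentage(s).
#' @examples roundPercent(c(14, 15, 16) / 16)
#' @export
roundPercent <- function(p) {
  x <- 100 * p
  as.integer(sign(x) * floor(abs(x) + 0.5))
}
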