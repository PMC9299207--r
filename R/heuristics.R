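#' Average cardiac cycle length from the dominant frequency
#'
#' Estimates the dominant pulsatile frequency `f*` of a batch as the argmax
#' of the FFT magnitude restricted to a plausible heart-rate band, and
#' returns the average cycle length `l_x = fs / f*` in samples. The batch is
#' mean-removed before the transform; no taper is applied.
#'
#' Respiratory modulation of the heart rate spreads the pulsatile peak into
#' a cluster of sidebands at `f_hr +/- k * f_resp` whose outer components can
#' individually exceed the carrier; the magnitude spectrum is therefore
#' smoothed with a narrow Gaussian kernel before the argmax, which aggregates
#' each cluster at its center. For an unmodulated tone the kernel is
#' symmetric around the single spectral line, so the estimate stays exact to
#' the FFT bin.
#'
#' @param batch A [signal_stream()] covering at least two complete cycles
#'   (enforced as at least `2 / band[1]` seconds).
#' @param band Frequency search band in Hz.
#' @param smooth_sd_hz Gaussian kernel standard deviation in Hz; `0` disables
#'   smoothing (raw argmax).
#' @return A list of class `cycle_length_estimate` with fields `l_x`
#'   (samples per cycle), `f_star` (Hz), and `n` (batch length in samples).
#' @export
estimate_cycle_length <- function(batch, band = c(0.5, 3.0),
                                  smooth_sd_hz = 0.2) {
  stopifnot(inherits(batch, "signal_stream"))
  n <- length(batch$samples)
  fs <- batch$fs
  if (n / fs < 2 / band[1]) {
    stop("batch too short: need at least ", 2 / band[1],
         " s to contain two cycles at ", band[1], " Hz")
  }
  if (band[2] >= fs / 2) stop("band must lie below the Nyquist frequency")
  x <- batch$samples - mean(batch$samples)
  spec <- Mod(stats::fft(x))
  freqs <- (seq_len(n) - 1) * fs / n
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (length(in_band) == 0) stop("no FFT bins inside the search band")
  score <- if (smooth_sd_hz > 0) {
    df <- fs / n
    half <- as.integer(ceiling(3 * smooth_sd_hz / df))
    kern <- stats::dnorm(seq(-half, half) * df, sd = smooth_sd_hz)
    vapply(in_band, function(i) {
      j <- max(1L, i - half):min(n, i + half)
      sum(spec[j] * kern[j - i + half + 1L])
    }, numeric(1))
  } else {
    spec[in_band]
  }
  f_peak <- freqs[in_band[which.max(score)]]
  # frequency modulation of the period makes the spectral peak sit at the
  # harmonic-mean rate 1/(T_bar * sqrt(1 - fm^2)), while the search windows
  # need the arithmetic-mean period T_bar; the modulation depth is read off
  # the second moment of the raw spectral cluster (sd = f * fm / sqrt(2))
  # and the peak corrected accordingly. An unmodulated tone has a
  # zero-width cluster, so the estimate then reduces to the raw peak.
  cl <- which(freqs >= 0.6 * f_peak & freqs <= 1.6 * f_peak)
  pw <- spec[cl]^2  # power weights: sideband variance is beta^2/2 in power
  wsum <- sum(pw)
  cen <- f_peak
  fm_hat <- 0
  if (wsum > 0) {
    # the cluster's power centroid estimates the harmonic-mean rate more
    # robustly than the (skew-sensitive) peak bin
    cen <- sum(pw * freqs[cl]) / wsum
    sdf <- sqrt(sum(pw * (freqs[cl] - cen)^2) / wsum)
    fm_hat <- min(0.35, sqrt(2) * sdf / cen)
  }
  f_star <- cen * sqrt(1 - fm_hat^2)
  structure(list(l_x = fs / f_star, f_star = f_star, f_peak = f_peak,
                 fm_hat = fm_hat, n = n),
            class = "cycle_length_estimate")
}

#' @export
print.cycle_length_estimate <- function(x, ...) {
  cat(sprintf("<cycle_length_estimate> f* = %.4g Hz, l_x = %.2f samples\n",
              x$f_star, x$l_x))
  invisible(x)
}

#' Candidate cycle endpoints: strict local minima
#'
#' Every strict local minimum of the (filtered) signal is a candidate onset/
#' endpoint. A plateau minimum contributes its first sample only, so ties
#' break deterministically; batch edges are never candidates.
#'
#' @param x Numeric vector or [signal_stream()].
#' @return Increasing integer vector of 1-based candidate indices (possibly
#'   empty).
#' @export
detect_candidates <- function(x) {
  if (inherits(x, "signal_stream")) x <- x$samples
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to detect local minima")
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  is_min <- logical(k)
  is_min[2:(k - 1)] <- r$values[2:(k - 1)] < r$values[1:(k - 2)] &
    r$values[2:(k - 1)] < r$values[3:k]
  starts[is_min]
}

#' Heuristic endpoint likelihood for candidates
#'
#' Scores each candidate by the steepness of the immediately following
#' upstroke: `g` is the maximum of the \[0, 1\]-scaled first derivative over
#' `(candidate, next candidate]` (through the batch end for the last
#' candidate), and the likelihood `p_c` equals `g` since the derivative is
#' already min--max scaled over the batch. A candidate with an empty
#' following region gets `p_c = 0`.
#'
#' @param candidates Integer candidate indices from [detect_candidates()].
#' @param derivative Scaled derivative from [first_derivative()], aligned
#'   with the batch.
#' @return A `data.frame` with columns `index`, `g`, `p_c`.
#' @export
score_candidates <- function(candidates, derivative) {
  n <- length(derivative)
  m <- length(candidates)
  g <- rep(NA_real_, m)
  p <- numeric(m)
  if (m > 0) {
    bounds <- c(candidates[-1], n)
    for (i in seq_len(m)) {
      from <- candidates[i] + 1L
      to <- bounds[i]
      if (from > to) {
        p[i] <- 0
      } else {
        g[i] <- max(derivative[from:to])
        p[i] <- g[i]
      }
    }
  }
  data.frame(index = as.integer(candidates), g = g, p_c = p)
}
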