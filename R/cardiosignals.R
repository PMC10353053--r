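## ECG fiducial measurement and HRV analysis with rat conventions: VLF
## 0-0.15 Hz, LF 0.15-1.5 Hz, HF 1.5-5 Hz; total power over 0-5 Hz. All RR
## intervals in ms, powers in ms^2. Ectopic-flagged intervals are excluded
## from every statistic.

#' Detect R peaks in an ECG trace
#'
#' Energy-based QRS detector: band-pass (5-60 Hz Butterworth, zero-phase),
#' squared derivative, short moving-average integration, fixed threshold at
#' a quantile of the integrated energy, and a 60 ms refractory period. Peak
#' times are refined to the local maximum of the raw trace. Deterministic.
#'
#' @param ecg an \code{\link{ECGRecord}} (>= 500 Hz for downstream interval
#'   measurement; at least ~10 beats of signal).
#' @return an \code{\link{RRSeries}} of the detected beats (no ectopic
#'   flags; see \code{\link{filterEctopicBeats}}).
#' @export
detectRPeaks <- function(ecg) {
  stopifnot(methods::is(ecg, "ECGRecord"))
  fs <- ecg@fsHz
  x <- ecg@samplesMv
  if (length(x) / fs < 1)
    stop("detectRPeaks: record too short")
  bf <- signal::butter(2, c(5, 60) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  energy <- c(0, diff(xf))^2
  w <- max(3L, round(0.02 * fs))                 # 20 ms integration
  energy <- stats::filter(energy, rep(1 / w, w), sides = 2)
  energy[is.na(energy)] <- 0
  thr <- max(0.2 * stats::quantile(energy, 0.995), 1e-9)
  above <- energy > thr
  if (!any(above)) stop("detectRPeaks: no beats detected above threshold")
  refr <- round(0.06 * fs)                       # 60 ms refractory
  half <- round(0.02 * fs)
  ## refine peak positions on a lightly smoothed trace: the R apex is
  ## locally flat, so raw-sample argmax jitters by several samples under
  ## wideband noise
  wr <- max(3L, round(0.0045 * fs))
  xs <- as.numeric(stats::filter(x, rep(1 / wr, wr), sides = 2))
  xs[is.na(xs)] <- 0
  cand <- which(above)
  peaks <- integer()
  last <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    j <- cand[i]
    if (j - last > refr) {
      lo <- max(1L, j - half)
      hi <- min(length(x), j + half)
      pk <- lo + which.max(xs[lo:hi]) - 1L
      if (length(peaks) == 0L || pk - peaks[length(peaks)] > refr) {
        peaks <- c(peaks, pk)
        last <- pk
      }
    }
    i <- i + 1L
  }
  if (length(peaks) < 2L) stop("detectRPeaks: fewer than two beats detected")
  beatT <- (peaks - 1L) / fs
  rr <- diff(beatT) * 1000
  methods::new("RRSeries", rrMs = rr, beatTimesS = beatT[-1L],
               ectopicFlags = rep(FALSE, length(rr)),
               qualityWarning = FALSE)
}

## linear-interpolated crossing time of |x - baseline| over level `thr`,
## scanning away from index `from` in direction `dir`
crossingTime <- function(x, fs, from, dir, thr, maxSamples) {
  n <- length(x)
  i <- from
  steps <- 0L
  while (steps < maxSamples) {
    j <- i + dir
    if (j < 1L || j > n) return(NA_real_)
    if (abs(x[j]) < thr) {
      frac <- (abs(x[i]) - thr) / max(abs(x[i]) - abs(x[j]), .Machine$double.eps)
      return(((i - 1L) + dir * frac) / fs)
    }
    i <- j
    steps <- steps + 1L
  }
  NA_real_
}

#' Measure ECG fiducial intervals
#'
#' Per-beat fiducials around each detected R peak, medians reported across
#' beats. Onsets and offsets are 10\%-of-peak threshold crossings of the
#' baseline-corrected trace (linearly interpolated between samples): QRS
#' onset/offset around the R peak, then the P wave located as the dominant
#' deflection in a pre-QRS search window scaled by the RR interval. PR is
#' the P onset to QRS onset interval; R amplitude is the median
#' peak-to-baseline voltage; heart rate comes from the median RR of the
#' usable beats.
#'
#' @param ecg an \code{\link{ECGRecord}}.
#' @param beats an \code{\link{RRSeries}} from \code{\link{detectRPeaks}}.
#' @return an \code{\link{ECGIntervals}}.
#' @export
measureEcgIntervals <- function(ecg, beats) {
  stopifnot(methods::is(ecg, "ECGRecord"), methods::is(beats, "RRSeries"))
  fs <- ecg@fsHz
  if (fs < 500)
    stop("measureEcgIntervals: sampling rate below 500 Hz")
  rIdx <- round(beats@beatTimesS * fs) + 1L
  rIdx <- c(round((beats@beatTimesS[1L] - beats@rrMs[1L] / 1000) * fs) + 1L,
            rIdx)
  rIdx <- rIdx[rIdx >= 1L & rIdx <= length(ecg@samplesMv)]
  if (length(rIdx) < 10L)
    stop("measureEcgIntervals: fewer than 10 usable beats")
  ## baseline = mode of the voltage distribution (the isoelectric line);
  ## robust to the duty cycle of the waves, unlike the median
  den <- stats::density(ecg@samplesMv, n = 1024)
  baseline <- den$x[which.max(den$y)]
  x <- ecg@samplesMv - baseline
  medRr <- stats::median(beats@rrMs) / 1000
  pr <- pd <- qrs <- ramp <- rep(NA_real_, length(rIdx))
  for (b in seq_along(rIdx)) {
    i <- rIdx[b]
    lo <- max(1L, i - round(0.01 * fs))
    hi <- min(length(x), i + round(0.01 * fs))
    i <- lo + which.max(x[lo:hi]) - 1L            # snap to local max
    rA <- x[i]
    if (rA <= 0) next
    thr <- 0.10 * rA
    win <- round(0.25 * medRr * fs)
    qOn <- crossingTime(x, fs, i, -1L, thr, win)
    qOff <- crossingTime(x, fs, i, +1L, thr, win)
    if (is.na(qOn) || is.na(qOff)) next
    ## P wave: dominant deflection in (qOn - 0.45 RR, qOn)
    pLo <- max(1L, floor((qOn - 0.45 * medRr) * fs) + 1L)
    pHi <- max(1L, floor((qOn - 0.005) * fs))
    if (pHi - pLo < 3L) next
    pIdx <- pLo + which.max(abs(x[pLo:pHi])) - 1L
    pA <- abs(x[pIdx])
    if (pA < 0.02 * rA) next
    pThr <- 0.10 * pA
    pOn <- crossingTime(x, fs, pIdx, -1L, pThr, win)
    pOff <- crossingTime(x, fs, pIdx, +1L, pThr, win)
    if (is.na(pOn) || is.na(pOff)) next
    pr[b] <- qOn - pOn
    pd[b] <- min(pOff, qOn) - pOn
    qrs[b] <- qOff - qOn
    ramp[b] <- rA
  }
  ok <- stats::complete.cases(cbind(pr, pd, qrs, ramp)) &
    pr > 0 & pd > 0 & qrs > 0
  if (sum(ok) < 10L)
    stop("measureEcgIntervals: fewer than 10 cleanly measured beats")
  methods::new("ECGIntervals",
               hrBpm = 60000 / stats::median(beats@rrMs),
               prS = stats::median(pr[ok]),
               pDurS = stats::median(pd[ok]),
               qrsS = stats::median(qrs[ok]),
               rAmpMv = stats::median(ramp[ok]),
               nBeatsUsed = as.integer(sum(ok)))
}

#' Flag ectopic beats in an RR series
#'
#' Flags intervals deviating more than \code{threshold} (default 30\%) from
#' the running median of their 11 nearest neighbours; after a premature
#' (short) flagged interval the immediately following interval (the
#' compensatory pause) is flagged as well. Flagged
#' intervals are excluded from every downstream HRV statistic. If more than
#' 20\% of the intervals end up flagged, a data-quality warning is emitted
#' and recorded on the returned object.
#'
#' @param rr an \code{\link{RRSeries}} with >= 30 intervals.
#' @param threshold fractional deviation above which an interval is flagged.
#' @return the \code{RRSeries} with updated \code{ectopicFlags}.
#' @export
filterEctopicBeats <- function(rr, threshold = 0.30) {
  stopifnot(methods::is(rr, "RRSeries"))
  x <- rr@rrMs
  n <- length(x)
  if (n < 30L) stop("filterEctopicBeats: need at least 30 intervals")
  med <- stats::runmed(x, 11L, endrule = "median")
  dev <- abs(x - med) / med
  flags <- dev > threshold
  ## the compensatory pause follows a premature (short) interval; long
  ## deviations do not trigger the follower rule
  flags <- flags | c(FALSE, (flags & x < med)[-n])
  qwarn <- mean(flags) > 0.20
  if (qwarn)
    warning("filterEctopicBeats: more than 20% of intervals flagged; ",
            "check data quality")
  methods::initialize(rr, ectopicFlags = flags, qualityWarning = qwarn)
}

## successive differences over unflagged adjacent pairs
cleanSuccDiffs <- function(rr) {
  ok <- !rr@ectopicFlags
  keep <- ok[-length(ok)] & ok[-1L]
  diff(rr@rrMs)[keep]
}

#' Time-domain HRV statistics
#'
#' SDRR (sample standard deviation, n - 1 denominator), CVRR (SDRR divided
#' by the mean RR), RMSSD (root mean square of successive differences over
#' unflagged adjacent pairs) and pRR50 (percentage of successive differences
#' exceeding 50 ms; threshold configurable).
#'
#' @param rr an \code{\link{RRSeries}} with >= 30 unflagged intervals.
#' @param prr50ThresholdMs successive-difference threshold (ms), default 50.
#' @return an \code{\link{HRVReport}} with the frequency-domain slots NA.
#' @export
hrvTimeDomain <- function(rr, prr50ThresholdMs = 50) {
  stopifnot(methods::is(rr, "RRSeries"))
  x <- rr@rrMs[!rr@ectopicFlags]
  if (length(x) < 30L)
    stop("hrvTimeDomain: need at least 30 unflagged intervals")
  d <- cleanSuccDiffs(rr)
  methods::new("HRVReport",
               sdrrMs = stats::sd(x),
               cvrr = stats::sd(x) / mean(x),
               rmssdMs = sqrt(mean(d^2)),
               prr50Pct = 100 * mean(abs(d) > prr50ThresholdMs),
               nBeats = length(x))
}

## one-sided Welch periodogram; scaling preserves variance (Parseval):
## integral of the returned PSD over frequency equals the signal variance
welchPsd <- function(x, fs, segmentS = 60, overlap = 0.5) {
  L <- round(segmentS * fs)
  if (length(x) < L)
    stop("record too short for one Welch segment")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))   # Hann
  wnorm <- sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(nf)]
    p <- Mod(X)^2 / (fs * wnorm)
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * fs / L, psd = acc / length(starts))
}

## trapezoid band power with linear interpolation at the exact band edges,
## so adjacent bands partition the spectrum additively
bandPower <- function(freq, psd, lo, hi) {
  if (hi <= freq[1L] || lo >= freq[length(freq)]) return(0)
  lo <- max(lo, freq[1L])
  hi <- min(hi, freq[length(freq)])
  inner <- freq > lo & freq < hi
  f <- c(lo, freq[inner], hi)
  p <- c(stats::approx(freq, psd, lo)$y, psd[inner],
         stats::approx(freq, psd, hi)$y)
  pracma::trapz(f, p)
}

#' Frequency-domain HRV statistics
#'
#' The unflagged beat series is resampled to an evenly spaced tachogram
#' (cubic interpolation at 20 Hz), linearly detrended, and its power
#' spectral density estimated by a Welch periodogram (60 s Hann segments,
#' 50\% overlap). Band powers are trapezoid integrals of the PSD over the
#' rat bands VLF [0, 0.15), LF [0.15, 1.5) and HF [1.5, 5) Hz; total power
#' spans [0, 5) Hz, so the three bands sum exactly to the total.
#'
#' @param rr an \code{\link{RRSeries}}; needs at least one Welch segment
#'   (>= 60 s) of unflagged data, and >= 3 min for stable estimates.
#' @param bandEdgesHz four increasing edges, default \code{c(0, 0.15, 1.5, 5)}.
#' @param resampleHz tachogram sampling rate, default 20.
#' @param segmentS,overlap Welch segment length (s) and fractional overlap.
#' @return an \code{\link{HRVReport}} with the time-domain slots NA.
#' @export
hrvFrequencyDomain <- function(rr, bandEdgesHz = c(0, 0.15, 1.5, 5),
                               resampleHz = 20, segmentS = 60,
                               overlap = 0.5) {
  stopifnot(methods::is(rr, "RRSeries"))
  if (length(bandEdgesHz) != 4L || is.unsorted(bandEdgesHz, strictly = TRUE))
    stop("hrvFrequencyDomain: bandEdgesHz must be four increasing edges")
  ok <- !rr@ectopicFlags
  tb <- rr@beatTimesS[ok]
  xb <- rr@rrMs[ok]
  if (length(xb) < 4L || (max(tb) - min(tb)) < segmentS)
    stop("hrvFrequencyDomain: insufficient data for one Welch segment")
  grid <- seq(min(tb), max(tb), by = 1 / resampleHz)
  tach <- stats::spline(tb, xb, xout = grid)$y
  tach <- stats::lm.fit(cbind(1, grid), tach)$residuals    # linear detrend
  ps <- welchPsd(tach, resampleHz, segmentS, overlap)
  e <- bandEdgesHz
  vlf <- bandPower(ps$freq, ps$psd, e[1L], e[2L])
  lf <- bandPower(ps$freq, ps$psd, e[2L], e[3L])
  hf <- bandPower(ps$freq, ps$psd, e[3L], e[4L])
  total <- bandPower(ps$freq, ps$psd, e[1L], e[4L])
  methods::new("HRVReport", totalPowerMs2 = total, vlfMs2 = vlf, lfMs2 = lf,
               hfMs2 = hf, bandEdgesHz = e, nBeats = length(xb))
}

#' Combined HRV report
#'
#' Convenience wrapper running the ectopic filter (optional), the
#' time-domain and the frequency-domain analyses, returning one complete
#' \code{\link{HRVReport}}.
#'
#' @param rr an \code{\link{RRSeries}}.
#' @param filter apply \code{\link{filterEctopicBeats}} first (default TRUE).
#' @param ectopicThreshold deviation threshold for the ectopic filter.
#' @param ... passed to \code{\link{hrvFrequencyDomain}}.
#' @inheritParams hrvTimeDomain
#' @export
hrvAnalysis <- function(rr, filter = TRUE, ectopicThreshold = 0.30,
                        prr50ThresholdMs = 50, ...) {
  if (filter) rr <- filterEctopicBeats(rr, ectopicThreshold)
  td <- hrvTimeDomain(rr, prr50ThresholdMs)
  fd <- hrvFrequencyDomain(rr, ...)
  methods::new("HRVReport", sdrrMs = td@sdrrMs, cvrr = td@cvrr,
               rmssdMs = td@rmssdMs, prr50Pct = td@prr50Pct,
               totalPowerMs2 = fd@totalPowerMs2, vlfMs2 = fd@vlfMs2,
               lfMs2 = fd@lfMs2, hfMs2 = fd@hfMs2,
               bandEdgesHz = fd@bandEdgesHz, nBeats = td@nBeats)
}
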