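## RR-series phantom: beat intervals produced by modulating the instantaneous
## heart period with band-limited sinusoidal components, plus optional
## ectopic (premature + compensatory) beat pairs with ground-truth flags.

## Fixed modulation frequencies, one physiologic component per rat band:
## VLF thermoregulatory/humoral drift (0.08 Hz), LF vasomotor oscillation
## (0.45 Hz), HF respiratory modulation at an anesthetized-rat breathing
## rate (1.55 Hz, ~93 breaths/min). Beat-interval sampling imposes a hard
## constraint: content above half the mean beat rate (~2.3 Hz at a 218 ms
## mean RR) cannot be represented, so HF content sits at the physiologic
## low end of its 1.5-5 Hz band.
rrModulationFreqs <- function() {
  list(vlf = 0.08, lf = 0.45, hf = 1.55)
}

#' Generate an RR-interval phantom with known band powers
#'
#' Produces a beat-interval series whose instantaneous heart period is the
#' mean RR plus a sum of sinusoids with fixed frequencies inside the rat VLF
#' / LF / HF bands and amplitudes set so each band carries its target power
#' (\eqn{\sum a_i^2/2}). Beat times follow by integrating the instantaneous
#' period. Optional ectopic beats are injected as isolated premature
#' intervals (40\% shortening, keeping the emitted deviation above the 30\%
#' ectopic definition with margin against the underlying modulation)
#' followed by a compensatory lengthening; both intervals are flagged in
#' the ground truth.
#'
#' The ground truth records two band-power readings: \code{analytic_ms2}
#' (\eqn{\sum a_i^2/2} per band) and \code{realized_ms2}, obtained by
#' least-squares projection of the emitted (non-ectopic) RR sequence onto
#' the known modulation sinusoids at the realized beat times - an oracle
#' independent of the spectral analysis pipeline.
#'
#' @param spec a \code{\link{phantomSpec}}; uses \code{meanRrMs},
#'   \code{bandPowerMs2}, \code{ectopicRate}, \code{rrDurationS}, \code{seed}.
#' @return list with \code{rr} (a \code{\link{RRSeries}}, ectopic flags set
#'   to the ground truth) and \code{truth} (band powers, ectopic indices,
#'   modulation parameters).
#' @examples
#' ph <- generateRRSeries(phantomSpec(rrDurationS = 120))
#' ph$rr
#' @export
generateRRSeries <- function(spec) {
  stopifnot(methods::is(spec, "PhantomSpec"))
  set.seed(spec@seed)
  freqs <- rrModulationFreqs()
  targets <- spec@bandPowerMs2[c("vlf", "lf", "hf")]
  comp <- do.call(rbind, lapply(names(freqs), function(b) {
    f <- freqs[[b]]
    a <- if (targets[[b]] > 0) sqrt(2 * targets[[b]] / length(f)) else 0
    data.frame(band = b, freq_hz = f, amp_ms = a,
               phase = stats::runif(length(f), 0, 2 * pi))
  }))
  modAt <- function(t) {
    m <- rep(0, length(t))
    for (i in seq_len(nrow(comp)))
      m <- m + comp$amp_ms[i] *
        sin(2 * pi * comp$freq_hz[i] * t + comp$phase[i])
    m
  }
  ## advance beat times so that each interval equals the instantaneous
  ## period evaluated at the beat's own time: h solves
  ## h = (meanRR + m(t + h)) / 1000. This makes every emitted RR value an
  ## exact sample of the band-limited modulation at the recorded beat time.
  ampSum <- sum(abs(comp$amp_ms))
  hiBound <- (spec@meanRrMs + ampSum) / 1000 + 1e-3
  loBound <- max((spec@meanRrMs - ampSum) / 1000 / 4, 1e-3)
  hGrid <- seq(loBound, hiBound, by = 0.002)
  solveStep <- function(t) {
    ## smallest root: the equation can have several solutions when the
    ## modulation period is comparable to the heart period; taking the
    ## first keeps the beat sequence on one consistent branch
    if (ampSum == 0) return(spec@meanRrMs / 1000)
    g <- function(h) h - (spec@meanRrMs + modAt(t + h)) / 1000
    gv <- hGrid - (spec@meanRrMs + modAt(t + hGrid)) / 1000
    i <- which(gv >= 0)[1L]
    if (is.na(i) || i == 1L) return(spec@meanRrMs / 1000)
    stats::uniroot(g, c(hGrid[i - 1L], hGrid[i]), tol = 1e-10)$root
  }
  nMax <- ceiling(spec@rrDurationS * 1000 / spec@meanRrMs * 2) + 10L
  beatT <- numeric(nMax)
  rr <- numeric(nMax)
  t <- 0
  k <- 0L
  while (t < spec@rrDurationS && k < nMax) {
    step <- solveStep(t)
    k <- k + 1L
    rr[k] <- step * 1000
    t <- t + step
    beatT[k] <- t
  }
  rr <- rr[seq_len(k)]
  beatT <- beatT[seq_len(k)]
  flags <- rep(FALSE, k)
  ectopicIdx <- integer()
  if (spec@ectopicRate > 0 && k > 10L) {
    nEct <- round(spec@ectopicRate * k)
    cand <- sample(seq(6L, k - 6L), min(nEct * 3L, k %/% 4L))
    cand <- sort(cand)
    keep <- integer()
    for (i in cand) {                           # isolated: min gap 4 beats
      if (length(keep) == 0L || i - keep[length(keep)] > 4L)
        keep <- c(keep, i)
      if (length(keep) >= nEct) break
    }
    for (i in keep) {
      short <- 0.40 * rr[i]
      rr[i] <- rr[i] - short
      rr[i + 1L] <- rr[i + 1L] + short          # compensatory pause
      flags[c(i, i + 1L)] <- TRUE
    }
    ectopicIdx <- keep
    beatT <- cumsum(rr) / 1000
  }
  ## realized band powers: LS projection of the clean RR sequence on the
  ## known sinusoid basis at the realized beat times
  ok <- !flags
  realized <- c(vlf = 0, lf = 0, hf = 0)
  if (any(comp$amp_ms > 0) && sum(ok) > 2L * nrow(comp) + 2L) {
    X <- do.call(cbind, lapply(seq_len(nrow(comp)), function(i)
      cbind(sin(2 * pi * comp$freq_hz[i] * beatT[ok]),
            cos(2 * pi * comp$freq_hz[i] * beatT[ok]))))
    fit <- stats::lm.fit(cbind(1, X), rr[ok])
    b <- fit$coefficients[-1L]
    pw <- (b[seq(1, length(b), 2)]^2 + b[seq(2, length(b), 2)]^2) / 2
    realized <- vapply(c("vlf", "lf", "hf"), function(bn)
      sum(pw[comp$band == bn]), numeric(1))
  }
  analytic <- vapply(c("vlf", "lf", "hf"), function(bn)
    sum(comp$amp_ms[comp$band == bn]^2) / 2, numeric(1))
  list(rr = methods::new("RRSeries", rrMs = rr, beatTimesS = beatT,
                         ectopicFlags = flags, qualityWarning = FALSE),
       truth = list(realized_ms2 = realized, analytic_ms2 = analytic,
                    total_realized_ms2 = sum(realized),
                    ectopic_index = ectopicIdx,
                    components = comp, mean_rr_ms = spec@meanRrMs))
}
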