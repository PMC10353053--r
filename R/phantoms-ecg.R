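## ECG phantom: periodic sum of Gaussian bumps (P, QRS triplet, T) with
## exactly known fiducials. Wave widths follow a 10%-of-peak onset/offset
## convention: a Gaussian of nominal duration d has sigma = d / (2 c), with
## c = sqrt(2 ln 10), so its 10% crossings sit exactly d apart. The interval
## measurement operation uses the same 10% convention, making the nominal
## durations recoverable to sub-millisecond accuracy on noise-free traces.

ECG_CROSS10 <- sqrt(2 * log(10))

#' Generate a synthetic rat ECG with known fiducials
#'
#' Builds a periodic ECG at the requested heart rate from Gaussian bumps:
#' P wave (duration \code{p_dur_s}, onset \code{pr_s} before the QRS onset),
#' a QRS triplet (small Q and S deflections around a dominant R of amplitude
#' \code{r_amp_mv} and nominal duration \code{qrs_s}) and a T wave. The
#' ground truth carries the exact per-beat R times and all nominal
#' fiducials.
#'
#' @param spec a \code{\link{phantomSpec}}; uses \code{ecgParams},
#'   \code{ecgFsHz}, \code{ecgDurationS}, \code{seed}.
#' @param noiseSdMv optional additive white Gaussian noise SD (mV).
#' @return list with \code{ecg} (an \code{\link{ECGRecord}}) and
#'   \code{truth} (fiducials and R-peak times).
#' @examples
#' ph <- generateEcg(phantomSpec(ecgDurationS = 10))
#' ph$ecg
#' @export
generateEcg <- function(spec, noiseSdMv = 0) {
  stopifnot(methods::is(spec, "PhantomSpec"))
  set.seed(spec@seed)
  ep <- spec@ecgParams
  hr <- ep[["hr_bpm"]]
  pDur <- ep[["p_dur_s"]]
  pr <- ep[["pr_s"]]
  qrs <- ep[["qrs_s"]]
  rAmp <- ep[["r_amp_mv"]]
  fs <- spec@ecgFsHz
  period <- 60 / hr
  if (pr + qrs >= period)
    stop("generateEcg: fiducials overlap between beats")
  tGrid <- seq(0, spec@ecgDurationS, by = 1 / fs)
  rTimes <- seq(0.5 * period + pr, spec@ecgDurationS - 0.5 * period,
                by = period)
  x <- numeric(length(tGrid))
  bump <- function(center, sigma, amp) {
    if (amp == 0 || sigma <= 0) return(invisible(NULL))
    lo <- max(1L, floor((center - 6 * sigma) * fs) + 1L)
    hi <- min(length(tGrid), ceiling((center + 6 * sigma) * fs) + 1L)
    if (lo > hi) return(invisible(NULL))
    idx <- lo:hi
    x[idx] <<- x[idx] + amp * exp(-(tGrid[idx] - center)^2 / (2 * sigma^2))
    invisible(NULL)
  }
  sigQ <- qrs / (2 * ECG_CROSS10)
  sigP <- pDur / (2 * ECG_CROSS10)
  for (tr in rTimes) {
    qrsOn <- tr - qrs / 2
    bump(tr, sigQ, rAmp)                           # R
    bump(tr - 0.35 * qrs, qrs / 12, -0.06 * rAmp)  # Q
    bump(tr + 0.35 * qrs, qrs / 12, -0.08 * rAmp)  # S
    pOn <- qrsOn - pr
    bump(pOn + pDur / 2, sigP, 0.18 * rAmp)        # P
    bump(tr + qrs / 2 + 0.030, 0.012, 0.25 * rAmp) # T
  }
  if (noiseSdMv > 0) x <- x + stats::rnorm(length(x), 0, noiseSdMv)
  list(ecg = ECGRecord(x, fs),
       truth = list(hr_bpm = hr, pr_s = pr, p_dur_s = pDur, qrs_s = qrs,
                    r_amp_mv = rAmp, r_times_s = rTimes,
                    rr_ms = 60000 / hr))
}
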