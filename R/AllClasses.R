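#' @include AllGenerics.R
NULL

## Central S4 containers. Orientation convention used throughout: space index 1
## is the LV apex, the last index is the base (mitral valve); velocities are in
## cm/s, positive toward the base, so early-diastolic inflow (base -> apex) is
## negative. Pressures are relative to the apex, in mmHg.

MMHG_PER_PA <- 1 / 133.322

#' Space-time transmitral velocity map
#'
#' Holds a color M-mode style velocity field sampled on a regular apex-to-base
#' by time grid, together with the geometry and the Nyquist velocity of the
#' acquisition. Rows are spatial samples (row 1 = apex, last row = base /
#' mitral valve), columns are time samples. Velocities are stored in cm/s,
#' positive toward the base.
#'
#' @slot values numeric matrix of velocities (cm/s), rows = space, cols = time.
#' @slot dsCm spatial step (cm).
#' @slot dtS temporal step (s).
#' @slot lvLengthCm left-ventricular scanline length L (cm).
#' @slot nyquistCms Nyquist (aliasing) velocity (cm/s); \code{NA} if unknown.
#' @slot dealiasWarning logical; set by \code{\link{dealiasVelocity}} when the
#'   unwrapped field still contains inter-sample jumps at or above the Nyquist
#'   velocity, i.e. when unwrapping was ambiguous.
#'
#' @param values,dsCm,dtS,lvLengthCm,nyquistCms see slot descriptions.
#' @param object a \code{VelocityField}.
#' @return \code{VelocityField()} returns a validated object. Accessors return
#'   the corresponding slot; \code{spaceAxis}/\code{timeAxis} return the apex
#'   distance (cm) and time (s) coordinates of the grid.
#' @examples
#' vf <- VelocityField(matrix(0, 8, 16), dsCm = 1.6 / 7, dtS = 0.01,
#'                     lvLengthCm = 1.6, nyquistCms = 60)
#' dim(velocityValues(vf))
#' @export VelocityField
#' @exportClass VelocityField
#' @aliases VelocityField-class velocityValues spatialStep timeStep lvLength
#'   nyquistVelocity spaceAxis timeAxis
setClass("VelocityField",
  representation(values = "matrix", dsCm = "numeric", dtS = "numeric",
                 lvLengthCm = "numeric", nyquistCms = "numeric",
                 dealiasWarning = "logical"),
  prototype(nyquistCms = NA_real_, dealiasWarning = FALSE),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@values) || !all(is.finite(object@values)))
      msg <- c(msg, "'values' must be a finite numeric matrix")
    if (length(object@dsCm) != 1L || object@dsCm <= 0)
      msg <- c(msg, "'dsCm' must be a single positive number")
    if (length(object@dtS) != 1L || object@dtS <= 0)
      msg <- c(msg, "'dtS' must be a single positive number")
    if (length(object@lvLengthCm) != 1L || object@lvLengthCm <= 0)
      msg <- c(msg, "'lvLengthCm' must be a single positive number")
    if (is.numeric(object@values) && nrow(object@values) >= 2 &&
        length(object@dsCm) == 1L && length(object@lvLengthCm) == 1L &&
        is.finite(object@dsCm) &&
        abs(object@dsCm * (nrow(object@values) - 1L) - object@lvLengthCm) >
          1e-6 * max(1, object@lvLengthCm))
      msg <- c(msg, "ds * (n_s - 1) must equal lvLengthCm")
    if (length(object@nyquistCms) != 1L ||
        (!is.na(object@nyquistCms) && object@nyquistCms <= 0))
      msg <- c(msg, "'nyquistCms' must be positive or NA")
    if (length(msg)) msg else TRUE
  })

VelocityField <- function(values, dsCm, dtS, lvLengthCm,
                          nyquistCms = NA_real_) {
  methods::new("VelocityField", values = values, dsCm = dsCm, dtS = dtS,
               lvLengthCm = lvLengthCm, nyquistCms = as.numeric(nyquistCms))
}

#' Relative intraventricular pressure field
#'
#' Relative pressures (mmHg, apex as zero reference) reconstructed from a
#' \code{\link{VelocityField}} by spatial integration of the one-dimensional
#' Euler equation. The total field is the elementwise sum of the inertial
#' (local acceleration) and convective (spatial advection) components; the
#' apex row is identically zero.
#'
#' @slot total,inertial,convective numeric matrices (mmHg), rows = space,
#'   cols = time, sharing the source field's grid.
#' @slot dsCm,dtS,lvLengthCm grid geometry, as in \code{VelocityField}.
#' @slot rhoKgM3 blood density used (kg/m^3).
#' @param object a \code{PressureField}.
#' @return accessors return the corresponding pressure matrix.
#' @seealso \code{\link{eulerPressureField}}, \code{\link{ivpdProfiles}}
#' @export PressureField
#' @exportClass PressureField
#' @aliases PressureField-class pressureTotal pressureInertial
#'   pressureConvective
setClass("PressureField",
  representation(total = "matrix", inertial = "matrix", convective = "matrix",
                 dsCm = "numeric", dtS = "numeric", lvLengthCm = "numeric",
                 rhoKgM3 = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@total)
    if (!identical(d, dim(object@inertial)) ||
        !identical(d, dim(object@convective)))
      msg <- c(msg, "component matrices must share dimensions")
    if (max(abs(object@total - object@inertial - object@convective)) > 1e-10)
      msg <- c(msg, "total must equal inertial + convective (1e-10 mmHg)")
    if (max(abs(object@total[1L, ])) != 0)
      msg <- c(msg, "apex (reference) row must be identically zero")
    if (object@rhoKgM3 <= 0) msg <- c(msg, "'rhoKgM3' must be positive")
    if (length(msg)) msg else TRUE
  })

PressureField <- function(total, inertial, convective, dsCm, dtS, lvLengthCm,
                          rhoKgM3) {
  methods::new("PressureField", total = total, inertial = inertial,
               convective = convective, dsCm = dsCm, dtS = dtS,
               lvLengthCm = lvLengthCm, rhoKgM3 = rhoKgM3)
}

#' IVPD/IVPG profiles and peaks
#'
#' Temporal intraventricular pressure-difference (IVPD, mmHg) and pressure
#' gradient (IVPG = IVPD / LV length, mmHg/cm) profiles for the five standard
#' segments, their peaks inside the analysis window, and the spatial pressure
#' profile at the time of peak total IVPD.
#'
#' Segments, as fractions of the apex-to-base length: apical [0, 1/3],
#' mid [1/3, 2/3], basal [2/3, 1], mid_to_apical [0, 2/3], total [0, 1].
#' Each segmental IVPD(t) is the total-pressure difference between the
#' segment's basal and apical ends, so basal + mid + apical = total exactly.
#'
#' @slot ivpd numeric matrix, rows = time samples, one column per segment
#'   (\code{total}, \code{basal}, \code{mid_to_apical}, \code{mid},
#'   \code{apical}), in mmHg.
#' @slot ivpg same layout, in mmHg/cm (IVPD / L).
#' @slot timeS time axis (s) for the profile rows.
#' @slot peaks data.frame with one row per segment: \code{segment},
#'   \code{ivpd_mmHg}, \code{ivpg_mmHg_cm}, \code{time_s} (peak = maximum of
#'   the signed profile inside the window; earliest time wins ties).
#' @slot spatialProfile data.frame (\code{s_cm}, \code{total},
#'   \code{inertial}, \code{convective}) at the time of peak total IVPD.
#' @slot window numeric length-2 analysis window (s).
#' @slot lvLengthCm LV length used for the IVPG normalization.
#' @param object a \code{IVPGResult}.
#' @param segment segment name for \code{ivpdProfile}.
#' @return \code{ivpdProfile} returns the named temporal profile (mmHg);
#'   \code{ivpgPeaks} the peak table.
#' @seealso \code{\link{ivpdProfiles}}
#' @export
#' @exportClass IVPGResult
#' @aliases IVPGResult-class ivpdProfile ivpgPeaks
setClass("IVPGResult",
  representation(ivpd = "matrix", ivpg = "matrix", timeS = "numeric",
                 peaks = "data.frame", spatialProfile = "data.frame",
                 window = "numeric", lvLengthCm = "numeric"),
  validity = function(object) {
    msg <- character()
    segs <- c("total", "basal", "mid_to_apical", "mid", "apical")
    if (!identical(colnames(object@ivpd), segs))
      msg <- c(msg, "ivpd columns must be the five standard segments")
    if (!identical(dim(object@ivpd), dim(object@ivpg)))
      msg <- c(msg, "ivpd and ivpg must share dimensions")
    if (nrow(object@ivpd) != length(object@timeS))
      msg <- c(msg, "timeS length must match profile rows")
    if (length(object@window) != 2L || diff(object@window) <= 0)
      msg <- c(msg, "window must be an increasing length-2 numeric")
    if (length(msg)) msg else TRUE
  })

#' Beat-interval (RR) series
#'
#' A sequence of RR intervals (ms) with the beat times and per-interval
#' ectopic flags. Flagged intervals are excluded from every HRV statistic.
#'
#' @slot rrMs RR intervals (ms), all positive.
#' @slot beatTimesS time (s) of the beat terminating each interval.
#' @slot ectopicFlags logical, same length as \code{rrMs}.
#' @slot qualityWarning logical; set when the ectopic filter flags more than
#'   20\% of the intervals.
#' @param rrMs,beatTimesS,ectopicFlags see slot descriptions.
#' @param object a \code{RRSeries}.
#' @export RRSeries
#' @exportClass RRSeries
#' @aliases RRSeries-class rrIntervals beatTimes ectopicFlags
setClass("RRSeries",
  representation(rrMs = "numeric", beatTimesS = "numeric",
                 ectopicFlags = "logical", qualityWarning = "logical"),
  prototype(qualityWarning = FALSE),
  validity = function(object) {
    msg <- character()
    if (any(object@rrMs <= 0) || any(!is.finite(object@rrMs)))
      msg <- c(msg, "RR intervals must be positive and finite")
    if (length(object@beatTimesS) != length(object@rrMs) ||
        length(object@ectopicFlags) != length(object@rrMs))
      msg <- c(msg, "rrMs, beatTimesS and ectopicFlags lengths must agree")
    if (length(msg)) msg else TRUE
  })

RRSeries <- function(rrMs, beatTimesS = cumsum(rrMs) / 1000,
                     ectopicFlags = rep(FALSE, length(rrMs))) {
  methods::new("RRSeries", rrMs = as.numeric(rrMs),
               beatTimesS = as.numeric(beatTimesS),
               ectopicFlags = as.logical(ectopicFlags))
}

#' Sampled ECG trace
#'
#' @slot samplesMv voltage samples (mV).
#' @slot fsHz sampling rate (Hz); interval measurement assumes >= 500 Hz.
#' @param samplesMv,fsHz see slot descriptions.
#' @param object a \code{ECGRecord}.
#' @export ECGRecord
#' @exportClass ECGRecord
#' @aliases ECGRecord-class ecgSamples samplingRate recordDuration
setClass("ECGRecord",
  representation(samplesMv = "numeric", fsHz = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(!is.finite(object@samplesMv)))
      msg <- c(msg, "samples must be finite")
    if (length(object@fsHz) != 1L || object@fsHz <= 0)
      msg <- c(msg, "'fsHz' must be a single positive number")
    if (length(msg)) msg else TRUE
  })

ECGRecord <- function(samplesMv, fsHz) {
  methods::new("ECGRecord", samplesMv = as.numeric(samplesMv),
               fsHz = as.numeric(fsHz))
}

#' Median ECG fiducial intervals
#'
#' Per-record summary of the measured ECG fiducials: heart rate, PR interval,
#' P-wave duration, QRS duration and R amplitude (medians across beats).
#'
#' @slot hrBpm,prS,pDurS,qrsS,rAmpMv measured values.
#' @slot nBeatsUsed number of beats entering the medians.
#' @export
#' @exportClass ECGIntervals
#' @aliases ECGIntervals-class
setClass("ECGIntervals",
  representation(hrBpm = "numeric", prS = "numeric", pDurS = "numeric",
                 qrsS = "numeric", rAmpMv = "numeric", nBeatsUsed = "integer"),
  validity = function(object) {
    msg <- character()
    vals <- c(object@hrBpm, object@prS, object@pDurS, object@qrsS,
              object@rAmpMv)
    if (any(vals <= 0, na.rm = TRUE))
      msg <- c(msg, "all measured intervals/amplitudes must be positive")
    if (!is.na(object@pDurS) && !is.na(object@prS) &&
        object@pDurS > object@prS + 1e-9)
      msg <- c(msg, "P duration cannot exceed the PR interval")
    if (length(msg)) msg else TRUE
  })

#' Heart rate variability report
#'
#' Time-domain (SDRR, CVRR, RMSSD, pRR50) and frequency-domain (total, VLF,
#' LF, HF power) HRV statistics. Unavailable halves are NA; see
#' \code{\link{hrvTimeDomain}} and \code{\link{hrvFrequencyDomain}}.
#'
#' Rat frequency bands: VLF 0-0.15 Hz, LF 0.15-1.5 Hz, HF 1.5-5 Hz; total
#' power spans 0-5 Hz, so VLF + LF + HF = total power.
#'
#' @slot sdrrMs,cvrr,rmssdMs,prr50Pct time-domain statistics (ms, unitless,
#'   ms, percent).
#' @slot totalPowerMs2,vlfMs2,lfMs2,hfMs2 band powers (ms^2).
#' @slot bandEdgesHz the four band edges (Hz), default c(0, 0.15, 1.5, 5).
#' @slot nBeats number of unflagged intervals used.
#' @export
#' @exportClass HRVReport
#' @aliases HRVReport-class
setClass("HRVReport",
  representation(sdrrMs = "numeric", cvrr = "numeric", rmssdMs = "numeric",
                 prr50Pct = "numeric", totalPowerMs2 = "numeric",
                 vlfMs2 = "numeric", lfMs2 = "numeric", hfMs2 = "numeric",
                 bandEdgesHz = "numeric", nBeats = "integer"),
  prototype(sdrrMs = NA_real_, cvrr = NA_real_, rmssdMs = NA_real_,
            prr50Pct = NA_real_, totalPowerMs2 = NA_real_, vlfMs2 = NA_real_,
            lfMs2 = NA_real_, hfMs2 = NA_real_,
            bandEdgesHz = c(0, 0.15, 1.5, 5), nBeats = NA_integer_),
  validity = function(object) {
    pw <- c(object@vlfMs2, object@lfMs2, object@hfMs2, object@totalPowerMs2)
    if (any(pw < 0, na.rm = TRUE)) return("band powers must be >= 0")
    if (length(object@bandEdgesHz) != 4L ||
        is.unsorted(object@bandEdgesHz, strictly = TRUE))
      return("bandEdgesHz must be four strictly increasing edges")
    TRUE
  })

setMethod("show", "VelocityField", function(object) {
  cat(sprintf(
    "VelocityField: %d space x %d time samples\n  L = %.3g cm, ds = %.3g cm, dt = %.3g s, Nyquist = %s cm/s\n  velocity range [%.3g, %.3g] cm/s%s\n",
    nrow(object@values), ncol(object@values), object@lvLengthCm, object@dsCm,
    object@dtS,
    ifelse(is.na(object@nyquistCms), "NA", format(object@nyquistCms)),
    min(object@values), max(object@values),
    if (isTRUE(object@dealiasWarning)) "\n  [warning: ambiguous de-aliasing]"
    else ""))
})

setMethod("show", "PressureField", function(object) {
  cat(sprintf(
    "PressureField (relative to apex): %d x %d, rho = %g kg/m^3\n  total pressure range [%.4g, %.4g] mmHg\n",
    nrow(object@total), ncol(object@total), object@rhoKgM3,
    min(object@total), max(object@total)))
})

setMethod("show", "IVPGResult", function(object) {
  cat(sprintf("IVPGResult: window [%.4g, %.4g] s, L = %g cm\n",
              object@window[1], object@window[2], object@lvLengthCm))
  print(object@peaks, row.names = FALSE, digits = 4)
})

setMethod("show", "RRSeries", function(object) {
  cat(sprintf(
    "RRSeries: %d intervals, mean RR %.1f ms, %d flagged ectopic%s\n",
    length(object@rrMs), mean(object@rrMs), sum(object@ectopicFlags),
    if (isTRUE(object@qualityWarning)) " [data-quality warning]" else ""))
})

setMethod("show", "ECGRecord", function(object) {
  cat(sprintf("ECGRecord: %.1f s at %g Hz (%d samples)\n",
              length(object@samplesMv) / object@fsHz, object@fsHz,
              length(object@samplesMv)))
})

setMethod("show", "ECGIntervals", function(object) {
  cat(sprintf(
    "ECGIntervals (medians over %d beats):\n  HR %.1f bpm, PR %.4f s, P %.4f s, QRS %.4f s, R %.3f mV\n",
    object@nBeatsUsed, object@hrBpm, object@prS, object@pDurS, object@qrsS,
    object@rAmpMv))
})

setMethod("show", "HRVReport", function(object) {
  cat("HRVReport\n")
  cat(sprintf("  time domain:  SDRR %.2f ms, CVRR %.4f, RMSSD %.2f ms, pRR50 %.2f %%\n",
              object@sdrrMs, object@cvrr, object@rmssdMs, object@prr50Pct))
  cat(sprintf("  freq domain:  total %.1f, VLF %.1f, LF %.1f, HF %.1f ms^2 (bands %s Hz)\n",
              object@totalPowerMs2, object@vlfMs2, object@lfMs2, object@hfMs2,
              paste(object@bandEdgesHz, collapse = "/")))
})

setMethod("velocityValues", "VelocityField", function(object) object@values)
setMethod("spatialStep", "VelocityField", function(object) object@dsCm)
setMethod("timeStep", "VelocityField", function(object) object@dtS)
setMethod("lvLength", "VelocityField", function(object) object@lvLengthCm)
setMethod("nyquistVelocity", "VelocityField", function(object) object@nyquistCms)
setMethod("spaceAxis", "VelocityField", function(object)
  (seq_len(nrow(object@values)) - 1L) * object@dsCm)
setMethod("timeAxis", "VelocityField", function(object)
  (seq_len(ncol(object@values)) - 1L) * object@dtS)

setMethod("pressureTotal", "PressureField", function(object) object@total)
setMethod("pressureInertial", "PressureField", function(object) object@inertial)
setMethod("pressureConvective", "PressureField",
          function(object) object@convective)

setMethod("rrIntervals", "RRSeries", function(object) object@rrMs)
setMethod("beatTimes", "RRSeries", function(object) object@beatTimesS)
setMethod("ectopicFlags", "RRSeries", function(object) object@ectopicFlags)

setMethod("ecgSamples", "ECGRecord", function(object) object@samplesMv)
setMethod("samplingRate", "ECGRecord", function(object) object@fsHz)
setMethod("recordDuration", "ECGRecord",
          function(object) length(object@samplesMv) / object@fsHz)

setMethod("ivpdProfile", "IVPGResult", function(object, segment = "total") {
  segment <- match.arg(segment, colnames(object@ivpd))
  stats::setNames(object@ivpd[, segment], format(object@timeS))
})
setMethod("ivpgPeaks", "IVPGResult", function(object) object@peaks)
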