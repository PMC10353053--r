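## Color M-mode processing: de-aliasing, smoothing, Euler-equation pressure
## reconstruction and IVPD/IVPG profile extraction.
##
## Discretization: central differences in both axes (one-sided at the
## boundaries) and cumulative trapezoidal integration in space from the apex,
## a standard second-order scheme whose convergence is checked against the
## phantom quadrature oracle in the test suite.

## central difference along rows (space) or columns (time) of a matrix
centralDiff <- function(m, h, along = c("row", "col")) {
  along <- match.arg(along)
  if (along == "col") return(t(centralDiff(t(m), h, "row")))
  n <- nrow(m)
  if (n < 2L) stop("need at least two samples to differentiate")
  d <- m
  d[1L, ] <- (m[2L, ] - m[1L, ]) / h
  d[n, ] <- (m[n, ] - m[n - 1L, ]) / h
  if (n > 2L)
    d[2:(n - 1L), ] <- (m[3:n, ] - m[1:(n - 2L), ]) / (2 * h)
  d
}

#' De-alias a wrapped color-Doppler velocity field
#'
#' Inverts Nyquist wrapping (period \eqn{2 V_{nyq}}) by one-dimensional
#' unwrapping along the time axis within each spatial row, followed by a
#' spatial consistency pass that unwraps the first time column along space
#' and shifts whole rows accordingly. Fields whose true sample-to-sample
#' change is below \eqn{V_{nyq}} (in time within rows, and in space along the
#' first column) and whose apex-onset sample lies inside the Nyquist interval
#' are recovered exactly; already-consistent fields are returned unchanged.
#'
#' If the unwrapped field still contains inter-sample jumps at or above
#' \eqn{V_{nyq}} the unwrapping was ambiguous: the result carries a
#' \code{dealiasWarning} flag (inspect with \code{dealiasWarning()}) and a
#' warning is emitted, never a silent return.
#'
#' @param field a \code{\link{VelocityField}} with Nyquist metadata.
#' @return the unwrapped \code{VelocityField}.
#' @seealso \code{\link{encodeAliasing}} for the forward (wrapping) operator.
#' @export
dealiasVelocity <- function(field) {
  stopifnot(methods::is(field, "VelocityField"))
  vn <- field@nyquistCms
  if (is.na(vn) || vn <= 0)
    stop("dealiasVelocity: positive Nyquist velocity metadata required")
  v <- field@values
  period <- 2 * vn
  nt <- ncol(v)
  ns <- nrow(v)
  if (nt >= 2L) {
    d <- v[, -1L, drop = FALSE] - v[, -nt, drop = FALSE]
    k <- round(d / period)
    if (any(k != 0)) {
      corr <- t(apply(k, 1L, cumsum)) * period
      if (ns == 1L) corr <- matrix(corr, 1L)
      v[, -1L] <- v[, -1L, drop = FALSE] - corr
    }
  }
  if (ns >= 2L) {
    d1 <- diff(v[, 1L])
    k1 <- cumsum(round(d1 / period))
    if (any(k1 != 0))
      v <- v - matrix(c(0, k1) * period, ns, nt)
  }
  ambiguous <- FALSE
  if (nt >= 2L)
    ambiguous <- max(abs(v[, -1L, drop = FALSE] - v[, -nt, drop = FALSE])) >= vn
  if (ambiguous)
    warning("dealiasVelocity: residual jumps >= Nyquist velocity; ",
            "unwrapping may be ambiguous")
  methods::initialize(field, values = v, dealiasWarning = ambiguous)
}

#' @rdname dealiasVelocity
#' @export
dealiasWarning <- function(field) field@dealiasWarning

#' Savitzky-Golay smoothing of a velocity field
#'
#' Separable local-polynomial smoothing along time then space. With
#' \code{smoothing = NULL} the field is returned unchanged. The filter
#' reproduces polynomials up to the chosen order exactly, so smooth
#' low-order structure is preserved while uncorrelated noise is attenuated.
#'
#' @param field a \code{\link{VelocityField}}.
#' @param smoothing \code{NULL} (identity) or a list/vector with
#'   \code{window} (odd, >= 3, smaller than each axis) and \code{order}
#'   (polynomial order < window).
#' @return the smoothed \code{VelocityField}.
#' @export
preprocessVelocity <- function(field, smoothing = NULL) {
  stopifnot(methods::is(field, "VelocityField"))
  if (is.null(smoothing)) return(field)
  sm <- as.list(smoothing)
  if (is.null(names(sm)) || !all(c("window", "order") %in% names(sm)))
    sm <- stats::setNames(sm[1:2], c("window", "order"))
  w <- as.integer(sm$window)
  p <- as.integer(sm$order)
  v <- field@values
  if (w < 3L || w %% 2L == 0L)
    stop("preprocessVelocity: smoothing window must be odd and >= 3")
  if (w > ncol(v) || w > nrow(v))
    stop("preprocessVelocity: smoothing window larger than a field axis")
  if (p >= w) stop("preprocessVelocity: polynomial order must be < window")
  v <- t(apply(v, 1L, function(x) signal::sgolayfilt(x, p = p, n = w)))
  v <- apply(v, 2L, function(x) signal::sgolayfilt(x, p = p, n = w))
  methods::initialize(field, values = v)
}

#' Reconstruct relative pressures from the Euler equation
#'
#' Evaluates the one-dimensional Euler relation
#' \deqn{\partial P/\partial s = -\rho\,(\partial v/\partial t +
#'   v\,\partial v/\partial s)}
#' on the velocity grid (central differences, one-sided at the boundaries),
#' splits the pressure gradient into its inertial (local acceleration) and
#' convective (spatial advection) parts, and integrates each in space from
#' the apex by cumulative trapezoid with \eqn{P(\mathrm{apex}) = 0}.
#' Pressures are returned in mmHg; the total field is the sum of the two
#' components.
#'
#' @param field a de-aliased, finite \code{\link{VelocityField}}.
#' @param rhoKgM3 blood density (kg/m^3), default 1060.
#' @return a \code{\link{PressureField}}.
#' @examples
#' ## spatially uniform ramp v = a t: IVPD = -rho a L, no convective part
#' ns <- 16; nt <- 32
#' v <- matrix(rep(100 * seq(0, 0.1, length.out = nt), each = ns), ns)
#' f <- VelocityField(v, dsCm = 1.6 / (ns - 1), dtS = 0.1 / (nt - 1),
#'                    lvLengthCm = 1.6)
#' p <- eulerPressureField(f)
#' pressureTotal(p)[ns, 5] # ~ -0.127 mmHg
#' @export
eulerPressureField <- function(field, rhoKgM3 = 1060) {
  stopifnot(methods::is(field, "VelocityField"))
  if (!all(is.finite(field@values)))
    stop("eulerPressureField: velocity field contains non-finite values")
  if (rhoKgM3 <= 0) stop("eulerPressureField: density must be positive")
  vm <- field@values / 100                       # m/s
  dsM <- field@dsCm / 100
  vt <- centralDiff(vm, field@dtS, "col")
  vs <- centralDiff(vm, dsM, "row")
  gradInertial <- -rhoKgM3 * vt                  # Pa/m
  gradConvective <- -rhoKgM3 * vm * vs
  sM <- (seq_len(nrow(vm)) - 1L) * dsM
  inertial <- pracma::cumtrapz(sM, gradInertial) * MMHG_PER_PA
  convective <- pracma::cumtrapz(sM, gradConvective) * MMHG_PER_PA
  PressureField(total = inertial + convective, inertial = inertial,
                convective = convective, dsCm = field@dsCm, dtS = field@dtS,
                lvLengthCm = field@lvLengthCm, rhoKgM3 = rhoKgM3)
}

## linear interpolation of a pressure matrix at normalized position u (0 =
## apex row, 1 = base row); returns the time profile
pressureAtU <- function(p, u) {
  ns <- nrow(p)
  x <- u * (ns - 1L)
  i <- min(floor(x), ns - 2L)
  frac <- x - i
  p[i + 1L, ] * (1 - frac) + p[i + 2L, ] * frac
}

#' Temporal and spatial IVPD/IVPG profiles
#'
#' Extracts the intraventricular pressure-difference profiles from a
#' reconstructed \code{\link{PressureField}}. With normalized apex-to-base
#' position \eqn{u = s/L}, the segments are apical \eqn{[0, 1/3]}, mid
#' \eqn{[1/3, 2/3]}, basal \eqn{[2/3, 1]} (the one-third basal / two-thirds
#' mid-apical convention) and mid-to-apical \eqn{[0, 2/3]}. Each segmental
#' IVPD(t) is the total-pressure difference across the segment, the total
#' IVPD is base minus apex, and IVPG = IVPD / L. Peaks are maxima of the
#' signed profiles inside the analysis window (earliest time wins ties,
#' reported at sample resolution); the spatial profile is extracted at the
#' time of peak total IVPD.
#'
#' @param pressure a \code{\link{PressureField}}.
#' @param window numeric length-2 analysis window (s), e.g. from
#'   \code{\link{detectDiastolicWindow}}; default the full record.
#' @return an \code{\link{IVPGResult}}.
#' @export
ivpdProfiles <- function(pressure, window = NULL) {
  stopifnot(methods::is(pressure, "PressureField"))
  p <- pressure@total
  nt <- ncol(p)
  tS <- (seq_len(nt) - 1L) * pressure@dtS
  if (is.null(window)) window <- c(tS[1L], tS[nt])
  if (length(window) != 2L || window[1L] < tS[1L] - 1e-12 ||
      window[2L] > tS[nt] + 1e-12 || window[2L] <= window[1L])
    stop("ivpdProfiles: window must lie inside the recorded time axis")
  inWin <- which(tS >= window[1L] - 1e-12 & tS <= window[2L] + 1e-12)
  if (length(inWin) < 3L)
    stop("ivpdProfiles: analysis window shorter than 3 samples")
  pAt <- list(a0 = pressureAtU(p, 0), a13 = pressureAtU(p, 1 / 3),
              a23 = pressureAtU(p, 2 / 3), a1 = pressureAtU(p, 1))
  ivpd <- cbind(total = pAt$a1 - pAt$a0,
                basal = pAt$a1 - pAt$a23,
                mid_to_apical = pAt$a23 - pAt$a0,
                mid = pAt$a23 - pAt$a13,
                apical = pAt$a13 - pAt$a0)
  L <- pressure@lvLengthCm
  ivpg <- ivpd / L
  peakIdx <- vapply(colnames(ivpd), function(seg)
    inWin[which.max(ivpd[inWin, seg])], integer(1))
  peaks <- data.frame(
    segment = colnames(ivpd),
    ivpd_mmHg = ivpd[cbind(peakIdx, seq_len(ncol(ivpd)))],
    ivpg_mmHg_cm = ivpg[cbind(peakIdx, seq_len(ncol(ivpd)))],
    time_s = tS[peakIdx],
    row.names = NULL, stringsAsFactors = FALSE)
  jPeak <- peakIdx[1L]                            # time of peak total IVPD
  spatial <- data.frame(
    s_cm = (seq_len(nrow(p)) - 1L) * pressure@dsCm,
    total = p[, jPeak],
    inertial = pressure@inertial[, jPeak],
    convective = pressure@convective[, jPeak])
  methods::new("IVPGResult", ivpd = ivpd, ivpg = ivpg, timeS = tS,
               peaks = peaks, spatialProfile = spatial,
               window = as.numeric(window), lvLengthCm = L)
}

#' Detect the diastolic analysis window of an inflow record
#'
#' Locates the filling phase around the dominant inflow wave from the
#' spatial-mean velocity magnitude \eqn{m(t)}: the window starts at the last
#' time before the E-wave crest at which \eqn{m(t)} sits at the zero floor
#' (below 5\% of the crest, or a sign change of the signed mean) and ends at
#' the first return of \eqn{m(t)} below 5\% of the crest after the last wave,
#' or at the end of the record. The returned window always contains the
#' global velocity maximum. An explicitly supplied window is echoed verbatim
#' with no detection.
#'
#' @param field a \code{\link{VelocityField}} containing at least one inflow
#'   wave.
#' @param window optional explicit window (s), returned unchanged.
#' @return numeric length-2: \code{c(t_start, t_end)} in seconds.
#' @export
detectDiastolicWindow <- function(field, window = NULL) {
  stopifnot(methods::is(field, "VelocityField"))
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, diff(window) > 0)
    return(as.numeric(window))
  }
  mSigned <- colMeans(field@values)
  m <- abs(mSigned)
  if (max(m) == 0)
    stop("detectDiastolicWindow: all-zero field (no flow)")
  tS <- (seq_len(length(m)) - 1L) * field@dtS
  crest <- which.max(m)
  floorLev <- 0.05 * m[crest]
  before <- which(seq_along(m) < crest &
                  (m < floorLev | c(FALSE, diff(sign(mSigned)) != 0)[seq_along(m)]))
  tStart <- if (length(before)) tS[max(before)] else tS[1L]
  lastAbove <- max(which(m >= floorLev))
  tEnd <- if (lastAbove < length(m)) tS[lastAbove + 1L] else tS[length(m)]
  c(tStart, tEnd)
}
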