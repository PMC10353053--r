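## Velocity-field phantom: closed-form transmitral inflow templates with an
## independent quadrature ground truth for the Euler-equation pressure
## reconstruction. All templates are differentiable in closed form, so the
## ground-truth IVPD comes from integrating -rho*(dv/dt + v*dv/ds) at high
## spatial resolution, never from the discrete pipeline under test.

## closed-form template factory: returns v, dv/dt, dv/ds as functions of
## (s_m, t_s) in SI units (m, s, m/s)
velocityTemplate <- function(spec, template = c("ea", "ramp", "shear"),
                             rampAccelCmS2 = 100, shearPerS = 50) {
  template <- match.arg(template)
  L <- spec@lvLengthCm / 100
  if (template == "ramp") {
    a <- rampAccelCmS2 / 100                     # m/s^2, uniform in space
    return(list(v = function(s, t) a * t + 0 * s,
                vt = function(s, t) a + 0 * s + 0 * t,
                vs = function(s, t) 0 * s + 0 * t))
  }
  if (template == "shear") {
    k <- shearPerS                               # 1/s, steady shear v = k*s
    return(list(v = function(s, t) k * s + 0 * t,
                vt = function(s, t) 0 * s + 0 * t,
                vs = function(s, t) k + 0 * s + 0 * t))
  }
  ## E/A bimodal inflow: base-to-apex propagating Gaussian waves under a
  ## smoothstep spatial envelope (0 at apex, 1 at base); inflow is negative
  ## (toward the apex) under the package orientation convention
  E <- spec@ePeakCms / 100
  A <- spec@aPeakCms / 100
  w <- spec@waveWidthS
  vp <- spec@propagationCmS / 100
  tE <- 0.25 * spec@velDurationS
  tA <- tE + spec@eaSeparationS
  env <- function(u) u * u * (3 - 2 * u)
  denv <- function(u) 6 * u * (1 - u)
  g <- function(x) exp(-x^2 / (2 * w^2))
  dg <- function(x) -x / w^2 * g(x)
  arg <- function(s, t) t - (L - s) / vp
  list(
    v = function(s, t) {
      x <- arg(s, t)
      -env(s / L) * (E * g(x - tE) + A * g(x - tA))
    },
    vt = function(s, t) {
      x <- arg(s, t)
      -env(s / L) * (E * dg(x - tE) + A * dg(x - tA))
    },
    vs = function(s, t) {
      x <- arg(s, t)
      -denv(s / L) / L * (E * g(x - tE) + A * g(x - tA)) -
        env(s / L) * (E * dg(x - tE) + A * dg(x - tA)) / vp
    })
}

## high-resolution quadrature of the Euler relation for a closed-form
## template; returns IVPD (mmHg) per segment at the supplied times
quadratureIvpd <- function(tmpl, lvLengthCm, rhoKgM3, timeS, refine = 10L,
                           nsBase = 64L) {
  L <- lvLengthCm / 100
  segs <- list(total = c(0, 1), basal = c(2 / 3, 1),
               mid_to_apical = c(0, 2 / 3), mid = c(1 / 3, 2 / 3),
               apical = c(0, 1 / 3))
  out <- matrix(NA_real_, length(timeS), length(segs),
                dimnames = list(NULL, names(segs)))
  for (k in seq_along(segs)) {
    npt <- max(64L, refine * nsBase) + 1L
    s <- seq(segs[[k]][1] * L, segs[[k]][2] * L, length.out = npt)
    for (j in seq_along(timeS)) {
      t <- timeS[j]
      integrand <- -rhoKgM3 * (tmpl$vt(s, t) + tmpl$v(s, t) * tmpl$vs(s, t))
      out[j, k] <- pracma::trapz(s, integrand) * MMHG_PER_PA
    }
  }
  out
}

#' Generate a transmitral velocity-field phantom with pressure ground truth
#'
#' Builds a space-time velocity map from a closed-form inflow template and
#' attaches the ground-truth IVPD profiles computed by high-resolution
#' quadrature of the one-dimensional Euler relation applied to the same
#' closed form (independent of the discrete reconstruction pipeline).
#'
#' The default \code{"ea"} template is a bimodal E/A-wave inflow: Gaussian
#' waves in time, delayed linearly with distance from the base (base-to-apex
#' propagation at \code{propagationCmS}), under a smoothstep spatial envelope
#' that vanishes at the apex and peaks at the mitral valve. Inflow is signed
#' negative (toward the apex). The \code{"ramp"} (spatially uniform
#' \eqn{v = a t}) and \code{"shear"} (steady \eqn{v = k s}) templates have
#' closed-form IVPDs (\eqn{-\rho a L} and \eqn{-\rho k^2 L^2 / 2}) and exist
#' for verification.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param template one of \code{"ea"}, \code{"ramp"}, \code{"shear"}.
#' @param rampAccelCmS2 acceleration for the ramp template (cm/s^2).
#' @param shearPerS shear rate for the shear template (1/s).
#' @param oracleRefine spatial refinement factor of the quadrature oracle
#'   relative to the phantom grid.
#' @return list with elements \code{field} (a \code{\link{VelocityField}})
#'   and \code{truth}: \code{ivpd_mmHg} (time x segment matrix from the
#'   quadrature oracle), \code{time_s}, and the template parameters.
#' @examples
#' ph <- generateVelocityPhantom(phantomSpec(gridNs = 16L, gridNt = 64L))
#' ph$field
#' max(abs(velocityValues(ph$field)))
#' @export
generateVelocityPhantom <- function(spec, template = c("ea", "ramp", "shear"),
                                    rampAccelCmS2 = 100, shearPerS = 50,
                                    oracleRefine = 10L) {
  stopifnot(methods::is(spec, "PhantomSpec"))
  template <- match.arg(template)
  ns <- spec@gridNs
  nt <- spec@gridNt
  L <- spec@lvLengthCm
  ds <- L / (ns - 1L)
  dt <- spec@velDurationS / (nt - 1L)
  sM <- (seq_len(ns) - 1L) * ds / 100
  tS <- (seq_len(nt) - 1L) * dt
  tmpl <- velocityTemplate(spec, template, rampAccelCmS2, shearPerS)
  vals <- outer(sM, tS, tmpl$v) * 100           # back to cm/s
  field <- methods::new("VelocityField", values = vals, dsCm = ds, dtS = dt,
                        lvLengthCm = L, nyquistCms = spec@nyquistCms)
  truth <- list(
    ivpd_mmHg = quadratureIvpd(tmpl, L, spec@rhoKgM3, tS,
                               refine = as.integer(oracleRefine),
                               nsBase = ns),
    time_s = tS, template = template, rho_kg_m3 = spec@rhoKgM3,
    lv_length_cm = L)
  list(field = field, truth = truth)
}

#' Wrap a velocity field into the Nyquist interval (aliasing encoder)
#'
#' Applies the color-Doppler aliasing operator: every sample is wrapped into
#' \eqn{[-V_{nyq}, +V_{nyq})} by modular arithmetic with period
#' \eqn{2 V_{nyq}}. The inverse operation is \code{\link{dealiasVelocity}}.
#' Idempotent on fields already inside the Nyquist interval.
#'
#' @param field a \code{\link{VelocityField}} with Nyquist metadata.
#' @return a \code{VelocityField} with wrapped values.
#' @export
encodeAliasing <- function(field) {
  stopifnot(methods::is(field, "VelocityField"))
  vn <- field@nyquistCms
  if (is.na(vn))
    stop("encodeAliasing: field has no Nyquist velocity metadata")
  wrapped <- field@values
  out <- wrapped < -vn | wrapped >= vn
  wrapped[out] <- ((wrapped[out] + vn) %% (2 * vn)) - vn
  methods::initialize(field, values = wrapped)
}

#' Random smooth velocity field
#'
#' Sum of a few low-frequency space-time cosine modes under a temporal onset
#' envelope that keeps the first time column at zero (flow onset), scaled to
#' a prescribed peak speed. Used for de-aliasing round-trip and smoothing
#' property checks.
#'
#' @param nS,nT grid sizes.
#' @param peakCms target peak |velocity| (cm/s).
#' @param nyquistCms Nyquist metadata attached to the field.
#' @param lvLengthCm,durationS geometry.
#' @param seed RNG seed.
#' @param nModes number of cosine modes.
#' @return a \code{\link{VelocityField}}.
#' @export
randomSmoothField <- function(nS = 32L, nT = 64L, peakCms = 100,
                              nyquistCms = 60, lvLengthCm = 1.6,
                              durationS = 0.16, seed = 1L, nModes = 4L) {
  set.seed(seed)
  u <- seq(0, 1, length.out = nS)
  tau <- seq(0, 1, length.out = nT)
  vals <- matrix(0, nS, nT)
  for (i in seq_len(nModes)) {
    a <- stats::runif(1, 0, 1.5)       # spatial cycles
    b <- stats::runif(1, 0.25, 2)      # temporal cycles (kept low: smooth)
    phi <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.3, 1)
    vals <- vals + amp * outer(u, tau, function(x, y)
      cos(2 * pi * (a * x + b * y) + phi))
  }
  vals <- vals * matrix(sin(pi * tau / 2)^2, nS, nT, byrow = TRUE)
  m <- max(abs(vals))
  if (m > 0) vals <- vals * (peakCms / m)
  methods::new("VelocityField", values = vals,
               dsCm = lvLengthCm / (nS - 1L), dtS = durationS / (nT - 1L),
               lvLengthCm = lvLengthCm, nyquistCms = nyquistCms)
}
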