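## PhantomSpec: the single parameter bundle behind every synthetic generator.
## Defaults reproduce the study conditions of a three-arm rat MI cohort
## (sham / MI / MI+TRE, n = 8 each); see the methods vignette for provenance
## of each default.

#' Parameter bundle for the synthetic-data generators
#'
#' A \code{PhantomSpec} drives every synthetic generator in the package
#' (velocity fields, RR series, ECG traces, lesion images, cohorts, qPCR
#' plates). Each generator reads only the slots it needs; every generator is
#' a pure function of the spec (same seed, same output).
#'
#' @slot seed integer RNG seed.
#' @slot lvLengthCm apex-to-base scanline length (cm); default 1.6, a typical
#'   adult-rat LV long axis.
#' @slot gridNs,gridNt velocity-field grid sizes (space, time), both >= 8.
#' @slot ePeakCms,aPeakCms peak early (E) and late (A) transmitral inflow
#'   speeds (cm/s). Defaults 77.01 and 37.73 (sham-group means).
#' @slot eaSeparationS time between the E and A wave crests (s).
#' @slot waveWidthS Gaussian time width (sigma, s) of each inflow wave.
#' @slot propagationCmS base-to-apex flow propagation speed (cm/s).
#' @slot velDurationS duration of the velocity record (s).
#' @slot nyquistCms color-Doppler Nyquist velocity (cm/s).
#' @slot rhoKgM3 blood density (kg/m^3), default 1060.
#' @slot meanRrMs mean RR interval for the RR-series phantom (ms); default
#'   60000/275.4 (sham heart rate).
#' @slot bandPowerMs2 named target band powers (ms^2) for \code{vlf},
#'   \code{lf}, \code{hf}; defaults are the sham-group values 162.3, 524.4,
#'   2162.
#' @slot ectopicRate fraction of beats replaced by an ectopic (premature +
#'   compensatory) pair, in [0, 1].
#' @slot rrDurationS RR record length (s), default 600 (10 min).
#' @slot ecgParams named numeric: \code{hr_bpm}, \code{p_dur_s}, \code{pr_s},
#'   \code{qrs_s}, \code{r_amp_mv}; defaults are the sham ECG means
#'   (275.4 bpm, 0.020 s, 0.052 s, 0.022 s, 0.940 mV).
#' @slot ecgFsHz ECG sampling rate (Hz), default 2000.
#' @slot ecgDurationS ECG trace length (s), default 60.
#' @slot lesionFraction fraction of the image covered by the lesion, (0, 1).
#' @slot lesionGray,backgroundGray 8-bit gray levels (0-255).
#' @slot imageSize image height and width in pixels.
#' @slot imageNoise half-width of the uniform integer noise added to every
#'   pixel (gray levels; 0 = noise free).
#' @slot cohortDesign data.frame (\code{group}, \code{n}, \code{parameter},
#'   \code{mean}, \code{sd}); default \code{\link{defaultCohortDesign}()}.
#' @slot qpcrDesign data.frame (\code{gene}, \code{group}, \code{fold}) of
#'   true expression fold changes relative to the control group; the
#'   reference gene is implicit (fold 1 everywhere).
#' @slot qpcrNoiseSd per-well Ct noise SD (cycles).
#'
#' @param ... named slot overrides, e.g. \code{phantomSpec(seed = 7,
#'   ePeakCms = 60)}.
#' @return a validated \code{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(seed = 1)
#' spec
#' @export phantomSpec
#' @exportClass PhantomSpec
#' @aliases PhantomSpec-class
setClass("PhantomSpec",
  representation(seed = "integer", lvLengthCm = "numeric",
                 gridNs = "integer", gridNt = "integer",
                 ePeakCms = "numeric", aPeakCms = "numeric",
                 eaSeparationS = "numeric", waveWidthS = "numeric",
                 propagationCmS = "numeric", velDurationS = "numeric",
                 nyquistCms = "numeric", rhoKgM3 = "numeric",
                 meanRrMs = "numeric", bandPowerMs2 = "numeric",
                 ectopicRate = "numeric", rrDurationS = "numeric",
                 ecgParams = "numeric", ecgFsHz = "numeric",
                 ecgDurationS = "numeric", lesionFraction = "numeric",
                 lesionGray = "integer", backgroundGray = "integer",
                 imageSize = "integer", imageNoise = "numeric",
                 cohortDesign = "data.frame", qpcrDesign = "data.frame",
                 qpcrNoiseSd = "numeric"),
  validity = function(object) {
    msg <- character()
    pos <- c(lvLengthCm = object@lvLengthCm, eaSeparationS = object@eaSeparationS,
             waveWidthS = object@waveWidthS, propagationCmS = object@propagationCmS,
             velDurationS = object@velDurationS, nyquistCms = object@nyquistCms,
             rhoKgM3 = object@rhoKgM3, meanRrMs = object@meanRrMs,
             rrDurationS = object@rrDurationS, ecgFsHz = object@ecgFsHz,
             ecgDurationS = object@ecgDurationS)
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    if (length(bad))
      msg <- c(msg, paste0("must be strictly positive: ",
                           paste(bad, collapse = ", ")))
    if (object@gridNs < 8L || object@gridNt < 8L)
      msg <- c(msg, "grid sizes must be >= 8")
    if (object@ePeakCms < 0 || object@aPeakCms < 0)
      msg <- c(msg, "wave peak speeds must be >= 0")
    if (any(object@bandPowerMs2 < 0) ||
        !all(c("vlf", "lf", "hf") %in% names(object@bandPowerMs2)))
      msg <- c(msg, "bandPowerMs2 needs non-negative vlf/lf/hf entries")
    if (object@ectopicRate < 0 || object@ectopicRate > 1)
      msg <- c(msg, "ectopicRate must lie in [0, 1]")
    ep <- object@ecgParams
    need <- c("hr_bpm", "p_dur_s", "pr_s", "qrs_s", "r_amp_mv")
    if (!all(need %in% names(ep))) {
      msg <- c(msg, "ecgParams must name hr_bpm, p_dur_s, pr_s, qrs_s, r_amp_mv")
    } else {
      if (ep["hr_bpm"] <= 50 || ep["hr_bpm"] >= 600)
        msg <- c(msg, "ecgParams['hr_bpm'] must lie in (50, 600)")
      if (ep["p_dur_s"] > ep["pr_s"])
        msg <- c(msg, "P duration cannot exceed the PR interval")
      if (ep["pr_s"] + ep["qrs_s"] >= 60 / ep["hr_bpm"])
        msg <- c(msg, "ECG waves must fit within one RR interval")
      if (ep["r_amp_mv"] < 0) msg <- c(msg, "R amplitude must be >= 0")
    }
    if (object@lesionFraction <= 0 || object@lesionFraction >= 1)
      msg <- c(msg, "lesionFraction must lie in (0, 1)")
    gl <- c(object@lesionGray, object@backgroundGray)
    if (any(gl < 0L) || any(gl > 255L))
      msg <- c(msg, "gray levels must lie in [0, 255]")
    if (any(object@imageSize < 8L))
      msg <- c(msg, "imageSize must be >= 8 in both dimensions")
    cd <- object@cohortDesign
    if (!all(c("group", "n", "parameter", "mean", "sd") %in% names(cd)))
      msg <- c(msg, "cohortDesign needs columns group, n, parameter, mean, sd")
    else {
      if (any(cd$sd < 0)) msg <- c(msg, "cohortDesign sds must be >= 0")
      nn <- unique(cd[, c("group", "n")])
      if (anyDuplicated(nn$group))
        msg <- c(msg, "duplicate group names with conflicting n in cohortDesign")
    }
    qd <- object@qpcrDesign
    if (!all(c("gene", "group", "fold") %in% names(qd)))
      msg <- c(msg, "qpcrDesign needs columns gene, group, fold")
    else if (any(qd$fold <= 0))
      msg <- c(msg, "qpcrDesign fold targets must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Default three-arm echocardiography cohort design
#'
#' The per-group means and SDs used by \code{\link{generateCohort}} for a
#' sham / MI / MI+TRE design with n = 8 per group, covering the sixteen
#' conventional echocardiographic parameters (dimensions, EF, FS, transmitral
#' and tissue-Doppler indices).
#'
#' @return data.frame with columns \code{group}, \code{n}, \code{parameter},
#'   \code{mean}, \code{sd}.
#' @export
defaultCohortDesign <- function() {
  par <- c("IVSd", "IVSs", "LVIDd", "LVIDs", "LVPWd", "LVPWs", "EF", "FS",
           "eV", "aV", "EA", "Sm", "Em", "Am", "EEm", "EmAm")
  sham <- c(1.852, 3.104, 7.076, 3.656, 2.260, 3.152, 88.20, 51.28,
            77.01, 37.73, 1.825, 4.852, 6.750, 4.287, 10.06, 1.556)
  sham_sd <- c(0.154, 0.360, 0.704, 0.232, 0.373, 0.355, 1.384, 2.114,
               2.855, 7.530, 0.212, 0.650, 0.681, 0.399, 0.933, 0.145)
  mi <- c(1.532, 2.056, 8.604, 5.616, 2.068, 2.388, 65.39, 29.86,
          62.64, 42.71, 1.478, 3.540, 4.970, 4.663, 14.00, 1.163)
  mi_sd <- c(0.162, 0.192, 0.667, 0.202, 0.140, 0.214, 1.982, 1.302,
             5.224, 5.066, 0.287, 0.555, 0.503, 0.455, 2.627, 0.045)
  tre <- c(1.808, 2.865, 7.774, 5.284, 2.230, 3.055, 76.53, 38.37,
           73.26, 39.48, 1.937, 4.147, 5.383, 3.910, 13.49, 1.402)
  tre_sd <- c(0.090, 0.138, 1.090, 0.258, 0.302, 0.262, 0.852, 0.745,
              11.44, 7.126, 0.586, 0.738, 0.359, 0.544, 1.230, 0.253)
  data.frame(
    group = rep(c("Sham", "MI", "MI+TRE"), each = length(par)),
    n = 8L,
    parameter = rep(par, 3L),
    mean = c(sham, mi, tre),
    sd = c(sham_sd, mi_sd, tre_sd),
    stringsAsFactors = FALSE)
}

#' Default per-group ECG fiducial parameters
#'
#' Group means and SDs (sham / MI / MI+TRE) for heart rate, PR interval,
#' P duration, QRS duration and R amplitude, used by the workflow to draw
#' per-subject ECG phantom parameters.
#'
#' @return data.frame with columns \code{group}, \code{parameter},
#'   \code{mean}, \code{sd}.
#' @export
defaultEcgDesign <- function() {
  par <- c("hr_bpm", "pr_s", "p_dur_s", "qrs_s", "r_amp_mv")
  data.frame(
    group = rep(c("Sham", "MI", "MI+TRE"), each = length(par)),
    parameter = rep(par, 3L),
    mean = c(275.4, 0.052, 0.020, 0.022, 0.940,
             136.5, 0.075, 0.034, 0.024, 0.623,
             194.1, 0.051, 0.021, 0.015, 0.774),
    sd = c(10.08, 0.004, 0.004, 0.001, 0.083,
           21.22, 0.005, 0.002, 0.0009, 0.156,
           25.00, 0.007, 0.007, 0.006, 0.286),
    stringsAsFactors = FALSE)
}

#' Default per-group HRV band-power targets
#'
#' Group targets (ms^2) for the VLF / LF / HF bands and the group mean RR,
#' used by the workflow when generating per-subject RR phantoms. The MI+TRE
#' HF value is not separately reported for the source cohort and is set to a
#' sham-like 2000 ms^2.
#'
#' @return data.frame with columns \code{group}, \code{mean_rr_ms},
#'   \code{vlf}, \code{lf}, \code{hf}.
#' @export
defaultHrvDesign <- function() {
  data.frame(
    group = c("Sham", "MI", "MI+TRE"),
    mean_rr_ms = 60000 / c(275.4, 136.5, 194.1),
    vlf = c(162.3, 197.9, 194.7),
    lf = c(524.4, 560.6, 411.3),
    hf = c(2162, 1578, 2000),
    stringsAsFactors = FALSE)
}

defaultQpcrDesign <- function() {
  genes <- c("IL-1b", "TNF-a", "IL-18", "Bcl-2", "BAX", "SOD1", "SOD2",
             "SOD3")
  ## inflammatory/apoptotic genes up in MI, partially restored by treatment;
  ## folds are generator truths for the synthetic study, not measurements
  mi_fold <- c(3.0, 2.5, 2.0, 0.5, 2.2, 0.6, 0.6, 0.7)
  tre_fold <- c(1.5, 1.3, 1.2, 0.8, 1.3, 0.9, 0.9, 0.9)
  data.frame(
    gene = rep(genes, 3L),
    group = rep(c("Sham", "MI", "MI+TRE"), each = length(genes)),
    fold = c(rep(1, length(genes)), mi_fold, tre_fold),
    stringsAsFactors = FALSE)
}

#' @rdname PhantomSpec-class
#' @export
phantomSpec <- function(...) {
  args <- list(...)
  defaults <- list(
    seed = 1L, lvLengthCm = 1.6, gridNs = 64L, gridNt = 512L,
    ePeakCms = 77.01, aPeakCms = 37.73, eaSeparationS = 0.06,
    waveWidthS = 0.012, propagationCmS = 40, velDurationS = 0.16,
    nyquistCms = 60, rhoKgM3 = 1060,
    meanRrMs = 60000 / 275.4,
    bandPowerMs2 = c(vlf = 162.3, lf = 524.4, hf = 2162),
    ectopicRate = 0, rrDurationS = 600,
    ecgParams = c(hr_bpm = 275.4, p_dur_s = 0.020, pr_s = 0.052,
                  qrs_s = 0.022, r_amp_mv = 0.940),
    ecgFsHz = 2000, ecgDurationS = 60,
    lesionFraction = 0.25, lesionGray = 200L, backgroundGray = 60L,
    imageSize = c(200L, 200L), imageNoise = 0,
    cohortDesign = defaultCohortDesign(),
    qpcrDesign = defaultQpcrDesign(), qpcrNoiseSd = 0)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("unknown PhantomSpec parameter(s): ", paste(unknown, collapse = ", "))
  ## partial override of named vectors (e.g. bandPowerMs2 = c(hf = 100))
  for (nm in c("bandPowerMs2", "ecgParams")) {
    if (nm %in% names(args) && !is.null(names(args[[nm]])) &&
        !all(names(defaults[[nm]]) %in% names(args[[nm]]))) {
      full <- defaults[[nm]]
      full[names(args[[nm]])] <- args[[nm]]
      args[[nm]] <- full
    }
  }
  ## wholesale slot replacement (modifyList would merge data.frame columns)
  p <- defaults
  p[names(args)] <- args
  methods::new("PhantomSpec",
    seed = as.integer(p$seed), lvLengthCm = p$lvLengthCm,
    gridNs = as.integer(p$gridNs), gridNt = as.integer(p$gridNt),
    ePeakCms = p$ePeakCms, aPeakCms = p$aPeakCms,
    eaSeparationS = p$eaSeparationS, waveWidthS = p$waveWidthS,
    propagationCmS = p$propagationCmS, velDurationS = p$velDurationS,
    nyquistCms = p$nyquistCms, rhoKgM3 = p$rhoKgM3,
    meanRrMs = p$meanRrMs, bandPowerMs2 = p$bandPowerMs2,
    ectopicRate = p$ectopicRate, rrDurationS = p$rrDurationS,
    ecgParams = p$ecgParams, ecgFsHz = p$ecgFsHz,
    ecgDurationS = p$ecgDurationS, lesionFraction = p$lesionFraction,
    lesionGray = as.integer(p$lesionGray),
    backgroundGray = as.integer(p$backgroundGray),
    imageSize = as.integer(p$imageSize), imageNoise = p$imageNoise,
    cohortDesign = p$cohortDesign, qpcrDesign = p$qpcrDesign,
    qpcrNoiseSd = p$qpcrNoiseSd)
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec (seed %d)\n  velocity: %dx%d grid, L = %g cm, E/A peaks %g/%g cm/s, Nyquist %g cm/s\n  RR: mean %0.1f ms, %g s, band targets vlf/lf/hf = %s ms^2, ectopic rate %g\n  ECG: %g bpm, P %g s, PR %g s, QRS %g s, R %g mV at %g Hz\n  image: %dx%d, lesion %g at gray %d over %d\n  cohort: %d group(s) x %d parameter(s)\n",
    object@seed, object@gridNs, object@gridNt, object@lvLengthCm,
    object@ePeakCms, object@aPeakCms, object@nyquistCms,
    object@meanRrMs, object@rrDurationS,
    paste(object@bandPowerMs2[c("vlf", "lf", "hf")], collapse = "/"),
    object@ectopicRate,
    object@ecgParams["hr_bpm"], object@ecgParams["p_dur_s"],
    object@ecgParams["pr_s"], object@ecgParams["qrs_s"],
    object@ecgParams["r_amp_mv"], object@ecgFsHz,
    object@imageSize[1], object@imageSize[2], object@lesionFraction,
    object@lesionGray, object@backgroundGray,
    length(unique(object@cohortDesign$group)),
    length(unique(object@cohortDesign$parameter))))
})
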