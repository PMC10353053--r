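## End-to-end synthetic study: generate one phantom dataset per subject per
## modality, run every analysis stage through its documented interface, and
## emit per-stage CSV files plus a single JSON report mirroring the layout
## of a three-arm MI study (descriptives, group comparisons, association
## matrices). Fully deterministic given the config seed.

studyConfigDefaults <- function() {
  list(
    seed = 1L,
    rho_kg_m3 = 1060,
    band_edges_hz = c(0, 0.15, 1.5, 5),
    prr50_threshold_ms = 50,
    ectopic_threshold = 0.70,
    ectopic_rate = 0,
    rr_duration_s = 600,
    ecg_duration_s = 30,
    ecg_fs_hz = 2000,
    grid_ns = 64L,
    grid_nt = 256L,
    vel_duration_s = 0.16,
    lv_length_cm = 1.6,
    nyquist_cms = 60,
    subject_cv = 0.08,
    px_per_mm = 40,
    image_noise = 4,
    qpcr_noise_sd = 0.1,
    alpha = 0.05,
    omnibus = "kruskal",
    histo_severity = c(Sham = 0.05, MI = 0.7, `MI+TRE` = 0.3),
    lesion_fraction = c(Sham = 0.05, MI = 0.35, `MI+TRE` = 0.15),
    lesion_gray = c(Sham = 110L, MI = 210L, `MI+TRE` = 150L),
    background_gray = 70L,
    cohort_design = NULL,      # NULL = defaultCohortDesign()
    ecg_design = NULL,         # NULL = defaultEcgDesign()
    hrv_design = NULL)         # NULL = defaultHrvDesign()
}

#' Validate a study configuration
#'
#' Accepts a YAML file path or a named list, checks it against the schema
#' (unknown keys rejected; types and ranges verified; every violation
#' listed), fills defaults, and returns the normalized configuration. An
#' empty input yields the full default configuration.
#'
#' @param config \code{NULL}, a named list of overrides, or a YAML file
#'   path.
#' @return a validated config list (class \code{studyConfig}).
#' @export
validateConfig <- function(config = NULL) {
  defaults <- studyConfigDefaults()
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  errs <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  cf <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  chkPos <- function(key) {
    v <- cf[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      errs <<- c(errs, paste0("`", key, "` must be a single positive number"))
  }
  for (key in c("rho_kg_m3", "prr50_threshold_ms", "rr_duration_s",
                "ecg_duration_s", "ecg_fs_hz", "vel_duration_s",
                "lv_length_cm", "nyquist_cms", "px_per_mm", "qpcr_noise_sd"))
    chkPos(key)
  be <- cf$band_edges_hz
  if (!is.numeric(be) || length(be) != 4L || is.unsorted(be, strictly = TRUE) ||
      be[1L] != 0 || be[4L] != 5)
    errs <- c(errs, "`band_edges_hz` must be 4 increasing edges partitioning [0, 5)")
  if (!is.numeric(cf$ectopic_rate) || cf$ectopic_rate < 0 ||
      cf$ectopic_rate > 1)
    errs <- c(errs, "`ectopic_rate` must lie in [0, 1]")
  if (cf$grid_ns < 8 || cf$grid_nt < 8)
    errs <- c(errs, "`grid_ns`/`grid_nt` must be >= 8")
  if (!is.numeric(cf$alpha) || cf$alpha <= 0 || cf$alpha >= 1)
    errs <- c(errs, "`alpha` must lie in (0, 1)")
  if (!cf$omnibus %in% c("kruskal", "friedman"))
    errs <- c(errs, "`omnibus` must be 'kruskal' or 'friedman'")
  if (length(errs))
    stop("invalid study config:\n  - ", paste(errs, collapse = "\n  - "))
  if (is.null(cf$cohort_design)) cf$cohort_design <- defaultCohortDesign()
  if (is.null(cf$ecg_design)) cf$ecg_design <- defaultEcgDesign()
  if (is.null(cf$hrv_design)) cf$hrv_design <- defaultHrvDesign()
  cf$seed <- as.integer(cf$seed)
  structure(cf, class = c("studyConfig", "list"))
}

## tiny polynomial rolling hash of the serialized config (provenance block)
configHash <- function(cf) {
  s <- jsonlite::toJSON(unclass(cf), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

drawEcgParams <- function(design, group, seed) {
  set.seed(seed)
  d <- design[design$group == group, ]
  v <- stats::setNames(stats::rnorm(nrow(d), d$mean, d$sd), d$parameter)
  ## physiologic floors / ordering guards for extreme draws
  v["qrs_s"] <- max(v["qrs_s"], 0.008)
  v["p_dur_s"] <- max(v["p_dur_s"], 0.008)
  v["pr_s"] <- max(v["pr_s"], v["p_dur_s"] + 0.004)
  v["hr_bpm"] <- min(max(v["hr_bpm"], 60), 500)
  v["r_amp_mv"] <- max(v["r_amp_mv"], 0.1)
  v
}

#' Run a complete synthetic study
#'
#' Generates one phantom dataset per subject per modality (echo cohort
#' values, velocity field, ECG trace, RR series, lesion image), runs the
#' full analysis pipeline (Euler IVPD/IVPG reconstruction, R-peak detection
#' and interval measurement, ectopic filtering and HRV analysis, ROI
#' metrics, qPCR relative quantification, histology score summaries), and
#' performs the statistics layer (group comparisons and association
#' matrices). Per-stage CSV files and a JSON report are written under
#' \code{outDir}; the report body contains no timestamps, so identical
#' config + seed gives byte-identical output.
#'
#' @param config a \code{\link{validateConfig}} result, a named list of
#'   overrides, or a YAML path.
#' @param outDir output directory (created if needed).
#' @return the study report, invisibly (list with \code{cohort},
#'   \code{comparisons}, \code{associations}, \code{rq}, \code{histology},
#'   \code{provenance}).
#' @export
runSyntheticStudy <- function(config = NULL, outDir = tempfile("study")) {
  cf <- if (inherits(config, "studyConfig")) config else validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stageFail <- function(stage, subject, e)
    stop(sprintf("study stage '%s' failed for subject '%s': %s",
                 stage, subject, conditionMessage(e)), call. = FALSE)

  cohortSpec <- phantomSpec(seed = cf$seed, cohortDesign = cf$cohort_design,
                            qpcrNoiseSd = cf$qpcr_noise_sd)
  echo <- generateCohort(cohortSpec)
  subjects <- unique(echo[, c("subject_id", "group")])
  rows <- list(echo)
  hrvD <- cf$hrv_design
  seedBase <- cf$seed * 1000L

  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    grp <- subjects$group[i]
    subjSeed <- seedBase + i
    wide <- echo[echo$subject_id == sid, ]
    val <- function(p) wide$value[wide$parameter == p]
    addRows <- function(params) {
      rows[[length(rows) + 1L]] <<- data.frame(
        subject_id = sid, group = grp, parameter = names(params),
        value = as.numeric(params), stringsAsFactors = FALSE)
    }

    ## --- color M-mode stage: subject's own E/A velocities drive the field
    res <- tryCatch({
      sp <- phantomSpec(seed = subjSeed, gridNs = cf$grid_ns,
                        gridNt = cf$grid_nt, lvLengthCm = cf$lv_length_cm,
                        velDurationS = cf$vel_duration_s,
                        nyquistCms = cf$nyquist_cms,
                        ePeakCms = max(val("eV"), 10),
                        aPeakCms = max(val("aV"), 5),
                        rhoKgM3 = cf$rho_kg_m3)
      ph <- generateVelocityPhantom(sp)
      field <- dealiasVelocity(encodeAliasing(ph$field))
      pf <- eulerPressureField(field, cf$rho_kg_m3)
      win <- detectDiastolicWindow(field)
      ivpdProfiles(pf, win)
    }, error = function(e) stageFail("cmme", sid, e))
    pk <- ivpgPeaks(res)
    addRows(stats::setNames(pk$ivpg_mmHg_cm,
                            paste0("ivpg_", pk$segment)))

    ## --- ECG stage
    iv <- tryCatch({
      ep <- drawEcgParams(cf$ecg_design, grp, subjSeed + 1L)
      esp <- phantomSpec(seed = subjSeed + 1L, ecgParams = ep,
                         ecgFsHz = cf$ecg_fs_hz,
                         ecgDurationS = cf$ecg_duration_s)
      e <- generateEcg(esp)
      measureEcgIntervals(e$ecg, detectRPeaks(e$ecg))
    }, error = function(e) stageFail("ecg", sid, e))
    addRows(c(hr_bpm = iv@hrBpm, pr_s = iv@prS, p_dur_s = iv@pDurS,
              qrs_s = iv@qrsS, r_amp_mv = iv@rAmpMv))

    ## --- HRV stage
    hrv <- tryCatch({
      hd <- hrvD[hrvD$group == grp, ]
      set.seed(subjSeed + 2L)
      jit <- function(x) x * exp(stats::rnorm(1, 0, cf$subject_cv))
      rsp <- phantomSpec(seed = subjSeed + 2L,
                         meanRrMs = jit(hd$mean_rr_ms),
                         bandPowerMs2 = c(vlf = jit(hd$vlf), lf = jit(hd$lf),
                                          hf = jit(hd$hf)),
                         ectopicRate = cf$ectopic_rate,
                         rrDurationS = cf$rr_duration_s)
      ph <- generateRRSeries(rsp)
      rr <- RRSeries(rrIntervals(ph$rr), beatTimes(ph$rr))  # flags unknown
      hrvAnalysis(rr, filter = TRUE,
                  ectopicThreshold = cf$ectopic_threshold,
                  prr50ThresholdMs = cf$prr50_threshold_ms,
                  bandEdgesHz = cf$band_edges_hz)
    }, error = function(e) stageFail("hrv", sid, e))
    addRows(c(sdrr_ms = hrv@sdrrMs, cvrr = hrv@cvrr, rmssd_ms = hrv@rmssdMs,
              prr50_pct = hrv@prr50Pct, vlf_ms2 = hrv@vlfMs2,
              lf_ms2 = hrv@lfMs2, hf_ms2 = hrv@hfMs2,
              total_power_ms2 = hrv@totalPowerMs2))

    ## --- gross image stage
    roi <- tryCatch({
      isp <- phantomSpec(seed = subjSeed + 3L,
                         lesionFraction = cf$lesion_fraction[[grp]],
                         lesionGray = cf$lesion_gray[[grp]],
                         backgroundGray = cf$background_gray,
                         imageNoise = cf$image_noise)
      li <- generateLesionImage(isp)
      roiIntensityMetrics(li$image, li$mask, cf$px_per_mm)
    }, error = function(e) stageFail("imaging", sid, e))
    addRows(c(mean_gray = roi$mean_gray,
              integrated_density = roi$integrated_density,
              median_gray = roi$median_gray))
  }

  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  cohort <- cohort[order(cohort$group, cohort$subject_id, cohort$parameter), ]

  ## --- statistics layer
  params <- unique(cohort$parameter)
  comparisons <- lapply(params, function(p)
    compareGroups(cohort, p, omnibus = cf$omnibus, alpha = cf$alpha))
  names(comparisons) <- params
  compTab <- do.call(rbind, lapply(comparisons, function(cm) {
    pw <- cm$pairwise
    data.frame(parameter = cm$parameter, omnibus_p = cm$p_value,
               contrast = pw$contrast, p_adj = pw$p_adj,
               significant = pw$significant, stringsAsFactors = FALSE)
  }))
  rownames(compTab) <- NULL

  ivpgSet <- paste0("ivpg_", c("total", "basal", "mid_to_apical", "mid",
                               "apical"))
  echoSet <- intersect(c("EF", "FS", "eV", "aV", "EA", "Em", "Am", "EmAm",
                         "EEm", "Sm"), params)
  hrvSet <- c("sdrr_ms", "cvrr", "rmssd_ms", "prr50_pct", "vlf_ms2",
              "lf_ms2", "hf_ms2")
  associations <- list(
    ivpg_echo = correlationRegression(cohort, ivpgSet, echoSet),
    hrv_echo = correlationRegression(cohort, hrvSet, echoSet),
    ivpg_hrv = correlationRegression(cohort, ivpgSet, hrvSet))

  ## --- study-level qPCR and histology stages
  rq <- tryCatch({
    plate <- generateQpcrPlate(cohortSpec)
    relativeQuantification(plate$ct, plate$truth$reference_gene,
                           controlGroup = subjects$group[1L])
  }, error = function(e) stageFail("qpcr", "(study)", e))
  histo <- tryCatch({
    hs <- generateHistoScores(cf$histo_severity, seed = cf$seed + 7L)
    summarizeHistoScores(hs)
  }, error = function(e) stageFail("histology", "(study)", e))

  provenance <- list(seed = cf$seed, config_hash = configHash(cf),
                     n_subjects = nrow(subjects),
                     groups = unique(subjects$group),
                     package = "cardioKit",
                     version = tryCatch(
                       as.character(utils::packageVersion("cardioKit")),
                       error = function(e) "unknown"))

  utils::write.csv(cohort, file.path(outDir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(compTab, file.path(outDir, "comparisons.csv"),
                   row.names = FALSE)
  for (nm in names(associations))
    utils::write.csv(associations[[nm]],
                     file.path(outDir, paste0("associations_", nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(rq$summary, file.path(outDir, "qpcr_fold_changes.csv"),
                   row.names = FALSE)
  utils::write.csv(histo$groups, file.path(outDir, "histology_groups.csv"),
                   row.names = FALSE)
  report <- list(provenance = provenance,
                 descriptives = lapply(comparisons, `[[`, "descriptives"),
                 comparisons = compTab, associations = associations,
                 qpcr = rq$summary, histology = histo$groups)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(cohort = cohort, comparisons = comparisons,
                 associations = associations, rq = rq, histology = histo,
                 provenance = provenance, out_dir = outDir))
}
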