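# Synthetic generators: determinism, ground-truth contracts, and the
# closed-form oracle values frozen from independent hand calculations.

test_that("velocity phantom honours the zero-field and peak-speed contracts", {
  zero <- generateVelocityPhantom(phantomSpec(ePeakCms = 0, aPeakCms = 0,
                                              gridNs = 16L, gridNt = 64L))
  expect_true(all(velocityValues(zero$field) == 0))
  expect_true(all(abs(zero$truth$ivpd_mmHg) < 1e-12))

  ph <- generateVelocityPhantom(phantomSpec())   # sham E-wave peak 77.01
  expect_equal(max(abs(velocityValues(ph$field))), 77.01, tolerance = 1e-3)

  ph2 <- generateVelocityPhantom(phantomSpec())
  expect_identical(velocityValues(ph$field), velocityValues(ph2$field))
})

test_that("ramp and shear templates match the closed-form pressure drops", {
  # v = a t uniform in s: IVPD = -rho a L = -0.1272 mmHg for
  # a = 100 cm/s^2, L = 1.6 cm, rho = 1060 (hand-converted); convective 0
  ramp <- generateVelocityPhantom(phantomSpec(gridNs = 32L, gridNt = 128L),
                                  template = "ramp", rampAccelCmS2 = 100)
  closed <- -1060 * 1.0 * 0.016 * MMHG_PER_PA_T
  expect_equal(unique(round(ramp$truth$ivpd_mmHg[, "total"], 10)),
               round(closed, 10))
  # steady v = k s: IVPD = -rho k^2 L^2 / 2 = -2.544 mmHg for k = 50/s
  shear <- generateVelocityPhantom(phantomSpec(gridNs = 32L, gridNt = 128L),
                                   template = "shear", shearPerS = 50)
  closedS <- -1060 * 50^2 * 0.016^2 / 2 * MMHG_PER_PA_T
  expect_equal(unique(round(shear$truth$ivpd_mmHg[, "total"], 8)),
               round(closedS, 8))
})

test_that("phantom ground truth satisfies the Euler relation at high resolution", {
  # re-integrating at a finer refinement changes the oracle by < 0.1%
  ph10 <- generateVelocityPhantom(phantomSpec(gridNs = 16L, gridNt = 64L),
                                  oracleRefine = 10L)
  ph40 <- generateVelocityPhantom(phantomSpec(gridNs = 16L, gridNt = 64L),
                                  oracleRefine = 40L)
  pk <- max(abs(ph40$truth$ivpd_mmHg[, "total"]))
  expect_lt(max(abs(ph10$truth$ivpd_mmHg - ph40$truth$ivpd_mmHg)) / pk, 1e-3)
})

test_that("aliasing encoder wraps into the Nyquist interval and is idempotent", {
  f <- randomSmoothField(16L, 32L, peakCms = 50, nyquistCms = 60, seed = 2)
  expect_identical(velocityValues(encodeAliasing(f)), velocityValues(f))

  v <- matrix(1.5 * 60, 8, 8)
  f2 <- VelocityField(v, dsCm = 1.6 / 7, dtS = 0.01, lvLengthCm = 1.6,
                      nyquistCms = 60)
  w <- encodeAliasing(f2)
  expect_equal(unique(as.vector(velocityValues(w))), -0.5 * 60)
  expect_identical(velocityValues(encodeAliasing(w)), velocityValues(w))

  f3 <- VelocityField(v, dsCm = 1.6 / 7, dtS = 0.01, lvLengthCm = 1.6)
  expect_error(encodeAliasing(f3), "Nyquist")
})

test_that("RR phantom: zero targets give a constant series; output is deterministic", {
  sp <- phantomSpec(bandPowerMs2 = c(vlf = 0, lf = 0, hf = 0),
                    rrDurationS = 60)
  ph <- generateRRSeries(sp)
  expect_equal(stats::sd(rrIntervals(ph$rr)), 0)
  expect_equal(ph$truth$total_realized_ms2, 0)

  a <- generateRRSeries(phantomSpec(seed = 9L, rrDurationS = 90))
  b <- generateRRSeries(phantomSpec(seed = 9L, rrDurationS = 90))
  expect_identical(rrIntervals(a$rr), rrIntervals(b$rr))
})

test_that("RR phantom realized band powers sum to the realized total within 1%", {
  for (sd in 1:5) {
    ph <- generateRRSeries(phantomSpec(seed = sd, rrDurationS = 300))
    expect_equal(sum(ph$truth$realized_ms2), ph$truth$total_realized_ms2,
                 tolerance = 0.01)
    # realized equals analytic: RR values are exact samples of the modulation
    expect_equal(unname(ph$truth$realized_ms2),
                 unname(ph$truth$analytic_ms2), tolerance = 0.01)
  }
})

test_that("RR phantom injects the requested fraction of flagged ectopic pairs", {
  sp <- phantomSpec(seed = 3L, ectopicRate = 0.02, rrDurationS = 450,
                    bandPowerMs2 = c(vlf = 30, lf = 90, hf = 180))
  ph <- generateRRSeries(sp)
  nBeats <- length(rrIntervals(ph$rr))
  nEvents <- length(ph$truth$ectopic_index)
  expect_equal(nEvents, round(0.02 * nBeats), tolerance = 0.15)
  expect_equal(sum(ectopicFlags(ph$rr)), 2 * nEvents)
  # injected premature intervals deviate > 30% from their neighbourhood
  rr <- rrIntervals(ph$rr)
  for (i in ph$truth$ectopic_index[1:10]) {
    local <- stats::median(rr[setdiff((i - 5):(i + 5), c(i, i + 1))])
    expect_gt(abs(rr[i] - local) / local, 0.30)
  }
})

test_that("ECG phantom carries its fiducials exactly and spaces R peaks by 60000/hr", {
  sp <- phantomSpec(ecgDurationS = 20)       # sham-group defaults
  ph <- generateEcg(sp)
  expect_equal(ph$truth$hr_bpm, 275.4)
  expect_equal(ph$truth$pr_s, 0.052)
  expect_equal(ph$truth$p_dur_s, 0.020)
  expect_equal(ph$truth$qrs_s, 0.022)
  expect_equal(ph$truth$r_amp_mv, 0.940)
  spacing <- diff(ph$truth$r_times_s) * 1000
  expect_true(all(abs(spacing - 60000 / 275.4) <= 1000 / samplingRate(ph$ecg)))

  flat <- generateEcg(phantomSpec(ecgParams = c(r_amp_mv = 0),
                                  ecgDurationS = 20))
  expect_error(detectRPeaks(flat$ecg), "no beats")

  expect_error(phantomSpec(ecgParams = c(hr_bpm = 400, pr_s = 0.12,
                                         qrs_s = 0.05)),
               "fit within one RR")
})

test_that("lesion image phantom: constant-region metrics and mask geometry", {
  sp <- phantomSpec(imageSize = c(200L, 200L), lesionFraction = 0.25,
                    lesionGray = 200L, backgroundGray = 60L, imageNoise = 0)
  li <- generateLesionImage(sp)
  expect_equal(li$truth$mean_gray, 200)
  expect_equal(li$truth$median_gray, 200)
  expect_equal(li$truth$integrated_density, 200 * li$truth$area_px)
  # mask area ~ lesion fraction up to boundary rasterization
  expect_equal(sum(li$mask), 0.25 * 200 * 200, tolerance = 0.02)
  # complement region is pure background
  expect_true(all(li$image[!li$mask] == 60))
})

test_that("cohort generator: 24 subjects, degenerate at sd = 0, reproducible", {
  co <- generateCohort(phantomSpec(seed = 1L))
  expect_equal(length(unique(co$subject_id)), 24L)
  expect_equal(nrow(co), 24L * 16L)

  d0 <- defaultCohortDesign()
  d0$sd <- 0
  co0 <- generateCohort(phantomSpec(cohortDesign = d0))
  m <- merge(co0, d0, by = c("group", "parameter"))
  expect_equal(m$value, m$mean)

  co2 <- generateCohort(phantomSpec(seed = 1L))
  expect_identical(co, co2)
})

test_that("qPCR plate: exact dCt identities without noise, recovery with noise", {
  sp <- phantomSpec(qpcrNoiseSd = 0)
  pl <- generateQpcrPlate(sp)
  rq <- relativeQuantification(pl$ct, "b-actin", "Sham")
  sham <- rq$summary[rq$summary$group == "Sham", ]
  expect_equal(sham$mean_fold, rep(1, nrow(sham)))
  # fold target 2 <=> ddCt -1 exactly
  des <- defaultCohortDesign()
  qd <- data.frame(gene = "g1", group = c("Sham", "MI"), fold = c(1, 2))
  pl2 <- generateQpcrPlate(phantomSpec(qpcrNoiseSd = 0, qpcrDesign = qd))
  rq2 <- relativeQuantification(pl2$ct, "b-actin", "Sham")
  expect_equal(unique(rq2$subjects$ddct[rq2$subjects$group == "MI"]), -1)
  expect_equal(unique(rq2$subjects$fold[rq2$subjects$group == "MI"]), 2)
})
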