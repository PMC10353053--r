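# Statistics layer: derived indices, group comparisons vs brute-force Dunn,
# Spearman vs the rank-formula oracle, 2^-ddCt, ANOVA sample size vs an
# independent noncentral-F oracle.

test_that("derived echo indices follow the printed averaging formulas", {
  rec <- data.frame(eV = 80, aV = 40, EEm_lateral = 10, EEm_septal = 14,
                    EmAm_lateral = 1.4, EmAm_septal = 1.4)
  out <- derivedEchoIndices(rec)
  expect_equal(out$EA, 2)
  expect_equal(out$EEm, 12)
  expect_equal(out$EmAm, 1.4)

  z <- derivedEchoIndices(data.frame(eV = 80, aV = 0))
  expect_true(is.na(z$EA))
})

test_that("three identical groups yield no significant contrasts", {
  vals <- rep(c(5, 7, 9, 11, 6, 8, 10, 12), 3)
  tab <- makeCohort(vals, rep(c("A", "B", "C"), each = 8))
  cm <- compareGroups(tab, "p")
  expect_gt(cm$p_value, 0.9)
  expect_false(any(cm$pairwise$significant))
})

test_that("constant data give the degenerate p = 1 result", {
  tab <- makeCohort(rep(4, 12), rep(c("A", "B", "C"), each = 4))
  cm <- compareGroups(tab, "p")
  expect_equal(cm$p_value, 1)
  expect_true(all(cm$pairwise$p_adj == 1))
})

test_that("well-separated groups: omnibus and Dunn match the brute-force oracle", {
  vals <- c(1:8, 11:18, 21:28)
  grp <- rep(c("A", "B", "C"), each = 8)
  cm <- compareGroups(makeCohort(vals, grp), "p")
  expect_lt(cm$p_value, 0.001)
  oracle <- bruteDunn(vals, grp)
  expect_equal(cm$pairwise$z, oracle$z, tolerance = 1e-12)
  expect_equal(cm$pairwise$p_adj, oracle$p_adj, tolerance = 1e-12)
  # extreme contrast significant after Bonferroni; adjacent contrasts are
  # significant only before adjustment (z = 2.262, p_unadj = 0.0237)
  expect_true(cm$pairwise$significant[cm$pairwise$contrast == "A - C"])
  expect_true(all(cm$pairwise$p_unadj < 0.05))
})

test_that("Dunn p-values match the exhaustive oracle on small random datasets", {
  set.seed(41)
  for (i in 1:30) {
    k <- sample(2:4, 1)
    sizes <- sample(3:9, k, replace = TRUE)
    grp <- rep(LETTERS[1:k], sizes)
    vals <- sample(1:12, sum(sizes), replace = TRUE)   # ties likely
    if (length(unique(vals)) == 1L) next
    got <- dunnPosthoc(vals, grp)
    want <- bruteDunn(vals, grp)
    expect_equal(got$z, want$z, tolerance = 1e-12)
    expect_equal(got$p_adj, want$p_adj, tolerance = 1e-12)
  }
})

test_that("Friedman omnibus option runs on balanced layouts", {
  set.seed(42)
  tab <- makeCohort(rnorm(24, rep(c(0, 1, 2), each = 8)),
                    rep(c("A", "B", "C"), each = 8))
  cm <- compareGroups(tab, "p", omnibus = "friedman")
  expect_true(is.finite(cm$statistic))
  expect_true(cm$p_value >= 0 && cm$p_value <= 1)
})

test_that("an EF-effect cohort at the study means flags the sham-MI contrast", {
  hits <- 0L
  nRun <- 100L
  design <- data.frame(group = c("Sham", "MI", "MI+TRE"), n = 8L,
                       parameter = "EF", mean = c(88.20, 65.39, 76.53),
                       sd = c(1.384, 1.982, 0.852))
  for (sd in seq_len(nRun)) {
    co <- generateCohort(phantomSpec(seed = sd, cohortDesign = design))
    cm <- compareGroups(co, "EF")
    sig <- cm$pairwise$significant[grepl("MI - Sham|Sham - MI",
                                         cm$pairwise$contrast)]
    if (any(sig)) hits <- hits + 1L
  }
  expect_gte(hits / nRun, 0.95)
})

test_that("Spearman r matches the rank-formula oracle to 1e-12", {
  set.seed(43)
  for (i in 1:20) {
    x <- sample(1:40, 24, replace = TRUE)     # with ties
    y <- x * 2 + rnorm(24, 0, 10)
    tab <- rbind(makeCohort(x, "G", "px"), makeCohort(y, "G", "py"))
    got <- correlationRegression(tab, "px", "py")
    expect_equal(got$spearman_r, bruteSpearman(x, y), tolerance = 1e-12)
  }
})

test_that("correlation/regression handles exact and degenerate relations", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  tab <- rbind(makeCohort(x, "G", "x"),
               makeCohort(2 * x + 1, "G", "lin"),
               makeCohort(-x^3, "G", "cub"),
               makeCohort(rep(3, 8), "G", "flat"))
  # exact linear data provokes R's perfect-fit note; harmless here
  out <- suppressWarnings(correlationRegression(tab, "x",
                                                c("lin", "cub", "flat")))
  lin <- out[out$y == "lin", ]
  expect_equal(lin$spearman_r, 1)
  expect_equal(lin$r_squared, 1)
  cub <- out[out$y == "cub", ]
  expect_equal(cub$spearman_r, -1)
  expect_lt(cub$r_squared, 1)
  expect_true(is.na(out$spearman_r[out$y == "flat"]))
})

test_that("Spearman r is invariant under strictly monotone transforms", {
  set.seed(44)
  x <- rnorm(30)
  y <- rnorm(30)
  tab1 <- rbind(makeCohort(x, "G", "x"), makeCohort(y, "G", "y"))
  tab2 <- rbind(makeCohort(exp(x), "G", "x"),
                makeCohort(y^3 + 2 * y, "G", "y"))
  r1 <- correlationRegression(tab1, "x", "y")$spearman_r
  r2 <- correlationRegression(tab2, "x", "y")$spearman_r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("2^-ddCt identities and reference-shift invariance hold", {
  qd <- data.frame(gene = rep(c("g1", "g2"), each = 2),
                   group = rep(c("Sham", "MI"), 2), fold = c(1, 2, 1, 0.5))
  pl <- generateQpcrPlate(phantomSpec(qpcrNoiseSd = 0, qpcrDesign = qd))
  rq <- relativeQuantification(pl$ct, "b-actin", "Sham")
  sham <- rq$summary[rq$summary$group == "Sham", ]
  expect_equal(sham$mean_fold, rep(1, 2))
  expect_equal(rq$summary$mean_fold[rq$summary$gene == "g1" &
                                      rq$summary$group == "MI"], 2)
  # adding a constant to every reference-gene Ct shifts all dCt equally,
  # cancelling in ddCt: folds unchanged
  ct2 <- pl$ct
  shift <- ct2$gene == "b-actin"
  ct2$ct[shift] <- ct2$ct[shift] + 3
  rq2 <- relativeQuantification(ct2, "b-actin", "Sham")
  expect_equal(rq2$summary$mean_fold, rq$summary$mean_fold,
               tolerance = 1e-12)

  # missing reference gene for one subject: dropped with warning
  ct3 <- pl$ct[!(pl$ct$subject_id == pl$ct$subject_id[1] &
                   pl$ct$gene == "b-actin"), ]
  expect_warning(relativeQuantification(ct3, "b-actin", "Sham"),
                 "without reference")
})

test_that("noisy fold-0.5 plates recover the geometric-mean fold within 10%", {
  qd <- data.frame(gene = "g1", group = c("Sham", "MI"), fold = c(1, 0.5))
  folds <- vapply(1:25, function(sd) {
    pl <- generateQpcrPlate(phantomSpec(seed = sd, qpcrNoiseSd = 0.1,
                                        qpcrDesign = qd))
    rq <- relativeQuantification(pl$ct, "b-actin", "Sham")
    rq$summary$geo_mean_fold[rq$summary$group == "MI"]
  }, numeric(1))
  expect_equal(exp(mean(log(folds))), 0.5, tolerance = 0.10)
})

test_that("ANOVA sample size is minimal against the noncentral-F oracle", {
  grid <- expand.grid(f = c(0.25, 0.4, 0.5, 0.9), alpha = c(0.05, 0.01),
                      power = c(0.80, 0.95), k = c(2, 3, 4))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- anovaSampleSize(g$f, g$alpha, g$power, g$k)
    N <- res$n_total
    expect_gte(brutePowerNoncentralF(N, g$f, g$alpha, g$k) + 1e-10, g$power)
    expect_lt(brutePowerNoncentralF(N - g$k, g$f, g$alpha, g$k), g$power)
    expect_equal(res$n_per_group, N / g$k)
  }
})

test_that("ANOVA power is monotone in N and in effect size", {
  pw <- vapply(seq(6, 200, by = 3), function(N)
    brutePowerNoncentralF(N, 0.5, 0.05, 3), numeric(1))
  expect_true(all(diff(pw) > -1e-12))
  p1 <- anovaSampleSize(0.5, 0.05, 0.8, 3)$achieved_power
  res <- anovaSampleSize(0.5, 0.05, 0.8, 3)
  expect_gt(brutePowerNoncentralF(res$n_total, 1.0, 0.05, 3), p1)
})
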