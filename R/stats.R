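## Statistics layer: derived echo indices, nonparametric group comparison
## (Shapiro-Wilk screening, Kruskal-Wallis or Friedman omnibus, Dunn's rank
## post hoc with Bonferroni adjustment), Spearman correlation with OLS R^2,
## 2^-ddCt relative quantification, and one-way ANOVA sample size from the
## noncentral F distribution.

#' Derived echocardiographic indices
#'
#' Adds the averaged tissue-Doppler indices to a per-subject record:
#' E/A = eV / aV, average E/e' = (E/e' lateral + E/e' septal) / 2 and
#' average Em/Am = (Em/Am lateral + Em/Am septal) / 2. A zero denominator
#' yields NA (flagged missing), never infinity.
#'
#' @param record data.frame with (any of) columns \code{eV}, \code{aV},
#'   \code{EEm_lateral}, \code{EEm_septal}, \code{EmAm_lateral},
#'   \code{EmAm_septal}.
#' @return the record with added \code{EA}, \code{EEm}, \code{EmAm} where
#'   computable.
#' @export
derivedEchoIndices <- function(record) {
  stopifnot(is.data.frame(record))
  if (all(c("eV", "aV") %in% names(record)))
    record$EA <- ifelse(record$aV == 0, NA_real_, record$eV / record$aV)
  if (all(c("EEm_lateral", "EEm_septal") %in% names(record)))
    record$EEm <- (record$EEm_lateral + record$EEm_septal) / 2
  if (all(c("EmAm_lateral", "EmAm_septal") %in% names(record)))
    record$EmAm <- (record$EmAm_lateral + record$EmAm_septal) / 2
  record
}

#' Dunn's rank-sum post hoc comparisons
#'
#' Pairwise z statistics on Kruskal-Wallis rank sums with the standard tie
#' correction, and Bonferroni adjustment over the tested contrasts.
#' For groups i, j with mean pooled ranks \eqn{\bar R_i, \bar R_j}:
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' with \eqn{T = \sum(t^3 - t) / (12 (N - 1))} over tied-value counts t.
#'
#' @param values numeric observations.
#' @param groups group labels (same length).
#' @return data.frame: \code{contrast}, \code{z}, \code{p_unadj},
#'   \code{p_adj} (Bonferroni over all pairwise contrasts, capped at 1).
#' @export
dunnPosthoc <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  S2 <- N * (N + 1) / 12 - Tcorr
  lev <- levels(groups)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2L)
  m <- ncol(pairs)
  out <- data.frame(contrast = character(m), z = numeric(m),
                    p_unadj = numeric(m), p_adj = numeric(m),
                    stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    se <- sqrt(S2 * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    out$contrast[i] <- paste(a, b, sep = " - ")
    out$z[i] <- z
    out$p_unadj[i] <- p
    out$p_adj[i] <- min(1, p * m)
  }
  out
}

#' Nonparametric comparison of one parameter across groups
#'
#' For one cohort parameter: Shapiro-Wilk normality p per group (reported,
#' not gating), a nonparametric omnibus test, Dunn's pairwise post hoc with
#' Bonferroni adjustment over the contrasts, and per-group descriptives
#' (mean, SD). The default omnibus is Kruskal-Wallis, appropriate for
#' independent groups; the Friedman test (which presumes a blocked /
#' repeated-measures layout, using the within-group subject order as the
#' block) is available as an option. Data constant across all groups yield
#' a degenerate result with p = 1.
#'
#' @param table long cohort data.frame (\code{subject_id}, \code{group},
#'   \code{parameter}, \code{value}).
#' @param parameter parameter name to compare.
#' @param omnibus \code{"kruskal"} (default) or \code{"friedman"}.
#' @param alpha significance threshold for the \code{significant} flags,
#'   default 0.05.
#' @return list (class \code{groupComparison}): \code{parameter},
#'   \code{omnibus}, \code{statistic}, \code{p_value}, \code{normality},
#'   \code{descriptives}, \code{pairwise}, \code{alpha}.
#' @export
compareGroups <- function(table, parameter,
                          omnibus = c("kruskal", "friedman"), alpha = 0.05) {
  omnibus <- match.arg(omnibus)
  d <- table[table$parameter == parameter, ]
  if (nrow(d) == 0L) stop("compareGroups: parameter not found: ", parameter)
  d$group <- factor(d$group, levels = unique(table$group))
  n <- tapply(d$value, d$group, length)
  if (any(n < 3L)) stop("compareGroups: need >= 3 subjects per group")
  normality <- vapply(levels(d$group), function(g) {
    v <- d$value[d$group == g]
    if (length(unique(v)) < 3L) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  descr <- data.frame(group = levels(d$group), n = as.integer(n),
                      mean = as.numeric(tapply(d$value, d$group, mean)),
                      sd = as.numeric(tapply(d$value, d$group, stats::sd)),
                      stringsAsFactors = FALSE)
  degenerate <- length(unique(d$value)) == 1L
  if (degenerate) {
    stat <- NA_real_
    p <- 1
    pw <- dunnPosthoc(d$value, d$group)
    pw$p_unadj <- pw$p_adj <- 1
  } else if (omnibus == "kruskal") {
    kt <- stats::kruskal.test(d$value, d$group)
    stat <- unname(kt$statistic)
    p <- kt$p.value
    pw <- dunnPosthoc(d$value, d$group)
  } else {
    ## blocked layout: subject order within group is the block
    d <- d[order(d$group, d$subject_id), ]
    if (length(unique(n)) != 1L)
      stop("compareGroups: Friedman omnibus needs equal group sizes")
    block <- stats::ave(seq_len(nrow(d)), d$group, FUN = seq_along)
    ft <- stats::friedman.test(d$value, d$group, block)
    stat <- unname(ft$statistic)
    p <- ft$p.value
    pw <- dunnPosthoc(d$value, d$group)
  }
  pw$significant <- pw$p_adj < alpha
  structure(list(parameter = parameter, omnibus = omnibus, statistic = stat,
                 p_value = p, normality = normality, descriptives = descr,
                 pairwise = pw, alpha = alpha),
            class = "groupComparison")
}

#' @export
print.groupComparison <- function(x, ...) {
  cat(sprintf("Group comparison of '%s' (%s omnibus): stat = %.4g, p = %.4g\n",
              x$parameter, x$omnibus, x$statistic, x$p_value))
  print(x$descriptives, row.names = FALSE, digits = 4)
  cat("Pairwise (Dunn, Bonferroni-adjusted):\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Spearman correlation and linear-regression R-squared matrix
#'
#' For every (x, y) parameter pair: Spearman's rank correlation (mid-ranks
#' for ties) with its p-value, and the coefficient of determination of the
#' ordinary least-squares fit of y on x, shaped like the study's
#' correlation/regression tables (r and R^2 side by side). Pairs with fewer
#' than 5 complete observations or zero variance are flagged undefined (NA).
#'
#' @param table long cohort data.frame.
#' @param xSet,ySet parameter names to cross.
#' @return data.frame: \code{x}, \code{y}, \code{n}, \code{spearman_r},
#'   \code{spearman_p}, \code{r_squared}.
#' @export
correlationRegression <- function(table, xSet, ySet) {
  wide <- stats::reshape(table[, c("subject_id", "parameter", "value")],
                         idvar = "subject_id", timevar = "parameter",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  missing <- setdiff(c(xSet, ySet), names(wide))
  if (length(missing))
    stop("correlationRegression: parameters not in table: ",
         paste(missing, collapse = ", "))
  out <- expand.grid(x = xSet, y = ySet, stringsAsFactors = FALSE)
  out$n <- NA_integer_
  out$spearman_r <- out$spearman_p <- out$r_squared <- NA_real_
  for (i in seq_len(nrow(out))) {
    xv <- wide[[out$x[i]]]
    yv <- wide[[out$y[i]]]
    ok <- stats::complete.cases(xv, yv)
    out$n[i] <- sum(ok)
    if (sum(ok) < 5L) next
    if (stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(xv[ok], yv[ok], method = "spearman"))
    out$spearman_r[i] <- unname(ct$estimate)
    out$spearman_p[i] <- ct$p.value
    out$r_squared[i] <- summary(stats::lm(yv[ok] ~ xv[ok]))$r.squared
  }
  out
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per subject and gene: dCt = Ct(gene) - Ct(reference gene); ddCt = dCt
#' minus the control group's mean dCt for that gene; fold = 2^-ddCt. Group
#' summaries report the arithmetic mean, SD and geometric mean of the
#' per-subject folds. Subjects lacking a reference-gene Ct are dropped with
#' a warning.
#'
#' @param ct data.frame (\code{subject_id}, \code{group}, \code{gene},
#'   \code{ct}).
#' @param referenceGene housekeeping gene name present for all subjects.
#' @param controlGroup group defining the baseline expression level.
#' @return list with \code{subjects} (per-subject dCt/ddCt/fold) and
#'   \code{summary} (per gene x group mean/sd/geometric-mean fold).
#' @export
relativeQuantification <- function(ct, referenceGene = "b-actin",
                                   controlGroup = "Sham") {
  stopifnot(all(c("subject_id", "group", "gene", "ct") %in% names(ct)))
  if (!referenceGene %in% ct$gene)
    stop("relativeQuantification: reference gene '", referenceGene,
         "' absent from the table")
  if (!controlGroup %in% ct$group)
    stop("relativeQuantification: control group '", controlGroup,
         "' absent from the table")
  ref <- ct[ct$gene == referenceGene, c("subject_id", "ct")]
  names(ref)[2L] <- "ref_ct"
  tgt <- ct[ct$gene != referenceGene, ]
  noRef <- setdiff(unique(tgt$subject_id), ref$subject_id)
  if (length(noRef)) {
    warning("relativeQuantification: dropping subject(s) without reference ",
            "Ct: ", paste(noRef, collapse = ", "))
    tgt <- tgt[!tgt$subject_id %in% noRef, ]
  }
  tgt <- merge(tgt, ref, by = "subject_id")
  tgt$dct <- tgt$ct - tgt$ref_ct
  ctrlMean <- tapply(tgt$dct[tgt$group == controlGroup],
                     tgt$gene[tgt$group == controlGroup], mean)
  if (any(!unique(tgt$gene) %in% names(ctrlMean)))
    stop("relativeQuantification: control group lacks some genes")
  tgt$ddct <- as.numeric(tgt$dct - ctrlMean[tgt$gene])
  tgt$fold <- 2^(-tgt$ddct)
  agg <- function(f) stats::aggregate(fold ~ gene + group, tgt, f)$fold
  summ <- stats::aggregate(fold ~ gene + group, tgt, mean)
  names(summ)[3L] <- "mean_fold"
  summ$sd_fold <- agg(stats::sd)
  summ$geo_mean_fold <- agg(function(v) exp(mean(log(v))))
  summ$n <- agg(length)
  list(subjects = tgt[order(tgt$gene, tgt$group, tgt$subject_id), ],
       summary = summ[order(summ$gene, summ$group), ])
}

## one-way ANOVA power at total sample size N for Cohen's f
anovaPower <- function(N, f, alpha, k) {
  df1 <- k - 1
  df2 <- N - k
  if (df2 < 1) return(0)
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = f^2 * N, lower.tail = FALSE)
}

#' One-way ANOVA sample size from the noncentral F distribution
#'
#' Smallest total N (rounded up to a multiple of the number of groups) whose
#' one-way ANOVA power reaches the target, with power
#' \eqn{P(F' > F_{crit})} under the noncentral F distribution with
#' \eqn{(k-1, N-k)} degrees of freedom and noncentrality
#' \eqn{\lambda = f^2 N} (Cohen's effect size f).
#'
#' @param effectSizeF Cohen's f (> 0).
#' @param alpha type-I error rate, in (0, 1).
#' @param power target power, in (0, 1).
#' @param kGroups number of groups (>= 2).
#' @return list: \code{n_total}, \code{n_per_group}, \code{achieved_power}.
#' @examples
#' anovaSampleSize(0.9, alpha = 0.05, power = 0.95, kGroups = 3)
#' @export
anovaSampleSize <- function(effectSizeF, alpha = 0.05, power = 0.80,
                            kGroups = 3L) {
  stopifnot(effectSizeF > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            kGroups >= 2L)
  k <- as.integer(kGroups)
  N <- 2L * k
  while (N <= 1e6L) {
    if (anovaPower(N, effectSizeF, alpha, k) >= power)
      return(list(n_total = N, n_per_group = N %/% k,
                  achieved_power = anovaPower(N, effectSizeF, alpha, k)))
    N <- N + k
  }
  stop("anovaSampleSize: power target unattainable at N <= 1e6")
}
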