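## Cohort-level phantoms: per-subject parameter tables drawn from per-group
## normal distributions, qPCR Ct plates with exact fold-change ground truth,
## and ordinal histopathology scores.

#' Generate a long-format cohort table
#'
#' One row per subject x parameter, values drawn independently from the
#' per-group normal distributions of the spec's \code{cohortDesign}.
#' Deterministic given the seed. The default design is the three-arm
#' sham / MI / MI+TRE echocardiography cohort with n = 8 per group
#' (\code{\link{defaultCohortDesign}}).
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return data.frame with columns \code{subject_id}, \code{group},
#'   \code{parameter}, \code{value}.
#' @examples
#' co <- generateCohort(phantomSpec(seed = 1))
#' length(unique(co$subject_id))  # 24 subjects
#' @export
generateCohort <- function(spec) {
  stopifnot(methods::is(spec, "PhantomSpec"))
  design <- spec@cohortDesign
  if (nrow(design) == 0L) stop("generateCohort: empty cohort design")
  if (anyDuplicated(design[, c("group", "parameter")]))
    stop("generateCohort: duplicate group x parameter rows in design")
  set.seed(spec@seed)
  groups <- unique(design$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    d <- design[design$group == g, ]
    n <- d$n[1L]
    ids <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", g), seq_len(n))
    do.call(rbind, lapply(seq_len(nrow(d)), function(i)
      data.frame(subject_id = ids, group = g, parameter = d$parameter[i],
                 value = stats::rnorm(n, d$mean[i], d$sd[i]),
                 stringsAsFactors = FALSE)))
  }))
  rownames(out) <- NULL
  out[order(out$group, out$subject_id, out$parameter), ]
}

#' Generate a qPCR Ct plate with exact fold-change ground truth
#'
#' Emits per-subject Ct values for each target gene and the reference gene
#' such that, before noise, the 2^-ddCt fold change of every group relative
#' to the control group equals the spec's \code{qpcrDesign} target exactly.
#'
#' @param spec a \code{\link{phantomSpec}}; uses \code{qpcrDesign},
#'   \code{qpcrNoiseSd}, \code{cohortDesign} (group sizes), \code{seed}.
#' @param referenceGene reference (housekeeping) gene name.
#' @param refCt baseline reference-gene Ct (cycles).
#' @return list with \code{ct} (data.frame \code{subject_id}, \code{group},
#'   \code{gene}, \code{ct}) and \code{truth} (the fold-change design).
#' @export
generateQpcrPlate <- function(spec, referenceGene = "b-actin", refCt = 16) {
  stopifnot(methods::is(spec, "PhantomSpec"))
  design <- spec@qpcrDesign
  if (any(design$fold <= 0)) stop("generateQpcrPlate: folds must be > 0")
  set.seed(spec@seed + 1L)
  groups <- unique(design$group)
  genes <- unique(design$gene)
  nPer <- vapply(groups, function(g) {
    i <- match(g, spec@cohortDesign$group)
    if (is.na(i)) 8L else as.integer(spec@cohortDesign$n[i])
  }, integer(1))
  baseDelta <- stats::setNames(seq(4, length.out = length(genes)), genes)
  rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    ids <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", g),
                   seq_len(nPer[gi]))
    for (id in ids) {
      rCt <- refCt + stats::rnorm(1, 0, spec@qpcrNoiseSd)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, group = g, gene = referenceGene, ct = rCt,
        stringsAsFactors = FALSE)
      for (gene in genes) {
        fold <- design$fold[design$group == g & design$gene == gene]
        if (length(fold) != 1L)
          stop("generateQpcrPlate: design must have one fold per gene x group")
        tCt <- rCt + baseDelta[[gene]] - log2(fold) +
          stats::rnorm(1, 0, spec@qpcrNoiseSd)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = id, group = g, gene = gene, ct = tCt,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(ct = do.call(rbind, rows),
       truth = list(fold_design = design, reference_gene = referenceGene))
}

#' Generate ordinal histopathology scores
#'
#' Draws per-section scores (0-4) for the four criteria from binomial
#' distributions whose severity parameter differs by group, emulating a
#' blinded ordinal grading of ten sections per group.
#'
#' @param severity named numeric in [0, 1]: per-group mean severity (the
#'   binomial probability; expected score = 4 * severity).
#' @param nSections sections per group.
#' @param seed RNG seed.
#' @return data.frame suitable for \code{\link{summarizeHistoScores}}.
#' @export
generateHistoScores <- function(severity = c(Sham = 0.05, MI = 0.7,
                                             `MI+TRE` = 0.3),
                                nSections = 10L, seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(names(severity), function(g) {
    sc <- matrix(stats::rbinom(nSections * 4L, 4L, severity[[g]]),
                 nSections, 4L, dimnames = list(NULL, HISTO_CRITERIA))
    cbind(data.frame(group = g, section = seq_len(nSections),
                     stringsAsFactors = FALSE), as.data.frame(sc))
  }))
}
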