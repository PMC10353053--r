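## Image quantification: ROI intensity metrics for gross-lesion scoring,
## stained (DAB-brown) cell counting, and ordinal histopathology score
## summaries. Pixel values are used as stored (0-255); the "reverse" 1-255
## gray convention sometimes quoted for such scores is not applied, since it
## conflicts with standard raster storage - documented in the vignette.

#' ROI intensity metrics (mean gray, integrated density, median)
#'
#' Computes the gross-lesion metrics over the pixels selected by a binary
#' mask: arithmetic mean gray value, integrated density (the plain sum of
#' the pixel values) and the median (lower of the two middle values for an
#' even pixel count, matching integer-histogram medians of common image
#' tools).
#'
#' @param image numeric/integer matrix, 8-bit gray values 0-255.
#' @param mask logical (or 0/1) matrix of the same shape; nonzero = ROI.
#' @param pxPerMm optional scale for the mm^2 ROI area.
#' @return list with \code{mean_gray}, \code{integrated_density},
#'   \code{median_gray}, \code{area_px} and (if scaled) \code{area_mm2}.
#' @examples
#' img <- matrix(1:9, 3)
#' roiIntensityMetrics(img, matrix(TRUE, 3, 3))
#' @export
roiIntensityMetrics <- function(image, mask, pxPerMm = NULL) {
  if (!identical(dim(image), dim(mask)))
    stop("roiIntensityMetrics: image and mask shapes differ")
  mask <- mask != 0
  if (!any(mask)) stop("roiIntensityMetrics: empty ROI mask")
  if (any(!is.finite(image))) stop("roiIntensityMetrics: non-finite pixels")
  px <- sort(as.numeric(image[mask]))
  n <- length(px)
  out <- list(mean_gray = mean(px), integrated_density = sum(px),
              median_gray = px[ceiling(n / 2)], area_px = n)
  if (!is.null(pxPerMm)) {
    if (pxPerMm <= 0) stop("roiIntensityMetrics: pxPerMm must be positive")
    out$area_mm2 <- n / pxPerMm^2
  }
  out
}

#' Count immunostained (brown) cells per square millimetre
#'
#' Detects DAB-brown objects by a channel-difference score
#' \eqn{R - \max(G, B)} per pixel, thresholds it, labels 8-connected
#' components, applies a size filter, and reports the count divided by the
#' imaged area in mm^2.
#'
#' @param image h x w x 3 RGB array with values in 0-255 (or 0-1, which is
#'   rescaled).
#' @param pxPerMm pixels per millimetre (> 0).
#' @param scoreThreshold brown-score threshold (0-255 scale), default 40.
#' @param minPx,maxPx component size filter (pixels).
#' @return list with \code{n_positive}, \code{area_mm2},
#'   \code{density_per_mm2}.
#' @export
countStainedCells <- function(image, pxPerMm, scoreThreshold = 40,
                              minPx = 5, maxPx = 2000) {
  if (length(dim(image)) != 3L || dim(image)[3L] < 3L)
    stop("countStainedCells: need an RGB array")
  if (missing(pxPerMm) || length(pxPerMm) != 1L || !is.finite(pxPerMm) ||
      pxPerMm <= 0)
    stop("countStainedCells: 'pxPerMm' must be a single positive number")
  if (max(image) <= 1) image <- image * 255
  score <- image[, , 1L] - pmax(image[, , 2L], image[, , 3L])
  bin <- score > scoreThreshold
  lab <- EBImage::bwlabel(bin)
  sizes <- tabulate(lab[lab > 0])
  n <- sum(sizes >= minPx & sizes <= maxPx)
  areaMm2 <- prod(dim(score)) / pxPerMm^2
  list(n_positive = n, area_mm2 = areaMm2, density_per_mm2 = n / areaMm2)
}

HISTO_CRITERIA <- c("mononuclear_infiltration", "interstitial_edema",
                    "necrosis", "myocyte_arrangement")

#' Summarize ordinal histopathology scores
#'
#' Per-section composite score (sum of the four criterion scores, each
#' graded 0 none to 4 very severe, composite 0-16) with per-group median and
#' IQR. The per-section composite table is returned unchanged for downstream
#' group comparison.
#'
#' @param scores data.frame with a \code{group} column and the four ordinal
#'   criteria \code{mononuclear_infiltration}, \code{interstitial_edema},
#'   \code{necrosis}, \code{myocyte_arrangement} (integers 0-4).
#' @return list with \code{sections} (input plus \code{composite}) and
#'   \code{groups} (group, n, median, IQR of the composite).
#' @export
summarizeHistoScores <- function(scores) {
  need <- c("group", HISTO_CRITERIA)
  if (!all(need %in% names(scores)))
    stop("summarizeHistoScores: missing columns: ",
         paste(setdiff(need, names(scores)), collapse = ", "))
  sc <- as.matrix(scores[, HISTO_CRITERIA])
  if (any(sc != round(sc)) || any(sc < 0) || any(sc > 4))
    stop("summarizeHistoScores: scores must be integers in [0, 4]")
  scores$composite <- as.integer(rowSums(sc))
  grp <- split(scores$composite, scores$group)
  groups <- data.frame(
    group = names(grp),
    n = vapply(grp, length, integer(1)),
    median = vapply(grp, stats::median, numeric(1)),
    iqr = vapply(grp, stats::IQR, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(sections = scores, groups = groups)
}
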