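## Raster phantoms: gross-lesion grayscale images with known ROI statistics
## and stained-section RGB images with a known number of positive cells.

#' Generate a gross-lesion image phantom
#'
#' 8-bit grayscale image with a connected (disc-shaped) lesion region at
#' \code{lesionGray} over a \code{backgroundGray} background, plus optional
#' bounded uniform integer noise. The mask marks the lesion ROI. The ground
#' truth carries both the nominal levels and the exact mean / integrated
#' density / median of the emitted pixels inside the mask.
#'
#' @param spec a \code{\link{phantomSpec}}; uses \code{imageSize},
#'   \code{lesionFraction}, \code{lesionGray}, \code{backgroundGray},
#'   \code{imageNoise} (half-width of uniform integer noise), \code{seed}.
#' @return list with \code{image} (integer matrix 0-255), \code{mask}
#'   (logical matrix) and \code{truth} (exact masked metrics and nominal
#'   parameters).
#' @export
generateLesionImage <- function(spec) {
  stopifnot(methods::is(spec, "PhantomSpec"))
  set.seed(spec@seed)
  h <- spec@imageSize[1L]
  w <- spec@imageSize[2L]
  r <- sqrt(spec@lesionFraction * h * w / pi)
  cy <- h / 2 + 0.5
  cx <- w / 2 + 0.5
  d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
  mask <- d2 <= r^2
  img <- matrix(spec@backgroundGray, h, w)
  img[mask] <- spec@lesionGray
  if (spec@imageNoise > 0) {
    k <- round(spec@imageNoise)
    img <- img + sample(seq(-k, k), h * w, replace = TRUE)
    img <- pmin(pmax(img, 0L), 255L)
  }
  storage.mode(img) <- "integer"
  px <- sort(img[mask])
  n <- length(px)
  truth <- list(
    mean_gray = mean(px), integrated_density = as.numeric(sum(px)),
    median_gray = as.numeric(px[ceiling(n / 2)]),  # lower-middle convention
    area_px = n,
    nominal = c(lesion_gray = spec@lesionGray,
                background_gray = spec@backgroundGray,
                lesion_fraction = spec@lesionFraction))
  list(image = img, mask = mask, truth = truth)
}

#' Generate a stained-section phantom with a known cell count
#'
#' RGB image (values 0-255) with \code{nCells} disjoint brown discs
#' (immunopositive cells) on a pale background, for validating
#' \code{\link{countStainedCells}}.
#'
#' @param nCells number of cells to place.
#' @param imageSize height and width (px).
#' @param cellRadiusPx disc radius (px).
#' @param seed RNG seed.
#' @return list with \code{image} (h x w x 3 array, 0-255) and \code{truth}
#'   (cell count and centers).
#' @export
generateStainedCellImage <- function(nCells = 25, imageSize = c(200L, 200L),
                                     cellRadiusPx = 4, seed = 1L) {
  set.seed(seed)
  h <- imageSize[1L]
  w <- imageSize[2L]
  img <- array(0, dim = c(h, w, 3L))
  img[, , 1L] <- 235; img[, , 2L] <- 225; img[, , 3L] <- 230  # pale mucosa
  margin <- cellRadiusPx + 2
  centers <- matrix(NA_real_, 0L, 2L)
  tries <- 0L
  while (nrow(centers) < nCells && tries < 20000L) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, margin, h - margin),
              stats::runif(1, margin, w - margin))
    if (nrow(centers) == 0L ||
        min((centers[, 1L] - cand[1L])^2 + (centers[, 2L] - cand[2L])^2) >
          (3 * cellRadiusPx)^2)
      centers <- rbind(centers, cand)
  }
  if (nrow(centers) < nCells)
    stop("generateStainedCellImage: could not place all cells disjointly")
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(h) - centers[i, 1L])^2,
                (seq_len(w) - centers[i, 2L])^2, `+`)
    disc <- d2 <= cellRadiusPx^2
    ## DAB brown: strong red, suppressed green/blue
    r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
    r[disc] <- 150; g[disc] <- 75; b[disc] <- 40
    img[, , 1L] <- r; img[, , 2L] <- g; img[, , 3L] <- b
  }
  list(image = img, truth = list(n_cells = nrow(centers), centers = centers))
}
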