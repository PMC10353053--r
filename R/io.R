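## Plain-text interchange formats: velocity fields as CSV matrix + JSON
## geometry sidecar, RR series as one interval per line, ECG as two-column
## CSV + sidecar, 8-bit images as PNG.

#' Read and write velocity fields (CSV + JSON sidecar)
#'
#' The CSV holds the velocity matrix (rows = spatial samples apex to base,
#' columns = time samples, cm/s); the JSON sidecar holds \code{ds_cm},
#' \code{dt_s}, \code{lv_length_cm}, \code{nyquist_cms}.
#'
#' @param field a \code{\link{VelocityField}}.
#' @param path CSV path; the sidecar is \code{<path>.json}.
#' @return \code{readVelocityField} returns a \code{VelocityField};
#'   \code{writeVelocityField} the CSV path, invisibly.
#' @export
writeVelocityField <- function(field, path) {
  stopifnot(methods::is(field, "VelocityField"))
  utils::write.table(field@values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(ds_cm = field@dsCm, dt_s = field@dtS,
               lv_length_cm = field@lvLengthCm,
               nyquist_cms = field@nyquistCms)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeVelocityField
#' @export
readVelocityField <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  methods::new("VelocityField", values = vals, dsCm = side$ds_cm,
               dtS = side$dt_s, lvLengthCm = side$lv_length_cm,
               nyquistCms = if (is.null(side$nyquist_cms)) NA_real_
                            else as.numeric(side$nyquist_cms))
}

#' Read and write RR-interval series (plain text)
#'
#' One interval (ms) per line; lines starting with \code{#} are comments.
#' Ectopic flags, if any, are appended as a \code{#flags} comment line of
#' 0/1 values and restored on read.
#'
#' @param rr an \code{\link{RRSeries}}.
#' @param path file path.
#' @export
writeRRSeries <- function(rr, path) {
  stopifnot(methods::is(rr, "RRSeries"))
  lines <- c("# RR intervals (ms)",
             format(rr@rrMs, digits = 12, trim = TRUE, scientific = FALSE))
  if (any(rr@ectopicFlags))
    lines <- c(lines, paste("#flags",
                            paste(as.integer(rr@ectopicFlags),
                                  collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeRRSeries
#' @export
readRRSeries <- function(path) {
  lines <- readLines(path)
  flagLine <- grep("^#flags", lines, value = TRUE)
  vals <- as.numeric(lines[!grepl("^#", lines)])
  flags <- rep(FALSE, length(vals))
  if (length(flagLine)) {
    bits <- strsplit(sub("^#flags\\s*", "", flagLine[1L]), "")[[1L]]
    flags <- bits == "1"
  }
  RRSeries(vals, ectopicFlags = flags)
}

#' Read and write ECG traces (CSV + JSON sidecar)
#'
#' Two-column CSV (\code{time_s}, \code{mv}); the sidecar holds
#' \code{fs_hz}.
#'
#' @param ecg an \code{\link{ECGRecord}}.
#' @param path CSV path; sidecar at \code{<path>.json}.
#' @export
writeEcgRecord <- function(ecg, path) {
  stopifnot(methods::is(ecg, "ECGRecord"))
  d <- data.frame(time_s = (seq_along(ecg@samplesMv) - 1L) / ecg@fsHz,
                  mv = ecg@samplesMv)
  utils::write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(list(fs_hz = ecg@fsHz), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEcgRecord
#' @export
readEcgRecord <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- utils::read.csv(path)
  ECGRecord(d$mv, side$fs_hz)
}

#' Read and write 8-bit grayscale PNG images
#'
#' @param image integer matrix with values 0-255 (write) / path (read).
#' @param path file path.
#' @return \code{readGrayPng} returns an integer matrix 0-255.
#' @export
writeGrayPng <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname writeGrayPng
#' @export
readGrayPng <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  mi <- round(m * 255)
  storage.mode(mi) <- "integer"
  mi
}
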