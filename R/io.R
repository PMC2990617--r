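# File formats. One CSV dialect everywhere: UTF-8, header row, '.' decimal,
# no index column; times in seconds, rates in s^-1. Time series are long
# format (time_s, peak, intensity); spectra are two-column (ppm,
# intensity); cohorts serialise to a directory with a JSON manifest.

.readCsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  df
}

#' Write a trajectory or peak series to CSV
#'
#' Long format with columns \code{time_s}, \code{peak}, \code{intensity}.
#'
#' @param x a \linkS4class{Trajectory} or \linkS4class{PeakSeries}.
#' @param path output file.
#' @param substrate,product peak labels for the two channels.
#' @return \code{path}, invisibly.
#' @export
writePeakSeries <- function(x, path, substrate = "pyruvate",
                            product = "lactate") {
  if (is(x, "Trajectory")) x <- asPeakSeries(x)
  stopifnot(is(x, "PeakSeries"))
  df <- rbind(
    data.frame(time_s = x@times, peak = substrate, intensity = x@substrate),
    data.frame(time_s = x@times, peak = product, intensity = x@product))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak series from CSV
#'
#' @param path CSV with columns \code{time_s}, \code{peak},
#'   \code{intensity}.
#' @param substrate,product which peak labels form the substrate/product
#'   channels; defaults to the first two labels in file order.
#' @return A raw \linkS4class{PeakSeries}.
#' @export
readPeakSeries <- function(path, substrate = NULL, product = NULL) {
  df <- .readCsv(path, c("time_s", "peak", "intensity"))
  labs <- unique(df$peak)
  if (is.null(substrate)) substrate <- labs[1]
  if (is.null(product)) product <- labs[2]
  s <- df[df$peak == substrate, ]
  p <- df[df$peak == product, ]
  if (!nrow(s)) stop("no rows for substrate peak '", substrate, "'")
  if (!nrow(p)) stop("no rows for product peak '", product, "'")
  s <- s[order(s$time_s), ]; p <- p[order(p$time_s), ]
  if (!isTRUE(all.equal(s$time_s, p$time_s)))
    stop("substrate and product time axes differ")
  PeakSeries(s$time_s, s$intensity, p$intensity)
}

#' Write / read a spectrum (two-column CSV: ppm, intensity)
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param path file path.
#' @return \code{path} (write) or a \linkS4class{Spectrum} (read).
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  utils::write.csv(data.frame(ppm = spectrum@ppm,
                              intensity = spectrum@intensity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  df <- .readCsv(path, c("ppm", "intensity"))
  Spectrum(df$ppm, df$intensity)
}

#' Read a peak table from CSV
#'
#' @param path CSV with columns name, shift, linewidth, amplitude.
#' @return A peak table data.frame.
#' @export
readPeakTable <- function(path) {
  .checkPeakTable(.readCsv(path, c("name", "shift", "linewidth", "amplitude")))
}

#' Serialise a cohort to a directory
#'
#' Writes \code{manifest.json} (per-sample metadata), one pyruvate and one
#' fumarate series CSV per sample, and one events CSV per sample with
#' columns annexin, sytox, nadh.
#'
#' @param samples list of \linkS4class{CohortSample}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  sch <- attr(samples, "scheme")
  if (!is.null(sch))
    manifest$scheme <- list(flip_angle = sch@flipAngle,
                            repetition_time = sch@repetitionTime,
                            n_transients = sch@nTransients,
                            t_first = sch@tFirst,
                            excluded_indices = sch@excludedIndices)
  manifest$samples <- lapply(samples, function(s) list(
    sampleId = s@sampleId, group = s@group, timepoint = s@timepoint,
    trueKp = s@trueKp, trueKf = s@trueKf, cellCount = s@cellCount,
    pyruvateFile = paste0(s@sampleId, "_pyruvate.csv"),
    fumarateFile = paste0(s@sampleId, "_fumarate.csv"),
    eventsFile = paste0(s@sampleId, "_events.csv")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (s in samples) {
    writePeakSeries(s@pyruvate, file.path(dir, paste0(s@sampleId, "_pyruvate.csv")),
                    "pyruvate", "lactate")
    writePeakSeries(s@fumarate, file.path(dir, paste0(s@sampleId, "_fumarate.csv")),
                    "fumarate", "malate")
    utils::write.csv(s@cytometry,
                     file.path(dir, paste0(s@sampleId, "_events.csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{writeCohort}}
#'
#' @param dir cohort directory containing \code{manifest.json}.
#' @return List of \linkS4class{CohortSample}.
#' @export
readCohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  samples <- lapply(manifest$samples, function(m) {
    pyr <- readPeakSeries(file.path(dir, m$pyruvateFile), "pyruvate", "lactate")
    fum <- readPeakSeries(file.path(dir, m$fumarateFile), "fumarate", "malate")
    evPath <- file.path(dir, m$eventsFile)
    events <- if (file.exists(evPath))
      .readCsv(evPath, c("annexin", "sytox", "nadh"))
    else data.frame(annexin = numeric(), sytox = numeric(), nadh = numeric())
    new("CohortSample", sampleId = m$sampleId, group = m$group,
        timepoint = as.numeric(m$timepoint), trueKp = as.numeric(m$trueKp),
        trueKf = as.numeric(m$trueKf), cellCount = as.numeric(m$cellCount),
        pyruvate = Trajectory(pyr@times, pyr@substrate, pyr@product),
        fumarate = Trajectory(fum@times, fum@substrate, fum@product),
        cytometry = events)
  })
  if (!is.null(manifest$scheme)) {
    s <- manifest$scheme
    attr(samples, "scheme") <- AcquisitionScheme(
      s$flip_angle, s$repetition_time, s$n_transients, tFirst = s$t_first,
      excludedIndices = as.integer(unlist(s$excluded_indices)))
  }
  samples
}
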