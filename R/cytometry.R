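# Synthetic annexin V / SYTOX flow cytometry with an NADH autofluorescence
# channel. Events are a mixture of three log-normal populations in the
# annexin x sytox plane (viable: double negative; apoptotic: annexin
# positive only; necrotic: double positive), with mixing weights from the
# treatment schedule. No instrument compensation or scatter gating is
# modelled.

.CYTO <- list(lowMeanlog = log(50), highMeanlog = log(2000), sdlog = 0.4,
              nadhMean = 1000, nadhSdlog = 0.3)

#' Default annexin/sytox gate thresholds
#'
#' The valley between the generated negative and positive populations (the
#' geometric midpoint of their medians).
#'
#' @return Named numeric vector with elements \code{annexin} and
#'   \code{sytox}.
#' @export
defaultGateThresholds <- function() {
  v <- exp((.CYTO$lowMeanlog + .CYTO$highMeanlog) / 2)
  c(annexin = v, sytox = v)
}

#' Generate synthetic flow-cytometry events
#'
#' Draws \code{nEvents} events from the treatment state at one schedule
#' timepoint: class weights are (viable, apoptotic, necrotic) =
#' (1 - a - n, a, n) from the schedule, fluorescence intensities are
#' log-normal per class, and the NADH autofluorescence channel has mean
#' proportional to the schedule's \code{nadhScale} (exactly: the log-normal
#' meanlog is shifted so the arithmetic mean scales).
#'
#' @param schedule a \linkS4class{TreatmentSchedule}.
#' @param timepoint one of the schedule's timepoints (h).
#' @param nEvents number of events, >= 100.
#' @param seed integer seed (NA uses the session RNG stream).
#' @return data.frame with columns \code{annexin}, \code{sytox},
#'   \code{nadh} (all fluorescence intensities, a.u., > 0).
#' @examples
#' ev <- generateCytometry(cellSchedule(), 72, nEvents = 1000, seed = 1)
#' gateEvents(ev)
#' @export
generateCytometry <- function(schedule, timepoint, nEvents = 20000L,
                              seed = NA_integer_) {
  stopifnot(is(schedule, "TreatmentSchedule"))
  if (nEvents < 100) stop("nEvents must be >= 100")
  st <- .scheduleAt(schedule, timepoint)
  w <- c(viable = 1 - st$apoptoticFrac - st$necroticFrac,
         apoptotic = st$apoptoticFrac, necrotic = st$necroticFrac)
  withSeed(seed, {
    cls <- sample(names(w), nEvents, replace = TRUE, prob = w)
    annexinHigh <- cls %in% c("apoptotic", "necrotic")
    sytoxHigh <- cls == "necrotic"
    mu <- function(high) ifelse(high, .CYTO$highMeanlog, .CYTO$lowMeanlog)
    nadhMeanlog <- log(.CYTO$nadhMean * max(st$nadhScale, 1e-9)) -
      .CYTO$nadhSdlog^2 / 2
    data.frame(
      annexin = stats::rlnorm(nEvents, mu(annexinHigh), .CYTO$sdlog),
      sytox = stats::rlnorm(nEvents, mu(sytoxHigh), .CYTO$sdlog),
      nadh = stats::rlnorm(nEvents, nadhMeanlog, .CYTO$nadhSdlog))
  })
}

#' Quadrant-gate cytometry events
#'
#' Viable cells stain with neither annexin V nor SYTOX; apoptotic cells
#' with annexin V but not SYTOX; necrotic cells with both. Annexin-negative
#' / SYTOX-positive events are reported separately as \code{other}.
#'
#' @param events data.frame with columns \code{annexin} and \code{sytox}.
#' @param thresholds named vector with positive cutoffs \code{annexin} and
#'   \code{sytox}.
#' @return Named numeric vector of fractions (viable, apoptotic, necrotic,
#'   other); the first three sum to <= 1.
#' @export
gateEvents <- function(events, thresholds = defaultGateThresholds()) {
  if (!nrow(events)) stop("empty event list")
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  aPos <- events$annexin > thresholds[["annexin"]]
  sPos <- events$sytox > thresholds[["sytox"]]
  n <- nrow(events)
  c(viable = sum(!aPos & !sPos) / n,
    apoptotic = sum(aPos & !sPos) / n,
    necrotic = sum(aPos & sPos) / n,
    other = sum(!aPos & sPos) / n)
}
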