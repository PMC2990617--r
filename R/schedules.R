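# Default treatment-effect schedules. Effect sizes come from the reported
# group statistics of the doxorubicin studies (never from figure
# digitisation): cell-suspension pyruvate-lactate exchange falls to 0.52x
# at 72 h and 0.28x at 96 h; fumarate-malate flux is undetectable before
# 72 h, then 2.8e-4 and 6.1e-4 s^-1; NADH autofluorescence falls to 0.23x
# and 0.11x. Tumour exchange falls to 0.51x (24 h) and 0.27x (48 h).
# Apoptotic/necrotic fractions are free design values chosen to follow the
# described time course (apoptosis peaking at 72 h, necrosis still rising
# at 96 h).

#' Default cell-suspension treatment schedule
#'
#' Untreated (0 h) plus 72 h and 96 h post-doxorubicin states of the
#' cell-suspension experiments.
#'
#' @return A \linkS4class{TreatmentSchedule}.
#' @examples
#' cellSchedule()
#' @export
cellSchedule <- function() {
  TreatmentSchedule(
    timepoints = c(0, 72, 96),
    kpScale = c(1, 0.52, 0.28),
    kfTrue = c(0, 2.8e-4, 6.1e-4),
    nadhScale = c(1, 0.23, 0.11),
    apoptoticFrac = c(0.05, 0.35, 0.25),
    necroticFrac = c(0.02, 0.15, 0.30))
}

#' Default tumour treatment schedule
#'
#' Untreated plus 24 h and 48 h post-doxorubicin states of the xenograft
#' experiments. Dynamic fumarate-malate fits are not feasible in vivo; the
#' kfTrue entries are the instantaneous-appearance idealisation
#' ratio(20 s) / 20 s of the measured 20-s malate/fumarate ratios (0.017
#' untreated, 0.090 at 24 h, held at 48 h where no ratio was measured).
#'
#' @return A \linkS4class{TreatmentSchedule}.
#' @examples
#' tumourSchedule()
#' @export
tumourSchedule <- function() {
  TreatmentSchedule(
    timepoints = c(0, 24, 48),
    kpScale = c(1, 0.51, 0.27),
    kfTrue = c(0.017, 0.090, 0.090) / 20,
    nadhScale = c(1, 1, 1),
    apoptoticFrac = c(0.05, 0.15, 0.20),
    necroticFrac = c(0.02, 0.12, 0.20))
}

# Row of a schedule at one timepoint (exact match required).
.scheduleAt <- function(schedule, timepoint) {
  i <- match(timepoint, schedule@timepoints)
  if (is.na(i))
    stop("timepoint ", timepoint, " h not in schedule (available: ",
         paste(schedule@timepoints, collapse = ", "), ")")
  list(timepoint = schedule@timepoints[i], kpScale = schedule@kpScale[i],
       kfTrue = schedule@kfTrue[i], nadhScale = schedule@nadhScale[i],
       apoptoticFrac = schedule@apoptoticFrac[i],
       necroticFrac = schedule@necroticFrac[i])
}
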