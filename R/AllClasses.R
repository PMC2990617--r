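# S4 classes for the hyperpolarised-exchange pipeline.

#' ExchangeParameters: rates of a two-pool label-exchange system
#'
#' Holds the first-order rate constants and longitudinal relaxation rates of
#' a hyperpolarised substrate/product pair, e.g. pyruvate/lactate (rate
#' constant k_P) or fumarate/malate (k_F), together with the initial
#' z-magnetisations.
#'
#' @slot kFwd forward rate constant substrate -> product (s^-1).
#' @slot kRev reverse rate constant product -> substrate (s^-1).
#' @slot r1Sub longitudinal relaxation rate (1/T1) of the substrate (s^-1).
#' @slot r1Prod longitudinal relaxation rate of the product (s^-1).
#' @slot m0Sub initial substrate z-magnetisation (arbitrary units), > 0.
#' @slot m0Prod initial product z-magnetisation, >= 0.
#' @export
setClass("ExchangeParameters",
  representation(kFwd = "numeric", kRev = "numeric",
                 r1Sub = "numeric", r1Prod = "numeric",
                 m0Sub = "numeric", m0Prod = "numeric"),
  prototype(kFwd = 0, kRev = 0, r1Sub = 1 / 30, r1Prod = 1 / 30,
            m0Sub = 1, m0Prod = 0))

setValidity("ExchangeParameters", function(object) {
  v <- c(kFwd = object@kFwd, kRev = object@kRev,
         r1Sub = object@r1Sub, r1Prod = object@r1Prod,
         m0Sub = object@m0Sub, m0Prod = object@m0Prod)
  if (any(lengths(list(object@kFwd, object@kRev, object@r1Sub,
                       object@r1Prod, object@m0Sub, object@m0Prod)) != 1L))
    return("all slots must be length-1 numeric")
  if (any(!is.finite(v))) return("all parameters must be finite")
  bad <- names(v)[v < 0]
  if (length(bad)) return(paste("negative value for:", paste(bad, collapse = ", ")))
  if (object@m0Sub <= 0) return("m0Sub must be > 0")
  TRUE
})

#' Construct ExchangeParameters
#'
#' @param kFwd,kRev exchange rate constants (s^-1); both default to 0.
#' @param r1Sub,r1Prod relaxation rates (s^-1); default 1/30 s^-1, i.e. the
#'   ~30 s polarisation half-life of [1-13C]pyruvate in vivo.
#' @param m0Sub,m0Prod initial magnetisations (arbitrary units).
#' @return An \linkS4class{ExchangeParameters} object.
#' @examples
#' ExchangeParameters(kFwd = 0.075)
#' @export
ExchangeParameters <- function(kFwd = 0, kRev = 0,
                               r1Sub = 1 / 30, r1Prod = 1 / 30,
                               m0Sub = 1, m0Prod = 0) {
  new("ExchangeParameters", kFwd = as.numeric(kFwd), kRev = as.numeric(kRev),
      r1Sub = as.numeric(r1Sub), r1Prod = as.numeric(r1Prod),
      m0Sub = as.numeric(m0Sub), m0Prod = as.numeric(m0Prod))
}

#' @rdname kFwd
#' @export
setMethod("kFwd", "ExchangeParameters", function(x) x@kFwd)

#' @rdname kFwd
#' @export
setMethod("kRev", "ExchangeParameters", function(x) x@kRev)

setMethod("show", "ExchangeParameters", function(object) {
  cat("ExchangeParameters\n")
  cat(sprintf("  kFwd: %.4g s^-1   kRev: %.4g s^-1\n", object@kFwd, object@kRev))
  cat(sprintf("  r1Sub: %.4g s^-1  r1Prod: %.4g s^-1 (T1 %.3g / %.3g s)\n",
              object@r1Sub, object@r1Prod,
              1 / object@r1Sub, 1 / object@r1Prod))
  cat(sprintf("  m0Sub: %.4g       m0Prod: %.4g\n", object@m0Sub, object@m0Prod))
})

#' AcquisitionScheme: timing of a pulse-and-acquire MRS readout train
#'
#' Describes a train of single-transient acquisitions: a small flip-angle
#' pulse every repetition time, each converting sin(theta) of the remaining
#' z-magnetisation to signal and leaving cos(theta).
#'
#' @slot flipAngle flip angle in degrees, strictly between 0 and 90.
#' @slot repetitionTime time between pulses (s), > 0.
#' @slot nTransients number of transients, >= 2.
#' @slot tFirst delay from substrate appearance to the first pulse (s).
#' @slot excludedIndices 1-based transient indices not usable for fitting
#'   (e.g. transients acquired from the whole coil-sensitive volume rather
#'   than the tumour slice).
#' @export
setClass("AcquisitionScheme",
  representation(flipAngle = "numeric", repetitionTime = "numeric",
                 nTransients = "integer", tFirst = "numeric",
                 excludedIndices = "integer"),
  prototype(flipAngle = 6, repetitionTime = 1, nTransients = 240L,
            tFirst = 1, excludedIndices = integer()))

setValidity("AcquisitionScheme", function(object) {
  if (length(object@flipAngle) != 1L || !is.finite(object@flipAngle) ||
      object@flipAngle <= 0 || object@flipAngle >= 90)
    return("flipAngle must be in (0, 90) degrees")
  if (length(object@repetitionTime) != 1L || !is.finite(object@repetitionTime) ||
      object@repetitionTime <= 0)
    return("repetitionTime must be > 0")
  if (length(object@nTransients) != 1L || object@nTransients < 2L)
    return("nTransients must be >= 2")
  if (length(object@tFirst) != 1L || !is.finite(object@tFirst) || object@tFirst < 0)
    return("tFirst must be >= 0")
  ei <- object@excludedIndices
  if (anyDuplicated(ei) || any(ei < 1L) || any(ei > object@nTransients))
    return("excludedIndices must be unique indices in [1, nTransients]")
  TRUE
})

#' Construct an AcquisitionScheme
#'
#' @param flipAngle flip angle (degrees).
#' @param repetitionTime inter-pulse interval (s).
#' @param nTransients number of transients.
#' @param tFirst delay to the first pulse (s); defaults to one repetition
#'   time (substrate appears at t = 0, first readout one TR later).
#' @param excludedIndices integer vector of 1-based transient indices to
#'   exclude from fitting.
#' @return An \linkS4class{AcquisitionScheme}.
#' @examples
#' cellScheme()
#' tumourScheme()
#' @export
AcquisitionScheme <- function(flipAngle, repetitionTime, nTransients,
                              tFirst = repetitionTime,
                              excludedIndices = integer()) {
  new("AcquisitionScheme", flipAngle = as.numeric(flipAngle),
      repetitionTime = as.numeric(repetitionTime),
      nTransients = as.integer(nTransients), tFirst = as.numeric(tFirst),
      excludedIndices = as.integer(sort(unique(excludedIndices))))
}

#' Standard acquisition schemes
#'
#' \code{cellScheme()} is the cell-suspension readout: one transient per
#' second for 240 s at a 6 degree flip angle. \code{tumourScheme()} is the
#' in-vivo readout: 128 transients, one per second, at a nominal 5 degree
#' flip angle; by default every sixteenth transient is excluded from fitting
#' (it samples the entire coil-sensitive volume, not the tumour slice).
#'
#' @param excludeEveryNth for \code{tumourScheme}, exclude every n-th
#'   transient (NULL to keep all).
#' @return An \linkS4class{AcquisitionScheme}.
#' @export
cellScheme <- function() AcquisitionScheme(6, 1, 240L)

#' @rdname cellScheme
#' @export
tumourScheme <- function(excludeEveryNth = 16L) {
  excl <- if (is.null(excludeEveryNth)) integer() else
    seq(as.integer(excludeEveryNth), 128L, by = as.integer(excludeEveryNth))
  AcquisitionScheme(5, 1, 128L, excludedIndices = excl)
}

setMethod("show", "AcquisitionScheme", function(object) {
  cat(sprintf("AcquisitionScheme: %g deg flip, TR %g s, %d transients, first pulse at %g s\n",
              object@flipAngle, object@repetitionTime, object@nTransients,
              object@tFirst))
  if (length(object@excludedIndices))
    cat("  excluded transients:", length(object@excludedIndices), "\n")
})

#' Trajectory: observed substrate/product signal per transient
#'
#' @slot times acquisition times (s), strictly increasing.
#' @slot signalSub substrate signal per transient (arbitrary units).
#' @slot signalProd product signal per transient.
#' @export
setClass("Trajectory",
  representation(times = "numeric", signalSub = "numeric",
                 signalProd = "numeric"))

setValidity("Trajectory", function(object) {
  n <- length(object@times)
  if (length(object@signalSub) != n || length(object@signalProd) != n)
    return("times, signalSub, signalProd must have equal length")
  if (n > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  TRUE
})

Trajectory <- function(times, signalSub, signalProd) {
  new("Trajectory", times = as.numeric(times),
      signalSub = as.numeric(signalSub), signalProd = as.numeric(signalProd))
}

#' @rdname times
#' @export
setMethod("times", "Trajectory", function(x) x@times)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d transients over %.4g-%.4g s\n",
              length(object@times), min(object@times), max(object@times)))
  cat(sprintf("  substrate peak signal %.4g, product peak signal %.4g\n",
              max(object@signalSub), max(object@signalProd)))
})

#' @export
#' @method as.data.frame Trajectory
as.data.frame.Trajectory <- function(x, ...) {
  data.frame(times = x@times, signalSub = x@signalSub,
             signalProd = x@signalProd)
}

setMethod("as.data.frame", "Trajectory", as.data.frame.Trajectory)

#' PeakSeries: per-peak intensity time course consumed by the fits
#'
#' A substrate/product intensity time course, optionally normalised by cell
#' count and by the initial substrate intensity (to correct for variation in
#' polarisation level between dissolutions).
#'
#' @slot times acquisition times (s).
#' @slot substrate substrate intensities.
#' @slot product product intensities.
#' @slot normalisation named list recording applied corrections
#'   (\code{cellCount}, \code{initialSubstrate}); empty if raw.
#' @export
setClass("PeakSeries",
  representation(times = "numeric", substrate = "numeric",
                 product = "numeric", normalisation = "list"),
  prototype(normalisation = list()))

setValidity("PeakSeries", function(object) {
  n <- length(object@times)
  if (length(object@substrate) != n || length(object@product) != n)
    return("times, substrate, product must have equal length")
  if (n > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  TRUE
})

#' Construct a PeakSeries
#'
#' @param times times (s).
#' @param substrate,product intensity vectors.
#' @param normalisation list of applied corrections (internal use).
#' @return A \linkS4class{PeakSeries}.
#' @export
PeakSeries <- function(times, substrate, product, normalisation = list()) {
  new("PeakSeries", times = as.numeric(times),
      substrate = as.numeric(substrate), product = as.numeric(product),
      normalisation = normalisation)
}

#' @rdname times
#' @export
setMethod("times", "PeakSeries", function(x) x@times)

setMethod("show", "PeakSeries", function(object) {
  cat(sprintf("PeakSeries: %d points over %.4g-%.4g s%s\n",
              length(object@times), min(object@times), max(object@times),
              if (length(object@normalisation)) " (normalised)" else ""))
})

#' Convert a Trajectory to a PeakSeries
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @return A raw (unnormalised) \linkS4class{PeakSeries}.
#' @export
asPeakSeries <- function(trajectory) {
  stopifnot(is(trajectory, "Trajectory"))
  PeakSeries(trajectory@times, trajectory@signalSub, trajectory@signalProd)
}

#' Spectrum: one synthetic 13C transient
#'
#' @slot ppm chemical-shift axis (ppm), monotonic.
#' @slot intensity intensity per point (arbitrary units).
#' @export
setClass("Spectrum",
  representation(ppm = "numeric", intensity = "numeric"))

setValidity("Spectrum", function(object) {
  if (length(object@ppm) != length(object@intensity))
    return("ppm and intensity must have equal length")
  d <- diff(object@ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    return("ppm axis must be monotonic")
  TRUE
})

Spectrum <- function(ppm, intensity)
  new("Spectrum", ppm = as.numeric(ppm), intensity = as.numeric(intensity))

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points, %.4g-%.4g ppm\n",
              length(object@ppm), min(object@ppm), max(object@ppm)))
})

#' SpectrumConfig: synthetic acquisition settings for one transient
#'
#' @slot spectralWidth spectral width (Hz); default 32000 (32 kHz).
#' @slot nPoints number of points (>= 256).
#' @slot carrierFrequency 13C carrier frequency (MHz); default 100 (9.4 T).
#' @slot centerPpm chemical shift at the centre of the window (ppm).
#' @slot noiseSd standard deviation of additive Gaussian noise (a.u.).
#' @slot seed integer seed for the noise draw (NA for the current RNG state).
#' @export
setClass("SpectrumConfig",
  representation(spectralWidth = "numeric", nPoints = "integer",
                 carrierFrequency = "numeric", centerPpm = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  prototype(spectralWidth = 32000, nPoints = 32768L, carrierFrequency = 100,
            centerPpm = 177, noiseSd = 0, seed = NA_integer_))

setValidity("SpectrumConfig", function(object) {
  if (object@spectralWidth <= 0) return("spectralWidth must be > 0")
  if (object@nPoints < 256L) return("nPoints must be >= 256")
  if (object@carrierFrequency <= 0) return("carrierFrequency must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Construct a SpectrumConfig
#'
#' @param spectralWidth spectral width (Hz).
#' @param nPoints number of points in the spectrum.
#' @param carrierFrequency carrier frequency (MHz); ppm = Hz / MHz.
#' @param centerPpm centre of the spectral window (ppm).
#' @param noiseSd additive Gaussian noise sd (a.u.).
#' @param seed integer seed making the noise reproducible; NA uses the
#'   session RNG stream.
#' @return A \linkS4class{SpectrumConfig}.
#' @export
SpectrumConfig <- function(spectralWidth = 32000, nPoints = 32768L,
                           carrierFrequency = 100, centerPpm = 177,
                           noiseSd = 0, seed = NA_integer_) {
  new("SpectrumConfig", spectralWidth = as.numeric(spectralWidth),
      nPoints = as.integer(nPoints),
      carrierFrequency = as.numeric(carrierFrequency),
      centerPpm = as.numeric(centerPpm), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' FitResult: one estimated exchange rate constant
#'
#' @slot k fitted forward rate constant (s^-1).
#' @slot kSe asymptotic standard error of k (s^-1).
#' @slot kRev fitted or fixed reverse rate constant (s^-1).
#' @slot m0 fitted initial substrate magnetisation.
#' @slot fixedParams named list of parameters held fixed (relaxation rates,
#'   reverse-rate convention).
#' @slot residualNorm residual sum of squares at the optimum.
#' @slot converged logical convergence flag.
#' @slot mode "unidirectional" or "bidirectional".
#' @export
setClass("FitResult",
  representation(k = "numeric", kSe = "numeric", kRev = "numeric",
                 m0 = "numeric", fixedParams = "list",
                 residualNorm = "numeric", converged = "logical",
                 mode = "character"))

setValidity("FitResult", function(object) {
  if (object@k < 0) return("k must be >= 0")
  if (object@residualNorm < 0) return("residualNorm must be >= 0")
  TRUE
})

#' @rdname kFwd
#' @export
setMethod("kFwd", "FitResult", function(x) x@k)

#' @rdname kFwd
#' @export
setMethod("kRev", "FitResult", function(x) x@kRev)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s): k = %.4g +/- %.2g s^-1%s\n", object@mode,
              object@k, object@kSe,
              if (object@converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  m0 = %.4g, residual norm = %.4g\n",
              object@m0, object@residualNorm))
})

#' TreatmentSchedule: cohort-level treatment effects over time
#'
#' Encodes, per post-treatment timepoint, the multiplicative effect on the
#' pyruvate-lactate rate constant (kpScale), the absolute fumarate-malate
#' rate constant (kfTrue, s^-1), the multiplicative effect on NADH
#' autofluorescence (nadhScale) and the apoptotic/necrotic cell fractions.
#' Timepoint 0 is the untreated state.
#'
#' @slot timepoints hours post-treatment.
#' @slot kpScale multiplicative k_P effect per timepoint.
#' @slot kfTrue absolute k_F (s^-1) per timepoint.
#' @slot nadhScale multiplicative NADH effect per timepoint.
#' @slot apoptoticFrac,necroticFrac cell fractions per timepoint.
#' @export
setClass("TreatmentSchedule",
  representation(timepoints = "numeric", kpScale = "numeric",
                 kfTrue = "numeric", nadhScale = "numeric",
                 apoptoticFrac = "numeric", necroticFrac = "numeric"))

setValidity("TreatmentSchedule", function(object) {
  n <- length(object@timepoints)
  if (any(lengths(list(object@kpScale, object@kfTrue, object@nadhScale,
                       object@apoptoticFrac, object@necroticFrac)) != n))
    return("all schedule vectors must match length(timepoints)")
  if (anyDuplicated(object@timepoints)) return("timepoints must be unique")
  if (any(object@kpScale < 0) || any(object@kfTrue < 0) ||
      any(object@nadhScale < 0))
    return("scales and rates must be >= 0")
  f <- object@apoptoticFrac + object@necroticFrac
  if (any(object@apoptoticFrac < 0) || any(object@necroticFrac < 0) ||
      any(object@apoptoticFrac > 1) || any(object@necroticFrac > 1) || any(f > 1))
    return("fractions must lie in [0,1] with apoptotic+necrotic <= 1")
  TRUE
})

#' Construct a TreatmentSchedule
#'
#' @param timepoints hours post-treatment (0 = untreated).
#' @param kpScale,kfTrue,nadhScale,apoptoticFrac,necroticFrac per-timepoint
#'   effect vectors; see \linkS4class{TreatmentSchedule}.
#' @return A \linkS4class{TreatmentSchedule}.
#' @export
TreatmentSchedule <- function(timepoints, kpScale, kfTrue, nadhScale,
                              apoptoticFrac, necroticFrac) {
  new("TreatmentSchedule", timepoints = as.numeric(timepoints),
      kpScale = as.numeric(kpScale), kfTrue = as.numeric(kfTrue),
      nadhScale = as.numeric(nadhScale),
      apoptoticFrac = as.numeric(apoptoticFrac),
      necroticFrac = as.numeric(necroticFrac))
}

setMethod("show", "TreatmentSchedule", function(object) {
  cat("TreatmentSchedule:\n")
  print(data.frame(timepoint_h = object@timepoints, kpScale = object@kpScale,
                   kfTrue = object@kfTrue, nadhScale = object@nadhScale,
                   apoptotic = object@apoptoticFrac,
                   necrotic = object@necroticFrac), row.names = FALSE)
})

#' CohortSample: one synthetic cell batch or animal
#'
#' @slot sampleId character identifier.
#' @slot group "untreated" or "treated".
#' @slot timepoint hours post-treatment.
#' @slot trueKp,trueKf the generating rate constants (s^-1).
#' @slot cellCount number of cells in the suspension.
#' @slot pyruvate observed pyruvate/lactate \linkS4class{Trajectory}.
#' @slot fumarate observed fumarate/malate \linkS4class{Trajectory}.
#' @slot cytometry data.frame of events (annexin, sytox, nadh), possibly
#'   0-row.
#' @export
setClass("CohortSample",
  representation(sampleId = "character", group = "character",
                 timepoint = "numeric", trueKp = "numeric",
                 trueKf = "numeric", cellCount = "numeric",
                 pyruvate = "Trajectory", fumarate = "Trajectory",
                 cytometry = "data.frame"))

setMethod("show", "CohortSample", function(object) {
  cat(sprintf("CohortSample %s [%s, %g h]: true kP %.4g, kF %.4g s^-1, %d events\n",
              object@sampleId, object@group, object@timepoint,
              object@trueKp, object@trueKf, nrow(object@cytometry)))
})

#' GroupSummary: mean +/- s.d. of one metric in one group
#'
#' @slot label group label.
#' @slot n number of values.
#' @slot mean,sd summary statistics.
#' @slot values the raw per-sample values.
#' @export
setClass("GroupSummary",
  representation(label = "character", n = "integer", mean = "numeric",
                 sd = "numeric", values = "numeric"))

setValidity("GroupSummary", function(object) {
  if (object@n != length(object@values))
    return("n must equal length(values)")
  if (!is.na(object@sd) && object@sd < 0) return("sd must be >= 0")
  TRUE
})

#' Summarise a group of values as mean +/- s.d.
#'
#' @param label group label.
#' @param values numeric vector.
#' @return A \linkS4class{GroupSummary}.
#' @export
groupSummary <- function(label, values) {
  values <- as.numeric(values)
  new("GroupSummary", label = as.character(label), n = length(values),
      mean = mean(values), sd = stats::sd(values), values = values)
}

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf("%s: %.4g +/- %.4g (n=%d)\n", object@label, object@mean,
              object@sd, object@n))
})
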