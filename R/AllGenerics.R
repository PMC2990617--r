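#' @import methods
NULL

#' Evolve a two-pool exchange system to time t
#'
#' @param params an \linkS4class{ExchangeParameters} object.
#' @param t numeric vector of times (s), all >= 0.
#' @param ... further arguments for methods.
#' @return A list with numeric vectors \code{mzSub} and \code{mzProd}, the
#'   longitudinal magnetisations of the two pools at each time.
#' @export
setGeneric("evolveClosedForm", function(params, t, ...)
  standardGeneric("evolveClosedForm"))

#' Simulate a small-flip-angle acquisition train
#'
#' @param params an \linkS4class{ExchangeParameters} object.
#' @param scheme an \linkS4class{AcquisitionScheme} object.
#' @param ... further arguments for methods.
#' @return A \linkS4class{Trajectory}.
#' @export
setGeneric("simulateAcquisition", function(params, scheme, ...)
  standardGeneric("simulateAcquisition"))

#' @rdname normaliseSeries
#' @export
setGeneric("normaliseSeries", function(series, cellCount)
  standardGeneric("normaliseSeries"))

#' Rate constant accessors
#'
#' \code{kFwd} and \code{kRev} return the forward and reverse exchange rate
#' constants (s^-1) stored in an object.
#'
#' @param x an object carrying rate constants.
#' @return numeric scalar.
#' @export
setGeneric("kFwd", function(x) standardGeneric("kFwd"))

#' @rdname kFwd
#' @export
setGeneric("kRev", function(x) standardGeneric("kRev"))

#' Transient sampling times
#'
#' @param x an object with a time axis.
#' @return numeric vector of times in seconds.
#' @export
setGeneric("times", function(x) standardGeneric("times"))
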