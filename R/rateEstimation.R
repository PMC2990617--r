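# Estimation of apparent exchange rate constants from peak time series by
# nonlinear least squares against the small-flip-angle two-site exchange
# forward model, and the 20-s malate/fumarate ratio readout.

#' Normalise a peak time series
#'
#' Divides all intensities by the cell count and then by the initial
#' substrate intensity, correcting for differences in cell number between
#' batches and in polarisation level between dissolutions. The applied
#' factors are recorded; re-normalising an already-normalised series is a
#' no-op (with a message).
#'
#' @param series a \linkS4class{PeakSeries}.
#' @param cellCount number of cells in the suspension, > 0.
#' @return A normalised \linkS4class{PeakSeries} whose substrate starts at 1.
#' @examples
#' s <- PeakSeries(0:3, c(4, 3, 2, 1), c(0, 0.5, 0.8, 0.9))
#' normaliseSeries(s, 2e7)
#' @export
setMethod("normaliseSeries", "PeakSeries", function(series, cellCount) {
  if (length(series@normalisation)) {
    message("series already normalised; returning unchanged")
    return(series)
  }
  if (cellCount <= 0) stop("cellCount must be > 0")
  if (series@substrate[1] <= 0)
    stop("first substrate intensity must be > 0 (uninterpretable run)")
  sub <- series@substrate / cellCount
  prod <- series@product / cellCount
  s0 <- sub[1]
  PeakSeries(series@times, sub / s0, prod / s0,
             normalisation = list(cellCount = cellCount,
                                  initialSubstrate = s0))
})

# Residual vector for the joint two-channel fit. p is on the log scale for
# positivity; layout depends on mode.
.fitResiduals <- function(p, series, scheme, mode, fixed, krevRatio,
                          productWeight, usable) {
  k <- exp(p[1])
  m0 <- exp(p[2])
  krev <- switch(mode,
                 unidirectional = 0,
                 bidirectional = if (is.null(krevRatio)) exp(p[3])
                                 else krevRatio * k)
  par <- ExchangeParameters(kFwd = k, kRev = krev, r1Sub = fixed[["r1Sub"]],
                            r1Prod = fixed[["r1Prod"]], m0Sub = m0,
                            m0Prod = 0)
  tr <- simulateAcquisition(par, scheme)
  c(tr@signalSub[usable] - series@substrate[usable],
    productWeight * (tr@signalProd[usable] - series@product[usable]))
}

#' Fit the two-site exchange rate constant to a peak time series
#'
#' Joint nonlinear least squares of both channels of the observed series
#' against \code{\link{simulateAcquisition}}. Free parameters are the
#' forward rate constant and the initial substrate magnetisation (plus the
#' reverse rate in free bidirectional mode); relaxation rates are held
#' fixed (with a single bolus and a <= 240 s window, k and 1/T1 are too
#' collinear to estimate jointly). Rates are log-parameterised, and the
#' optimiser (Levenberg-Marquardt, \code{minpack.lm}) is multi-started from
#' log-spaced initial rate values to avoid the k ~ 0 local basin.
#'
#' @param series a \linkS4class{PeakSeries} (raw or normalised).
#' @param scheme the \linkS4class{AcquisitionScheme} used to acquire the
#'   series; its excluded transients are dropped from the fit.
#' @param mode "unidirectional" (reverse rate fixed at 0; the default for
#'   fumarate -> malate, which is far from equilibrium on this timescale)
#'   or "bidirectional".
#' @param fixed named numeric vector/list with elements \code{r1Sub} and
#'   \code{r1Prod} (s^-1) held fixed during the fit.
#' @param krevRatio in bidirectional mode, if non-NULL the reverse rate is
#'   constrained to \code{krevRatio * k} instead of fitted freely.
#' @param productWeight weight applied to product-channel residuals
#'   (default 1: ordinary least squares on both channels).
#' @param nStarts number of log-spaced initial rate values (>= 5).
#' @param kRange range of initial rate values (s^-1).
#' @return A \linkS4class{FitResult}. If no start converges the result has
#'   \code{converged = FALSE} and carries the best attempt.
#' @examples
#' truth <- ExchangeParameters(kFwd = 0.075)
#' tr <- simulateAcquisition(truth, tumourScheme())
#' fitExchangeRate(asPeakSeries(tr), tumourScheme())
#' @export
fitExchangeRate <- function(series, scheme,
                            mode = c("unidirectional", "bidirectional"),
                            fixed = c(r1Sub = 1 / 30, r1Prod = 1 / 30),
                            krevRatio = NULL, productWeight = 1,
                            nStarts = 5, kRange = c(1e-4, 1)) {
  mode <- match.arg(mode)
  stopifnot(is(series, "PeakSeries"), is(scheme, "AcquisitionScheme"))
  if (length(series@times) != scheme@nTransients)
    stop("series length does not match scheme nTransients")
  fixed <- as.list(fixed)
  usable <- setdiff(seq_len(scheme@nTransients), scheme@excludedIndices)
  if (length(usable) < 10)
    stop("need >= 10 usable transients after exclusions")
  nStarts <- max(5, nStarts)
  kStarts <- exp(seq(log(kRange[1]), log(kRange[2]), length.out = nStarts))
  m0Guess <- max(series@substrate[usable][1], 1e-12) /
    sin(scheme@flipAngle * pi / 180)
  best <- NULL
  for (k0 in kStarts) {
    p0 <- c(log(k0), log(m0Guess))
    if (mode == "bidirectional" && is.null(krevRatio)) p0 <- c(p0, log(k0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = .fitResiduals, series = series,
                         scheme = scheme, mode = mode, fixed = fixed,
                         krevRatio = krevRatio,
                         productWeight = productWeight, usable = usable,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- fit$info %in% 1:4
    if (is.null(best) || (conv && !best$conv) ||
        (conv == best$conv && fit$deviance < best$fit$deviance))
      best <- list(fit = fit, conv = conv)
  }
  if (is.null(best))
    return(new("FitResult", k = 0, kSe = NA_real_, kRev = 0, m0 = m0Guess,
               fixedParams = fixed, residualNorm = Inf, converged = FALSE,
               mode = mode))
  fit <- best$fit
  k <- exp(fit$par[1])
  m0 <- exp(fit$par[2])
  krev <- switch(mode, unidirectional = 0,
                 bidirectional = if (is.null(krevRatio)) exp(fit$par[3])
                                 else krevRatio * k)
  # delta-method SE of k from the log-scale covariance
  kSe <- NA_real_
  dof <- 2 * length(usable) - length(fit$par)
  covLog <- tryCatch(solve(fit$hessian) * fit$deviance / dof,
                     error = function(e) NULL)
  if (!is.null(covLog) && is.finite(covLog[1, 1]) && covLog[1, 1] >= 0)
    kSe <- k * sqrt(covLog[1, 1])
  if (!is.null(krevRatio)) fixed$krevRatio <- krevRatio
  new("FitResult", k = k, kSe = kSe, kRev = krev, m0 = m0,
      fixedParams = fixed, residualNorm = fit$deviance,
      converged = best$conv, mode = mode)
}

#' Malate/fumarate ratio
#'
#' The positive-contrast cell-death readout: combined malate area divided
#' by the fumarate area in a single spectrum acquired ~20 s after fumarate
#' injection.
#'
#' @param fumarateArea fumarate peak area, > 0.
#' @param malateArea combined malate area (from \code{\link{combineMalate}}).
#' @return The ratio (unitless).
#' @examples
#' malateFumarateRatio(100, combineMalate(4.5, 4.5))
#' @export
malateFumarateRatio <- function(fumarateArea, malateArea) {
  if (fumarateArea <= 0) stop("fumarateArea must be > 0 (no substrate signal)")
  malateArea / fumarateArea
}

#' Spectral malate/fumarate measurement
#'
#' End-to-end 20-s-spectrum readout: render (or accept) a spectrum, quantify
#' the declared peaks, combine the malate C-1/C-4 areas and return their
#' ratio to fumarate.
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param peaks declared peak table (defaults to the in-vivo linewidth
#'   table).
#' @param ... passed to \code{\link{quantifyPeaks}}.
#' @return List with \code{ratio}, \code{fumarate} and \code{malate} areas.
#' @export
measureMalateFumarate <- function(spectrum, peaks = defaultPeakTable(60), ...) {
  areas <- quantifyPeaks(spectrum, peaks, ...)
  mal <- combineMalate(areas[["malate_C1"]], areas[["malate_C4"]])
  list(ratio = malateFumarateRatio(areas[["fumarate"]], mal),
       fumarate = areas[["fumarate"]], malate = mal)
}
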