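# Cohort-level response report: per-group summaries of the fitted rate
# constants, gated death fractions and NADH signal, with percent/fold
# changes and Mann-Whitney p-values against the untreated group.

.gsAsList <- function(gs)
  list(label = gs@label, n = gs@n, mean = gs@mean, sd = gs@sd,
       values = gs@values)

#' Build a treatment-response report for a fitted cohort
#'
#' Summarises each timepoint group (mean +/- s.d. of fitted k_P, fitted
#' k_F, gated viable/apoptotic/necrotic fractions and mean NADH signal) and
#' compares every treated timepoint against the untreated group with
#' percent change, fold change and the exact Mann-Whitney test. Raw values
#' are retained at full precision; displayed percents are rounded to
#' integers and rate constants to two significant figures.
#'
#' @param samples list of \linkS4class{CohortSample}.
#' @param fits data.frame from \code{\link{fitCohort}}; computed here if
#'   NULL.
#' @param scheme acquisition scheme, used only when \code{fits} is NULL.
#' @return List of class \code{hyperfluxReport}: \code{groups} (per
#'   timepoint metric summaries), \code{comparisons} (vs untreated),
#'   \code{missing} (samples whose fits did not converge; listed, never
#'   silently dropped).
#' @export
buildReport <- function(samples, fits = NULL, scheme = cellScheme()) {
  if (is.null(fits)) fits <- fitCohort(samples, scheme)
  tps <- sort(unique(fits$timepoint))
  if (length(tps) < 2) stop("need >= 2 groups to build a report")
  if (!0 %in% tps) stop("no untreated (0 h) group in cohort")

  missing <- fits$sampleId[(!is.na(fits$convergedP) & !fits$convergedP) |
                           (!is.na(fits$convergedF) & !fits$convergedF)]

  metricValues <- function(tp) {
    sel <- fits$timepoint == tp
    sub <- samples[vapply(samples, function(s) s@timepoint == tp, logical(1))]
    out <- list(kP = fits$khatP[sel], kF = fits$khatF[sel])
    gated <- lapply(sub, function(s)
      if (nrow(s@cytometry)) gateEvents(s@cytometry) else
        c(viable = NA_real_, apoptotic = NA_real_, necrotic = NA_real_,
          other = NA_real_))
    out$viableFrac <- vapply(gated, `[[`, numeric(1), "viable")
    out$apoptoticFrac <- vapply(gated, `[[`, numeric(1), "apoptotic")
    out$necroticFrac <- vapply(gated, `[[`, numeric(1), "necrotic")
    out$nadh <- vapply(sub, function(s)
      if (nrow(s@cytometry)) mean(s@cytometry$nadh) else NA_real_, numeric(1))
    lapply(out, function(v) v[!is.na(v)])
  }

  groupLabel <- function(tp) if (tp == 0) "untreated" else sprintf("%gh", tp)
  values <- stats::setNames(lapply(tps, metricValues), vapply(tps, groupLabel, ""))

  groups <- lapply(seq_along(tps), function(i) {
    lab <- groupLabel(tps[i])
    mets <- values[[lab]]
    list(timepoint = tps[i],
         metrics = lapply(mets, function(v)
           if (length(v)) .gsAsList(groupSummary(lab, v)) else NULL))
  })
  names(groups) <- names(values)

  base <- values[["untreated"]]
  comparisons <- list()
  for (tp in setdiff(tps, 0)) {
    lab <- groupLabel(tp)
    trt <- values[[lab]]
    cmp <- list()
    for (m in names(trt)) {
      bv <- base[[m]]; tv <- trt[[m]]
      if (length(bv) < 2 || length(tv) < 2 || mean(bv) <= 0) next
      test <- rankSumTest(bv, tv)
      cmp[[m]] <- list(
        percentChange = percentChange(mean(bv), mean(tv)),
        percentChangeRounded = percentChange(mean(bv), mean(tv), digits = 0),
        foldChange = foldChange(mean(bv), mean(tv)),
        p.value = test$p.value, significant = test$significant)
    }
    comparisons[[lab]] <- cmp
  }

  structure(list(groups = groups, comparisons = comparisons,
                 missing = as.character(missing)),
            class = "hyperfluxReport")
}

#' Write a report as machine-readable JSON
#'
#' @param report a \code{hyperfluxReport} from \code{\link{buildReport}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.hyperfluxReport <- function(x, ...) {
  cat("Treatment-response report\n=========================\n")
  for (g in names(x$groups)) {
    cat(sprintf("\nGroup %s:\n", g))
    for (m in names(x$groups[[g]]$metrics)) {
      s <- x$groups[[g]]$metrics[[m]]
      if (is.null(s)) next
      cat(sprintf("  %-14s %s +/- %s (n=%d)\n", m, signif(s$mean, 2),
                  signif(s$sd, 2), s$n))
    }
  }
  for (cmpName in names(x$comparisons)) {
    cat(sprintf("\n%s vs untreated:\n", cmpName))
    for (m in names(x$comparisons[[cmpName]])) {
      cc <- x$comparisons[[cmpName]][[m]]
      cat(sprintf("  %-14s %+d%% change (%.2g-fold), P = %.3g%s\n", m,
                  -as.integer(cc$percentChangeRounded), cc$foldChange,
                  cc$p.value, if (cc$significant) " *" else ""))
    }
  }
  if (length(x$missing))
    cat("\nNon-converged fits:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
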