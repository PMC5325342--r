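#' @importFrom minpack.lm nlsLM nls.lm.control
NULL

.fourPL <- function(logc, bottom, top, hill, log_ic50) {
  bottom + (top - bottom) / (1 + 10^((log_ic50 - logc) * hill))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Variable-slope model on log10 concentration,
#' \deqn{R(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
#'   {1 + 10^{(\log_{10}\mathrm{IC}_{50} - \log_{10} c)\,h}},}
#' fitted by least squares (Levenberg-Marquardt) over a deterministic
#' multi-start grid (hill in -0.5, -1, -2; curve midpoint started at the
#' dose whose mean response is closest to halfway between the data extremes
#' and at the median log dose), under box constraints appropriate for a
#' decreasing viability curve (bottom at or above zero, plateaus on either
#' side of the data midpoint, negative slope).
#' Responses are first normalized to the no-drug control mean (= 100%)
#' unless \code{normalize = FALSE}. Both the curve midpoint IC50
#' (\code{ic50}) and the absolute IC50 — the concentration giving 50% of
#' control growth — are reported; the latter matches the common operational
#' definition of half-maximal inhibition.
#'
#' @param concentration dose per well (uM); 0 marks control wells.
#' @param response measured fluorescence (or pre-normalized response) per
#'   well; replicates are fitted as individual points.
#' @param normalize divide by the control-well mean and scale to percent
#'   (default TRUE; requires at least one control well).
#' @return list of class \code{"fit4PL"}: bottom, top, hill, log_ic50, ic50,
#'   ic50_abs, rss, n, converged, increasing (response rises with dose),
#'   extrapolated (ic50_abs outside the fitted dose span).
#' @export
fit4PL <- function(concentration, response, normalize = TRUE) {
  stopifnot(length(concentration) == length(response))
  if (any(concentration < 0)) stop("negative concentration")
  ctrl <- response[concentration == 0]
  if (normalize) {
    if (!length(ctrl)) stop("no control wells (concentration 0)")
    response <- response / mean(ctrl) * 100
  }
  dose <- concentration > 0
  conc <- concentration[dose]; resp <- response[dose]
  if (length(unique(conc)) < 4)
    stop("at least 4 distinct positive concentrations required")
  out <- list(bottom = NA_real_, top = NA_real_, hill = NA_real_,
              log_ic50 = NA_real_, ic50 = NA_real_, ic50_abs = NA_real_,
              rss = NA_real_, n = length(resp), converged = FALSE,
              increasing = FALSE, extrapolated = FALSE)
  class(out) <- "fit4PL"
  logc <- log10(conc)
  mresp <- tapply(resp, conc, mean)
  if (stats::sd(resp) == 0) return(out)  # flat response: no curve to fit
  out$increasing <- stats::cor(log10(as.numeric(names(mresp))), mresp) > 0
  mid <- (max(resp) + min(resp)) / 2
  start_logc <- log10(as.numeric(names(mresp))[which.min(abs(mresp - mid))])
  # box constraints for a decreasing viability curve: plateaus on either
  # side of the data midpoint, midpoint inside (an extended) dose span
  lo <- c(bottom = 0, top = mid, hill = -10, log_ic50 = min(logc) - 2)
  hi <- c(bottom = mid, top = 1.5 * max(resp), hill = -0.01,
          log_ic50 = max(logc) + 2)
  best <- NULL
  for (h0 in c(-0.5, -1, -2)) for (l0 in unique(c(start_logc, stats::median(logc)))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        resp ~ .fourPL(logc, bottom, top, hill, log_ic50),
        start = list(bottom = max(0, min(resp)),
                     top = min(max(resp), hi[["top"]]),
                     hill = h0, log_ic50 = l0),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(out)
  cf <- stats::coef(best$fit)
  out$bottom <- unname(cf["bottom"]); out$top <- unname(cf["top"])
  out$hill <- unname(cf["hill"]); out$log_ic50 <- unname(cf["log_ic50"])
  out$ic50 <- 10^out$log_ic50
  out$rss <- best$rss
  out$converged <- out$bottom < out$top && !out$increasing
  # absolute IC50: response = 50% of control
  if (out$converged && min(out$bottom, out$top) < 50 &&
      max(out$bottom, out$top) > 50) {
    ratio <- (out$top - out$bottom) / (50 - out$bottom) - 1
    out$ic50_abs <- 10^(out$log_ic50 - log10(ratio) / out$hill)
    out$extrapolated <- out$ic50_abs < min(conc) || out$ic50_abs > max(conc)
  }
  out
}

#' @export
print.fit4PL <- function(x, ...) {
  cat("4PL fit:", if (x$converged) "converged" else "NOT converged", "\n")
  if (x$converged)
    cat(sprintf("  bottom %.3g, top %.3g, hill %.3g, IC50 %.4g (abs %.4g)\n",
                x$bottom, x$top, x$hill, x$ic50, x$ic50_abs))
  cat("  n =", x$n, " rss =", format(x$rss), "\n")
  invisible(x)
}

#' Fit 4PL curves for every (cell line, VPA status) group of a plate table
#'
#' @param table a dose-response data.frame (see
#'   \code{\link{readDoseResponse}}).
#' @return data.frame of fit parameters, one row per curve.
#' @export
fitDoseResponse <- function(table) {
  grp <- interaction(table$cell_line, table$vpa_status, drop = TRUE)
  do.call(rbind, lapply(levels(grp), function(g) {
    sub <- table[grp == g, ]
    f <- fit4PL(sub$concentration, sub$fluorescence)
    data.frame(cell_line = sub$cell_line[1], vpa_status = sub$vpa_status[1],
               bottom = f$bottom, top = f$top, hill = f$hill,
               ic50 = f$ic50, ic50_abs = f$ic50_abs, rss = f$rss,
               n = f$n, converged = f$converged, row.names = NULL)
  }))
}

#' Relative IC50 reduction after VPA pretreatment
#'
#' \code{1 - ic50_vpa / ic50_naive}; positive values mean sensitization
#' (the dose-response curve shifted left), negative values desensitization.
#'
#' @param ic50_naive,ic50_vpa positive IC50 estimates.
#' @return Relative reduction (vectorized).
#' @export
ic50Reduction <- function(ic50_naive, ic50_vpa) {
  .assertPositive(ic50_naive, "ic50_naive")
  .assertPositive(ic50_vpa, "ic50_vpa")
  1 - ic50_vpa / ic50_naive
}

#' siRNA rescue ratios relative to control siRNA
#'
#' For each siRNA, the VPA-induced temozolomide effect is
#' \deqn{\mathrm{effect} = \frac{P(\mathrm{VPA}+,\mathrm{TMZ}+)/P(\mathrm{VPA}+,\mathrm{TMZ}-)}
#'   {P(\mathrm{VPA}-,\mathrm{TMZ}+)/P(\mathrm{VPA}-,\mathrm{TMZ}-)}}
#' on mean proliferation readings P, and the reported value is
#' \code{effect(siRNA) / effect(siCTRL)}, so the control siRNA is exactly 1.
#' Values above 1 indicate desensitization by the knockdown (the presumed
#' rescue of the VPA effect), values below 1 additional sensitization.
#'
#' @param readings data.frame with columns \code{sirna}, \code{vpa}
#'   (logical), \code{tmz} (logical), \code{value} (positive proliferation
#'   reading; replicates are averaged).
#' @param control control siRNA identifier (default \code{"siCTRL"}).
#' @return data.frame: sirna, effect, relative, interpretation
#'   (sensitized/desensitized/neutral).
#' @export
sirnaRescue <- function(readings, control = "siCTRL") {
  need <- c("sirna", "vpa", "tmz", "value")
  miss <- setdiff(need, colnames(readings))
  if (length(miss)) stop("readings lack column(s): ", paste(miss, collapse = ", "))
  .assertPositive(readings$value, "proliferation readings")
  if (!control %in% readings$sirna) stop("control siRNA '", control, "' absent")
  effectOf <- function(si) {
    sub <- readings[readings$sirna == si, ]
    m <- function(v, t) {
      x <- sub$value[sub$vpa == v & sub$tmz == t]
      if (!length(x)) stop("siRNA '", si, "': missing condition vpa=", v,
                           ", tmz=", t)
      mean(x)
    }
    (m(TRUE, TRUE) / m(TRUE, FALSE)) / (m(FALSE, TRUE) / m(FALSE, FALSE))
  }
  sirnas <- unique(readings$sirna)
  eff <- vapply(sirnas, effectOf, 0)
  rel <- eff / eff[[control]]
  data.frame(sirna = sirnas, effect = unname(eff), relative = unname(rel),
             interpretation = ifelse(abs(rel - 1) < 1e-12, "neutral",
                                     ifelse(rel > 1, "desensitized",
                                            "sensitized")),
             row.names = NULL)
}

#' Delta-delta-Ct fold change
#'
#' \code{2^-ddCt} with \code{ddCt = (Ct_target_sample - Ct_ref_sample) -
#' (Ct_target_calibrator - Ct_ref_calibrator)}; the reference transcript
#' (e.g. GAPDH) normalizes input amounts, the calibrator (e.g.
#' non-neoplastic tissue) anchors the fold change.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_calibrator,ct_ref_calibrator
#'   finite Ct values (vectorized).
#' @return Fold changes.
#' @export
ddctFold <- function(ct_target_sample, ct_ref_sample,
                     ct_target_calibrator, ct_ref_calibrator) {
  vals <- c(ct_target_sample, ct_ref_sample,
            ct_target_calibrator, ct_ref_calibrator)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
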