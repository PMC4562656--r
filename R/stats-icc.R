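#' Classify an ICC point estimate
#'
#' Values above 0.9 are excellent, values between 0.8 and 0.9 (inclusive)
#' moderate, and values below 0.8 insufficient.
#'
#' @param icc numeric ICC estimate(s)
#' @return character vector of classifications
#' @export
#' @examples
#' classifyICC(c(0.92, 0.90, 0.75))
classifyICC <- function(icc) {
  ifelse(icc > 0.9, "excellent",
         ifelse(icc >= 0.8, "moderate", "insufficient"))
}

#' Single-measures intraclass correlation ICC(1,1)
#'
#' Computes the one-way random-effects, single-measures intraclass
#' correlation from ANOVA variance components,
#' \deqn{ICC = (MSB - MSW) / (MSB + (k_{eff} - 1) MSW),}
#' with an exact F-based confidence interval: with \eqn{F = MSB/MSW} and
#' the \eqn{F} quantiles \eqn{f^*} at \eqn{\alpha/2} on
#' \eqn{(a - 1, N - a)} degrees of freedom, each bound is
#' \eqn{(F/f^* - 1) / (F/f^* + k_{eff} - 1)}. Negative point estimates
#' (down to \eqn{-1/(k_{eff}-1)}) are reported as is, not truncated to
#' zero, so that simulation studies remain unbiased.
#'
#' @param vc a \code{\link{VarianceComponents-class}} from
#'   \code{\link{onewayAnova}}
#' @param alpha two-sided confidence level is \code{1 - alpha}
#'   (default 0.05)
#' @return an \code{\link{ICCResult-class}} object
#' @export
#' @examples
#' iccOneway(onewayAnova(c(1, 2, 3, 4, 9, 10), rep(1:3, each = 2)))
iccOneway <- function(vc, alpha = 0.05) {
  stopifnot(is(vc, "VarianceComponents"))
  if (vc@MSB == 0 && vc@MSW == 0)
    stop("ICC undefined: MSB and MSW are both zero")
  k <- vc@kEff
  a <- vc@nUnits
  N <- sum(vc@groupSizes)
  icc <- (vc@MSB - vc@MSW) / (vc@MSB + (k - 1) * vc@MSW)
  if (vc@MSW == 0) {
    lo <- hi <- 1
  } else {
    F <- vc@MSB / vc@MSW
    FL <- F / stats::qf(1 - alpha / 2, a - 1, N - a)
    FU <- F * stats::qf(1 - alpha / 2, N - a, a - 1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
  }
  new("ICCResult", icc = icc, ciLow = min(lo, icc), ciHigh = max(hi, icc),
      classification = classifyICC(icc))
}

#' Coefficient of repeatability
#'
#' The coefficient of repeatability is the within-subject standard
#' deviation multiplied by 2.77 (the conventional rounding of
#' \eqn{\sqrt{2} \times 1.96}); the absolute difference between two
#' repeated measurements of the same eye stays below it with 95 percent
#' probability. The constant is fixed at the printed value 2.77 so that
#' published tables are reproduced digit for digit.
#'
#' @param vc a \code{\link{VarianceComponents-class}} from
#'   \code{\link{onewayAnova}}
#' @return a \code{\link{CRResult-class}} with \code{sw} = sqrt(MSW)
#' @export
#' @examples
#' coefficientOfRepeatability(
#'   onewayAnova(c(1, 2, 3, 4, 9, 10), rep(1:3, each = 2)))
coefficientOfRepeatability <- function(vc) {
  stopifnot(is(vc, "VarianceComponents"))
  sw <- sqrt(vc@MSW)
  new("CRResult", cr = 2.77 * sw, sw = sw)
}
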