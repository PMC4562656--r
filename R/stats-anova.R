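#' One-way ANOVA variance components for repeated measurements
#'
#' Decomposes repeated thickness measurements into between-unit and
#' within-unit mean squares, with the eye as the unit of measurement.
#' Units contributing a single session carry no within-unit information
#' and are dropped with a warning. For unbalanced designs the effective
#' number of sessions per unit is
#' \deqn{k_0 = (N - \sum_i n_i^2 / N) / (a - 1)}
#' with \eqn{a} units and \eqn{N} total observations; for balanced designs
#' \eqn{k_0} reduces to the common group size \eqn{k}.
#'
#' @param values numeric vector of measurements (micrometres)
#' @param unit vector identifying the eye each measurement belongs to
#' @return a \code{\link{VarianceComponents-class}} object
#' @export
#' @examples
#' vc <- onewayAnova(c(1, 2, 3, 4, 9, 10), rep(1:3, each = 2))
#' vc  # MSB = 34.667, MSW = 0.5
onewayAnova <- function(values, unit) {
  stopifnot(length(values) == length(unit))
  keep <- !is.na(values) & !is.na(unit)
  values <- values[keep]
  unit <- as.character(unit)[keep]
  sizes <- table(unit)
  single <- names(sizes)[sizes < 2L]
  if (length(single)) {
    warning(length(single), " unit(s) with a single session dropped: ",
            paste(utils::head(single, 5L), collapse = ", "))
    keep <- !unit %in% single
    values <- values[keep]
    unit <- unit[keep]
    sizes <- table(unit)
  }
  a <- length(sizes)
  if (a < 2L)
    stop("at least 2 units with >= 2 sessions are required (got ", a, ")")
  N <- length(values)
  if (stats::var(values) == 0)
    stop("degenerate data: zero total variance across all measurements")
  means <- tapply(values, unit, mean)
  grand <- mean(values)
  ni <- as.numeric(sizes[names(means)])
  MSB <- sum(ni * (means - grand)^2) / (a - 1)
  MSW <- sum((values - means[unit])^2) / (N - a)
  kEff <- if (length(unique(ni)) == 1L) ni[1L] else
    (N - sum(ni^2) / N) / (a - 1)
  new("VarianceComponents", nUnits = a,
      groupSizes = as.integer(sizes[names(means)]),
      MSB = MSB, MSW = MSW, kEff = kEff)
}
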