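#' Bland-Altman analysis of repeated measurements
#'
#' For each eye, every unordered pair of sessions (j < l) contributes the
#' point (mean of the pair, difference x_j - x_l); an eye measured three
#' times therefore contributes three pairs. Bias, the SD of the
#' differences and the 1.96 SD limits of agreement are computed over the
#' pooled point cloud. With pure session noise of SD sigma_w the LoA
#' half-width 1.96 sqrt(2) sigma_w coincides with the coefficient of
#' repeatability.
#'
#' @param values numeric measurements (micrometres)
#' @param unit eye identifier per measurement
#' @param session session number per measurement (defines pair order)
#' @return a \code{\link{BlandAltmanResult-class}}
#' @export
#' @examples
#' blandAltman(c(1, 2, 3, 4, 9, 10), rep(1:3, each = 2), rep(1:2, 3))
blandAltman <- function(values, unit, session) {
  stopifnot(length(values) == length(unit),
            length(values) == length(session))
  keep <- !is.na(values)
  values <- values[keep]
  unit <- as.character(unit)[keep]
  session <- session[keep]
  pts <- list()
  for (u in unique(unit)) {
    i <- which(unit == u)
    i <- i[order(session[i])]
    if (length(i) < 2L) next
    cmb <- utils::combn(i, 2L)
    pts[[u]] <- data.frame(
      unit = u,
      mean = (values[cmb[1L, ]] + values[cmb[2L, ]]) / 2,
      diff = values[cmb[1L, ]] - values[cmb[2L, ]],
      stringsAsFactors = FALSE)
  }
  if (!length(pts))
    stop("no unit has two or more sessions: nothing to pair")
  points <- do.call(rbind, pts)
  rownames(points) <- NULL
  bias <- mean(points$diff)
  sdDiff <- if (nrow(points) > 1L) stats::sd(points$diff) else 0
  new("BlandAltmanResult", points = points, bias = bias, sdDiff = sdDiff,
      loaLow = bias - 1.96 * sdDiff, loaHigh = bias + 1.96 * sdDiff)
}
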