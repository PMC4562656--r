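#' Repeatability grid: ICC and CR per estimate and layer
#'
#' Runs the one-way ANOVA, ICC(1,1) with confidence interval, and the
#' coefficient of repeatability for every (estimate, layer) cell of a
#' long-format repeated-measures table, optionally restricted to one
#' cohort. The eye is the unit of measurement; both eyes of a subject
#' enter as independent units. Mixed cohorts are typically unbalanced
#' (controls with three sessions, patients with two) and are handled via
#' the effective group size k0.
#'
#' @param table repeated-measures data.frame as produced by
#'   \code{\link{applyAll}} (columns \code{subject_id}, \code{eye},
#'   \code{group}, \code{session}, \code{device}, \code{estimate},
#'   \code{layer}, \code{thickness_um})
#' @param cohort \code{"mixed"} (all rows), \code{"HC"} or \code{"MS"}
#' @param alpha confidence level for the ICC interval (default 0.05)
#' @return data.frame with one row per populated (estimate, layer) cell:
#'   \code{estimate}, \code{layer}, \code{n_eyes}, \code{n_obs},
#'   \code{icc}, \code{ci_low}, \code{ci_high}, \code{classification},
#'   \code{sw}, \code{cr}; ordered estimates A..L by layer report order.
#' @export
repeatabilityTable <- function(table, cohort = c("mixed", "HC", "MS"),
                               alpha = 0.05) {
  cohort <- match.arg(cohort)
  if (cohort != "mixed") table <- table[table$group == cohort, ,
                                        drop = FALSE]
  if (nrow(table) == 0L)
    stop("no records left after filtering for cohort '", cohort, "'")
  ests <- intersect(LETTERS[1:12], unique(table$estimate))
  out <- list()
  for (est in ests) {
    for (layer in intersect(retinalLayers(), unique(table$layer))) {
      cell <- table[table$estimate == est & table$layer == layer, ,
                    drop = FALSE]
      if (nrow(cell) == 0L) next
      unit <- paste(cell$subject_id, cell$eye, sep = ":")
      res <- tryCatch({
        vc <- onewayAnova(cell$thickness_um, unit)
        icc <- iccOneway(vc, alpha = alpha)
        cr <- coefficientOfRepeatability(vc)
        data.frame(estimate = est, layer = layer, n_eyes = vc@nUnits,
                   n_obs = sum(vc@groupSizes), icc = icc@icc,
                   ci_low = icc@ciLow, ci_high = icc@ciHigh,
                   classification = icc@classification, sw = cr@sw,
                   cr = cr@cr, stringsAsFactors = FALSE)
      }, error = function(e) {
        warning("cell (", est, ", ", layer, ") skipped: ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(res)) out[[paste(est, layer)]] <- res
    }
  }
  if (!length(out)) stop("no computable (estimate, layer) cell")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## report column labels: the macular RNFL is conventionally printed mRNFL
.layerLabels <- function() {
  c(RNFL = "mRNFL", GCL = "GCL", IPL = "IPL", GCIP = "GCIP", INL = "INL",
    OPL = "OPL", ONL = "ONL")
}

.wideGrid <- function(rt, fill) {
  labs <- .layerLabels()
  grid <- matrix(NA_character_, 12L, length(labs),
                 dimnames = list(LETTERS[1:12], unname(labs)))
  for (i in seq_len(nrow(rt)))
    grid[rt$estimate[i], labs[[rt$layer[i]]]] <- fill(rt[i, ])
  data.frame(Estimate = rownames(grid), grid, check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Format a repeatability grid the way reliability tables are printed
#'
#' \code{formatICCTable} renders each populated cell as
#' \code{"icc [low-high]"} with two decimals; \code{formatCRTable}
#' renders the coefficient of repeatability in micrometres with two
#' decimals. Rows are estimates A..L, columns the seven layers in report
#' order (mRNFL, GCL, IPL, GCIP, INL, OPL, ONL); cells an estimate does
#' not provide (e.g. GCL under the Cirrus estimates K and L) stay
#' \code{NA}.
#'
#' @param rt long repeatability grid from \code{\link{repeatabilityTable}}
#' @return data.frame with an \code{Estimate} column plus one character
#'   column per layer
#' @export
formatICCTable <- function(rt) {
  .wideGrid(rt, function(row)
    sprintf("%.2f [%.2f-%.2f]", row$icc, row$ci_low, row$ci_high))
}

#' @rdname formatICCTable
#' @export
formatCRTable <- function(rt) {
  .wideGrid(rt, function(row) sprintf("%.2f", row$cr))
}
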