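## Interchange formats: the long repeated-measures TSV that links the
## estimate engine to the reliability statistics, and the generic
## surface-export CSV for segmentation boundaries.

.longTableColumns <- c("subject_id", "eye", "group", "session", "device",
                       "estimate", "layer", "thickness_um", "n_cells")

#' Read and validate a repeated-measures TSV
#'
#' The long-format table has one row per eye x session x estimate x layer
#' with tab-separated columns \code{subject_id}, \code{eye}, \code{group},
#' \code{session}, \code{device}, \code{estimate}, \code{layer},
#' \code{thickness_um}, \code{n_cells} (UTF-8, one header row). Unknown
#' extra columns are preserved. Schema violations - missing required
#' columns, non-numeric thickness, negative thickness, duplicated
#' (eye, session, estimate, layer) keys - are rejected with the offending
#' row number.
#'
#' @param path file path
#' @return validated data.frame
#' @export
readLongTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  missing <- setdiff(.longTableColumns, names(tab))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  num <- suppressWarnings(as.numeric(tab$thickness_um))
  bad <- which(is.na(num) & !is.na(tab$thickness_um) &
                 tab$thickness_um != "NA")
  if (length(bad))
    stop("non-numeric thickness_um '", tab$thickness_um[bad[1L]],
         "' at row ", bad[1L] + 1L)  # +1 for the header line
  tab$thickness_um <- num
  tab$session <- as.integer(tab$session)
  tab$n_cells <- as.integer(tab$n_cells)
  validateLongTable(tab)
  tab
}

#' @rdname readLongTable
#' @param table data.frame to validate or write
#' @export
validateLongTable <- function(table) {
  bad <- which(!is.na(table$thickness_um) & table$thickness_um < 0)
  if (length(bad))
    stop("negative thickness_um at row ", bad[1L] + 1L)
  bad <- which(is.na(table$session) | table$session < 1L)
  if (length(bad))
    stop("invalid session at row ", bad[1L] + 1L)
  key <- with(table, paste(subject_id, eye, session, estimate, layer,
                           sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (eye, session, estimate, layer) at row ",
         dup[1L] + 1L, ": ", gsub("\r", "/", key[dup[1L]]))
  invisible(table)
}

#' @rdname readLongTable
#' @export
writeLongTable <- function(table, path) {
  validateLongTable(table)
  ord <- c(intersect(.longTableColumns, names(table)),
           setdiff(names(table), .longTableColumns))
  utils::write.table(table[, ord, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write and read segmentation surfaces in the generic export schema
#'
#' One file per eye and session: a header block of \code{# key: value}
#' lines carrying the protocol (name, extents, axial scale, device, ART
#' frames) and acquisition tags, followed by CSV columns
#' \code{bscan_index}, \code{ascan_index}, \code{boundary_name},
#' \code{position_px}. Missing positions are omitted from the file and
#' read back as \code{NA}.
#'
#' @param volume a \code{\link{SegmentedVolume-class}}
#' @param path file path
#' @return \code{writeSurfaceCSV}: the path, invisibly;
#'   \code{readSurfaceCSV}: a \code{\link{SegmentedVolume-class}}
#' @export
writeSurfaceCSV <- function(volume, path) {
  stopifnot(is(volume, "SegmentedVolume"))
  p <- volume@protocol
  hdr <- c(
    paste0("# protocol: ", p@name),
    paste0("# width_mm: ", format(p@widthMm)),
    paste0("# height_mm: ", format(p@heightMm)),
    paste0("# axial_scale_um_per_px: ", format(p@axialScaleUmPerPx)),
    paste0("# device: ", p@device),
    paste0("# art_frames: ", p@artFrames),
    vapply(names(volume@meta), function(k)
      paste0("# meta_", k, ": ", volume@meta[[k]]), character(1L)))
  rows <- lapply(names(volume@boundaries), function(nm) {
    b <- volume@boundaries[[nm]]
    idx <- which(!is.na(b), arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(bscan_index = idx[, 1L], ascan_index = idx[, 2L],
               boundary_name = nm, position_px = b[idx])
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$bscan_index, tab$ascan_index,
                   match(tab$boundary_name, boundaryNames())), ]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSurfaceCSV
#' @export
readSurfaceCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  isHdr <- grepl("^#", lines)
  hdr <- lines[isHdr]
  kv <- regmatches(hdr, regexec("^# *([^:]+): *(.*)$", hdr))
  keys <- vapply(kv, `[`, character(1L), 2L)
  vals <- vapply(kv, `[`, character(1L), 3L)
  names(vals) <- keys
  need <- c("protocol", "width_mm", "height_mm", "axial_scale_um_per_px")
  if (!all(need %in% keys))
    stop("surface CSV header lacks: ",
         paste(setdiff(need, keys), collapse = ", "))
  geom <- parseProtocolName(vals[["protocol"]])
  protocol <- ScanProtocol(
    geom$direction, geom$nBScans, geom$nAScans,
    as.numeric(vals[["width_mm"]]), as.numeric(vals[["height_mm"]]),
    as.numeric(vals[["axial_scale_um_per_px"]]),
    artFrames = if ("art_frames" %in% keys)
      suppressWarnings(as.integer(vals[["art_frames"]])) else NA,
    device = if ("device" %in% keys) vals[["device"]] else "spectralis")
  metaKeys <- keys[startsWith(keys, "meta_")]
  meta <- as.list(vals[metaKeys])
  names(meta) <- sub("^meta_", "", metaKeys)
  if (!is.null(meta$session)) meta$session <- as.integer(meta$session)
  tab <- utils::read.csv(text = lines[!isHdr], header = TRUE)
  need <- c("bscan_index", "ascan_index", "boundary_name", "position_px")
  if (!all(need %in% names(tab)))
    stop("surface CSV lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  boundaries <- lapply(
    split(tab, factor(tab$boundary_name,
                      intersect(boundaryNames(),
                                unique(tab$boundary_name)))),
    function(d) {
      m <- matrix(NA_real_, protocol@nBScans, protocol@nAScans)
      if (any(d$bscan_index < 1L | d$bscan_index > protocol@nBScans |
              d$ascan_index < 1L | d$ascan_index > protocol@nAScans))
        stop("surface CSV index outside the ", protocol@name, " grid")
      m[cbind(d$bscan_index, d$ascan_index)] <- d$position_px
      m
    })
  SegmentedVolume(protocol, boundaries, meta = meta)
}
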