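# Image and table I/O: TIFF stacks in, single-channel TIFFs, CSV tables
# and RGB overlays out. Disk representation is unsigned-integer digital
# numbers (DN): a b-bit plane holds integers in [0, 2^b - 1] and round
# trips bit-exactly; 32-bit float planes are read as stored.

tiffPixelSizeUm <- function(info) {
  if (is.null(info)) return(NA_real_)
  xres <- info$x.resolution
  unit <- info$resolution.unit
  if (is.null(xres) || !is.numeric(xres) || !length(xres) ||
      !is.finite(xres[1]) || xres[1] <= 0)
    return(NA_real_)
  if (is.null(unit) || !length(unit)) return(NA_real_)
  perUm <- switch(as.character(unit[1]),
                  inch = xres[1] / 25400,
                  cm   = xres[1] / 1e4,
                  return(NA_real_))
  1 / perUm
}

#' Read a multi-channel TIFF stack
#'
#' Each plane of the stack becomes one channel, in plane order, with
#' pixel values preserved bit-exactly (integer planes are read as raw
#' digital numbers, float planes as stored). The pixel size is taken
#' from the TIFF resolution metadata when present; an explicit
#' \code{pixelSizeUm} always wins; if neither is available the read
#' fails, because all downstream distances are reported in micrometres.
#'
#' @param path path to a single- or multi-plane grayscale TIFF
#'   (8/16-bit unsigned or 32-bit float).
#' @param pixelSizeUm optional pixel-size override in micrometres.
#' @param channelNames optional character vector of channel names;
#'   defaults to \code{ch1..chN}.
#' @return a \linkS4class{MultiChannelImage}.
#' @export
readStack <- function(path, pixelSizeUm = NULL, channelNames = NULL) {
  planes <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e)
      stopCondition("read_error",
                    sprintf("cannot read TIFF '%s': %s", path,
                            conditionMessage(e))))
  if (!is.list(planes)) planes <- list(planes)
  if (length(planes) == 0L)
    stopCondition("empty_stack_error", sprintf("no planes in '%s'", path))
  if (any(vapply(planes, function(p) length(dim(p)) != 2L, logical(1))))
    stopCondition("read_error",
                  "only single-sample (grayscale) planes are supported")
  ps <- if (!is.null(pixelSizeUm)) as.numeric(pixelSizeUm)
        else tiffPixelSizeUm(attributes(planes[[1]]))
  if (is.na(ps))
    stopCondition("calibration_error",
                  "no pixel size in TIFF metadata and no override supplied")
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_along(planes))
  if (length(channelNames) < length(planes))
    stopCondition("parameter_error", "fewer channel names than planes")
  chs <- lapply(seq_along(planes), function(i) {
    m <- planes[[i]]
    attributes(m) <- list(dim = dim(m))
    storage.mode(m) <- "double"
    ChannelImage(channelNames[i], m, ps)
  })
  MultiChannelImage(chs)
}

#' Write a multi-channel TIFF stack
#'
#' Channels are written as planes of an unsigned-integer TIFF; values
#' must be integers in \code{[0, 2^bitsPerSample - 1]} so that
#' \code{writeStack} then \code{\link{readStack}} is a bit-exact round
#' trip. No resolution metadata is written; supply the pixel size when
#' reading back.
#'
#' @param stack a \linkS4class{MultiChannelImage} (or single
#'   \linkS4class{ChannelImage}).
#' @param path output path.
#' @param bitsPerSample 8 or 16.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, bitsPerSample = 16L) {
  if (is(stack, "ChannelImage")) stack <- MultiChannelImage(list(stack))
  if (!bitsPerSample %in% c(8L, 16L))
    stopCondition("parameter_error", "bitsPerSample must be 8 or 16")
  mx <- 2^bitsPerSample - 1
  planes <- lapply(stack@channels, function(ch) {
    p <- ch@pixels
    if (any(p > mx) || any(p != round(p)))
      stopCondition("parameter_error", sprintf(
        "pixel values must be integers in [0, %d] for %d-bit output",
        mx, bitsPerSample))
    p / mx
  })
  ok <- tryCatch({
    tiff::writeTIFF(planes, path, bits.per.sample = bitsPerSample,
                    reduce = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopCondition("write_error", sprintf("cannot write '%s'", path))
  invisible(path)
}

#' Split a stack into single-channel TIFF files
#'
#' Mirrors batch stack-to-single-channel conversion: one grayscale TIFF
#' per channel, named \code{<stem><suffix_i>.tif} in channel order, each
#' pixel-identical to its source channel.
#'
#' @param stack a \linkS4class{MultiChannelImage}.
#' @param suffixes character vector, at least one suffix per channel
#'   (extras are ignored).
#' @param outDir writable output directory.
#' @param stem file-name stem; default \code{"image"}.
#' @param bitsPerSample bit depth passed to \code{\link{writeStack}}.
#' @return character vector of written paths, in channel order.
#' @export
splitChannels <- function(stack, suffixes, outDir, stem = "image",
                          bitsPerSample = 16L) {
  nch <- length(stack@channels)
  if (length(suffixes) < nch)
    stopCondition("suffix_count_error", sprintf(
      "%d suffixes supplied for %d channels; one suffix per channel is required",
      length(suffixes), nch))
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  paths <- character(nch)
  for (i in seq_len(nch)) {
    paths[i] <- file.path(outDir, paste0(stem, suffixes[i], ".tif"))
    writeStack(stack@channels[[i]], paths[i], bitsPerSample = bitsPerSample)
  }
  paths
}

#' Merge channels by per-pixel maximum
#'
#' Produces a comprehensive nuclear image from several nuclear-emitting
#' channels (e.g. mAG + mKO2 + DRAQ7 when no dedicated DNA stain was
#' imaged). The per-pixel maximum keeps the merged image a valid seed
#' image for segmentation and cannot overflow; merging is commutative
#' and idempotent.
#'
#' @param channels list of \linkS4class{ChannelImage} with identical
#'   dimensions and pixel size.
#' @return a \linkS4class{ChannelImage} named \code{"merged"}.
#' @export
mergeChannels <- function(channels) {
  if (is(channels, "MultiChannelImage")) channels <- channels@channels
  if (length(channels) < 1L)
    stopCondition("parameter_error", "at least one channel is required")
  d <- dim(channels[[1]]@pixels)
  for (ch in channels)
    if (!identical(dim(ch@pixels), d))
      stopCondition("shape_error", "channel dimensions differ")
  out <- Reduce(pmax, lapply(channels, pixels))
  ChannelImage("merged", out, channels[[1]]@pixelSizeUm)
}

# Canonical number formatting for tables: locale-independent, 9
# significant digits, so that write -> read -> write is byte-identical.
formatTableField <- function(x) {
  if (is.integer(x)) return(as.character(x))
  if (is.logical(x)) return(ifelse(x, "TRUE", "FALSE"))
  if (is.numeric(x)) {
    out <- sprintf("%.9g", x)
    out[is.na(x)] <- "NA"
    return(out)
  }
  as.character(x)
}

#' Write an object-record table as CSV
#'
#' Comma-delimited, UTF-8, Unix newlines, one header row and one row per
#' object. Doubles are printed with 9 significant digits and a period
#' decimal separator, so numeric values round-trip losslessly at that
#' precision and a write/read/write cycle is byte-identical.
#'
#' @param records data.frame of per-object records.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeObjectTable <- function(records, path) {
  stopifnot(is.data.frame(records))
  cols <- lapply(records, formatTableField)
  lines <- paste(names(records), collapse = ",")
  if (nrow(records) > 0)
    lines <- c(lines, do.call(paste, c(cols, sep = ",")))
  con <- tryCatch(file(path, "wb"),
                  error = function(e)
                    stopCondition("write_error",
                                  sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read back a CSV written by \code{\link{writeObjectTable}}
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readObjectTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.categoryColours <- c(accepted = "green", discarded_size = "magenta",
                      discarded_border = "yellow")
.colourRGB <- list(green = c(0, 1, 0), magenta = c(1, 0, 1),
                   yellow = c(1, 1, 0))

#' Render a segmentation overlay
#'
#' Draws object outlines (or fills) over the min-max rescaled grayscale
#' image, coloured by category: accepted objects green, size-discarded
#' magenta, border-discarded yellow. Outline pixels are the 8-neighbour
#' label-boundary pixels (object pixels adjacent to background, another
#' label, or the image border).
#'
#' @param image a \linkS4class{ChannelImage}.
#' @param labels a \linkS4class{LabelMap} of the same dimensions.
#' @param mode \code{"outlines"} or \code{"filled"}.
#' @return an 8-bit quantised RGB array with dim \code{c(nrow, ncol, 3)}
#'   and values in [0, 1].
#' @export
renderOverlay <- function(image, labels, mode = c("outlines", "filled")) {
  mode <- match.arg(mode)
  px <- image@pixels
  lb <- labels@labels
  if (!identical(dim(px), dim(lb)))
    stopCondition("shape_error", "image and label dimensions differ")
  rng <- range(px)
  g <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1]) else px * 0
  rgb <- array(g, dim = c(dim(px), 3L))
  sel <- if (mode == "outlines") boundaryPixelMask(lb) else lb > 0L
  idx <- which(sel)
  if (length(idx)) {
    cat4 <- labels@categories[lb[idx]]
    col <- .categoryColours[cat4]
    n <- length(px)
    for (k in 1:3) {
      plane <- rgb[, , k]
      plane[idx] <- vapply(col, function(cc) .colourRGB[[cc]][k], numeric(1))
      rgb[, , k] <- plane
    }
  }
  round(rgb * 255) / 255
}

#' Write an overlay as PNG
#'
#' @param rgb RGB array from \code{\link{renderOverlay}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOverlayPNG <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}
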