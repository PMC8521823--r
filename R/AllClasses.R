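#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib SpheroidProfiler, .registration = TRUE
NULL

#' ChannelImage: one calibrated fluorescence channel
#'
#' A single-channel 2D pixel grid with a physical calibration. Pixels are
#' stored as a numeric matrix indexed \code{[row, col]}; exported pixel
#' coordinates are 0-based and row-major, and a pixel's centroid
#' contribution is its index (no half-pixel offset). Intensities are in
#' arbitrary units (typically integer digital numbers as read from an
#' 8/16-bit TIFF) and must be finite and non-negative.
#'
#' @slot channelName single character label, e.g. \code{"DAPI"},
#'   \code{"pimonidazole"}, \code{"DRAQ7"}, \code{"mAG"}, \code{"mKO2"},
#'   \code{"PBMC"}.
#' @slot pixels numeric matrix of intensities.
#' @slot pixelSizeUm physical edge length of one pixel in micrometres.
#'
#' @examples
#' ch <- ChannelImage("DAPI", matrix(0, 8, 8), pixelSizeUm = 2)
#' dim(pixels(ch))
#' @export
setClass("ChannelImage",
  representation(channelName = "character",
                 pixels = "matrix",
                 pixelSizeUm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@channelName) != 1L || is.na(object@channelName))
      msg <- c(msg, "channelName must be a single non-NA string")
    p <- object@pixels
    if (!is.numeric(p) || length(p) == 0L)
      msg <- c(msg, "pixels must be a non-empty numeric matrix")
    else if (anyNA(p) || any(!is.finite(p)) || any(p < 0))
      msg <- c(msg, "all intensities must be finite and >= 0")
    if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
        object@pixelSizeUm <= 0)
      msg <- c(msg, "pixelSizeUm must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' @rdname ChannelImage-class
#' @param channelName channel label.
#' @param pixels numeric matrix of intensities.
#' @param pixelSizeUm pixel edge length in micrometres.
#' @export
ChannelImage <- function(channelName, pixels, pixelSizeUm) {
  storage.mode(pixels) <- "double"
  new("ChannelImage", channelName = as.character(channelName),
      pixels = pixels, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' MultiChannelImage: an ordered set of co-registered channels
#'
#' All channels must share the same grid dimensions and pixel size and
#' carry unique names.
#'
#' @slot channels list of \linkS4class{ChannelImage}.
#' @export
setClass("MultiChannelImage",
  representation(channels = "list"),
  validity = function(object) {
    ch <- object@channels
    if (length(ch) < 1L)
      return("at least one channel is required")
    if (!all(vapply(ch, is, logical(1), "ChannelImage")))
      return("channels must all be ChannelImage objects")
    dims <- vapply(ch, function(x) dim(x@pixels), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      return("all channels must share identical dimensions")
    ps <- vapply(ch, function(x) x@pixelSizeUm, numeric(1))
    if (any(ps != ps[1]))
      return("all channels must share the same pixelSizeUm")
    nm <- vapply(ch, function(x) x@channelName, character(1))
    if (anyDuplicated(nm))
      return("channel names must be unique")
    TRUE
  })

#' @rdname MultiChannelImage-class
#' @param channels list of \linkS4class{ChannelImage}.
#' @export
MultiChannelImage <- function(channels) {
  new("MultiChannelImage", channels = channels)
}

#' LabelMap: integer-labelled segmentation with accept/discard classes
#'
#' Non-zero pixels belong to objects labelled with consecutive positive
#' integers; label 0 is background. Each label carries a category:
#' \code{accepted}, \code{discarded_size} (equivalent diameter outside
#' the configured range) or \code{discarded_border} (touching the image
#' border, which overrides the size class). Object pixel sets are
#' 8-connected.
#'
#' @slot labels integer matrix (0 = background).
#' @slot categories character vector, one entry per label.
#' @slot pixelSizeUm pixel edge length in micrometres.
#' @export
setClass("LabelMap",
  representation(labels = "matrix",
                 categories = "character",
                 pixelSizeUm = "numeric"),
  validity = function(object) {
    msg <- character()
    lb <- object@labels
    if (!is.numeric(lb)) msg <- c(msg, "labels must be an integer matrix")
    mx <- if (length(lb)) max(lb) else 0
    if (any(lb < 0)) msg <- c(msg, "labels must be non-negative")
    present <- sort(unique(lb[lb > 0]))
    if (length(present) && !identical(as.integer(present),
                                      seq_len(as.integer(mx))))
      msg <- c(msg, "positive labels must be consecutive from 1")
    if (length(object@categories) != mx)
      msg <- c(msg, "categories must have one entry per label")
    bad <- setdiff(object@categories,
                   c("accepted", "discarded_size", "discarded_border"))
    if (length(bad))
      msg <- c(msg, paste("unknown category:", paste(bad, collapse = ", ")))
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
      msg <- c(msg, "pixelSizeUm must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' @rdname LabelMap-class
#' @param labels integer matrix of object labels.
#' @param categories per-label category tags.
#' @param pixelSizeUm pixel edge length in micrometres.
#' @export
LabelMap <- function(labels, categories = rep("accepted", max(labels, 0)),
                     pixelSizeUm = 1) {
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels, categories = categories,
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' SpheroidMask: the parent-object footprint defining depth zero
#'
#' One 8-connected binary component whose perimeter (mask pixels with at
#' least one background 4-neighbour, counting out-of-image as background)
#' is the zero-depth surface for all distance measurements.
#'
#' @slot mask logical matrix.
#' @slot perimeter two-column matrix of 0-based (row, col) perimeter
#'   pixel indices.
#' @slot centroid 0-based (row, col) centroid of the mask pixel set.
#' @slot equivalentDiameterPx diameter of the circle with the mask's area.
#' @slot pixelSizeUm pixel edge length in micrometres.
#' @export
setClass("SpheroidMask",
  representation(mask = "matrix",
                 perimeter = "matrix",
                 centroid = "numeric",
                 equivalentDiameterPx = "numeric",
                 pixelSizeUm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
    if (!any(object@mask)) msg <- c(msg, "mask must be non-empty")
    if (ncol(object@perimeter) != 2L)
      msg <- c(msg, "perimeter must have two columns")
    if (length(object@centroid) != 2L)
      msg <- c(msg, "centroid must be (row, col)")
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
      msg <- c(msg, "pixelSizeUm must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Construct a SpheroidMask from a binary matrix
#'
#' The perimeter, centroid and equivalent diameter are derived from the
#' mask. The mask must consist of a single 8-connected component.
#'
#' @param mask logical matrix (TRUE = spheroid).
#' @param pixelSizeUm pixel edge length in micrometres.
#' @return a \linkS4class{SpheroidMask}.
#' @export
SpheroidMask <- function(mask, pixelSizeUm = 1) {
  mask <- mask != 0
  if (!any(mask)) stopCondition("invalid_mask_error", "empty spheroid mask")
  lab <- cpp_label8(mask)
  if (max(lab) != 1L)
    stopCondition("invalid_mask_error",
                  "mask must be a single 8-connected component")
  per <- perimeterPixels(mask)
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
  eqd <- 2 * sqrt(sum(mask) / pi)
  new("SpheroidMask", mask = mask, perimeter = per, centroid = centroid,
      equivalentDiameterPx = eqd, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' DepthProfile: a per-depth-bin statistic
#'
#' Bins are half-open intervals \code{[edge_k, edge_{k+1})} of distance
#' from the spheroid surface in micrometres, the first edge at 0. The
#' statistic may be a mean intensity, a positive fraction, a raw or
#' area-normalised count, or a two-class ratio; bins where it is
#' undefined (no objects, or zero denominator) carry \code{NA} and
#' \code{defined = FALSE} rather than a fabricated zero.
#'
#' @slot binEdgesUm strictly ascending bin edges, first edge 0.
#' @slot value per-bin statistic (NA where undefined).
#' @slot nObjects per-bin number of inside-spheroid objects.
#' @slot valueKind one of \code{"mean_intensity"},
#'   \code{"positive_fraction"}, \code{"count"}, \code{"count_density"},
#'   \code{"ratio"}.
#' @slot defined logical, per-bin.
#' @slot extra list of auxiliary per-bin vectors (e.g. positive counts,
#'   numerator/denominator counts, outside-spheroid count).
#' @export
setClass("DepthProfile",
  representation(binEdgesUm = "numeric",
                 value = "numeric",
                 nObjects = "integer",
                 valueKind = "character",
                 defined = "logical",
                 extra = "list"),
  validity = function(object) {
    msg <- character()
    e <- object@binEdgesUm
    nb <- length(e) - 1L
    if (length(e) < 2L || e[1] != 0 || any(diff(e) <= 0))
      msg <- c(msg, "binEdgesUm must be strictly ascending from 0")
    if (length(object@value) != nb || length(object@nObjects) != nb ||
        length(object@defined) != nb)
      msg <- c(msg, "value, nObjects and defined must have one entry per bin")
    if (any(object@nObjects < 0)) msg <- c(msg, "nObjects must be >= 0")
    if (object@valueKind %in% c("positive_fraction")) {
      v <- object@value[object@defined]
      if (length(v) && (any(v < 0) || any(v > 1)))
        msg <- c(msg, "fractions must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })
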