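#' @rdname ChannelImage-class
#' @param object,x a SpheroidProfiler object.
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))
#' @rdname ChannelImage-class
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname ChannelImage-class
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))
#' @rdname MultiChannelImage-class
#' @param x a \linkS4class{MultiChannelImage}.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname MultiChannelImage-class
#' @param name channel to extract.
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))
#' @rdname LabelMap-class
#' @param x a \linkS4class{LabelMap}.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname LabelMap-class
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))
#' @rdname LabelMap-class
#' @export
setGeneric("acceptedLabels", function(x) standardGeneric("acceptedLabels"))
#' @rdname SpheroidMask-class
#' @param x a \linkS4class{SpheroidMask}.
#' @export
setGeneric("perimeter", function(x) standardGeneric("perimeter"))
#' @rdname SpheroidMask-class
#' @export
setGeneric("equivalentDiameterPx",
           function(x) standardGeneric("equivalentDiameterPx"))
#' @rdname DepthProfile-class
#' @param x a \linkS4class{DepthProfile}.
#' @export
setGeneric("binEdgesUm", function(x) standardGeneric("binEdgesUm"))
#' @rdname DepthProfile-class
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

setMethod("channelName", "ChannelImage", function(x) x@channelName)
setMethod("pixels", "ChannelImage", function(x) x@pixels)
setMethod("pixelSizeUm", "ChannelImage", function(x) x@pixelSizeUm)
setMethod("pixelSizeUm", "MultiChannelImage",
          function(x) x@channels[[1]]@pixelSizeUm)
setMethod("pixelSizeUm", "LabelMap", function(x) x@pixelSizeUm)
setMethod("pixelSizeUm", "SpheroidMask", function(x) x@pixelSizeUm)

setMethod("channelNames", "MultiChannelImage",
          function(x) vapply(x@channels, channelName, character(1)))
setMethod("getChannel", "MultiChannelImage", function(x, name) {
  i <- if (is.numeric(name)) as.integer(name)
       else match(name, channelNames(x))
  if (is.na(i) || i < 1L || i > length(x@channels))
    stopCondition("parameter_error", sprintf("no such channel: %s", name))
  x@channels[[i]]
})
setMethod("length", "MultiChannelImage", function(x) length(x@channels))

setMethod("labelMatrix", "LabelMap", function(x) x@labels)
setMethod("categories", "LabelMap", function(x) x@categories)
setMethod("acceptedLabels", "LabelMap",
          function(x) which(x@categories == "accepted"))
setMethod("perimeter", "SpheroidMask", function(x) x@perimeter)
setMethod("equivalentDiameterPx", "SpheroidMask",
          function(x) x@equivalentDiameterPx)
setMethod("binEdgesUm", "DepthProfile", function(x) x@binEdgesUm)
setMethod("profileValues", "DepthProfile", function(x) x@value)

setMethod("show", "ChannelImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ChannelImage '%s': %d x %d px, %.3g um/px, range [%.4g, %.4g]\n",
              object@channelName, d[1], d[2], object@pixelSizeUm,
              min(object@pixels), max(object@pixels)))
})
setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object@channels[[1]]@pixels)
  cat(sprintf("MultiChannelImage: %d channel(s) [%s], %d x %d px, %.3g um/px\n",
              length(object@channels),
              paste(channelNames(object), collapse = ", "),
              d[1], d[2], pixelSizeUm(object)))
})
setMethod("show", "LabelMap", function(object) {
  tab <- table(factor(object@categories,
                      c("accepted", "discarded_size", "discarded_border")))
  cat(sprintf(
    "LabelMap: %d object(s) (%d accepted, %d size-discarded, %d border-discarded), %d x %d px\n",
    length(object@categories), tab[1], tab[2], tab[3],
    nrow(object@labels), ncol(object@labels)))
})
setMethod("show", "SpheroidMask", function(object) {
  cat(sprintf(
    "SpheroidMask: area %d px, equivalent diameter %.1f px (%.1f um), %d perimeter px\n",
    sum(object@mask), object@equivalentDiameterPx,
    object@equivalentDiameterPx * object@pixelSizeUm,
    nrow(object@perimeter)))
})
setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("DepthProfile (%s): %d bin(s), %d object(s), %d undefined bin(s)\n",
              object@valueKind, length(object@value), sum(object@nObjects),
              sum(!object@defined)))
})

#' Convert a DepthProfile to a data.frame
#'
#' @param x a \linkS4class{DepthProfile}.
#' @param row.names,optional,... ignored, present for generic consistency.
#' @return data.frame with columns \code{bin_start_um}, \code{bin_end_um},
#'   \code{n_objects}, \code{value}, \code{value_kind}, \code{defined},
#'   plus any auxiliary per-bin vectors.
#' @method as.data.frame DepthProfile
#' @export
as.data.frame.DepthProfile <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  e <- x@binEdgesUm
  df <- data.frame(bin_start_um = e[-length(e)], bin_end_um = e[-1],
                   n_objects = x@nObjects, value = x@value,
                   value_kind = x@valueKind, defined = x@defined,
                   stringsAsFactors = FALSE)
  for (nm in names(x@extra))
    if (length(x@extra[[nm]]) == nrow(df)) df[[nm]] <- x@extra[[nm]]
  df
}
setMethod("as.data.frame", "DepthProfile", as.data.frame.DepthProfile)
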