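# Quantification: per-object intensity features, positivity calls, and
# the four depth-profile analytics (mean intensity, positive fraction,
# infiltration count, two-channel ratio).

#' Per-object intensity features
#'
#' Mean, median and integrated (summed) intensity over each accepted
#' object's member pixels in one channel. Integrated equals mean times
#' area up to rounding.
#'
#' @param objects a \linkS4class{LabelMap}.
#' @param channel a \linkS4class{ChannelImage} of the same dimensions.
#' @return data.frame with \code{object_id}, \code{mean}, \code{median},
#'   \code{integrated}.
#' @export
measureObjectIntensity <- function(objects, channel) {
  lb <- objects@labels
  px <- channel@pixels
  if (!identical(dim(lb), dim(px)))
    stopCondition("shape_error", "objects and channel dimensions differ")
  acc <- acceptedLabels(objects)
  if (length(acc) == 0L)
    return(data.frame(object_id = integer(0), mean = numeric(0),
                      median = numeric(0), integrated = numeric(0)))
  sel <- lb %in% acc
  f <- factor(lb[sel], levels = sort(acc))
  v <- px[sel]
  data.frame(object_id = sort(acc),
             mean = as.numeric(tapply(v, f, mean)),
             median = as.numeric(tapply(v, f, stats::median)),
             integrated = as.numeric(tapply(v, f, sum)),
             row.names = NULL)
}

#' Classify objects as positive for a stain
#'
#' Manual: positive iff the per-object mean exceeds the threshold.
#' Automatic: Otsu on the distribution of per-object means. The applied
#' threshold is attached as attribute \code{threshold}.
#'
#' @param means numeric vector of per-object mean intensities.
#' @param strategy \code{"automatic"} or \code{"manual"}.
#' @param manualThreshold intensity, required iff manual.
#' @return logical vector of positivity flags with attribute
#'   \code{threshold}.
#' @export
classifyPositive <- function(means, strategy = c("automatic", "manual"),
                             manualThreshold = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "manual") {
    if (is.null(manualThreshold))
      stopCondition("parameter_error",
                    "manual strategy requires manualThreshold")
    thr <- manualThreshold
  } else {
    if (length(means) < 1L)
      stopCondition("parameter_error",
                    "automatic strategy needs at least one object")
    if (length(unique(means)) < 2L)
      stopCondition("degenerate_distribution_error",
                    "automatic thresholding needs >= 2 distinct mean values")
    thr <- otsuThreshold(means)
  }
  structure(means > thr, threshold = thr)
}

# Shared binning: half-open bins [k*w, (k+1)*w) over inside-spheroid
# records. maxDepthUm fixes the last edge (e.g. the spheroid radius);
# by default bins extend to cover the deepest inside object.
depthBins <- function(records, binWidthUm, maxDepthUm = NULL) {
  if (binWidthUm <= 0)
    stopCondition("parameter_error", "binWidthUm must be positive")
  inside <- records[records$inside_spheroid, , drop = FALSE]
  top <- if (!is.null(maxDepthUm)) maxDepthUm
         else if (nrow(inside)) max(inside$distance_to_surface_um) else 0
  nb <- max(1L, as.integer(ceiling(top / binWidthUm)))
  # a record exactly at the last edge falls in the final half-open bin
  if (nrow(inside) && nb * binWidthUm <= max(inside$distance_to_surface_um))
    nb <- nb + 1L
  edges <- seq(0, by = binWidthUm, length.out = nb + 1L)
  bin <- findInterval(inside$distance_to_surface_um, edges,
                      rightmost.closed = FALSE)
  list(inside = inside, edges = edges, bin = bin, nBins = nb)
}

newDepthProfile <- function(edges, value, n, kind, extra = list()) {
  new("DepthProfile", binEdgesUm = edges, value = value,
      nObjects = as.integer(n), valueKind = kind,
      defined = !is.na(value), extra = extra)
}

#' Mean-intensity depth profile
#'
#' Per-bin unweighted mean of the per-object mean intensities of the
#' named channel (the unit of analysis is the cell, not the pixel),
#' over inside-spheroid objects. Empty bins are undefined.
#'
#' @param records object records carrying
#'   \code{distance_to_surface_um}, \code{inside_spheroid} and a
#'   \code{<channel>_mean} column.
#' @param channel channel name.
#' @param binWidthUm bin width in micrometres (default 25).
#' @param maxDepthUm optional fixed profile extent.
#' @return a \linkS4class{DepthProfile}.
#' @export
meanIntensityProfile <- function(records, channel, binWidthUm = 25,
                                 maxDepthUm = NULL) {
  colName <- paste0(channel, "_mean")
  if (!colName %in% names(records))
    stopCondition("parameter_error",
                  sprintf("records lack column '%s'", colName))
  b <- depthBins(records, binWidthUm, maxDepthUm)
  f <- factor(b$bin, levels = seq_len(b$nBins))
  n <- as.integer(table(f))
  value <- as.numeric(tapply(b$inside[[colName]], f, mean))
  newDepthProfile(b$edges, value, n, "mean_intensity")
}

#' Positive-fraction depth profile
#'
#' Per-bin fraction of objects flagged positive for the named channel
#' (stored as a fraction; rendered plots conventionally use percent).
#'
#' @param records object records carrying a \code{<flag>_positive}
#'   logical column.
#' @param flag channel name of the positivity flag.
#' @inheritParams meanIntensityProfile
#' @return a \linkS4class{DepthProfile} with per-bin positive counts in
#'   \code{extra$n_positive}.
#' @export
positiveFractionProfile <- function(records, flag, binWidthUm = 25,
                                    maxDepthUm = NULL) {
  colName <- paste0(flag, "_positive")
  if (!colName %in% names(records))
    stopCondition("parameter_error",
                  sprintf("records lack column '%s'", colName))
  b <- depthBins(records, binWidthUm, maxDepthUm)
  f <- factor(b$bin, levels = seq_len(b$nBins))
  n <- as.integer(table(f))
  pos <- as.integer(tapply(b$inside[[colName]], f, sum))
  pos[is.na(pos)] <- 0L
  value <- ifelse(n > 0, pos / n, NA_real_)
  newDepthProfile(b$edges, value, n, "positive_fraction",
                  extra = list(n_positive = pos))
}

#' PBMC infiltration-count depth profile
#'
#' Per-bin count of inside-spheroid objects; with
#' \code{normalize = "ring_area"} the count is divided by the annulus
#' area (in square micrometres) of an idealised circular spheroid of the
#' given radius, yielding a density. Surface-adherent objects (negative
#' distance) are reported separately in \code{extra$outside_count}.
#'
#' @param records PBMC object records related to the spheroid.
#' @param binWidthUm bin width in micrometres.
#' @param normalize \code{"none"} or \code{"ring_area"}.
#' @param spheroidRadiusUm equivalent spheroid radius, required for
#'   ring-area normalisation (and used as the profile extent).
#' @param maxDepthUm optional fixed profile extent.
#' @return a \linkS4class{DepthProfile}.
#' @export
infiltrationCountProfile <- function(records, binWidthUm = 25,
                                     normalize = c("none", "ring_area"),
                                     spheroidRadiusUm = NULL,
                                     maxDepthUm = NULL) {
  normalize <- match.arg(normalize)
  if (normalize == "ring_area" && is.null(spheroidRadiusUm))
    stopCondition("parameter_error",
                  "ring_area normalisation requires spheroidRadiusUm")
  if (is.null(maxDepthUm) && !is.null(spheroidRadiusUm))
    maxDepthUm <- spheroidRadiusUm
  b <- depthBins(records, binWidthUm, maxDepthUm)
  f <- factor(b$bin, levels = seq_len(b$nBins))
  n <- as.integer(table(f))
  value <- as.numeric(n)
  kind <- "count"
  if (normalize == "ring_area") {
    R <- spheroidRadiusUm
    a <- b$edges[-length(b$edges)]
    bb <- pmin(b$edges[-1], R)
    area <- pi * (pmax(R - a, 0)^2 - pmax(R - bb, 0)^2)
    value <- ifelse(area > 0, n / area, NA_real_)
    kind <- "count_density"
  }
  outside <- sum(!records$inside_spheroid)
  newDepthProfile(b$edges, value, n, kind,
                  extra = list(outside_count = outside))
}

#' Two-channel positive-count ratio depth profile
#'
#' Per-bin ratio of numerator-positive to denominator-positive object
#' counts, e.g. mKO2+/mAG+: low values indicate proliferation, a rise
#' with depth indicates G1 arrest, and the necrotic core typically loses
#' both signals. Bins with zero denominator are undefined (never
#' infinite); both class counts are retained per bin.
#'
#' @param records object records with both positivity flags.
#' @param numeratorFlag,denominatorFlag channel names (default
#'   mKO2 / mAG).
#' @inheritParams meanIntensityProfile
#' @return a \linkS4class{DepthProfile} with \code{extra$n_numerator}
#'   and \code{extra$n_denominator}.
#' @export
ratioProfile <- function(records, numeratorFlag = "mKO2",
                         denominatorFlag = "mAG", binWidthUm = 25,
                         maxDepthUm = NULL) {
  cNum <- paste0(numeratorFlag, "_positive")
  cDen <- paste0(denominatorFlag, "_positive")
  for (cn in c(cNum, cDen))
    if (!cn %in% names(records))
      stopCondition("parameter_error",
                    sprintf("records lack column '%s'", cn))
  b <- depthBins(records, binWidthUm, maxDepthUm)
  f <- factor(b$bin, levels = seq_len(b$nBins))
  n <- as.integer(table(f))
  num <- as.integer(tapply(b$inside[[cNum]], f, sum))
  den <- as.integer(tapply(b$inside[[cDen]], f, sum))
  num[is.na(num)] <- 0L; den[is.na(den)] <- 0L
  value <- ifelse(den > 0, num / den, NA_real_)
  newDepthProfile(b$edges, value, n, "ratio",
                  extra = list(n_numerator = num, n_denominator = den))
}

#' Write a DepthProfile as CSV
#'
#' @param profile a \linkS4class{DepthProfile}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProfileTable <- function(profile, path) {
  writeObjectTable(as.data.frame(profile), path)
}

#' Plot a DepthProfile
#'
#' Line-and-point rendering against bin midpoints; fractions are drawn
#' as percentages, matching the field's axis convention.
#'
#' @param profile a \linkS4class{DepthProfile}.
#' @param main plot title.
#' @param ... further arguments to \code{\link[graphics]{plot}}.
#' @export
plotProfile <- function(profile, main = profile@valueKind, ...) {
  e <- profile@binEdgesUm
  mid <- (e[-1] + e[-length(e)]) / 2
  v <- profile@value
  ylab <- profile@valueKind
  if (profile@valueKind == "positive_fraction") {
    v <- v * 100
    ylab <- "positive cells (%)"
  }
  graphics::plot(mid, v, type = "b", pch = 16,
                 xlab = "distance from spheroid surface (um)",
                 ylab = ylab, main = main, ...)
  invisible(NULL)
}
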