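# Spatial relations: distance of child objects to the spheroid surface,
# parent-child association, and pixel-set neighbour counting.

#' Signed distance from a point to the spheroid surface
#'
#' The exact minimum over all perimeter pixels of the Euclidean distance
#' from the (possibly fractional, 0-based) centroid, in micrometres.
#' The sign is positive if the centroid's containing pixel lies inside
#' the mask and negative otherwise, so surface-adherent but
#' non-infiltrated objects stay in the record set and remain
#' filterable. The result is 1-Lipschitz in the centroid.
#'
#' @param centroid numeric (row, col), 0-based pixel coordinates, or an
#'   n x 2 matrix of such points.
#' @param spheroid a \linkS4class{SpheroidMask}.
#' @return signed distance(s) in micrometres.
#' @export
distanceToSurface <- function(centroid, spheroid) {
  per <- spheroid@perimeter
  if (nrow(per) == 0L)
    stopCondition("invalid_mask_error", "spheroid mask has no perimeter")
  if (is.null(dim(centroid))) centroid <- matrix(centroid, ncol = 2)
  n <- nrow(centroid)
  out <- numeric(n)
  nr <- nrow(spheroid@mask); nc <- ncol(spheroid@mask)
  for (i in seq_len(n)) {
    d2 <- (per[, 1] - centroid[i, 1])^2 + (per[, 2] - centroid[i, 2])^2
    d <- sqrt(min(d2))
    # containing pixel: pixel j covers [j - 0.5, j + 0.5)
    pr <- floor(centroid[i, 1] + 0.5) + 1
    pc <- floor(centroid[i, 2] + 0.5) + 1
    inside <- pr >= 1 && pr <= nr && pc >= 1 && pc <= nc &&
      spheroid@mask[pr, pc]
    out[i] <- (if (inside) d else -d) * spheroid@pixelSizeUm
  }
  out
}

#' Relate child objects to the spheroid
#'
#' Emits one record per accepted child object, sorted by object id:
#' centroid (mean of member pixel indices, 0-based), pixel area, signed
#' distance to the spheroid surface and containment flag. Children
#' entirely outside the mask are retained with negative distance (e.g.
#' surface-adherent PBMCs); children straddling the boundary are decided
#' by their centroid's containing pixel.
#'
#' @param children a \linkS4class{LabelMap}.
#' @param spheroid a \linkS4class{SpheroidMask} with the same dimensions
#'   and pixel size.
#' @return data.frame with columns \code{object_id},
#'   \code{centroid_row}, \code{centroid_col}, \code{area_px},
#'   \code{distance_to_surface_um}, \code{inside_spheroid}.
#' @export
relateObjects <- function(children, spheroid) {
  lb <- children@labels
  if (!identical(dim(lb), dim(spheroid@mask)))
    stopCondition("shape_error", "children and spheroid dimensions differ")
  acc <- acceptedLabels(children)
  empty <- data.frame(object_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0),
                      distance_to_surface_um = numeric(0),
                      inside_spheroid = logical(0))
  if (length(acc) == 0L) return(empty)
  idx <- which(lb > 0L, arr.ind = TRUE)
  labs <- lb[lb > 0L]
  keep <- labs %in% acc
  idx <- idx[keep, , drop = FALSE]; labs <- labs[keep]
  if (length(labs) == 0L) return(empty)
  f <- factor(labs, levels = sort(acc))
  area <- as.integer(table(f))
  cr <- tapply(idx[, 1] - 1, f, mean)
  cc <- tapply(idx[, 2] - 1, f, mean)
  dist <- distanceToSurface(cbind(cr, cc), spheroid)
  data.frame(object_id = sort(acc), centroid_row = as.numeric(cr),
             centroid_col = as.numeric(cc), area_px = area,
             distance_to_surface_um = dist,
             inside_spheroid = dist >= 0, row.names = NULL)
}

#' Count object neighbours
#'
#' Two objects are neighbours iff the minimum Euclidean distance between
#' their pixel sets (boundary-to-boundary, not centroids) is at most
#' \code{neighborDistancePx}. The relation is symmetric and an object is
#' never its own neighbour. Intended for co-culture analyses (e.g. how
#' many fibroblasts surround each melanoma cell, or which cell types
#' infiltrating PBMCs settle next to).
#'
#' @param objects a \linkS4class{LabelMap}.
#' @param neighborDistancePx non-negative distance in pixels.
#' @return integer vector of neighbour counts, one per label.
#' @export
countNeighbors <- function(objects, neighborDistancePx) {
  if (neighborDistancePx < 0)
    stopCondition("parameter_error", "neighborDistancePx must be >= 0")
  nLab <- length(objects@categories)
  if (nLab == 0L) return(integer(0))
  adj <- cpp_neighbor_adjacency(objects@labels, neighborDistancePx, nLab)
  as.integer(rowSums(adj))
}
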