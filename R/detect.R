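#' Nucleus detection parameters
#'
#' Parameters of the automatic cell detection run on the nuclear channel.
#' Defaults mirror the documented defaults of widely used whole-slide cell
#' detectors: Gaussian smoothing of 1.5 um, automatic (triangle) intensity
#' threshold, nucleus area bounds of 10-400 um2, splitting of touching
#' nuclei on the distance transform, and a 5 um whole-cell expansion.
#'
#' @param smoothingSigmaUm Gaussian smoothing applied to the nuclear channel.
#' @param nucleusThreshold numeric intensity in [0,255], or \code{"auto"}
#'   for a triangle threshold on the smoothed channel.
#' @param minNucleusAreaUm2,maxNucleusAreaUm2 area bounds for accepted
#'   nuclei.
#' @param watershedSplit split touching nuclei at distance-transform maxima.
#' @param cellExpansionUm radial expansion of nuclei into cell outlines.
#' @return a list of class \code{DetectionParams}.
#' @export
detectionParams <- function(smoothingSigmaUm = 1.5, nucleusThreshold = "auto",
                            minNucleusAreaUm2 = 10, maxNucleusAreaUm2 = 400,
                            watershedSplit = TRUE, cellExpansionUm = 5) {
  stopifnot(smoothingSigmaUm >= 0, minNucleusAreaUm2 > 0,
            minNucleusAreaUm2 < maxNucleusAreaUm2, cellExpansionUm >= 0)
  if (!identical(nucleusThreshold, "auto"))
    stopifnot(is.numeric(nucleusThreshold), nucleusThreshold >= 0,
              nucleusThreshold <= 255)
  structure(list(smoothingSigmaUm = smoothingSigmaUm,
                 nucleusThreshold = nucleusThreshold,
                 minNucleusAreaUm2 = minNucleusAreaUm2,
                 maxNucleusAreaUm2 = maxNucleusAreaUm2,
                 watershedSplit = watershedSplit,
                 cellExpansionUm = cellExpansionUm),
            class = "DetectionParams")
}

#' Detect nuclei on the nuclear channel
#'
#' Smooths the nuclear (Hoechst/DAPI) channel, thresholds it (triangle
#' method by default), labels connected components and - when
#' \code{watershedSplit} is on - splits touching nuclei by propagating
#' distance-transform maxima. Detections outside the area bounds are
#' discarded and the survivors are renumbered in raster order of their
#' centroids, so the output ordering is deterministic.
#'
#' @param stack a \linkS4class{ChannelStack} containing a \code{DAPI}
#'   channel.
#' @param params a \code{\link{detectionParams}} list.
#' @return a \linkS4class{CellSet} with nucleus labels and a per-cell table
#'   (centroids in um, nucleus areas); cell compartments not yet expanded.
#' @export
detectNuclei <- function(stack, params = detectionParams()) {
  if (!"DAPI" %in% names(stack@channels))
    stop("configuration error: no 'DAPI' (nuclear) channel in the stack")
  px <- stack@pixelSizeUm
  ch <- getChannel(stack, "DAPI")
  sm <- if (params$smoothingSigmaUm > 0)
    gaussBlur(ch, params$smoothingSigmaUm / px) else ch + 0
  thr <- if (identical(params$nucleusThreshold, "auto"))
    triangleThreshold(sm) else params$nucleusThreshold
  mask <- sm > thr
  if (!any(mask)) return(emptyCellSet(dim(ch), px))

  comp <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
  if (params$watershedSplit) {
    lab <- splitTouchingNuclei(mask, comp, sm, px)
  } else lab <- comp
  rm(comp)

  # area filter + raster-order renumbering
  nlab <- max(lab)
  counts <- .c_label_counts(lab, nlab)
  areas <- counts * px^2
  ok <- which(areas >= params$minNucleusAreaUm2 & areas <= params$maxNucleusAreaUm2)
  if (!length(ok)) return(emptyCellSet(dim(ch), px))
  cen <- .c_label_centroids(lab, nlab)
  cxp <- cen$sj[ok] / counts[ok]; cyp <- cen$si[ok] / counts[ok]
  ord <- order(round(cyp), cxp)  # raster order of centroids
  remap <- integer(nlab)
  remap[ok[ord]] <- seq_along(ok)
  lab2 <- lab
  pos <- lab2 > 0L
  lab2[pos] <- remap[lab2[pos]]
  tab <- data.frame(cell_id = seq_along(ok),
                    x_um = idxToUm(cxp[ord], px), y_um = idxToUm(cyp[ord], px),
                    nucleus_area_um2 = areas[ok][ord])
  new("CellSet", table = tab, nucleusLabels = lab2,
      cellLabels = matrix(0L, 0, 0), pixelSizeUm = px)
}

emptyCellSet <- function(d, px)
  new("CellSet",
      table = data.frame(cell_id = integer(0), x_um = numeric(0),
                         y_um = numeric(0), nucleus_area_um2 = numeric(0)),
      nucleusLabels = matrix(0L, d[1], d[2]),
      cellLabels = matrix(0L, 0, 0), pixelSizeUm = px)

# split touching nuclei: local maxima of the smoothed nuclear intensity
# become seeds (one per nucleus even when thresholded blobs merge), then
# each foreground pixel joins its nearest seed
splitTouchingNuclei <- function(mask, comp, sm, px) {
  r <- max(1L, as.integer(round(2.5 / px / 2)))
  mx <- .c_max_filter(sm, r)
  peaks <- mask & (sm >= mx - 1e-9)
  seeds <- matrix(as.integer(EBImage::bwlabel(peaks)), nrow(mask), ncol(mask))
  if (max(seeds) == 0) return(comp)
  lab <- nearestSeedLabel(seeds, maxDistPx = 12 / px)
  lab[!mask] <- 0L
  lab
}

#' Expand nuclei into whole-cell compartments
#'
#' Each nucleus is dilated by \code{expansionUm}; where expansions of
#' neighbouring nuclei meet, territory is clipped along the frontier
#' equidistant from the two nucleus boundaries, so cell interiors are
#' mutually disjoint. Expansion is clipped to the image bounds.
#'
#' @param cells a \linkS4class{CellSet} from \code{\link{detectNuclei}}.
#' @param expansionUm non-negative radial expansion in um.
#' @return the \linkS4class{CellSet} with \code{cellLabels} and
#'   \code{cell_area_um2} filled in.
#' @export
expandCells <- function(cells, expansionUm = 5) {
  if (expansionUm < 0) stop("parameter error: expansion must be non-negative")
  px <- cells@pixelSizeUm
  nuc <- cells@nucleusLabels
  if (nrow(cells@table) == 0 || expansionUm == 0) {
    cells@cellLabels <- nuc
    cells@table$cell_area_um2 <- cells@table$nucleus_area_um2 %||% numeric(0)
    return(cells)
  }
  # the distance cap doubles as the dilation cutoff
  lab <- nearestSeedLabel(nuc, maxDistPx = expansionUm / px + .edgeOffsetPx)
  cells@cellLabels <- lab
  counts <- .c_label_counts(lab, nrow(cells@table))
  cells@table$cell_area_um2 <- counts * px^2
  cells
}

#' Measure per-compartment intensity features
#'
#' Mean pixel intensity of every channel over each cell's nucleus, whole
#' cell, and cytoplasm (cell minus nucleus) compartments, added to the cell
#' table as \code{<channel>_<compartment>_mean} columns on the 0-255 scale.
#' A cell whose cytoplasm rasterizes to zero pixels gets \code{NA} there.
#'
#' @param cells an expanded \linkS4class{CellSet}.
#' @param stack the \linkS4class{ChannelStack} the cells were detected on.
#' @return the \linkS4class{CellSet} with feature columns filled.
#' @export
measureFeatures <- function(cells, stack) {
  if (!length(cells@cellLabels)) stop("expand cells before measuring features")
  n <- nrow(cells@table)
  for (nm in names(stack@channels)) {
    ch <- stack@channels[[nm]]
    sn <- .c_label_stats(cells@nucleusLabels, ch, n)
    sc <- .c_label_stats(cells@cellLabels, ch, n)
    cyN <- sc$n - sn$n
    cells@table[[paste0(nm, "_nucleus_mean")]] <- sn$sum / sn$n
    cells@table[[paste0(nm, "_cell_mean")]] <- sc$sum / sc$n
    cells@table[[paste0(nm, "_cytoplasm_mean")]] <-
      ifelse(cyN > 0, (sc$sum - sn$sum) / cyN, NA_real_)
  }
  cells
}

#' Detect, expand and measure in one call
#'
#' @param stack a \linkS4class{ChannelStack}.
#' @param params a \code{\link{detectionParams}} list.
#' @return a fully measured \linkS4class{CellSet}.
#' @export
detectCells <- function(stack, params = detectionParams()) {
  cells <- detectNuclei(stack, params)
  cells <- expandCells(cells, params$cellExpansionUm)
  measureFeatures(cells, stack)
}
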