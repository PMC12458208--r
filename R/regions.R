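#' Ring specification
#'
#' Geometry of the proximity analysis around each islet: a narrow peri-islet
#' collar plus a set of wider concentric rings. Defaults are the published
#' design: a 10 um peri-islet region and eight 25 um rings reaching 200 um
#' from the islet boundary.
#'
#' @param periWidthUm width of the peri-islet collar.
#' @param nRings number of concentric rings.
#' @param ringWidthUm width of each ring.
#' @return a list of class \code{RingSpec}.
#' @export
ringSpec <- function(periWidthUm = 10, nRings = 8, ringWidthUm = 25) {
  stopifnot(periWidthUm > 0, nRings >= 1, ringWidthUm > 0)
  structure(list(periWidthUm = periWidthUm, nRings = as.integer(nRings),
                 ringWidthUm = ringWidthUm), class = "RingSpec")
}

#' Segment insulin-containing islets from the insulin channel
#'
#' Smooths the insulin channel (sigma 2 um), thresholds it with the
#' triangle method, applies a morphological closing (radius 5 um), fills
#' holes, and discards components below the minimum islet area. The result
#' is a label mask of candidate insulin-containing islet (ICI) regions.
#'
#' @param stack a \linkS4class{ChannelStack} with an \code{INS} channel, or
#'   an integer matrix of insulin intensities (then supply
#'   \code{pixelSizeUm}).
#' @param minIsletAreaUm2 components smaller than this are dropped.
#' @param smoothingSigmaUm,closingRadiusUm pre-processing scales.
#' @param pixelSizeUm required when \code{stack} is a bare matrix.
#' @return list: \code{labels} (integer matrix, islet ids),
#'   \code{table} (islet_id, area_um2).
#' @export
segmentIslets <- function(stack, minIsletAreaUm2 = 1000,
                          smoothingSigmaUm = 2, closingRadiusUm = 5,
                          pixelSizeUm = NULL) {
  if (is(stack, "ChannelStack")) {
    ch <- getChannel(stack, "INS"); px <- stack@pixelSizeUm
  } else { ch <- stack; px <- pixelSizeUm }
  stopifnot(!is.null(px))
  sm <- gaussBlur(ch, smoothingSigmaUm / px)
  # the triangle threshold finds the background elbow, which dilates the
  # mask by the smoothing skirt; a refinement pass re-cuts halfway between
  # the background level and the diffuse islet-fill level (lower quartile
  # of the pre-mask, robust to the bright per-cell insulin blobs), placing
  # the boundary at the half-height of the smoothed islet edge
  thr <- triangleThreshold(sm)
  pre <- sm > thr
  empty <- list(labels = matrix(0L, nrow(ch), ncol(ch)),
                table = data.frame(islet_id = integer(0), area_um2 = numeric(0)))
  if (any(pre) && !all(pre)) {
    bgLevel <- stats::median(sm[!pre])
    fillLevel <- stats::quantile(sm[pre], 0.25, names = FALSE)
    # a pixel-classifier needs real contrast: without a fill level clearly
    # above background the channel carries no islets, only noise
    if (fillLevel - bgLevel < 8) return(empty)
    thr <- max(thr, (bgLevel + fillLevel) / 2)
  } else return(empty)
  mask <- sm > thr
  rm(pre)
  if (!any(mask))
    return(list(labels = matrix(0L, nrow(ch), ncol(ch)),
                table = data.frame(islet_id = integer(0), area_um2 = numeric(0))))
  rm(sm)
  # closing by closingRadiusUm via two distance thresholds
  r <- closingRadiusUm / px
  dil <- nearestSeedLabel(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                          maxDistPx = r + 0.5) > 0L
  closed <- nearestSeedLabel(matrix(as.integer(!dil), nrow(mask), ncol(mask)),
                             maxDistPx = r + 0.5) == 0L
  rm(dil)
  closed <- matrix(as.integer(EBImage::fillHull(EBImage::Image(closed))),
                   nrow(mask), ncol(mask)) > 0
  lab <- matrix(as.integer(EBImage::bwlabel(closed)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab == 0)
    return(list(labels = lab, table = data.frame(islet_id = integer(0),
                                                 area_um2 = numeric(0))))
  areas <- .c_label_counts(lab, nlab) * px^2
  keep <- which(areas >= minIsletAreaUm2)
  remap <- integer(nlab); remap[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  list(labels = lab,
       table = data.frame(islet_id = seq_along(keep), area_um2 = areas[keep]))
}

#' Load insulin-deficient islet annotations from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection and returns the polygons whose
#' \code{classification} property is \code{"Islet-IDI"}, with coordinates
#' interpreted in micrometres.
#'
#' @param path GeoJSON file path.
#' @return list of polygon matrices (columns x, y in um).
#' @export
loadIdiRegions <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("malformed GeoJSON: expected a FeatureCollection")
  out <- list()
  for (f in gj$features) {
    cls <- f$properties$classification %||% ""
    if (!identical(cls, "Islet-IDI")) next
    if (is.null(f$geometry) || f$geometry$type != "Polygon")
      stop("malformed GeoJSON: IDI features must be Polygons")
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("x", "y")
    # drop the closing vertex GeoJSON requires
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    out[[length(out) + 1]] <- m
  }
  out
}

#' Combine segmented ICIs with annotated IDIs into one islet mask
#'
#' Rasterizes the IDI polygons onto the ICI label mask. An IDI overlapping
#' an existing islet is an error (an islet cannot be both
#' insulin-containing and insulin-deficient).
#'
#' @param seg result of \code{\link{segmentIslets}}.
#' @param idiPolys list of polygon matrices in um (possibly empty).
#' @param pixelSizeUm micrometres per pixel.
#' @return list: \code{labels} (integer mask), \code{classes} (character
#'   vector \code{"islet_ICI"}/\code{"islet_IDI"} per islet id).
#' @export
combineIslets <- function(seg, idiPolys = list(), pixelSizeUm) {
  lab <- seg$labels
  nIci <- nrow(seg$table)
  classes <- rep("islet_ICI", nIci)
  px <- pixelSizeUm
  for (q in seq_along(idiPolys)) {
    poly <- idiPolys[[q]]
    id <- nIci + q
    j0 <- max(1L, umToIdx(min(poly[, 1]) - 1, px))
    j1 <- min(ncol(lab), umToIdx(max(poly[, 1]) + 1, px))
    i0 <- max(1L, umToIdx(min(poly[, 2]) - 1, px))
    i1 <- min(nrow(lab), umToIdx(max(poly[, 2]) + 1, px))
    grid <- expand.grid(x = idxToUm(j0:j1, px), y = idxToUm(i0:i1, px))
    inside <- matrix(pointsInPolygon(grid, poly), nrow = j1 - j0 + 1)  # x fastest
    inside <- t(inside)
    sub <- lab[i0:i1, j0:j1]
    clash <- unique(sub[inside & sub > 0])
    if (length(clash))
      stop(sprintf("IDI region %d overlaps islet region(s) %s", id,
                   paste(clash, collapse = ", ")))
    sub[inside] <- as.integer(id)
    lab[i0:i1, j0:j1] <- sub
    classes <- c(classes, "islet_IDI")
  }
  list(labels = lab, classes = classes)
}

#' Build the region geometry around a set of islets
#'
#' Computes the nearest-islet distance field once and derives every region
#' family from it. Returns a \linkS4class{RegionSet} containing the islet
#' regions; add collars and rings with \code{\link{makePeriIslet}} and
#' \code{\link{makeRingSet}}, and exocrine squares with
#' \code{\link{sampleExocrine}}.
#'
#' @param isletLabels integer matrix of islet ids (0 outside).
#' @param classes character vector of islet classes per id
#'   (\code{"islet_ICI"} or \code{"islet_IDI"}).
#' @param tissueRect numeric(4) xmin, xmax, ymin, ymax in um.
#' @param pixelSizeUm micrometres per pixel.
#' @param spec a \code{\link{ringSpec}}.
#' @return a \linkS4class{RegionSet}.
#' @export
buildRegionSet <- function(isletLabels, classes, tissueRect, pixelSizeUm,
                           spec = ringSpec()) {
  px <- pixelSizeUm
  storage.mode(isletLabels) <- "integer"
  nIsl <- length(classes)
  if (nIsl > 0) {
    vdt <- nearestSeed(isletLabels)
    dist <- (vdt$dist - .edgeOffsetPx) * px
    dist[dist < 0] <- 0
    dist[isletLabels > 0L] <- 0
    owner <- vdt$label
    rm(vdt)
  } else {
    dist <- matrix(Inf, nrow(isletLabels), ncol(isletLabels))
    owner <- matrix(0L, nrow(isletLabels), ncol(isletLabels))
  }
  cr <- rectIdx(tissueRect, dim(isletLabels), px)
  tab <- data.frame(region_id = integer(0), region_class = character(0),
                    parent_islet_id = integer(0), k = integer(0),
                    area_um2 = numeric(0))
  if (nIsl > 0) {
    sub <- isletLabels[cr$i, cr$j]
    areas <- .c_label_counts(sub, nIsl) * px^2
    tab <- data.frame(region_id = seq_len(nIsl), region_class = classes,
                      parent_islet_id = NA_integer_, k = NA_integer_,
                      area_um2 = areas)
  }
  new("RegionSet", table = tab, isletLabels = isletLabels, dist = dist,
      owner = owner, ringSpec = unclass(spec),
      exocrine = data.frame(region_id = integer(0), x0_um = numeric(0),
                            y0_um = numeric(0), side_um = numeric(0)),
      tissueRect = as.numeric(tissueRect), pixelSizeUm = px)
}

# 1-based index ranges of pixel centres inside a um rectangle
rectIdx <- function(rect, d, px) {
  j0 <- max(1L, as.integer(ceiling(rect[1] / px + 1 - 1e-9)))
  j1 <- min(d[2], as.integer(floor(rect[2] / px + 1 + 1e-9)))
  i0 <- max(1L, as.integer(ceiling(rect[3] / px + 1 - 1e-9)))
  i1 <- min(d[1], as.integer(floor(rect[4] / px + 1 + 1e-9)))
  list(i = i0:i1, j = j0:j1)
}

# per-islet pixel counts of the distance bands with upper edges `uppers`
# ((0,u1], (u1,u2], ...), clipped to tissue and excluding islet interiors;
# returns an nIslets x nBands matrix from a single pass over the crop
collarBandCounts <- function(rs, uppers) {
  cr <- rectIdx(rs@tissueRect, dim(rs@isletLabels), rs@pixelSizeUm)
  d <- rs@dist[cr$i, cr$j]
  o <- rs@owner[cr$i, cr$j]
  l <- rs@isletLabels[cr$i, cr$j]
  band <- findInterval(d, c(0, uppers), left.open = TRUE)
  band[band > length(uppers)] <- 0L
  band[l > 0L] <- 0L
  dim(band) <- dim(d)
  storage.mode(band) <- "integer"
  nIsl <- sum(rs@table$region_class %in% c("islet_ICI", "islet_IDI"))
  .c_label_band_counts(o, band, nIsl, length(uppers))
}

#' Add peri-islet collar regions
#'
#' For every islet, the peri-islet region is the set of tissue pixels
#' outside all islets within \code{periWidthUm} of an islet boundary,
#' assigned to the islet whose boundary is nearest - so collars of
#' neighbouring islets share a frontier on the equidistant line and never
#' overlap.
#'
#' @param rs a \linkS4class{RegionSet} from \code{\link{buildRegionSet}}.
#' @param widthUm collar width (defaults to the ring spec's).
#' @return the \linkS4class{RegionSet} with \code{peri_islet} rows added.
#' @export
makePeriIslet <- function(rs, widthUm = NULL) {
  widthUm <- widthUm %||% rs@ringSpec$periWidthUm
  if (widthUm <= 0) stop("parameter error: peri-islet width must be positive")
  nIsl <- sum(rs@table$region_class %in% c("islet_ICI", "islet_IDI"))
  if (nIsl == 0) return(rs)
  counts <- collarBandCounts(rs, widthUm)[, 1]
  px <- rs@pixelSizeUm
  base <- max(rs@table$region_id, 0L)
  add <- data.frame(region_id = base + seq_len(nIsl),
                    region_class = "peri_islet",
                    parent_islet_id = seq_len(nIsl), k = NA_integer_,
                    area_um2 = counts * px^2)
  rs@ringSpec$periWidthUm <- widthUm
  rs@table <- rbind(rs@table, add)
  rs
}

#' Add the concentric ring regions
#'
#' Ring k of an islet covers tissue pixels outside all islets whose
#' distance to the nearest islet boundary lies in
#' \code{((k-1) w, k w]} with that islet nearest, for ring width w. Within
#' one islet the rings partition its collar out to \code{nRings * w}; between
#' islets, territory goes to the nearer boundary, so the whole ring family
#' is pairwise disjoint and excludes every islet interior.
#'
#' @param rs a \linkS4class{RegionSet}.
#' @param spec optional \code{\link{ringSpec}} overriding the stored one.
#' @return the \linkS4class{RegionSet} with \code{ring_k} rows added.
#' @export
makeRingSet <- function(rs, spec = NULL) {
  if (!is.null(spec)) rs@ringSpec[c("nRings", "ringWidthUm")] <-
      spec[c("nRings", "ringWidthUm")]
  w <- rs@ringSpec$ringWidthUm
  nR <- rs@ringSpec$nRings
  if (w <= 0) stop("parameter error: ring width must be positive")
  nIsl <- sum(rs@table$region_class %in% c("islet_ICI", "islet_IDI"))
  if (nIsl == 0) return(rs)
  px <- rs@pixelSizeUm
  base <- max(rs@table$region_id, 0L)
  counts <- collarBandCounts(rs, seq_len(nR) * w)
  for (k in seq_len(nR)) {
    add <- data.frame(region_id = base + (k - 1) * nIsl + seq_len(nIsl),
                      region_class = paste0("ring_", k),
                      parent_islet_id = seq_len(nIsl), k = as.integer(k),
                      area_um2 = counts[, k] * px^2)
    rs@table <- rbind(rs@table, add)
  }
  rs
}

#' Sample non-overlapping exocrine squares
#'
#' Places axis-aligned squares uniformly at random in the tissue rectangle,
#' rejecting any square that comes within the peri-islet buffer of an islet
#' boundary, lands inside an islet, leaves the tissue, or overlaps an
#' accepted square. Uses the current RNG state; placement is bounded
#' rejection sampling.
#'
#' @param rs a \linkS4class{RegionSet}.
#' @param nRegions number of squares (published design: 15).
#' @param sideUm square side length.
#' @param maxAttempts total proposal budget.
#' @return the \linkS4class{RegionSet} with \code{exocrine} rows added.
#' @export
sampleExocrine <- function(rs, nRegions = 15, sideUm = 500, maxAttempts = 10000) {
  if (nRegions == 0) return(rs)
  bp <- labelBoundaries(rs@isletLabels)
  px <- rs@pixelSizeUm
  bx <- idxToUm(bp$j, px); by <- idxToUm(bp$i, px)
  insideIslet <- function(x, y) {
    i <- umToIdx(y, px); j <- umToIdx(x, px)
    i >= 1 && i <= nrow(rs@isletLabels) && j >= 1 && j <= ncol(rs@isletLabels) &&
      rs@isletLabels[i, j] > 0L
  }
  sq <- sampleExocrineSquares(rs@tissueRect, cbind(bx, by), insideIslet,
                              nRegions, sideUm, rs@ringSpec$periWidthUm,
                              maxAttempts)
  base <- max(rs@table$region_id, 0L)
  sq$region_id <- base + seq_len(nrow(sq))
  rs@exocrine <- sq[c("region_id", "x0_um", "y0_um", "side_um")]
  rs@table <- rbind(rs@table,
                    data.frame(region_id = sq$region_id,
                               region_class = "exocrine",
                               parent_islet_id = NA_integer_, k = NA_integer_,
                               area_um2 = sideUm^2))
  rs
}

#' Geometry-level exocrine square sampler
#'
#' The placement core of \code{\link{sampleExocrine}}, usable with polygon
#' input when no raster mask exists. Rejection rules: the square (expanded
#' by \code{bufferUm}) must contain no islet boundary point, its centre must
#' not lie inside an islet, it must lie fully inside the tissue rectangle,
#' and it must not overlap any accepted square.
#'
#' @param tissueRect numeric(4) xmin, xmax, ymin, ymax (um).
#' @param boundaryPts two-column matrix of islet boundary points (um).
#' @param insideIslet function(x, y) -> logical, or NULL.
#' @param nRegions,sideUm,bufferUm,maxAttempts as in
#'   \code{\link{sampleExocrine}}.
#' @return data.frame \code{x0_um, y0_um, side_um}.
#' @export
sampleExocrineSquares <- function(tissueRect, boundaryPts, insideIslet,
                                  nRegions, sideUm, bufferUm = 10,
                                  maxAttempts = 10000) {
  if (tissueRect[2] - tissueRect[1] < sideUm ||
      tissueRect[4] - tissueRect[3] < sideUm)
    stop("tissue rectangle smaller than one exocrine square")
  acc <- matrix(numeric(0), 0, 2)
  att <- 0
  while (nrow(acc) < nRegions && att < maxAttempts) {
    att <- att + 1
    x0 <- stats::runif(1, tissueRect[1], tissueRect[2] - sideUm)
    y0 <- stats::runif(1, tissueRect[3], tissueRect[4] - sideUm)
    if (nrow(boundaryPts) &&
        any(boundaryPts[, 1] >= x0 - bufferUm &
            boundaryPts[, 1] <= x0 + sideUm + bufferUm &
            boundaryPts[, 2] >= y0 - bufferUm &
            boundaryPts[, 2] <= y0 + sideUm + bufferUm)) next
    if (!is.null(insideIslet) && insideIslet(x0 + sideUm / 2, y0 + sideUm / 2)) next
    if (nrow(acc) && any(abs(acc[, 1] - x0) < sideUm &
                         abs(acc[, 2] - y0) < sideUm)) next
    acc <- rbind(acc, c(x0, y0))
  }
  if (nrow(acc) < nRegions)
    stop(sprintf("exocrine placement infeasible: %d of %d squares placed after %d attempts",
                 nrow(acc), nRegions, att))
  data.frame(x0_um = acc[, 1], y0_um = acc[, 2], side_um = sideUm)
}

#' Assign cells to regions
#'
#' A cell belongs to a region when its nucleus centroid lies in the
#' region's (closed) footprint; a centroid exactly on a ring's outer edge
#' belongs to that ring, not the next. Each region family (islets,
#' peri-islet collars, rings, exocrine squares) is internally disjoint, so
#' a cell gets at most one region per family; families overlap by design
#' (the peri-islet collar lies inside ring 1; outer rings may cross
#' exocrine squares). Every cell inside the tissue rectangle is also
#' assigned to the \code{tissue} region.
#'
#' @param cells a \linkS4class{CellSet} or data.frame with \code{cell_id,
#'   x_um, y_um}.
#' @param rs a \linkS4class{RegionSet}.
#' @return data.frame: \code{cell_id, region_id, region_class}.
#' @export
assignCells <- function(cells, rs) {
  tab <- if (is(cells, "CellSet")) cells@table else cells
  px <- rs@pixelSizeUm
  n <- nrow(tab)
  if (n == 0)
    return(data.frame(cell_id = integer(0), region_id = integer(0),
                      region_class = character(0)))
  i <- umToIdx(tab$y_um, px); j <- umToIdx(tab$x_um, px)
  d <- dim(rs@isletLabels)
  inImg <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
  ii <- cbind(pmin(pmax(i, 1L), d[1]), pmin(pmax(j, 1L), d[2]))
  rect <- rs@tissueRect
  inTissue <- inImg & tab$x_um >= rect[1] & tab$x_um <= rect[2] &
    tab$y_um >= rect[3] & tab$y_um <= rect[4]
  lab <- ifelse(inTissue, rs@isletLabels[ii], 0L)
  dst <- ifelse(inTissue, rs@dist[ii], Inf)
  own <- ifelse(inTissue, rs@owner[ii], 0L)

  tt <- rs@table
  lookup <- function(class, parent = NA, k = NA) {
    sel <- tt$region_class == class &
      (is.na(parent) | (!is.na(tt$parent_islet_id) & tt$parent_islet_id == parent)) &
      (is.na(k) | (!is.na(tt$k) & tt$k == k))
    tt$region_id[sel][1]
  }
  out <- list()
  emit <- function(sel, ids, class)
    if (any(sel)) out[[length(out) + 1]] <<-
      data.frame(cell_id = tab$cell_id[sel], region_id = ids,
                 region_class = class)

  # islet family: islet region_id equals the mask label
  isIsl <- lab > 0L
  if (any(isIsl)) {
    ids <- lab[isIsl]
    out[[length(out) + 1]] <- data.frame(cell_id = tab$cell_id[isIsl],
      region_id = ids, region_class = tt$region_class[match(ids, tt$region_id)])
  }
  # peri family
  if (any(tt$region_class == "peri_islet")) {
    wPeri <- rs@ringSpec$periWidthUm
    sel <- !isIsl & dst > 0 & dst <= wPeri
    if (any(sel)) {
      periRows <- tt[tt$region_class == "peri_islet", ]
      ids <- periRows$region_id[match(own[sel], periRows$parent_islet_id)]
      emit(sel, ids, "peri_islet")
    }
  }
  # ring family
  ringRows <- tt[grepl("^ring_", tt$region_class), ]
  if (nrow(ringRows)) {
    w <- rs@ringSpec$ringWidthUm; nR <- rs@ringSpec$nRings
    sel <- !isIsl & dst > 0 & dst <= nR * w
    if (any(sel)) {
      k <- pmax(1L, as.integer(ceiling(dst[sel] / w - 1e-9)))
      key <- paste(own[sel], k)
      rkey <- paste(ringRows$parent_islet_id, ringRows$k)
      m <- match(key, rkey)
      emit(sel, ringRows$region_id[m], ringRows$region_class[m])
    }
  }
  # exocrine family (closed squares)
  if (nrow(rs@exocrine)) {
    for (q in seq_len(nrow(rs@exocrine))) {
      e <- rs@exocrine[q, ]
      sel <- inTissue & tab$x_um >= e$x0_um & tab$x_um <= e$x0_um + e$side_um &
        tab$y_um >= e$y0_um & tab$y_um <= e$y0_um + e$side_um
      emit(sel, e$region_id, "exocrine")
    }
  }
  # tissue
  if (any(tt$region_class == "tissue"))
    emit(inTissue, lookup("tissue"), "tissue")
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(cell_id = integer(0), region_id = integer(0),
                                      region_class = character(0))
  res[order(res$cell_id, res$region_id), , drop = FALSE]
}

#' Add a whole-tissue region row
#'
#' @param rs a \linkS4class{RegionSet}.
#' @return the \linkS4class{RegionSet} with a \code{tissue} row covering the
#'   tissue rectangle.
#' @export
addTissueRegion <- function(rs) {
  r <- rs@tissueRect
  rs@table <- rbind(rs@table,
    data.frame(region_id = max(rs@table$region_id, 0L) + 1L,
               region_class = "tissue", parent_islet_id = NA_integer_,
               k = NA_integer_,
               area_um2 = (r[2] - r[1]) * (r[4] - r[3])))
  rs
}

#' Construct every region family in one call
#'
#' Convenience wrapper: islets (segmented ICIs plus optional IDI
#' annotations), peri-islet collars, rings, exocrine squares and the
#' tissue region. Exocrine sampling consumes the current RNG state.
#'
#' @param stack a \linkS4class{ChannelStack}.
#' @param idiPolys optional list of IDI polygons (um).
#' @param spec a \code{\link{ringSpec}}.
#' @param nExocrine,exocrineSideUm exocrine sampling parameters.
#' @param tissueRect optional tissue rectangle; defaults to the image inset
#'   by 100 um.
#' @param minIsletAreaUm2 passed to \code{\link{segmentIslets}}.
#' @return a complete \linkS4class{RegionSet}.
#' @export
buildRegions <- function(stack, idiPolys = list(), spec = ringSpec(),
                         nExocrine = 15, exocrineSideUm = 500,
                         tissueRect = NULL, minIsletAreaUm2 = 1000) {
  px <- stack@pixelSizeUm
  d <- dim(stack@channels[[1]])
  if (is.null(tissueRect))
    tissueRect <- c(100, d[2] * px - 100, 100, d[1] * px - 100)
  seg <- segmentIslets(stack, minIsletAreaUm2 = minIsletAreaUm2)
  cmb <- combineIslets(seg, idiPolys, px)
  rs <- buildRegionSet(cmb$labels, cmb$classes, tissueRect, px, spec)
  rs <- makePeriIslet(rs)
  rs <- makeRingSet(rs)
  if (nExocrine > 0)
    rs <- tryCatch(sampleExocrine(rs, nExocrine, exocrineSideUm),
                   error = function(e) { warning(conditionMessage(e)); rs })
  addTissueRegion(rs)
}
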