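## OME-TIFF, GeoJSON and CSV interchange

omeXml <- function(channelNames, pixelSizeUm, sizeX, sizeY) {
  chans <- paste(sprintf('<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
                         seq_along(channelNames) - 1, channelNames),
                 collapse = "")
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0" Name="isletrings">',
    sprintf('<Pixels ID="Pixels:0" DimensionOrder="XYCZT" Type="uint8" SizeX="%d" SizeY="%d" SizeC="%d" SizeZ="1" SizeT="1" PhysicalSizeX="%g" PhysicalSizeXUnit="µm" PhysicalSizeY="%g" PhysicalSizeYUnit="µm">',
            sizeX, sizeY, length(channelNames), pixelSizeUm, pixelSizeUm),
    chans, '</Pixels></Image></OME>')
}

companionPath <- function(path) paste0(path, ".companion.ome")

#' Write a ChannelStack as OME-TIFF
#'
#' One 8-bit plane per channel. The OME-XML metadata (channel names,
#' physical pixel size in micrometres) is written to a companion OME-XML
#' file next to the TIFF (\code{<path>.companion.ome}), the standard
#' pattern when the TIFF container itself cannot carry the header.
#'
#' @param stack a \linkS4class{ChannelStack}.
#' @param path output file.
#' @return the paths written (TIFF and companion), invisibly.
#' @export
writeChannelStack <- function(stack, path) {
  d <- dim(stack@channels[[1]])
  xml <- omeXml(names(stack@channels), stack@pixelSizeUm, d[2], d[1])
  planes <- lapply(stack@channels, function(m) m / 255)
  tiff::writeTIFF(planes, path, bits.per.sample = 8L, compression = "LZW")
  writeLines(xml, companionPath(path))
  invisible(c(path, companionPath(path)))
}

#' Read an OME-TIFF into a ChannelStack
#'
#' Channel names and pixel size are taken from the OME-XML description
#' when present; otherwise supply them.
#'
#' @param path OME-TIFF file.
#' @param channelNames,pixelSizeUm fallbacks when no OME-XML is present.
#' @return a \linkS4class{ChannelStack}.
#' @export
readChannelStack <- function(path, channelNames = NULL, pixelSizeUm = NULL) {
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  desc <- attr(planes[[1]], "description")
  if (is.null(desc) && file.exists(companionPath(path)))
    desc <- paste(readLines(companionPath(path), warn = FALSE), collapse = "")
  if (!is.null(desc) && grepl("<OME", desc, fixed = TRUE)) {
    x <- xml2::read_xml(desc)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(x), d1 = "ome")
    px <- xml2::xml_find_first(x, ".//ome:Pixels", ns)
    if (is.null(pixelSizeUm))
      pixelSizeUm <- as.numeric(xml2::xml_attr(px, "PhysicalSizeX"))
    if (is.null(channelNames))
      channelNames <- xml2::xml_attr(xml2::xml_find_all(x, ".//ome:Channel", ns),
                                     "Name")
  }
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_along(planes))
  if (is.null(pixelSizeUm)) stop("pixel size not found in file; supply pixelSizeUm")
  chans <- lapply(planes, function(p)
    matrix(pmin(pmax(as.integer(round(p * 255)), 0L), 255L), nrow(p), ncol(p)))
  names(chans) <- channelNames
  channelStack(chans, pixelSizeUm)
}

geojsonFeature <- function(coords, properties) {
  ring <- lapply(seq_len(nrow(coords)), function(i) c(coords[i, 1], coords[i, 2]))
  ring[[length(ring) + 1]] <- ring[[1]]
  list(type = "Feature",
       geometry = list(type = "Polygon", coordinates = list(ring)),
       properties = properties)
}

#' Write ground-truth regions as GeoJSON
#'
#' One feature per islet polygon (classification \code{"Islet-ICI"} or
#' \code{"Islet-IDI"}) plus the tissue rectangle
#' (classification \code{"Tissue"}); coordinates in micrometres.
#'
#' @param truth a \linkS4class{GroundTruthTissue}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTruthRegions <- function(truth, path) {
  feats <- lapply(seq_along(truth@islets), function(id) {
    isl <- truth@islets[[id]]
    geojsonFeature(isl$poly, list(classification = paste0("Islet-", isl$label),
                                  region_id = id))
  })
  r <- truth@tissueRect
  rectPoly <- cbind(c(r[1], r[2], r[2], r[1]), c(r[3], r[3], r[4], r[4]))
  feats[[length(feats) + 1]] <-
    geojsonFeature(rectPoly, list(classification = "Tissue"))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a RegionSet as GeoJSON
#'
#' Exports islet and exocrine region outlines with properties
#' \code{classification}, \code{region_id}, \code{parent_islet_id} and
#' \code{area_um2}. Ring and peri-islet regions are raster-partition
#' derived; their rows are exported as properties-only features (no
#' geometry) unless \code{traceRings} is set, in which case their outlines
#' are traced from the raster masks.
#'
#' @param rs a \linkS4class{RegionSet}.
#' @param path output file.
#' @param traceRings trace ring/peri outlines (slow on large images).
#' @return the path, invisibly.
#' @export
writeRegionsGeoJSON <- function(rs, path, traceRings = FALSE) {
  px <- rs@pixelSizeUm
  feats <- list()
  islTab <- rs@table[rs@table$region_class %in% c("islet_ICI", "islet_IDI"), ]
  if (nrow(islTab)) {
    oc <- EBImage::ocontour(EBImage::Image(t(rs@isletLabels)))
    for (q in seq_len(nrow(islTab))) {
      id <- islTab$region_id[q]
      if (id > length(oc) || !nrow(oc[[id]])) next
      poly <- (oc[[id]]) * px  # ocontour on transposed image: x, y order
      feats[[length(feats) + 1]] <- geojsonFeature(poly,
        list(classification = islTab$region_class[q], region_id = id,
             area_um2 = islTab$area_um2[q]))
    }
  }
  for (q in seq_len(nrow(rs@exocrine))) {
    e <- rs@exocrine[q, ]
    poly <- cbind(e$x0_um + c(0, e$side_um, e$side_um, 0),
                  e$y0_um + c(0, 0, e$side_um, e$side_um))
    feats[[length(feats) + 1]] <- geojsonFeature(poly,
      list(classification = "exocrine", region_id = e$region_id,
           area_um2 = e$side_um^2))
  }
  other <- rs@table[!rs@table$region_class %in%
                      c("islet_ICI", "islet_IDI", "exocrine"), ]
  for (q in seq_len(nrow(other))) {
    props <- list(classification = other$region_class[q],
                  region_id = other$region_id[q],
                  parent_islet_id = other$parent_islet_id[q],
                  area_um2 = other$area_um2[q])
    if (traceRings) {
      m <- regionMask(rs, other$region_id[q])
      oc <- EBImage::ocontour(EBImage::Image(t(m)))
      if (length(oc) && nrow(oc[[1]]))
        feats[[length(feats) + 1]] <- geojsonFeature(oc[[1]] * px, props)
      else feats[[length(feats) + 1]] <- list(type = "Feature",
        geometry = NULL, properties = props)
    } else {
      feats[[length(feats) + 1]] <- list(type = "Feature", geometry = NULL,
                                         properties = props)
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Binary footprint of one region
#'
#' @param rs a \linkS4class{RegionSet}.
#' @param regionId region id from the table.
#' @return logical matrix (tissue-clipped for collar/ring regions).
#' @export
regionMask <- function(rs, regionId) {
  row <- rs@table[rs@table$region_id == regionId, ]
  if (!nrow(row)) stop("unknown region_id")
  cls <- row$region_class
  d <- dim(rs@isletLabels)
  inRect <- matrix(FALSE, d[1], d[2])
  cr <- rectIdx(rs@tissueRect, d, rs@pixelSizeUm)
  inRect[cr$i, cr$j] <- TRUE
  if (cls %in% c("islet_ICI", "islet_IDI"))
    return(rs@isletLabels == row$region_id)
  if (cls == "peri_islet")
    return(inRect & rs@isletLabels == 0L & rs@owner == row$parent_islet_id &
             rs@dist > 0 & rs@dist <= rs@ringSpec$periWidthUm)
  if (grepl("^ring_", cls)) {
    w <- rs@ringSpec$ringWidthUm
    return(inRect & rs@isletLabels == 0L & rs@owner == row$parent_islet_id &
             rs@dist > (row$k - 1) * w & rs@dist <= row$k * w)
  }
  if (cls == "exocrine") {
    e <- rs@exocrine[rs@exocrine$region_id == regionId, ]
    px <- rs@pixelSizeUm
    m <- matrix(FALSE, d[1], d[2])
    cr2 <- rectIdx(c(e$x0_um, e$x0_um + e$side_um, e$y0_um, e$y0_um + e$side_um),
                   d, px)
    m[cr2$i, cr2$j] <- TRUE
    return(m)
  }
  if (cls == "tissue") return(inRect)
  stop("unsupported region class")
}

#' Write a density map as 32-bit TIFF
#'
#' @param dm a \code{DensityMap} from \code{\link{densityMap}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDensityMap <- function(dm, path) {
  g <- dm$grid
  mx <- max(g, 1e-12)
  tiff::writeTIFF(g / mx, path, bits.per.sample = 32L, compression = "none")
  side <- paste0(path, ".json")
  jsonlite::write_json(list(scale_per_mm2 = mx,
                            grid_spacing_um = dm$gridSpacingUm,
                            bandwidth_um = dm$bandwidthUm,
                            origin_um = dm$originUm),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}
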