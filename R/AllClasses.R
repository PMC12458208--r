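#' @import methods
NULL

#' Multi-channel calibrated image stack
#'
#' A pixel-registered set of 2-D, 8-bit channels with a physical pixel size,
#' the raw input of the imaging stages. Channels are stored as integer
#' matrices (rows = y, columns = x) with values in 0-255. The pixel centre of
#' matrix element \code{[i, j]} sits at physical coordinates
#' \code{((j - 1) * pixelSize, (i - 1) * pixelSize)} micrometres, i.e. pixel
#' (0,0) is the top-left corner, x grows rightwards and y downwards.
#'
#' @slot channels named list of integer matrices, one per channel, all of
#'   identical dimension, values in \code{[0, 255]}.
#' @slot pixelSizeUm positive numeric scalar, micrometres per pixel.
#' @export
setClass("ChannelStack",
  representation(channels = "list", pixelSizeUm = "numeric"))

setValidity("ChannelStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0) return("at least one channel required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named")
  dims <- vapply(ch, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all channels must have identical dimensions")
  for (nm in names(ch)) {
    r <- range(ch[[nm]])
    if (r[1] < 0 || r[2] > 255)
      return(sprintf("channel '%s' has values outside [0, 255]", nm))
  }
  if (length(object@pixelSizeUm) != 1 || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a positive scalar")
  TRUE
})

#' Construct a ChannelStack
#'
#' @param channels named list of numeric/integer matrices in 0-255.
#' @param pixelSizeUm micrometres per pixel.
#' @return A \linkS4class{ChannelStack}.
#' @export
channelStack <- function(channels, pixelSizeUm) {
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "integer"
    m
  })
  new("ChannelStack", channels = channels, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' @describeIn ChannelStack channel names
#' @param x a ChannelStack
#' @export
setMethod("names", "ChannelStack", function(x) names(x@channels))

#' Extract one channel as an integer matrix
#' @param stack a \linkS4class{ChannelStack}
#' @param name channel name
#' @return integer matrix
#' @export
getChannel <- function(stack, name) {
  if (!name %in% names(stack@channels))
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(names(stack@channels), collapse = ", ")))
  stack@channels[[name]]
}

#' @describeIn ChannelStack pixel size accessor (micrometres)
#' @param object a ChannelStack
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ChannelStack", function(object) object@pixelSizeUm)

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("ChannelStack: %d x %d px (%.2f x %.2f mm), %.3f um/px\n",
              d[2], d[1],
              d[2] * object@pixelSizeUm / 1000, d[1] * object@pixelSizeUm / 1000,
              object@pixelSizeUm))
  cat("channels:", paste(names(object@channels), collapse = ", "), "\n")
})

#' Synthetic tissue configuration
#'
#' Holds every parameter of the synthetic multiplex-IF pancreas generator:
#' geometry of the virtual section, islet shapes, cell density and spacing,
#' zone-wise macrophage (CD68+) fractions, HLA-II co-expression structure and
#' the per-channel intensity model. Fixed imaging constants default to the
#' acquisition they emulate: 0.325 um pixels and the full 8-bit range.
#'
#' @slot imageSizePx integer pair (width, height) in pixels.
#' @slot pixelSizeUm micrometres per pixel (default 0.325).
#' @slot nIslets number of islets to place.
#' @slot isletRadiusUmRange min/max mean islet radius (um).
#' @slot isletShapeIrregularity in [0,1]; 0 gives circles, larger values add
#'   low-order radial harmonics.
#' @slot iciFraction fraction of islets that are insulin-containing.
#' @slot cellDensityPerMm2 expected total cell density.
#' @slot nucleusRadiusUmRange min/max nucleus radius (um).
#' @slot minSpacingUm hard-core minimum centre-to-centre cell spacing (um);
#'   must be at least 1.5x the minimum nucleus radius.
#' @slot zoneMacrophageFraction named numeric over
#'   \code{c("islet", "ring1".."ring8", "exocrine")}, each in [0,1].
#' @slot hla2FractionMacrophage mean per-islet fraction of macrophages that
#'   are HLA-II+, and the global fraction outside islet/peri zones.
#' @slot hla2FractionBeta mean per-islet fraction of beta cells HLA-II+.
#' @slot hla2FractionOther background HLA-II+ rate in other cells.
#' @slot betaFractionInIslet fraction of non-macrophage cells inside an
#'   insulin-containing islet that are beta cells.
#' @slot coexpressionRankCorrelation target Spearman correlation between the
#'   per-islet macrophage HLA-II+ fraction and the per-islet beta-cell
#'   HLA-II+ fraction, realised through a Gaussian copula.
#' @slot copulaSdMacrophage latent between-islet SD of the macrophage
#'   HLA-II+ fraction (beta marginal).
#' @slot copulaSdBeta latent between-islet SD of the beta-cell HLA-II+
#'   fraction.
#' @slot intensityModel per-channel list with \code{bgMean}, \code{bgSd},
#'   \code{fgMean}, \code{fgSd} (0-255); the INS channel additionally has
#'   \code{isletFill}, the diffuse insulin level inside an ICI.
#' @slot seed integer RNG seed; the whole generation is a pure function of
#'   the configuration including this seed.
#' @export
setClass("TissueConfig",
  representation(
    imageSizePx = "integer", pixelSizeUm = "numeric", nIslets = "integer",
    isletRadiusUmRange = "numeric", isletShapeIrregularity = "numeric",
    iciFraction = "numeric", cellDensityPerMm2 = "numeric",
    nucleusRadiusUmRange = "numeric", minSpacingUm = "numeric",
    zoneMacrophageFraction = "numeric", hla2FractionMacrophage = "numeric",
    hla2FractionBeta = "numeric", hla2FractionOther = "numeric",
    betaFractionInIslet = "numeric", coexpressionRankCorrelation = "numeric",
    copulaSdMacrophage = "numeric", copulaSdBeta = "numeric",
    intensityModel = "list", seed = "integer"))

.zoneNames <- c("islet", paste0("ring", 1:8), "exocrine")

setValidity("TissueConfig", function(object) {
  frac01 <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (length(object@imageSizePx) != 2 || any(object@imageSizePx < 16))
    return("imageSizePx must be a pair of at least 16 px")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  if (object@nIslets < 0) return("nIslets must be non-negative")
  if (length(object@isletRadiusUmRange) != 2 ||
      any(object@isletRadiusUmRange <= 0) || diff(object@isletRadiusUmRange) < 0)
    return("isletRadiusUmRange must be an increasing positive pair")
  if (!frac01(object@isletShapeIrregularity)) return("isletShapeIrregularity must be in [0,1]")
  if (!frac01(object@iciFraction)) return("iciFraction must be in [0,1]")
  if (object@cellDensityPerMm2 <= 0) return("cellDensityPerMm2 must be positive")
  if (length(object@nucleusRadiusUmRange) != 2 ||
      any(object@nucleusRadiusUmRange <= 0) || diff(object@nucleusRadiusUmRange) < 0)
    return("nucleusRadiusUmRange must be an increasing positive pair")
  if (object@minSpacingUm < 1.5 * object@nucleusRadiusUmRange[1])
    return("minSpacingUm must be at least 1.5x the minimum nucleus radius")
  if (!identical(sort(names(object@zoneMacrophageFraction)), sort(.zoneNames)))
    return(sprintf("zoneMacrophageFraction must be named over: %s",
                   paste(.zoneNames, collapse = ", ")))
  if (!frac01(object@zoneMacrophageFraction))
    return("zoneMacrophageFraction values must be in [0,1]")
  if (!frac01(c(object@hla2FractionMacrophage, object@hla2FractionBeta,
                object@hla2FractionOther, object@betaFractionInIslet)))
    return("all fractions must be in [0,1]")
  if (abs(object@coexpressionRankCorrelation) > 1)
    return("coexpressionRankCorrelation must be in [-1,1]")
  for (nm in c("DAPI", "INS", "CD68", "HLAII")) {
    im <- object@intensityModel[[nm]]
    if (is.null(im)) return(sprintf("intensityModel missing channel '%s'", nm))
    if (any(c(im$bgMean, im$fgMean) < 0) || any(c(im$bgMean, im$fgMean) > 255))
      return("intensity means must lie within [0, 255]")
  }
  TRUE
})

setMethod("show", "TissueConfig", function(object) {
  cat(sprintf("TissueConfig: %d x %d px at %.3f um/px, %d islets, %.0f cells/mm2, seed %d\n",
              object@imageSizePx[1], object@imageSizePx[2], object@pixelSizeUm,
              object@nIslets, object@cellDensityPerMm2, object@seed))
  z <- object@zoneMacrophageFraction[.zoneNames]
  cat("CD68+ zone fractions:",
      paste(sprintf("%s=%.3f", names(z), z), collapse = " "), "\n")
})

#' Ground truth of a generated tissue
#'
#' The generator's record of true cell positions, types and marker states,
#' plus the true islet shapes and tissue rectangle - the oracle for every
#' recovery test run against the imaging pipeline.
#'
#' @slot cells data.frame, one row per cell: \code{cell_id, x_um, y_um,
#'   cell_type, insulin_pos, cd68_pos, hla2_pos, zone, parent_islet_id,
#'   nucleus_r_um, aspect, theta}.
#' @slot islets list of islet descriptors (centre, radial-harmonic shape,
#'   polygon and ICI/IDI label).
#' @slot isletTable data.frame: \code{islet_id, label, cx_um, cy_um,
#'   mean_radius_um, area_um2}.
#' @slot tissueRect numeric(4): xmin, xmax, ymin, ymax of the tissue
#'   rectangle in micrometres.
#' @slot config the \linkS4class{TissueConfig} that produced it.
#' @export
setClass("GroundTruthTissue",
  representation(cells = "data.frame", islets = "list",
                 isletTable = "data.frame", tissueRect = "numeric",
                 config = "TissueConfig"))

setValidity("GroundTruthTissue", function(object) {
  cl <- object@cells
  need <- c("cell_id", "x_um", "y_um", "cell_type", "insulin_pos",
            "cd68_pos", "hla2_pos", "zone", "parent_islet_id")
  if (!all(need %in% names(cl))) return("cells table misses required columns")
  if (nrow(cl)) {
    if (any(cl$cell_type == "beta" & !cl$insulin_pos))
      return("beta cells must be insulin_pos")
    if (any(cl$cell_type == "macrophage" & !cl$cd68_pos))
      return("macrophages must be cd68_pos")
    if (any(cl$cell_type == "other" & (cl$insulin_pos | cl$cd68_pos)))
      return("'other' cells must be insulin- and CD68-negative")
  }
  if (length(object@tissueRect) != 4) return("tissueRect must be xmin,xmax,ymin,ymax")
  TRUE
})

setMethod("show", "GroundTruthTissue", function(object) {
  cat(sprintf("GroundTruthTissue: %d cells (%d CD68+, %d beta), %d islets (%d ICI)\n",
              nrow(object@cells), sum(object@cells$cd68_pos),
              sum(object@cells$cell_type == "beta"),
              nrow(object@isletTable), sum(object@isletTable$label == "ICI")))
})

#' Detected cells with compartment geometry and features
#'
#' The unit of counting for the whole analysis: nuclei detected from the
#' nuclear channel, optionally expanded into whole-cell compartments, with
#' per-channel mean intensities measured over nucleus, cell and cytoplasm.
#' Compartments are raster label masks sharing the cell ids of \code{table}.
#'
#' @slot table data.frame, one row per cell: \code{cell_id, x_um, y_um,
#'   nucleus_area_um2}, plus \code{cell_area_um2} after expansion and
#'   \code{<channel>_<compartment>_mean} feature columns after measurement.
#' @slot nucleusLabels integer matrix of nucleus pixel labels (0 background).
#' @slot cellLabels integer matrix of expanded-cell labels, or a 0x0 matrix
#'   before expansion.
#' @slot pixelSizeUm micrometres per pixel.
#' @export
setClass("CellSet",
  representation(table = "data.frame", nucleusLabels = "matrix",
                 cellLabels = "matrix", pixelSizeUm = "numeric"))

setMethod("show", "CellSet", function(object) {
  cat(sprintf("CellSet: %d cells, %s, %.3f um/px\n", nrow(object@table),
              if (length(object@cellLabels)) "expanded" else "nuclei only",
              object@pixelSizeUm))
})

#' Region geometry of one tissue section
#'
#' All region families constructed around the islets: the islet regions
#' themselves (ICI from the insulin channel, IDI from annotations), the
#' 10-um peri-islet collars, the eight 25-um concentric rings, randomly
#' placed exocrine squares and the tissue rectangle. Ring and peri-islet
#' territory between neighbouring islets is partitioned by nearest islet
#' boundary so regions of one family never overlap.
#'
#' Geometry is raster-based: \code{isletLabels} holds the islet id per pixel,
#' \code{dist} the distance (um) from each non-islet pixel to the nearest
#' islet boundary, and \code{owner} that islet's id. Distances use the
#' convention that the region boundary runs half a pixel outside the
#' outermost islet pixel centres.
#'
#' @slot table data.frame: \code{region_id, region_class, parent_islet_id,
#'   k, area_um2}.
#' @slot isletLabels integer matrix of islet ids (0 elsewhere).
#' @slot dist numeric matrix, distance to nearest islet in um (Inf when no
#'   islets; 0 inside islets).
#' @slot owner integer matrix, id of the nearest islet (0 inside islets'
#'   own pixels mean the pixel belongs to that islet).
#' @slot ringSpec list: \code{periWidthUm}, \code{nRings}, \code{ringWidthUm}.
#' @slot exocrine data.frame of exocrine squares: \code{region_id, x0_um,
#'   y0_um, side_um}.
#' @slot tissueRect numeric(4): xmin, xmax, ymin, ymax (um).
#' @slot pixelSizeUm micrometres per pixel.
#' @export
setClass("RegionSet",
  representation(table = "data.frame", isletLabels = "matrix",
                 dist = "matrix", owner = "matrix", ringSpec = "list",
                 exocrine = "data.frame", tissueRect = "numeric",
                 pixelSizeUm = "numeric"))

setMethod("show", "RegionSet", function(object) {
  tab <- table(object@table$region_class)
  cat("RegionSet:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
})

#' Per-cell marker classifier
#'
#' One model per marker (insulin, CD68, HLA-II), each either a fixed
#' intensity threshold on a chosen compartment mean or a seeded random-forest
#' over all compartment features, plus per-channel minimum intensity floors
#' below which a cell can never be called positive.
#'
#' @slot markers named list over \code{c("INS", "CD68", "HLAII")}; each entry
#'   is a list with \code{type} ("threshold" or "rf"), \code{channel},
#'   \code{compartment} and either \code{threshold} or \code{fit}.
#' @slot channelFloor named numeric, minimum compartment-mean intensity per
#'   channel (0 disables the floor).
#' @export
setClass("ClassifierModel",
  representation(markers = "list", channelFloor = "numeric"))

setValidity("ClassifierModel", function(object) {
  if (!all(c("INS", "CD68", "HLAII") %in% names(object@markers)))
    return("a model must exist for each of INS, CD68, HLAII")
  for (nm in names(object@markers)) {
    m <- object@markers[[nm]]
    if (!m$type %in% c("threshold", "rf")) return("marker type must be 'threshold' or 'rf'")
    if (m$type == "threshold" &&
        (m$threshold < 0 || m$threshold > 255))
      return("thresholds must lie within [0, 255]")
    if (!m$compartment %in% c("nucleus", "cell", "cytoplasm"))
      return("compartment must be nucleus, cell or cytoplasm")
  }
  TRUE
})

setMethod("show", "ClassifierModel", function(object) {
  for (nm in names(object@markers)) {
    m <- object@markers[[nm]]
    if (m$type == "threshold")
      cat(sprintf("%s: %s_%s_mean > %.1f\n", nm, m$channel, m$compartment, m$threshold))
    else
      cat(sprintf("%s: random forest on all features (%d trees)\n", nm, m$fit$ntree))
  }
  if (any(object@channelFloor > 0))
    cat("floors:", paste(sprintf("%s=%.1f", names(object@channelFloor),
                                 object@channelFloor), collapse = " "), "\n")
})
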