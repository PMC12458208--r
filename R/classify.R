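#' Calibrate per-channel minimum intensity floors
#'
#' Computes, for every channel, the 99.5th percentile of the background
#' pixels - pixels farther than \code{marginUm} from any detected nucleus.
#' Cells whose relevant compartment mean does not exceed the floor can
#' never be called positive, which protects threshold and forest models
#' alike from calling positives in empty tissue.
#'
#' @param stack a \linkS4class{ChannelStack}.
#' @param cells a \linkS4class{CellSet} (its nucleus mask defines
#'   foreground); pass NULL to treat every pixel as background.
#' @param marginUm dilation of nuclei excluded from the background
#'   (default 5 um).
#' @param prob percentile of background used as the floor.
#' @return named numeric vector of floors, one per channel.
#' @export
calibrateChannelFloors <- function(stack, cells = NULL, marginUm = 5,
                                   prob = 0.995) {
  bg <- NULL
  if (!is.null(cells) && nrow(cells@table) > 0) {
    lab <- nearestSeedLabel(cells@nucleusLabels,
                            maxDistPx = marginUm / stack@pixelSizeUm +
                              .edgeOffsetPx)
    bg <- lab == 0L
    rm(lab)
  }
  vapply(stack@channels, function(ch) {
    v <- if (is.null(bg)) as.vector(ch) else ch[bg]
    if (!length(v)) return(0)
    # deterministic stride subsample: the percentile of millions of
    # background pixels is estimated to well under one grey level
    if (length(v) > 2e6) v <- v[as.integer(seq(1, length(v), length.out = 2e6))]
    as.numeric(stats::quantile(v, prob, names = FALSE))
  }, numeric(1))
}

#' Fixed-threshold marker classifier
#'
#' The fully deterministic classifier variant: a cell is positive for a
#' marker when its chosen compartment mean on the marker's channel exceeds
#' a fixed threshold (and the channel floor).
#'
#' @param insThreshold,cd68Threshold,hla2Threshold thresholds on 0-255.
#' @param compartment compartment whose mean is compared
#'   (default \code{"cell"} for all three markers).
#' @param channelFloor optional named floors from
#'   \code{\link{calibrateChannelFloors}}.
#' @return a \linkS4class{ClassifierModel}.
#' @export
thresholdClassifier <- function(insThreshold, cd68Threshold, hla2Threshold,
                                compartment = "cell", channelFloor = NULL) {
  mk <- function(channel, thr) list(type = "threshold", channel = channel,
                                    compartment = compartment, threshold = thr)
  if (is.null(channelFloor))
    channelFloor <- c(DAPI = 0, INS = 0, CD68 = 0, HLAII = 0)
  new("ClassifierModel",
      markers = list(INS = mk("INS", insThreshold),
                     CD68 = mk("CD68", cd68Threshold),
                     HLAII = mk("HLAII", hla2Threshold)),
      channelFloor = channelFloor)
}

#' Midpoint threshold model for a generator configuration
#'
#' Thresholds each marker channel halfway between its background (for INS:
#' islet-fill) level and its foreground level - the natural operating point
#' when the intensity model is known.
#'
#' @param config a \linkS4class{TissueConfig}.
#' @param channelFloor optional floors.
#' @return a \linkS4class{ClassifierModel}.
#' @export
midpointClassifier <- function(config, channelFloor = NULL) {
  im <- config@intensityModel
  thresholdClassifier(
    insThreshold = (im$INS$isletFill + im$INS$fgMean) / 2,
    cd68Threshold = (im$CD68$bgMean + im$CD68$fgMean) / 2,
    hla2Threshold = (im$HLAII$bgMean + im$HLAII$fgMean) / 2,
    channelFloor = channelFloor)
}

#' Train a random-forest marker classifier
#'
#' Trains a seeded decision-tree ensemble (random forest, 50 trees, depth
#' capped at 8) for one marker over all per-compartment intensity features
#' of all channels. Training is deterministic given the seed.
#'
#' @param features data.frame of feature columns
#'   (\code{<channel>_<compartment>_mean}) for the training cells.
#' @param labels logical vector of marker positivity, one per row.
#' @param marker one of \code{"INS"}, \code{"CD68"}, \code{"HLAII"}.
#' @param ntree,maxDepth forest size and depth cap.
#' @param seed RNG seed for the forest.
#' @return a marker-model entry usable inside a
#'   \linkS4class{ClassifierModel}.
#' @export
trainMarkerClassifier <- function(features, labels, marker, ntree = 50,
                                  maxDepth = 8, seed = 1) {
  stopifnot(marker %in% c("INS", "CD68", "HLAII"))
  labels <- as.logical(labels)
  for (cls in c(TRUE, FALSE)) {
    n <- sum(labels == cls)
    if (n == 0)
      stop(sprintf("single-class training set: no %s examples for %s",
                   if (cls) "positive" else "negative", marker))
    if (n < 20)
      stop(sprintf("need >= 20 %s examples for %s (got %d)",
                   if (cls) "positive" else "negative", marker, n))
  }
  fcols <- grep("_(nucleus|cell|cytoplasm)_mean$", names(features), value = TRUE)
  X <- features[fcols]
  X[is.na(X)] <- 0
  fit <- withSeed(seed, randomForest::randomForest(
    x = X, y = factor(labels, levels = c(FALSE, TRUE)),
    ntree = ntree, maxnodes = min(2^maxDepth, max(2L, nrow(X)))))
  list(type = "rf", channel = marker, compartment = "cell",
       fit = fit, features = fcols)
}

#' Assemble a ClassifierModel from trained marker entries
#'
#' @param ins,cd68,hla2 marker entries from
#'   \code{\link{trainMarkerClassifier}} (or threshold entries).
#' @param channelFloor optional named floors.
#' @return a \linkS4class{ClassifierModel}.
#' @export
classifierModel <- function(ins, cd68, hla2, channelFloor = NULL) {
  if (is.null(channelFloor))
    channelFloor <- c(DAPI = 0, INS = 0, CD68 = 0, HLAII = 0)
  new("ClassifierModel", markers = list(INS = ins, CD68 = cd68, HLAII = hla2),
      channelFloor = channelFloor)
}

#' Classify cells into marker and composite calls
#'
#' Applies the per-marker models, overrides a call to negative when the
#' marker compartment mean does not exceed the channel floor, and derives
#' the composite (double-positive) calls by conjunction:
#' CD68+HLA-II+ (activated macrophages) and insulin+HLA-II+ (HLA-II
#' expressing beta cells).
#'
#' @param cells a measured \linkS4class{CellSet} (or its feature
#'   data.frame).
#' @param model a \linkS4class{ClassifierModel}.
#' @return data.frame: \code{cell_id, x_um, y_um, insulin_pos, cd68_pos,
#'   hla2_pos, cd68_hla2_pos, insulin_hla2_pos}.
#' @export
classifyCells <- function(cells, model) {
  tab <- if (is(cells, "CellSet")) cells@table else cells
  n <- nrow(tab)
  call1 <- function(entry) {
    if (n == 0) return(logical(0))
    if (entry$type == "threshold") {
      col <- paste0(entry$channel, "_", entry$compartment, "_mean")
      if (!col %in% names(tab)) stop(sprintf("missing feature '%s'", col))
      v <- tab[[col]]
      bad <- which(is.na(v))
      if (length(bad) && entry$compartment != "cytoplasm")
        stop(sprintf("missing feature %s for cell_id(s): %s", col,
                     paste(utils::head(tab$cell_id[bad], 5), collapse = ", ")))
      pos <- !is.na(v) & v > entry$threshold
    } else {
      X <- tab[entry$features]
      X[is.na(X)] <- 0
      pos <- stats::predict(entry$fit, X) == "TRUE"
    }
    # channel floor: compartment mean must exceed the floor to be positive
    fl <- model@channelFloor[entry$channel]
    if (!is.na(fl) && fl > 0) {
      col <- paste0(entry$channel, "_", entry$compartment, "_mean")
      if (col %in% names(tab)) pos <- pos & !is.na(tab[[col]]) & tab[[col]] > fl
    }
    as.logical(pos)
  }
  ins <- call1(model@markers$INS)
  cd68 <- call1(model@markers$CD68)
  hla2 <- call1(model@markers$HLAII)
  data.frame(cell_id = tab$cell_id,
             x_um = tab$x_um %||% rep(NA_real_, n),
             y_um = tab$y_um %||% rep(NA_real_, n),
             insulin_pos = ins, cd68_pos = cd68, hla2_pos = hla2,
             cd68_hla2_pos = cd68 & hla2, insulin_hla2_pos = ins & hla2)
}
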