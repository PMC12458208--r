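#' Pipeline configuration
#'
#' Bundles every stage's parameters for an end-to-end run. Defaults encode
#' the published design constants: a 10 um peri-islet collar, eight 25 um
#' rings, 15 exocrine regions and 0.325 um pixels.
#'
#' @param tissue a \linkS4class{TissueConfig}.
#' @param detection a \code{\link{detectionParams}} list.
#' @param classifier \code{"midpoint"} (threshold model at the generator's
#'   intensity midpoints), \code{"train-on-groundtruth"} (random forests
#'   trained on a labelled subset of the generated cells), or a
#'   \linkS4class{ClassifierModel}.
#' @param rings a \code{\link{ringSpec}}.
#' @param nExocrine,exocrineSideUm exocrine sampling design.
#' @param useChannelFloors calibrate and apply per-channel minimum
#'   intensity floors.
#' @param densityGridUm,densityBandwidthUm density-map resolution.
#' @param seed pipeline seed; overrides the tissue config's seed.
#' @return a list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(tissue = tissueConfig(),
                           detection = detectionParams(),
                           classifier = "midpoint",
                           rings = ringSpec(),
                           nExocrine = 15, exocrineSideUm = 500,
                           useChannelFloors = TRUE,
                           densityGridUm = 50, densityBandwidthUm = 100,
                           seed = NULL) {
  structure(list(tissue = tissue, detection = detection,
                 classifier = classifier, rings = rings,
                 nExocrine = nExocrine, exocrineSideUm = exocrineSideUm,
                 useChannelFloors = useChannelFloors,
                 densityGridUm = densityGridUm,
                 densityBandwidthUm = densityBandwidthUm,
                 seed = as.integer(seed %||% tissue@seed)),
            class = "PipelineConfig")
}

resolveClassifier <- function(config, stack, cells, truth) {
  floors <- if (config$useChannelFloors)
    calibrateChannelFloors(stack, cells) else NULL
  if (is(config$classifier, "ClassifierModel")) return(config$classifier)
  if (identical(config$classifier, "midpoint"))
    return(midpointClassifier(config$tissue, floors))
  if (identical(config$classifier, "train-on-groundtruth")) {
    if (is.null(truth)) stop("train-on-groundtruth requires a generated tissue")
    lab <- matchToTruth(cells, truth)
    sub <- which(!is.na(lab$truth_idx))
    nTrain <- min(4000L, length(sub))
    sub <- sub[round(seq(1, length(sub), length.out = nTrain))]
    feats <- cells@table[sub, ]
    tcl <- truth@cells[lab$truth_idx[sub], ]
    seeds <- childSeed(config$seed, 41:43)
    return(classifierModel(
      ins = trainMarkerClassifier(feats, tcl$insulin_pos, "INS", seed = seeds[1]),
      cd68 = trainMarkerClassifier(feats, tcl$cd68_pos, "CD68", seed = seeds[2]),
      hla2 = trainMarkerClassifier(feats, tcl$hla2_pos, "HLAII", seed = seeds[3]),
      channelFloor = floors))
  }
  stop("unknown classifier specification")
}

#' Match detected cells to ground-truth cells
#'
#' Greedy mutual-nearest matching within a radius: each detection is
#' paired with the nearest unmatched true cell within \code{radiusUm}.
#'
#' @param cells a \linkS4class{CellSet} (or data.frame with x_um, y_um).
#' @param truth a \linkS4class{GroundTruthTissue}.
#' @param radiusUm matching radius (default 5 um).
#' @return list: \code{truth_idx} (row in truth per detection, NA if
#'   unmatched), \code{recall}, \code{precision}, \code{f1},
#'   \code{mean_dist_um}.
#' @export
matchToTruth <- function(cells, truth, radiusUm = 5) {
  tab <- if (is(cells, "CellSet")) cells@table else cells
  tc <- truth@cells
  nD <- nrow(tab); nT <- nrow(tc)
  truth_idx <- rep(NA_integer_, nD)
  if (nD && nT) {
    # grid-bucketed nearest neighbour
    cw <- radiusUm
    key <- function(x, y) paste(floor(x / cw), floor(y / cw))
    buckets <- split(seq_len(nT), key(tc$x_um, tc$y_um))
    taken <- logical(nT)
    dists <- rep(NA_real_, nD)
    ord <- seq_len(nD)
    for (q in ord) {
      bx <- floor(tab$x_um[q] / cw); by <- floor(tab$y_um[q] / cw)
      cand <- unlist(buckets[paste(rep(bx + (-1:1), each = 3), by + (-1:1))],
                     use.names = FALSE)
      cand <- cand[!is.na(cand)]
      if (!length(cand)) next
      dd <- sqrt((tc$x_um[cand] - tab$x_um[q])^2 +
                 (tc$y_um[cand] - tab$y_um[q])^2)
      ok <- which(dd <= radiusUm & !taken[cand])
      if (!length(ok)) next
      pick <- ok[which.min(dd[ok])]
      truth_idx[q] <- cand[pick]
      dists[q] <- dd[pick]
      taken[cand[pick]] <- TRUE
    }
    tp <- sum(!is.na(truth_idx))
    list(truth_idx = truth_idx,
         recall = tp / nT, precision = if (nD) tp / nD else NA,
         f1 = if (tp) 2 * tp / (nD + nT) else 0,
         mean_dist_um = mean(dists, na.rm = TRUE))
  } else {
    list(truth_idx = truth_idx, recall = if (nT) 0 else NA,
         precision = if (nD) 0 else NA, f1 = 0, mean_dist_um = NA)
  }
}

#' Run the full pipeline on one (synthetic) tissue section
#'
#' Simulate, detect, classify, build regions, quantify, map density - in
#' one deterministic pass. When \code{outputDir} is given, every artefact
#' (OME-TIFF image, ground-truth tables, cell/call CSVs, regions GeoJSON,
#' stats CSV, density TIFF) is written and listed in a JSON manifest with
#' content hashes, the configuration snapshot and per-stage timings.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outputDir directory for artefacts, or NULL for in-memory only.
#' @param writeImage include the (large) OME-TIFF in the outputs.
#' @return list: \code{truth}, \code{cells} (table only), \code{calls},
#'   \code{regions} (region table), \code{stats}, \code{wholeTissue},
#'   \code{density}, \code{detection} (match quality), \code{manifest}.
#' @export
runPipeline <- function(config, outputDir = NULL, writeImage = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- proc.time()[3]
  timings <- c()
  stage <- function(nm, expr) {
    s <- proc.time()[3]
    r <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)), call. = FALSE))
    timings[nm] <<- round(proc.time()[3] - s, 2)
    r
  }
  tissue <- config$tissue
  tissue@seed <- config$seed
  gen <- stage("simulate", generateTissue(tissue, render = TRUE))
  truth <- gen$truth; stack <- gen$stack
  cells <- stage("detect", detectCells(stack, config$detection))
  model <- stage("classifier", resolveClassifier(config, stack, cells, truth))
  calls <- stage("classify", classifyCells(cells, model))
  det <- matchToTruth(cells, truth)
  cellTab <- cells@table
  rm(cells); invisible(gc(FALSE))
  rs <- stage("regions", {
    seg <- segmentIslets(stack)
    idi <- Filter(function(i) i$label == "IDI", truth@islets)
    cmb <- combineIslets(seg, lapply(idi, `[[`, "poly"), stack@pixelSizeUm)
    r <- buildRegionSet(cmb$labels, cmb$classes, truth@tissueRect,
                        stack@pixelSizeUm, config$rings)
    r <- makePeriIslet(r)
    r <- makeRingSet(r)
    if (config$nExocrine > 0)
      r <- withSeed(childSeed(config$seed, 7),
                    tryCatch(sampleExocrine(r, config$nExocrine,
                                            config$exocrineSideUm),
                             error = function(e) { warning(conditionMessage(e)); r }))
    addTissueRegion(r)
  })
  if (!writeImage) rm(stack)
  gen$stack <- NULL; invisible(gc(FALSE))
  assign <- stage("assign", assignCells(cellTab, rs))
  stats <- stage("quantify", regionStats(assign, calls, rs))
  regionTab <- rs@table; exoTab <- rs@exocrine
  rsLight <- NULL
  if (!is.null(outputDir)) {
    # keep what GeoJSON export needs (islet outlines), drop the big fields
    rsLight <- rs
    rsLight@dist <- matrix(0, 0, 0)
    rsLight@owner <- matrix(0L, 0, 0)
  }
  rm(rs); invisible(gc(FALSE))
  rect <- truth@tissueRect
  wt <- wholeTissueStats(calls, (rect[2] - rect[1]) * (rect[4] - rect[3]))
  dm <- stage("density", densityMap(calls, rect, config$densityGridUm,
                                    config$densityBandwidthUm))

  manifest <- list(seed = config$seed, timings = as.list(timings),
                   n_cells_true = nrow(truth@cells),
                   n_cells_detected = nrow(cellTab),
                   detection_f1 = det$f1, files = list())
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    wf <- function(nm, writer) {
      p <- file.path(outputDir, nm)
      written <- writer(p)
      if (!is.character(written)) written <- p
      for (w in written)
        manifest$files[[basename(w)]] <<- list(path = w, md5 = fileHash(w))
      p
    }
    if (writeImage)
      wf("image.ome.tif", function(p) writeChannelStack(stack, p))
    wf("truth_cells.csv", function(p) utils::write.csv(truth@cells, p, row.names = FALSE))
    wf("truth_regions.geojson", function(p) writeTruthRegions(truth, p))
    wf("cells.csv", function(p) utils::write.csv(cellTab, p, row.names = FALSE))
    wf("calls.csv", function(p) utils::write.csv(calls, p, row.names = FALSE))
    wf("regions.geojson", function(p) writeRegionsGeoJSON(rsLight, p))
    wf("region_stats.csv", function(p) utils::write.csv(stats, p, row.names = FALSE))
    wf("whole_tissue.csv", function(p) utils::write.csv(wt, p, row.names = FALSE))
    wf("density.tif", function(p) writeDensityMap(dm, p))
    manifest$elapsed_s <- round(proc.time()[3] - t0, 2)
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(truth = truth, cells = cellTab, calls = calls,
       regions = regionTab, exocrine = exoTab, assignments = assign,
       stats = stats, wholeTissue = wt, density = dm, detection = det,
       manifest = manifest)
}

#' Per-islet observation table from one pipeline run
#'
#' Extracts the per-region observations the group analyses consume:
#' percentage of CD68+ cells per islet/peri/ring/exocrine region, the
#' activated-macrophage share (CD68+HLA-II+ of CD68+), and per-islet
#' beta-cell HLA-II percentages from the ground truth pairing.
#'
#' @param run result of \code{\link{runPipeline}}.
#' @return data.frame: \code{region_id, region_class, ring_index,
#'   parent_islet_id, n_cells, pct_cd68, pct_cd68_hla2_of_cd68}.
#' @export
regionObservations <- function(run) {
  st <- run$stats
  ring <- rep(NA_integer_, nrow(st))
  isRing <- grepl("^ring_", st$region_class)
  ring[isRing] <- as.integer(sub("^ring_", "", st$region_class[isRing]))
  ring[st$region_class %in% c("islet_ICI", "islet_IDI")] <- 0L
  data.frame(region_id = st$region_id, region_class = st$region_class,
             ring_index = ring, parent_islet_id = st$parent_islet_id,
             n_cells = st$n_cells, pct_cd68 = st$pct_cd68,
             dens_cd68 = st$dens_cd68,
             pct_cd68_hla2_of_cd68 = ifelse(st$n_cd68 > 0,
                                            100 * st$n_cd68_hla2 / st$n_cd68,
                                            NA_real_))
}

#' Simulate and analyse a multi-group experiment
#'
#' Generates \code{donorsPerGroup} tissue sections per disease-group
#' configuration (each donor gets a derived seed), runs the full pipeline
#' on every section, pools the per-region observations, and runs the group
#' statistics battery: whole-tissue comparison across groups (donor level),
#' peri-islet comparison (region level), the two-way group x ring analysis,
#' and per-islet co-expression correlations.
#'
#' @param groupConfigs named list of \linkS4class{TissueConfig} objects,
#'   one per group.
#' @param donorsPerGroup sections per group (study design: 5).
#' @param seed experiment seed.
#' @param pipelineArgs extra arguments to \code{\link{pipelineConfig}}.
#' @return list: \code{observations} (pooled region table with group and
#'   donor), \code{wholeTissue} (per donor), \code{stats} (test results;
#'   NULL with a message when fewer than two groups).
#' @export
runGroupExperiment <- function(groupConfigs, donorsPerGroup = 5, seed = 1,
                               pipelineArgs = list()) {
  stopifnot(length(groupConfigs) >= 1, !is.null(names(groupConfigs)))
  obs <- list(); wt <- list(); co <- list()
  for (gi in seq_along(groupConfigs)) {
    gname <- names(groupConfigs)[gi]
    for (d in seq_len(donorsPerGroup)) {
      cfgT <- groupConfigs[[gi]]
      cfgT@seed <- childSeed(seed, gi * 1000 + d)
      pc <- do.call(pipelineConfig, c(list(tissue = cfgT), pipelineArgs))
      run <- runPipeline(pc)
      ro <- regionObservations(run)
      ro$group <- gname; ro$donor <- sprintf("%s_%d", gname, d)
      obs[[length(obs) + 1]] <- ro
      w <- run$wholeTissue
      w$group <- gname; w$donor <- sprintf("%s_%d", gname, d)
      wt[[length(wt) + 1]] <- w
      co[[length(co) + 1]] <- isletCoexpressionObservations(run, gname)
    }
  }
  observations <- do.call(rbind, obs)
  wholeTissue <- do.call(rbind, wt)
  coex <- do.call(rbind, co)
  stats <- NULL
  if (length(groupConfigs) >= 2) {
    peri <- observations[observations$region_class == "peri_islet" &
                           is.finite(observations$pct_cd68), ]
    ringObs <- observations[is.finite(observations$ring_index) &
                              is.finite(observations$pct_cd68), ]
    stats <- list(
      whole_tissue_pct = tryCatch(
        compareGroups(wholeTissue$pct_cd68, wholeTissue$group),
        error = function(e) conditionMessage(e)),
      whole_tissue_density = tryCatch(
        compareGroups(wholeTissue$dens_cd68, wholeTissue$group),
        error = function(e) conditionMessage(e)),
      peri_pct = tryCatch(
        compareGroups(peri$pct_cd68, peri$group),
        error = function(e) conditionMessage(e)),
      ring_profile = tryCatch(
        twoWayRingAnova(data.frame(value = ringObs$pct_cd68,
                                   group = ringObs$group,
                                   ring = ringObs$ring_index)),
        error = function(e) conditionMessage(e)))
  } else message("single group: statistics stage skipped")
  corr <- NULL
  if (!is.null(coex) && nrow(coex) >= 4) {
    ok <- is.finite(coex$pct_cd68_hla2) & is.finite(coex$pct_beta_hla2)
    if (sum(ok) >= 4)
      corr <- tryCatch(spearmanWithCI(coex$pct_cd68_hla2[ok],
                                      coex$pct_beta_hla2[ok]),
                       error = function(e) conditionMessage(e))
  }
  list(observations = observations, wholeTissue = wholeTissue,
       coexpression = coex, stats = stats, correlation = corr)
}

# per-islet co-expression observations (islet + peri-islet pooled), using
# the measured calls; beta-cell HLA-II share uses measured insulin+ cells
isletCoexpressionObservations <- function(run, gname) {
  st <- run$stats
  isl <- st[st$region_class %in% c("islet_ICI", "islet_IDI"), ]
  if (!nrow(isl)) return(NULL)
  peri <- st[st$region_class == "peri_islet", ]
  m <- match(isl$region_id, peri$parent_islet_id)
  nC <- isl$n_cells + ifelse(is.na(m), 0, peri$n_cells[m])
  nCd <- isl$n_cd68 + ifelse(is.na(m), 0, peri$n_cd68[m])
  nCdH <- isl$n_cd68_hla2 + ifelse(is.na(m), 0, peri$n_cd68_hla2[m])
  data.frame(group = gname, islet_id = isl$region_id,
             n_cells = nC,
             pct_cd68 = ifelse(nC > 0, 100 * nCd / nC, NA_real_),
             pct_cd68_hla2 = ifelse(nC > 0, 100 * nCdH / nC, NA_real_),
             pct_beta_hla2 = ifelse(isl$n_insulin > 0,
                                    100 * isl$n_insulin_hla2 / isl$n_insulin,
                                    NA_real_))
}

#' Write a tissue configuration as YAML
#'
#' @param config a \linkS4class{TissueConfig}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTissueConfigYaml <- function(config, path) {
  sl <- methods::slotNames("TissueConfig")
  lst <- lapply(sl, function(s) {
    v <- methods::slot(config, s)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  })
  names(lst) <- sl
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a tissue configuration from YAML
#'
#' Round-trips the output of \code{\link{writeTissueConfigYaml}} to an
#' equivalent \linkS4class{TissueConfig}.
#'
#' @param path YAML file.
#' @return a \linkS4class{TissueConfig}.
#' @export
readTissueConfigYaml <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$zoneMacrophageFraction <- unlist(lst$zoneMacrophageFraction)
  lst$imageSizePx <- as.integer(unlist(lst$imageSizePx))
  for (nm in c("isletRadiusUmRange", "nucleusRadiusUmRange"))
    lst[[nm]] <- as.numeric(unlist(lst[[nm]]))
  do.call(tissueConfig, lst)
}
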