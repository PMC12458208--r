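# lazily built, memoised fixtures shared across test files

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# a 0.6 x 0.6 mm rendered section with 3 ICIs (~3,400 cells)
smallRun <- function() fixture("smallRun", {
  cfg <- tissueConfig(imageSizePx = c(1846, 1846), nIslets = 3,
                      isletRadiusUmRange = c(30, 45), seed = 42)
  gen <- generateTissue(cfg)
  cells <- detectCells(gen$stack)
  floors <- calibrateChannelFloors(gen$stack, cells)
  model <- midpointClassifier(cfg, floors)
  calls <- classifyCells(cells, model)
  seg <- segmentIslets(gen$stack)
  rs <- buildRegionSet(seg$labels, rep("islet_ICI", nrow(seg$table)),
                       gen$truth@tissueRect, 0.325)
  rs <- makeRingSet(makePeriIslet(rs))
  rs <- addTissueRegion(rs)
  asg <- assignCells(cells, rs)
  list(cfg = cfg, gen = gen, cells = cells, model = model, calls = calls,
       seg = seg, rs = rs, asg = asg,
       stats = regionStats(asg, calls, rs))
})

# raster disc mask helper (um units, 0.325 um pixels)
discMask <- function(r0, cx, cy, npx, px = 0.325) {
  xs <- (seq_len(npx) - 1) * px
  m <- outer((xs - cy)^2, (xs - cx)^2, "+") <= r0^2
  lab <- matrix(0L, npx, npx)
  lab[m] <- 1L
  lab
}

# render a bare DAPI stack with given nucleus centres/radii (um)
nucleusStack <- function(cx, cy, r, npx = 400, value = 185, px = 0.325) {
  img <- matrix(0, npx, npx)
  .c_render <- get(".c_render_blobs", asNamespace("isletrings"))
  .c_render(img, cx / px + 1, cy / px + 1, r / px, r / px,
            rep(0, length(cx)), rep(value, length(cx)), 0.8 / px)
  ch <- round(img + 8)
  storage.mode(ch) <- "integer"
  blank <- matrix(5L, npx, npx)
  channelStack(list(DAPI = ch, INS = blank, CD68 = blank, HLAII = blank), px)
}
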