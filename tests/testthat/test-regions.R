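px <- 0.325

circleRegionSet <- function(r0 = 100, extentUm = 900) {
  npx <- ceiling(extentUm / px)
  lab <- discMask(r0, extentUm / 2, extentUm / 2, npx)
  rs <- buildRegionSet(lab, "islet_ICI", c(0, extentUm, 0, extentUm), px)
  makeRingSet(makePeriIslet(rs))
}

test_that("peri-islet and ring areas match the analytic annuli", {
  rs <- circleRegionSet(100)
  tab <- rs@table
  peri <- tab$area_um2[tab$region_class == "peri_islet"]
  expect_lt(abs(peri / (pi * (110^2 - 100^2)) - 1), 0.01)
  for (k in c(1, 8)) {
    a <- tab$area_um2[tab$region_class == paste0("ring_", k)]
    e <- pi * ((100 + 25 * k)^2 - (100 + 25 * (k - 1))^2)
    expect_lt(abs(a / e - 1), 0.01)
  }
  # rings telescope to the full 200 um collar
  sumr <- sum(tab$area_um2[grepl("^ring_", tab$region_class)])
  expect_lt(abs(sumr / (pi * (300^2 - 100^2)) - 1), 0.01)
  # peri-islet width -> 0 limit: area -> 0
  rs2 <- makePeriIslet(buildRegionSet(discMask(50, 200, 200, 1230),
                                      "islet_ICI", c(0, 400, 0, 400), px),
                       widthUm = 0.5)
  expect_lt(rs2@table$area_um2[rs2@table$region_class == "peri_islet"],
            0.05 * pi * (60^2 - 50^2))
})

test_that("neighbouring islet collars split on the equidistant line", {
  npx <- 2154  # 700 um
  lab <- discMask(50, 200, 350, npx) + 2L * discMask(50, 312, 350, npx)
  storage.mode(lab) <- "integer"
  rs <- makeRingSet(makePeriIslet(
    buildRegionSet(lab, c("islet_ICI", "islet_ICI"), c(0, 700, 0, 700), px)))
  tab <- rs@table
  peri <- tab$area_um2[tab$region_class == "peri_islet"]
  # boundaries 12 um apart: collars clipped, so below 2 free annuli
  expect_lt(sum(peri), 2 * pi * (60^2 - 50^2))
  expect_gt(min(peri), 0.5 * pi * (60^2 - 50^2))
  # ownership frontier = vertical midline (equidistant from both boundaries)
  own <- rs@owner; d <- rs@dist
  mid <- isletrings:::umToIdx(256, px)
  collar <- lab == 0L & d <= 200
  left <- collar & col(own) <= (mid - 2)
  right <- collar & col(own) >= (mid + 2)
  expect_true(all(own[left] == 1L))
  expect_true(all(own[right] == 2L))
  # ring families of the two islets are pairwise disjoint by construction:
  # every collar pixel carries exactly one (owner, band) pair
  expect_true(all(own[collar] %in% 1:2))
})

test_that("a blank insulin channel yields no islets", {
  seg <- segmentIslets(matrix(0L, 500, 500), pixelSizeUm = px)
  expect_equal(nrow(seg$table), 0)
})

test_that("rendered ICIs are segmented with high overlap", {
  run <- smallRun()
  tm <- trueIsletMask(run$gen$truth)
  seg <- run$seg
  expect_equal(nrow(seg$table), nrow(run$gen$truth@isletTable))
  for (id in seq_len(max(tm))) {
    tmid <- tm == id
    ov <- table(seg$labels[tmid]); ov <- ov[names(ov) != "0"]
    expect_gt(length(ov), 0)
    sid <- as.integer(names(ov)[which.max(ov)])
    s <- seg$labels == sid
    expect_gte(sum(tmid & s) / sum(tmid | s), 0.90)
  }
})

test_that("IDI polygons round-trip through GeoJSON vertex-exact", {
  cfg <- tissueConfig(imageSizePx = c(1500, 1500), nIslets = 2,
                      iciFraction = 0, seed = 13)
  tt <- generateTissue(cfg, render = FALSE)
  path <- tempfile(fileext = ".geojson")
  writeTruthRegions(tt$truth, path)
  polys <- loadIdiRegions(path)
  expect_length(polys, 2)
  for (q in 1:2)
    expect_equal(unname(polys[[q]]), unname(tt$truth@islets[[q]]$poly),
                 tolerance = 1e-9)
  # empty FeatureCollection -> empty list
  jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                       path, auto_unbox = TRUE)
  expect_length(loadIdiRegions(path), 0)
})

test_that("an IDI overlapping an ICI is rejected with both ids", {
  seg <- list(labels = discMask(30, 100, 100, 616),
              table = data.frame(islet_id = 1L, area_um2 = pi * 900))
  idi <- cbind(x = c(90, 150, 150, 90), y = c(90, 90, 150, 150))
  expect_error(combineIslets(seg, list(idi), px), "overlaps islet")
})

test_that("exocrine sampling is disjoint, buffered, and seeded", {
  # geometry level on a 10 x 10 mm tissue with 30 polygonal islets
  cfg <- tissueConfig(imageSizePx = c(31385, 31385), nIslets = 30,
                      isletRadiusUmRange = c(40, 80), seed = 3)
  isl <- withSeed(5, sampleIsletPolygons(cfg))
  bp <- do.call(rbind, lapply(isl, `[[`, "poly"))
  inside <- function(x, y) any(vapply(isl, function(i)
    isletrings:::pointsInPolygon(cbind(x, y), i$poly), logical(1)))
  rect <- c(100, 10100, 100, 10100)
  sq1 <- withSeed(7, sampleExocrineSquares(rect, bp, inside, 15, 500, 10))
  sq2 <- withSeed(7, sampleExocrineSquares(rect, bp, inside, 15, 500, 10))
  expect_identical(sq1, sq2)
  expect_equal(nrow(sq1), 15)
  # brute-force pairwise disjointness and islet-buffer clearance
  for (a in seq_len(15)) {
    for (b in seq_len(a - 1))
      expect_true(abs(sq1$x0_um[a] - sq1$x0_um[b]) >= 500 ||
                    abs(sq1$y0_um[a] - sq1$y0_um[b]) >= 500)
    nearX <- pmin(pmax(bp[, 1], sq1$x0_um[a]), sq1$x0_um[a] + 500)
    nearY <- pmin(pmax(bp[, 2], sq1$y0_um[a]), sq1$y0_um[a] + 500)
    expect_gt(min(sqrt((bp[, 1] - nearX)^2 + (bp[, 2] - nearY)^2)), 10 - 1e-9)
    expect_true(sq1$x0_um[a] >= rect[1] && sq1$x0_um[a] + 500 <= rect[2])
  }
  # n = 0 -> empty; infeasible -> error reporting achieved count
  rs <- circleRegionSet(50, 400)
  expect_equal(nrow(sampleExocrine(rs, 0)@exocrine), 0)
  expect_error(withSeed(1, sampleExocrineSquares(c(0, 1200, 0, 1200),
                                                 bp[0, , drop = FALSE], NULL,
                                                 10, 500, 10,
                                                 maxAttempts = 200)),
               "placement infeasible")
})

test_that("cell assignment follows the closed-boundary convention", {
  # hand-built geometry: one islet, dist field set directly
  lab <- matrix(0L, 10, 10); lab[5, 5] <- 1L
  rs <- buildRegionSet(lab, "islet_ICI", c(0, 3.25, 0, 3.25), px)
  rs <- makeRingSet(makePeriIslet(rs))
  # a centroid whose pixel distance is exactly 25 um joins ring 1, not 2
  rs@dist[3, 3] <- 25; rs@owner[3, 3] <- 1L
  rs@dist[3, 4] <- 25 + 1e-3; rs@owner[3, 4] <- 1L
  cells <- data.frame(cell_id = 1:2,
                      x_um = isletrings:::idxToUm(c(3, 4), px),
                      y_um = isletrings:::idxToUm(c(3, 3), px))
  asg <- assignCells(cells, rs)
  expect_equal(asg$region_class[asg$cell_id == 1 &
                                  grepl("ring", asg$region_class)], "ring_1")
  expect_equal(asg$region_class[asg$cell_id == 2 &
                                  grepl("ring", asg$region_class)], "ring_2")
})

test_that("assignment equals brute force over every cell-region pair", {
  run <- smallRun()
  rs <- run$rs
  cells <- run$cells@table
  n <- min(nrow(cells), 1000)
  cells <- cells[seq_len(n), ]
  asg <- assignCells(cells, rs)
  # independent O(n x m) membership: per-cell scalar lookups per region
  d <- dim(rs@isletLabels)
  rect <- rs@tissueRect
  brute <- list()
  for (q in seq_len(n)) {
    x <- cells$x_um[q]; y <- cells$y_um[q]
    i <- isletrings:::umToIdx(y, px); j <- isletrings:::umToIdx(x, px)
    inT <- x >= rect[1] && x <= rect[2] && y >= rect[3] && y <= rect[4]
    for (rr in seq_len(nrow(rs@table))) {
      row <- rs@table[rr, ]
      member <- FALSE
      if (inT) {
        if (row$region_class %in% c("islet_ICI", "islet_IDI"))
          member <- rs@isletLabels[i, j] == row$region_id
        else if (row$region_class == "peri_islet")
          member <- rs@isletLabels[i, j] == 0L &&
            rs@owner[i, j] == row$parent_islet_id &&
            rs@dist[i, j] > 0 && rs@dist[i, j] <= 10
        else if (grepl("^ring_", row$region_class))
          member <- rs@isletLabels[i, j] == 0L &&
            rs@owner[i, j] == row$parent_islet_id &&
            rs@dist[i, j] > (row$k - 1) * 25 && rs@dist[i, j] <= row$k * 25
        else if (row$region_class == "tissue") member <- TRUE
      }
      if (member)
        brute[[length(brute) + 1]] <- data.frame(cell_id = cells$cell_id[q],
                                                 region_id = row$region_id)
    }
  }
  brute <- do.call(rbind, brute)
  got <- asg[order(asg$cell_id, asg$region_id), c("cell_id", "region_id")]
  want <- brute[order(brute$cell_id, brute$region_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("assignment is invariant to region table order", {
  run <- smallRun()
  rs2 <- run$rs
  set.seed(99)
  rs2@table <- rs2@table[sample(nrow(rs2@table)), ]
  a1 <- assignCells(run$cells, run$rs)
  a2 <- assignCells(run$cells, rs2)
  key <- function(a) paste(a$cell_id, a$region_id)
  expect_setequal(key(a1), key(a2))
  # a cell outside all regions gets none
  far <- data.frame(cell_id = 1L, x_um = -50, y_um = -50)
  expect_equal(nrow(assignCells(far, run$rs)), 0)
})
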