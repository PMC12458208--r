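test_that("a blank nuclear channel yields no detections", {
  blank <- matrix(0L, 200, 200)
  st <- channelStack(list(DAPI = blank, INS = blank, CD68 = blank,
                          HLAII = blank), 0.325)
  expect_equal(nrow(detectNuclei(st)@table), 0)
})

test_that("a missing nuclear channel is a configuration error", {
  st <- channelStack(list(INS = matrix(0L, 50, 50)), 0.325)
  expect_error(detectNuclei(st), "DAPI")
})

test_that("sparse nuclei are each recovered within 1 um", {
  cfg <- tissueConfig(imageSizePx = c(2200, 2200), nIslets = 0,
                      cellDensityPerMm2 = 130, minSpacingUm = 10.5, seed = 17)
  gen <- generateTissue(cfg)
  nTrue <- nrow(gen$truth@cells)
  expect_gt(nTrue, 30)
  cells <- detectNuclei(gen$stack)
  expect_equal(nrow(cells@table), nTrue)
  mt <- matchToTruth(cells, gen$truth, radiusUm = 5)
  expect_equal(mt$recall, 1)
  dd <- sqrt((cells@table$x_um - gen$truth@cells$x_um[mt$truth_idx])^2 +
               (cells@table$y_um - gen$truth@cells$y_um[mt$truth_idx])^2)
  expect_lt(max(dd), 1)
})

test_that("watershed splitting separates a touching pair", {
  st <- nucleusStack(cx = c(45, 51), cy = c(50, 50), r = c(3.2, 3.2))
  on <- detectNuclei(st, detectionParams(watershedSplit = TRUE))
  off <- detectNuclei(st, detectionParams(watershedSplit = FALSE))
  expect_equal(nrow(on@table), 2)
  expect_equal(nrow(off@table), 1)
})

test_that("zero expansion reproduces the nucleus compartment", {
  st <- nucleusStack(cx = 50, cy = 50, r = 3)
  cells <- expandCells(detectNuclei(st), 0)
  expect_identical(cells@cellLabels, cells@nucleusLabels)
  expect_equal(cells@table$cell_area_um2, cells@table$nucleus_area_um2)
})

test_that("negative expansion is rejected", {
  st <- nucleusStack(cx = 50, cy = 50, r = 3)
  expect_error(expandCells(detectNuclei(st), -1), "non-negative")
})

test_that("disc dilation matches the analytic area", {
  # nucleus = perfect disc r = 4 um, expansion 5 um -> area ~ pi * 9^2
  lab <- discMask(4, 50, 50, 308)
  cs <- new("CellSet",
            table = data.frame(cell_id = 1L, x_um = 50, y_um = 50,
                               nucleus_area_um2 = sum(lab > 0) * 0.325^2),
            nucleusLabels = lab, cellLabels = matrix(0L, 0, 0),
            pixelSizeUm = 0.325)
  cs <- expandCells(cs, 5)
  expect_lt(abs(cs@table$cell_area_um2 / (pi * 81) - 1), 0.02)
})

test_that("expansion clipping splits territory at the equidistant line", {
  px <- 0.325
  lab <- discMask(3, 46, 50, 308) + 2L * discMask(3, 54, 50, 308)
  storage.mode(lab) <- "integer"
  cs <- new("CellSet",
            table = data.frame(cell_id = 1:2, x_um = c(46, 54), y_um = 50,
                               nucleus_area_um2 = rep(pi * 9, 2)),
            nucleusLabels = lab, cellLabels = matrix(0L, 0, 0),
            pixelSizeUm = px)
  cs <- expandCells(cs, 10)
  cl <- cs@cellLabels
  # interiors disjoint by construction; areas clipped below the free disc
  expect_lt(sum(cs@table$cell_area_um2), 2 * pi * 13^2)
  expect_gt(min(cs@table$cell_area_um2), pi * 13^2 / 2)
  # frontier is the vertical midline at x = 50 um
  mid <- isletrings:::umToIdx(50, px)
  expect_true(all(cl[, seq_len(mid - 2)] != 2L))
  expect_true(all(cl[, (mid + 2):ncol(cl)] != 1L))
  # both cells retain their nuclei
  expect_true(all(cl[lab == 1L] == 1L))
  expect_true(all(cl[lab == 2L] == 2L))
})

test_that("feature means are exact against brute-force accumulation", {
  st <- nucleusStack(cx = c(20, 50, 80), cy = c(30, 60, 40), r = c(2.5, 3, 3.4),
                     npx = 350)
  set.seed(31)
  noisy <- matrix(sample.int(256, 350 * 350, TRUE) - 1L, 350, 350)
  st@channels$CD68 <- noisy
  cells <- measureFeatures(expandCells(detectNuclei(st), 5), st)
  for (id in cells@table$cell_id) {
    nucPx <- cells@nucleusLabels == id
    cellPx <- cells@cellLabels == id
    expect_equal(cells@table$CD68_nucleus_mean[id], mean(noisy[nucPx]),
                 tolerance = 1e-9)
    expect_equal(cells@table$CD68_cell_mean[id], mean(noisy[cellPx]),
                 tolerance = 1e-9)
    expect_equal(cells@table$CD68_cytoplasm_mean[id],
                 mean(noisy[cellPx & !nucPx]), tolerance = 1e-9)
  }
})

test_that("constant channels give constant feature means", {
  st <- nucleusStack(cx = 50, cy = 50, r = 3)
  st@channels$HLAII <- matrix(100L, 400, 400)
  cells <- measureFeatures(expandCells(detectNuclei(st), 5), st)
  expect_equal(cells@table$HLAII_nucleus_mean, 100)
  expect_equal(cells@table$HLAII_cell_mean, 100)
  expect_equal(cells@table$HLAII_cytoplasm_mean, 100)
})

test_that("raising the threshold never increases the detection count", {
  run <- smallRun()
  counts <- vapply(c(20, 60, 100, 140, 180), function(thr)
    nrow(detectNuclei(run$gen$stack,
                      detectionParams(nucleusThreshold = thr))@table),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cell compartments stay disjoint and conserve the count", {
  run <- smallRun()
  cells <- run$cells
  expect_equal(nrow(cells@table), max(cells@nucleusLabels))
  counts <- isletrings:::.c_label_counts(cells@cellLabels, nrow(cells@table))
  expect_true(all(counts > 0))
  expect_lte(sum(counts), length(cells@cellLabels))
  # nucleus pixels keep their own cell's label
  sub <- cells@nucleusLabels > 0L
  expect_true(all(cells@cellLabels[sub] == cells@nucleusLabels[sub]))
})
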