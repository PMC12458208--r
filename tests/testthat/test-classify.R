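test_that("channel floors reflect the background percentile", {
  zeroCh <- matrix(0L, 300, 300)
  st0 <- channelStack(list(DAPI = zeroCh, INS = zeroCh, CD68 = zeroCh,
                           HLAII = zeroCh), 0.325)
  expect_equal(unname(calibrateChannelFloors(st0)["CD68"]), 0)

  # background ~ N(10, 2) clipped to [0, 255]: 99.5th pct in [12, 22]
  set.seed(21)
  bg <- matrix(pmax(0L, as.integer(round(rnorm(300 * 300, 10, 2)))), 300, 300)
  st <- channelStack(list(DAPI = zeroCh, INS = zeroCh, CD68 = bg,
                          HLAII = zeroCh), 0.325)
  fl <- calibrateChannelFloors(st)
  expect_gte(fl["CD68"], 12); expect_lte(fl["CD68"], 22)

  # adding signal inside (dilated) nuclei leaves the floor unchanged
  lab <- discMask(4, 48.75, 48.75, 300)
  cells <- new("CellSet",
               table = data.frame(cell_id = 1L, x_um = 48.75, y_um = 48.75,
                                  nucleus_area_um2 = sum(lab > 0) * 0.325^2),
               nucleusLabels = lab, cellLabels = matrix(0L, 0, 0),
               pixelSizeUm = 0.325)
  fl1 <- calibrateChannelFloors(st, cells)
  st2 <- st
  ch <- st2@channels$CD68; ch[lab > 0L] <- 250L
  st2@channels$CD68 <- ch
  fl2 <- calibrateChannelFloors(st2, cells)
  expect_equal(fl1["CD68"], fl2["CD68"])
})

featureFrame <- function(n, seed = 1) {
  set.seed(seed)
  df <- data.frame(cell_id = seq_len(n), x_um = runif(n), y_um = runif(n))
  for (chn in c("DAPI", "INS", "CD68", "HLAII"))
    for (cp in c("nucleus", "cell", "cytoplasm"))
      df[[paste0(chn, "_", cp, "_mean")]] <- runif(n, 0, 255)
  df
}

test_that("the forest learns a separable rule perfectly", {
  df <- featureFrame(400, seed = 2)
  labels <- df$CD68_cell_mean > 100
  train <- seq_len(200); test <- 201:400
  m <- trainMarkerClassifier(df[train, ], labels[train], "CD68", seed = 5)
  model <- classifierModel(
    ins = list(type = "threshold", channel = "INS", compartment = "cell",
               threshold = 100),
    cd68 = m,
    hla2 = list(type = "threshold", channel = "HLAII", compartment = "cell",
                threshold = 100))
  calls <- classifyCells(df[test, ], model)
  expect_equal(mean(calls$cd68_pos == labels[test]), 1)
})

test_that("uninformative labels give chance-level accuracy", {
  df <- featureFrame(400, seed = 3)
  set.seed(4)
  labels <- sample(c(TRUE, FALSE), 400, TRUE)
  m <- trainMarkerClassifier(df[1:200, ], labels[1:200], "CD68", seed = 6)
  model <- classifierModel(
    ins = list(type = "threshold", channel = "INS", compartment = "cell",
               threshold = 300 / 2),
    cd68 = m,
    hla2 = list(type = "threshold", channel = "HLAII", compartment = "cell",
                threshold = 300 / 2))
  acc <- mean(classifyCells(df[201:400, ], model)$cd68_pos == labels[201:400])
  expect_gte(acc, 0.35); expect_lte(acc, 0.65)
})

test_that("forest training is deterministic given the seed", {
  df <- featureFrame(200, seed = 7)
  labels <- df$HLAII_cell_mean > 120
  m1 <- trainMarkerClassifier(df, labels, "HLAII", seed = 9)
  m2 <- trainMarkerClassifier(df, labels, "HLAII", seed = 9)
  p1 <- predict(m1$fit, df[m1$features])
  p2 <- predict(m2$fit, df[m2$features])
  expect_identical(p1, p2)
})

test_that("single-class training sets fail naming the missing class", {
  df <- featureFrame(100, seed = 8)
  expect_error(trainMarkerClassifier(df, rep(TRUE, 100), "CD68"),
               "no negative examples")
  expect_error(trainMarkerClassifier(df, rep(FALSE, 100), "INS"),
               "no positive examples")
})

test_that("threshold calls are strict and composites are conjunctions", {
  df <- featureFrame(3, seed = 10)
  df$CD68_cell_mean <- c(49, 50, 51)
  df$HLAII_cell_mean <- c(200, 200, 10)
  df$INS_cell_mean <- c(10, 10, 10)
  model <- thresholdClassifier(insThreshold = 100, cd68Threshold = 50,
                               hla2Threshold = 100)
  calls <- classifyCells(df, model)
  expect_equal(calls$cd68_pos, c(FALSE, FALSE, TRUE))
  expect_equal(calls$cd68_hla2_pos, calls$cd68_pos & calls$hla2_pos)
  expect_equal(calls$insulin_hla2_pos, calls$insulin_pos & calls$hla2_pos)
  expect_false(any(calls$cd68_hla2_pos[!calls$hla2_pos]))
})

test_that("composite subset law holds on pipeline output", {
  calls <- smallRun()$calls
  expect_true(all(calls$cd68_hla2_pos <= calls$cd68_pos))
  expect_true(all(calls$cd68_hla2_pos <= calls$hla2_pos))
  expect_true(all(calls$insulin_hla2_pos <= calls$insulin_pos))
})

test_that("raising a threshold never increases the positive count", {
  run <- smallRun()
  nPos <- vapply(c(40, 80, 120, 160, 200), function(thr) {
    m <- thresholdClassifier(insThreshold = 110, cd68Threshold = thr,
                             hla2Threshold = 99)
    sum(classifyCells(run$cells, m)$cd68_pos)
  }, numeric(1))
  expect_true(all(diff(nPos) <= 0))
})

test_that("a missing feature column is reported with the cell id", {
  df <- featureFrame(5, seed = 11)
  df$CD68_cell_mean[3] <- NA
  model <- thresholdClassifier(100, 100, 100)
  expect_error(classifyCells(df, model), "cell_id")
})

test_that("classification against ground truth is near-perfect", {
  run <- smallRun()
  mt <- matchToTruth(run$cells, run$gen$truth)
  ok <- !is.na(mt$truth_idx)
  tc <- run$gen$truth@cells[mt$truth_idx[ok], ]
  cc <- run$calls[ok, ]
  expect_gte(mean(cc$insulin_pos == tc$insulin_pos), 0.98)
  expect_gte(mean(cc$cd68_pos == tc$cd68_pos), 0.98)
  expect_gte(mean(cc$hla2_pos == tc$hla2_pos), 0.98)
})
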