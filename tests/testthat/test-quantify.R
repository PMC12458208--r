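emptyMaskRS <- function(table) {
  new("RegionSet", table = table, isletLabels = matrix(0L, 1, 1),
      dist = matrix(Inf, 1, 1), owner = matrix(0L, 1, 1),
      ringSpec = list(periWidthUm = 10, nRings = 8L, ringWidthUm = 25),
      exocrine = data.frame(region_id = integer(0), x0_um = numeric(0),
                            y0_um = numeric(0), side_um = numeric(0)),
      tissueRect = c(0, 1, 0, 1), pixelSizeUm = 0.325)
}

mkCalls <- function(n, cd68 = logical(n), hla2 = logical(n),
                    ins = logical(n)) {
  data.frame(cell_id = seq_len(n), x_um = runif(n), y_um = runif(n),
             insulin_pos = ins, cd68_pos = cd68, hla2_pos = hla2,
             cd68_hla2_pos = cd68 & hla2, insulin_hla2_pos = ins & hla2)
}

test_that("region statistics compute the published formulas", {
  tab <- data.frame(region_id = 1:2, region_class = c("islet_ICI", "exocrine"),
                    parent_islet_id = NA_integer_, k = NA_integer_,
                    area_um2 = c(0.01e6, 0.5e6))
  rs <- emptyMaskRS(tab)
  set.seed(1)
  calls <- mkCalls(10, cd68 = rep(c(TRUE, FALSE), c(3, 7)))
  asg <- data.frame(cell_id = 1:10, region_id = 1L, region_class = "islet_ICI")
  st <- regionStats(asg, calls, rs)
  expect_equal(st$pct_cd68[1], 30)
  expect_equal(st$dens_cd68[1], 300)   # 3 cells in 0.01 mm2
  # the empty region: counts 0, pct missing, densities 0
  expect_equal(st$n_cells[2], 0)
  expect_true(is.na(st$pct_cd68[2]))
  expect_equal(st$dens_cd68[2], 0)
})

test_that("an unknown cell id in the assignment is an error", {
  tab <- data.frame(region_id = 1L, region_class = "islet_ICI",
                    parent_islet_id = NA_integer_, k = NA_integer_,
                    area_um2 = 1e4)
  rs <- emptyMaskRS(tab)
  calls <- mkCalls(3)
  asg <- data.frame(cell_id = c(1, 99), region_id = 1L,
                    region_class = "islet_ICI")
  expect_error(regionStats(asg, calls, rs), "99")
})

test_that("region stats equal a brute-force recount", {
  run <- smallRun()
  st <- run$stats
  for (rid in sample(st$region_id, 12)) {
    ids <- run$asg$cell_id[run$asg$region_id == rid]
    sub <- run$calls[run$calls$cell_id %in% ids, ]
    row <- st[st$region_id == rid, ]
    expect_equal(row$n_cells, nrow(sub))
    expect_equal(row$n_cd68, sum(sub$cd68_pos))
    expect_equal(row$n_cd68_hla2, sum(sub$cd68_hla2_pos))
    if (nrow(sub) > 0)
      expect_equal(row$pct_cd68, 100 * mean(sub$cd68_pos))
  }
  # invariants on every row
  pcts <- as.matrix(st[grepl("^pct_", names(st))])
  expect_true(all(is.na(pcts) | (pcts >= 0 & pcts <= 100)))
  expect_true(all(st$n_cd68_hla2 <= pmin(st$n_cd68, st$n_hla2)))
  expect_true(all(as.matrix(st[grepl("^dens_", names(st))]) >= 0))
})

test_that("ring-family counts conserve the collar total", {
  run <- smallRun()
  st <- run$stats
  fam <- st[st$region_class %in% c("islet_ICI", "islet_IDI") |
              grepl("^ring_", st$region_class), ]
  cells <- run$cells@table
  rs <- run$rs
  i <- isletrings:::umToIdx(cells$y_um, 0.325)
  j <- isletrings:::umToIdx(cells$x_um, 0.325)
  ii <- cbind(i, j)
  rect <- rs@tissueRect
  inT <- cells$x_um >= rect[1] & cells$x_um <= rect[2] &
    cells$y_um >= rect[3] & cells$y_um <= rect[4]
  inFam <- inT & (rs@isletLabels[ii] > 0L | rs@dist[ii] <= 200)
  expect_equal(sum(fam$n_cells), sum(inFam))
})

test_that("whole-tissue stats cover the degenerate and binomial cases", {
  wt0 <- wholeTissueStats(mkCalls(0), 2e6)
  expect_equal(wt0$n_cells, 0)
  expect_true(is.na(wt0$pct_cd68))
  expect_equal(wt0$dens_cd68, 0)

  cl <- generateTissue(tissueConfig(imageSizePx = c(5077, 5077), nIslets = 0,
    zoneMacrophageFraction = uniformZoneFractions(0.086), seed = 14),
    render = FALSE)$truth@cells
  calls <- data.frame(cell_id = cl$cell_id, x_um = cl$x_um, y_um = cl$y_um,
                      insulin_pos = cl$insulin_pos, cd68_pos = cl$cd68_pos,
                      hla2_pos = cl$hla2_pos,
                      cd68_hla2_pos = cl$cd68_pos & cl$hla2_pos,
                      insulin_hla2_pos = cl$insulin_pos & cl$hla2_pos)
  wt <- wholeTissueStats(calls, 1450^2)
  band <- 100 * qbinom(c(0.005, 0.995), nrow(calls), 0.086) / nrow(calls)
  expect_gte(wt$pct_cd68, band[1]); expect_lte(wt$pct_cd68, band[2])
  expect_lte(wt$pct_cd68_hla2, wt$pct_cd68)
})

test_that("density maps bin, smooth, and conserve mass", {
  rect <- c(0, 1000, 0, 1000)
  # no CD68+ cells -> all-zero map
  dm0 <- densityMap(mkCalls(5), rect, 50, 0)
  expect_true(all(dm0$grid == 0))
  # one cell, zero bandwidth: single bin at 1 / (spacing^2 / 1e6)
  one <- mkCalls(1, cd68 = TRUE)
  one$x_um <- 325; one$y_um <- 760
  dm1 <- densityMap(one, rect, 50, 0)
  expect_equal(sum(dm1$grid > 0), 1)
  expect_equal(max(dm1$grid), 1 / (50^2 / 1e6))
  # mass conservation at zero bandwidth
  set.seed(2)
  many <- mkCalls(400, cd68 = runif(400) < 0.5)
  many$x_um <- runif(400, 0, 1000); many$y_um <- runif(400, 0, 1000)
  dm <- densityMap(many, rect, 50, 0)
  expect_equal(sum(dm$grid) * 50^2 / 1e6, sum(many$cd68_pos))
  # uniform 300/mm2 field smoothed at 100 um: interior mean within 5%
  set.seed(3)
  n <- rpois(1, 300 * 16)  # 4 x 4 mm
  u <- mkCalls(n, cd68 = rep(TRUE, n))
  u$x_um <- runif(n, 0, 4000); u$y_um <- runif(n, 0, 4000)
  dmu <- densityMap(u, c(0, 4000, 0, 4000), 50, 100)
  interior <- dmu$grid[16:65, 16:65]
  expect_lt(abs(mean(interior) / 300 - 1), 0.05)
})
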