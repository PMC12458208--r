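.markerCols <- c(insulin = "insulin_pos", cd68 = "cd68_pos",
                 hla2 = "hla2_pos", cd68_hla2 = "cd68_hla2_pos",
                 insulin_hla2 = "insulin_hla2_pos")

#' Per-region counts, percentages and densities
#'
#' For each region: its area, total cell count, and for every marker and
#' composite the positive count, the percentage of cells positive (0-100;
#' missing when the region holds no cells) and the density per mm2
#' (1 mm2 = 1e6 um2). Counting is exact set arithmetic over the
#' assignment table.
#'
#' @param assignments data.frame from \code{\link{assignCells}}.
#' @param calls data.frame from \code{\link{classifyCells}}.
#' @param rs a \linkS4class{RegionSet} (or its region table).
#' @return data.frame, one row per region, with \code{n_cells},
#'   \code{n_<marker>}, \code{pct_<marker>}, \code{dens_<marker>} columns.
#' @export
regionStats <- function(assignments, calls, rs) {
  tab <- if (is(rs, "RegionSet")) rs@table else rs
  unknown <- setdiff(assignments$cell_id, calls$cell_id)
  if (length(unknown))
    stop(sprintf("assignment references unknown cell_id(s): %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  m <- match(assignments$cell_id, calls$cell_id)
  out <- tab[c("region_id", "region_class", "parent_islet_id", "area_um2")]
  f <- factor(assignments$region_id, levels = tab$region_id)
  out$n_cells <- as.integer(table(f))
  for (mk in names(.markerCols)) {
    pos <- calls[[.markerCols[mk]]][m]
    np <- vapply(split(pos, f), sum, numeric(1))
    out[[paste0("n_", mk)]] <- as.integer(np)
    out[[paste0("pct_", mk)]] <- ifelse(out$n_cells > 0,
                                        100 * np / out$n_cells, NA_real_)
    out[[paste0("dens_", mk)]] <- ifelse(out$area_um2 > 0,
                                         np / (out$area_um2 / 1e6), 0)
  }
  rownames(out) <- NULL
  out
}

#' Whole-tissue statistics
#'
#' Treats the entire tissue section as a single region and applies the same
#' count/percentage/density formulas to all cells.
#'
#' @param calls data.frame from \code{\link{classifyCells}}.
#' @param tissueAreaUm2 area of the tissue in um2.
#' @return single-row data.frame with \code{region_class = "tissue"}.
#' @export
wholeTissueStats <- function(calls, tissueAreaUm2) {
  n <- nrow(calls)
  out <- data.frame(region_id = NA_integer_, region_class = "tissue",
                    parent_islet_id = NA_integer_, area_um2 = tissueAreaUm2,
                    n_cells = n)
  for (mk in names(.markerCols)) {
    np <- if (n) sum(calls[[.markerCols[mk]]]) else 0L
    out[[paste0("n_", mk)]] <- as.integer(np)
    out[[paste0("pct_", mk)]] <- if (n > 0) 100 * np / n else NA_real_
    out[[paste0("dens_", mk)]] <- if (tissueAreaUm2 > 0)
      np / (tissueAreaUm2 / 1e6) else 0
  }
  out
}

#' Macrophage density map
#'
#' Bins CD68+ cell centroids on a square grid over the tissue rectangle,
#' converts counts to densities per mm2, and smooths with a Gaussian kernel
#' of the given bandwidth (the kernel SD). With zero bandwidth the map
#' conserves mass exactly: grid value x grid-cell area sums to the CD68+
#' count inside the tissue.
#'
#' @param calls data.frame with \code{x_um, y_um, cd68_pos}.
#' @param tissueRect numeric(4) xmin, xmax, ymin, ymax (um).
#' @param gridSpacingUm grid cell side (default 50 um).
#' @param bandwidthUm Gaussian smoothing SD (default 100 um; 0 disables).
#' @return list of class \code{DensityMap}: \code{grid} (matrix, rows = y),
#'   \code{gridSpacingUm}, \code{bandwidthUm}, \code{originUm}.
#' @export
densityMap <- function(calls, tissueRect, gridSpacingUm = 50,
                       bandwidthUm = 100) {
  stopifnot(gridSpacingUm > 0, bandwidthUm >= 0)
  r <- tissueRect
  nx <- max(1L, as.integer(ceiling((r[2] - r[1]) / gridSpacingUm)))
  ny <- max(1L, as.integer(ceiling((r[4] - r[3]) / gridSpacingUm)))
  pos <- calls[calls$cd68_pos & calls$x_um >= r[1] & calls$x_um <= r[2] &
                 calls$y_um >= r[3] & calls$y_um <= r[4], , drop = FALSE]
  gx <- pmin(nx, pmax(1L, as.integer(ceiling((pos$x_um - r[1]) / gridSpacingUm))))
  gy <- pmin(ny, pmax(1L, as.integer(ceiling((pos$y_um - r[3]) / gridSpacingUm))))
  cnt <- matrix(0, ny, nx)
  if (nrow(pos)) {
    t2 <- table(factor(gy, levels = 1:ny), factor(gx, levels = 1:nx))
    cnt <- matrix(as.numeric(t2), ny, nx)
  }
  dens <- cnt / (gridSpacingUm^2 / 1e6)
  if (bandwidthUm > 0) dens <- gaussBlur(dens, bandwidthUm / gridSpacingUm)
  structure(list(grid = dens, gridSpacingUm = gridSpacingUm,
                 bandwidthUm = bandwidthUm, originUm = c(r[1], r[3])),
            class = "DensityMap")
}
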