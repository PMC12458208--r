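#' Build a synthetic tissue configuration
#'
#' Returns a \linkS4class{TissueConfig} describing one virtual multiplex-IF
#' pancreas section. Defaults encode the imaging constants the generator
#' emulates (0.325 um pixels, 8-bit dynamic range) and a type 1 diabetes
#' insulin-containing-islet macrophage profile for the zone-wise CD68+
#' fractions; see \code{\link{groupPreset}} for the disease-group profiles.
#'
#' The total cell density default (9950 cells/mm2) is the value implied by
#' the paired whole-tissue CD68+ percentages and densities of the study this
#' generator emulates. The minimum cell spacing default (6.5 um) exceeds the
#' hard floor of 1.5x the minimum nucleus radius so that nuclei in a single
#' plane rarely touch, as in thin FFPE sections.
#'
#' @param imageSizePx integer pair (width, height) in pixels.
#' @param pixelSizeUm micrometres per pixel.
#' @param nIslets number of islets.
#' @param isletRadiusUmRange range of mean islet radii (um).
#' @param isletShapeIrregularity 0 = circles; up to 1 for wobblier shapes.
#' @param iciFraction fraction of islets that are insulin-containing.
#' @param cellDensityPerMm2 expected cell density.
#' @param nucleusRadiusUmRange range of nucleus radii (um).
#' @param minSpacingUm hard-core minimum centre-to-centre spacing (um).
#' @param zoneMacrophageFraction named numeric over
#'   \code{c("islet","ring1".."ring8","exocrine")}.
#' @param hla2FractionMacrophage mean fraction of macrophages HLA-II+.
#' @param hla2FractionBeta mean fraction of beta cells HLA-II+.
#' @param hla2FractionOther HLA-II+ rate among other cells.
#' @param betaFractionInIslet beta fraction of non-macrophage islet cells.
#' @param coexpressionRankCorrelation target Spearman correlation of the
#'   per-islet macrophage-HLA-II+ and beta-HLA-II+ fractions.
#' @param copulaSdMacrophage between-islet SD of the macrophage fraction.
#' @param copulaSdBeta between-islet SD of the beta-cell fraction.
#' @param intensityModel per-channel intensity model; see
#'   \linkS4class{TissueConfig}.
#' @param seed integer seed; generation is fully deterministic given the
#'   configuration.
#' @return A validated \linkS4class{TissueConfig}.
#' @examples
#' cfg <- tissueConfig(imageSizePx = c(1200, 1200), nIslets = 2, seed = 7)
#' cfg
#' @export
tissueConfig <- function(imageSizePx = c(3692, 3692),
                         pixelSizeUm = 0.325,
                         nIslets = 8L,
                         isletRadiusUmRange = c(30, 60),
                         isletShapeIrregularity = 0.3,
                         iciFraction = 1,
                         cellDensityPerMm2 = 9950,
                         nucleusRadiusUmRange = c(2.2, 3.1),
                         minSpacingUm = 6.5,
                         zoneMacrophageFraction = NULL,
                         hla2FractionMacrophage = 0.492,
                         hla2FractionBeta = 0.30,
                         hla2FractionOther = 0.02,
                         betaFractionInIslet = 0.7,
                         coexpressionRankCorrelation = 0.74,
                         copulaSdMacrophage = 0.10,
                         copulaSdBeta = 0.15,
                         intensityModel = NULL,
                         seed = 1L) {
  if (is.null(zoneMacrophageFraction))
    zoneMacrophageFraction <- groupPreset("t1d_ici")$zoneMacrophageFraction
  if (is.null(intensityModel)) intensityModel <- defaultIntensityModel()
  new("TissueConfig",
      imageSizePx = as.integer(imageSizePx), pixelSizeUm = pixelSizeUm,
      nIslets = as.integer(nIslets), isletRadiusUmRange = isletRadiusUmRange,
      isletShapeIrregularity = isletShapeIrregularity,
      iciFraction = iciFraction, cellDensityPerMm2 = cellDensityPerMm2,
      nucleusRadiusUmRange = nucleusRadiusUmRange, minSpacingUm = minSpacingUm,
      zoneMacrophageFraction = zoneMacrophageFraction,
      hla2FractionMacrophage = hla2FractionMacrophage,
      hla2FractionBeta = hla2FractionBeta,
      hla2FractionOther = hla2FractionOther,
      betaFractionInIslet = betaFractionInIslet,
      coexpressionRankCorrelation = coexpressionRankCorrelation,
      copulaSdMacrophage = copulaSdMacrophage, copulaSdBeta = copulaSdBeta,
      intensityModel = intensityModel, seed = as.integer(seed))
}

#' Default per-channel intensity model
#'
#' Gaussian foreground/background levels on the 0-255 scale, chosen so that
#' thresholding pipelines separate signal cleanly: bright nuclear and marker
#' blobs over a dim background, and a diffuse intermediate insulin fill
#' inside insulin-containing islets that stays well below the per-cell
#' insulin signal of beta cells.
#' @return named list over DAPI, INS, CD68, HLAII.
#' @export
defaultIntensityModel <- function() {
  list(
    DAPI  = list(bgMean = 10, bgSd = 4, fgMean = 185, fgSd = 14),
    INS   = list(bgMean = 8,  bgSd = 4, fgMean = 190, fgSd = 12, isletFill = 30),
    CD68  = list(bgMean = 8,  bgSd = 4, fgMean = 190, fgSd = 12),
    HLAII = list(bgMean = 8,  bgSd = 4, fgMean = 190, fgSd = 12))
}

#' Disease-group generator presets
#'
#' Zone-wise CD68+ fractions and macrophage HLA-II+ fractions configured to
#' the group means of the study the generator emulates: non-diabetic,
#' autoantibody-positive (Aab+), and type 1 diabetes with insulin-containing
#' (ICI) or insulin-deficient (IDI) islets. Ring-1 and islet values are the
#' printed group means; rings 2-8, for which only the qualitative profile is
#' reported (a decline after ring 1 that stabilises above the islet level in
#' T1D ICIs, near-uniform elsewhere), interpolate between the ring-1 and
#' exocrine values.
#'
#' @param group one of \code{"non_diabetic"}, \code{"aab_pos"},
#'   \code{"t1d_ici"}, \code{"t1d_idi"}.
#' @return list with \code{zoneMacrophageFraction},
#'   \code{hla2FractionMacrophage}, \code{iciFraction}.
#' @export
groupPreset <- function(group = c("t1d_ici", "t1d_idi", "aab_pos", "non_diabetic")) {
  group <- match.arg(group)
  zone <- function(islet, ring1, rings, exo)
    stats::setNames(c(islet, ring1, rep(rings, 7), exo), .zoneNames)
  switch(group,
    t1d_ici = list(
      zoneMacrophageFraction = zone(0.062, 0.136, 0.100, 0.079),
      hla2FractionMacrophage = 0.492, iciFraction = 1),
    t1d_idi = list(
      zoneMacrophageFraction = zone(0.016, 0.075, 0.075, 0.079),
      hla2FractionMacrophage = 0.326, iciFraction = 0),
    aab_pos = list(
      zoneMacrophageFraction = zone(0.004, 0.026, 0.026, 0.023),
      hla2FractionMacrophage = 0.199, iciFraction = 1),
    non_diabetic = list(
      zoneMacrophageFraction = zone(0.003, 0.013, 0.013, 0.010),
      hla2FractionMacrophage = 0.248, iciFraction = 1))
}

#' Desk-scale recovery configurations
#'
#' Standard configurations for parameter-recovery runs against the printed
#' group values. \code{"whole_tissue"} is one 1.65 mm section (about 20,000
#' cells) with a uniform per-cell CD68+ probability; \code{"zone"} is one
#' 2.2 mm section packed with 200 insulin-containing islets carrying the
#' type 1 diabetes ICI zone profile (islet 6.2\%, ring-1 13.6\%); and
#' \code{"peri"} is the same geometry with the 0-25 um collar probability
#' set to the peri-islet value (19.6\%), so the 0-10 um peri-islet collar
#' carries that probability. Macrophage HLA-II positivity is 49.2\% in all
#' three.
#'
#' @param profile one of \code{"whole_tissue"}, \code{"zone"},
#'   \code{"peri"}.
#' @param seed generator seed.
#' @param uniformP per-cell CD68+ probability for
#'   \code{"whole_tissue"} (default: the printed type 1 diabetes
#'   whole-tissue mean, 8.6\%).
#' @return a \linkS4class{TissueConfig}.
#' @export
recoveryConfig <- function(profile = c("whole_tissue", "zone", "peri"),
                           seed = 1, uniformP = 0.086) {
  profile <- match.arg(profile)
  if (profile == "whole_tissue")
    return(tissueConfig(imageSizePx = c(5077, 5077), nIslets = 6,
                        zoneMacrophageFraction = uniformZoneFractions(uniformP),
                        seed = seed))
  zm <- groupPreset("t1d_ici")$zoneMacrophageFraction
  if (profile == "peri") zm["ring1"] <- 0.196
  tissueConfig(imageSizePx = c(6770, 6770), nIslets = 200,
               isletRadiusUmRange = c(22, 42),
               zoneMacrophageFraction = zm, seed = seed)
}

#' Uniform zone fraction map
#'
#' Convenience for whole-tissue recovery runs: every zone gets the same
#' per-cell CD68+ probability.
#' @param p probability in [0,1].
#' @return named numeric usable as \code{zoneMacrophageFraction}.
#' @export
uniformZoneFractions <- function(p) stats::setNames(rep(p, 10), .zoneNames)

## ---- islet shapes -------------------------------------------------------

# radial-harmonic islet radius at angles theta
isletRadiusAt <- function(islet, theta) {
  r <- rep(islet$r0, length(theta))
  h <- islet$harm
  if (length(h$k))
    for (q in seq_along(h$k))
      r <- r + islet$r0 * h$a[q] * cos(h$k[q] * theta + h$phi[q])
  r
}

#' Sample islet shapes and labels
#'
#' Places \code{nIslets} mutually disjoint star-shaped islets (circles
#' perturbed by low-order radial harmonics) inside the tissue rectangle,
#' keeping a 200 um margin from the image border whenever the image is large
#' enough to afford it. ICI/IDI labels are Bernoulli with
#' \code{iciFraction}. Uses the current RNG state.
#'
#' @param config a \linkS4class{TissueConfig}.
#' @param maxAttempts rejection-sampling budget per islet.
#' @return list of islets: \code{cx, cy, r0, harm, maxR, label, poly}
#'   (polygon as an n x 2 matrix in um).
#' @export
sampleIsletPolygons <- function(config, maxAttempts = 400) {
  n <- config@nIslets
  if (n == 0) return(list())
  px <- config@pixelSizeUm
  W <- config@imageSizePx[1] * px; H <- config@imageSizePx[2] * px
  rect <- tissueRectOf(config)
  rng <- config@isletRadiusUmRange
  irr <- config@isletShapeIrregularity
  out <- vector("list", n)
  cx <- cy <- mr <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(maxAttempts)) {
      r0 <- stats::runif(1, rng[1], rng[2])
      maxR <- r0 * (1 + 0.4 * irr)
      # prefer a 200 um image margin when it leaves most of the tissue usable
      marg <- if (W - 2 * (maxR + 200) >= 0.5 * (rect[2] - rect[1]) &&
                  H - 2 * (maxR + 200) >= 0.5 * (rect[4] - rect[3]))
        maxR + 200 else maxR + 10
      x0 <- max(rect[1] + maxR + 5, marg)
      x1 <- min(rect[2] - maxR - 5, W - marg)
      y0 <- max(rect[3] + maxR + 5, marg)
      y1 <- min(rect[4] - maxR - 5, H - marg)
      if (x1 <= x0 || y1 <= y0) next
      x <- stats::runif(1, x0, x1); y <- stats::runif(1, y0, y1)
      if (length(cx) && any(sqrt((cx - x)^2 + (cy - y)^2) < mr + maxR + 15)) next
      k <- 2:5
      harm <- list(k = k, a = irr * stats::runif(4, 0.02, 0.09),
                   phi = stats::runif(4, 0, 2 * pi))
      isl <- list(cx = x, cy = y, r0 = r0, harm = harm, maxR = maxR,
                  label = if (stats::runif(1) < config@iciFraction) "ICI" else "IDI")
      th <- seq(0, 2 * pi, length.out = 181)[-181]
      rr <- isletRadiusAt(isl, th)
      isl$poly <- cbind(x = x + rr * cos(th), y = y + rr * sin(th))
      out[[i]] <- isl
      cx <- c(cx, x); cy <- c(cy, y); mr <- c(mr, maxR)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("infeasible geometry: could not place islet %d of %d after %d attempts",
                   i, n, maxAttempts))
  }
  out
}

# tissue rectangle: image inset by 100 um on every side
tissueRectOf <- function(config) {
  px <- config@pixelSizeUm
  c(xmin = 100, xmax = config@imageSizePx[1] * px - 100,
    ymin = 100, ymax = config@imageSizePx[2] * px - 100)
}

# rasterize islets into an integer label mask (pixel-centre-inside rule)
isletMaskFromList <- function(islets, dimPx, px) {
  lab <- matrix(0L, nrow = dimPx[2], ncol = dimPx[1])  # rows = y
  for (id in seq_along(islets)) {
    isl <- islets[[id]]
    j0 <- max(1L, umToIdx(isl$cx - isl$maxR - 1, px))
    j1 <- min(dimPx[1], umToIdx(isl$cx + isl$maxR + 1, px))
    i0 <- max(1L, umToIdx(isl$cy - isl$maxR - 1, px))
    i1 <- min(dimPx[2], umToIdx(isl$cy + isl$maxR + 1, px))
    xs <- idxToUm(j0:j1, px) - isl$cx
    ys <- idxToUm(i0:i1, px) - isl$cy
    rho <- sqrt(outer(ys^2, xs^2, "+"))
    th <- atan2(matrix(ys, length(ys), length(xs)),
                matrix(xs, length(ys), length(xs), byrow = TRUE))
    inside <- rho <= isletRadiusAt(isl, th)
    sub <- lab[i0:i1, j0:j1]
    sub[inside] <- id
    lab[i0:i1, j0:j1] <- sub
  }
  lab
}

## ---- co-expression copula ----------------------------------------------

#' Draw per-islet co-expression fractions from a Gaussian copula
#'
#' Samples paired per-islet fractions (macrophage HLA-II+ fraction,
#' beta-cell HLA-II+ fraction) with Beta marginals and a Gaussian copula
#' whose latent Pearson correlation is \code{2 sin(pi * rhoS / 6)}, so that
#' the population Spearman correlation equals \code{rhoS} exactly.
#' Uses the current RNG state.
#'
#' @param n number of islets.
#' @param rhoS target Spearman correlation in [-1, 1].
#' @param meanMac,sdMac mean and between-islet SD of the macrophage fraction.
#' @param meanBeta,sdBeta mean and SD of the beta-cell fraction.
#' @return data.frame with columns \code{pMacHla2}, \code{pBetaHla2}.
#' @examples
#' set.seed(1)
#' co <- sampleIsletCoexpression(500, 0.74)
#' cor(co$pMacHla2, co$pBetaHla2, method = "spearman")
#' @export
sampleIsletCoexpression <- function(n, rhoS, meanMac = 0.492, sdMac = 0.10,
                                    meanBeta = 0.30, sdBeta = 0.15) {
  stopifnot(n >= 1, abs(rhoS) <= 1)
  rp <- 2 * sin(pi * rhoS / 6)
  z1 <- stats::rnorm(n)
  z2 <- rp * z1 + sqrt(max(0, 1 - rp^2)) * stats::rnorm(n)
  betaPar <- function(m, s) {
    v <- min(s^2, 0.95 * m * (1 - m))
    nu <- m * (1 - m) / v - 1
    c(a = m * nu, b = (1 - m) * nu)
  }
  pm <- betaPar(meanMac, sdMac); pb <- betaPar(meanBeta, sdBeta)
  data.frame(pMacHla2 = stats::qbeta(stats::pnorm(z1), pm["a"], pm["b"]),
             pBetaHla2 = stats::qbeta(stats::pnorm(z2), pb["a"], pb["b"]))
}

## ---- cells ---------------------------------------------------------------

#' Sample ground-truth cells
#'
#' Places cell centres uniformly in the tissue rectangle at the configured
#' density under a hard-core minimum spacing, assigns each cell its zone
#' (inside an islet, one of the eight 25-um rings, or exocrine beyond
#' 200 um) from the islet geometry, then draws marker states: CD68+ is
#' Bernoulli with the zone's configured fraction; HLA-II states follow the
#' per-islet Gaussian-copula fractions for macrophages and beta cells in the
#' islet and its 10-um peri-islet collar, and global fractions elsewhere.
#' Uses the current RNG state.
#'
#' @param config a \linkS4class{TissueConfig}.
#' @param islets islet list from \code{\link{sampleIsletPolygons}}.
#' @param isletMask optional precomputed islet label mask.
#' @return list: \code{cells} (data.frame), \code{isletCoexpression}
#'   (per-islet copula draws).
#' @export
sampleCells <- function(config, islets, isletMask = NULL) {
  px <- config@pixelSizeUm
  rect <- tissueRectOf(config)
  areaMm2 <- (rect[2] - rect[1]) * (rect[4] - rect[3]) / 1e6
  nTarget <- stats::rpois(1, config@cellDensityPerMm2 * areaMm2)
  # hard-core dart throwing in batches
  xs <- ys <- numeric(0)
  batch <- max(1000L, 2L * nTarget)
  for (round in 1:12) {
    if (length(xs) >= nTarget) break
    nx <- stats::runif(batch, rect[1], rect[2])
    ny <- stats::runif(batch, rect[3], rect[4])
    keep <- .c_hardcore_filter(c(xs, nx), c(ys, ny), config@minSpacingUm)
    xs <- c(xs, nx)[keep]; ys <- c(ys, ny)[keep]
  }
  if (length(xs) < nTarget)
    stop(sprintf("could not place %d cells at spacing %.1f um (got %d); density infeasible",
                 nTarget, config@minSpacingUm, length(xs)))
  xs <- xs[seq_len(nTarget)]; ys <- ys[seq_len(nTarget)]

  # zone from islet geometry
  if (is.null(isletMask))
    isletMask <- isletMaskFromList(islets, config@imageSizePx, px)
  if (length(islets)) {
    vdt <- nearestSeed(isletMask)
    ii <- cbind(umToIdx(ys, px), umToIdx(xs, px))
    lab0 <- isletMask[ii]
    dUm <- pmax(0, (vdt$dist[ii] - .edgeOffsetPx)) * px
    owner <- vdt$label[ii]
  } else {
    lab0 <- integer(nTarget); dUm <- rep(Inf, nTarget); owner <- integer(nTarget)
  }
  inIslet <- lab0 > 0L
  ringK <- ifelse(inIslet | dUm > 200, NA_integer_, pmax(1L, ceiling(dUm / 25)))
  zone <- ifelse(inIslet, "islet",
                 ifelse(!is.na(ringK), paste0("ring", ringK), "exocrine"))
  parent <- ifelse(inIslet, lab0, ifelse(!is.na(ringK), owner, NA_integer_))

  pCd68 <- config@zoneMacrophageFraction[zone]
  cd68 <- stats::runif(nTarget) < pCd68
  iciIds <- which(vapply(islets, function(i) i$label == "ICI", logical(1)))
  inIci <- inIslet & lab0 %in% iciIds
  beta <- !cd68 & inIci & stats::runif(nTarget) < config@betaFractionInIslet
  type <- ifelse(cd68, "macrophage", ifelse(beta, "beta", "other"))

  co <- if (length(islets))
    sampleIsletCoexpression(length(islets), config@coexpressionRankCorrelation,
                            config@hla2FractionMacrophage, config@copulaSdMacrophage,
                            config@hla2FractionBeta, config@copulaSdBeta)
  else data.frame(pMacHla2 = numeric(0), pBetaHla2 = numeric(0))

  # islet + 10 um peri-islet collar uses the islet-specific fractions
  periOf <- ifelse(inIslet, lab0, ifelse(dUm <= 10, owner, 0L))
  pHla2 <- rep(config@hla2FractionOther, nTarget)
  isMac <- type == "macrophage"
  pHla2[isMac] <- config@hla2FractionMacrophage
  macLocal <- isMac & periOf > 0L
  pHla2[macLocal] <- co$pMacHla2[periOf[macLocal]]
  isBeta <- type == "beta"
  pHla2[isBeta] <- co$pBetaHla2[lab0[isBeta]]
  hla2 <- stats::runif(nTarget) < pHla2

  rr <- stats::runif(nTarget, config@nucleusRadiusUmRange[1],
                     config@nucleusRadiusUmRange[2])
  cells <- data.frame(
    cell_id = seq_len(nTarget), x_um = xs, y_um = ys,
    cell_type = type, insulin_pos = type == "beta", cd68_pos = cd68,
    hla2_pos = hla2, zone = zone, parent_islet_id = as.integer(parent),
    nucleus_r_um = rr, aspect = stats::runif(nTarget, 0.75, 1),
    theta = stats::runif(nTarget, 0, pi))
  list(cells = cells, isletCoexpression = co)
}

## ---- rendering -----------------------------------------------------------

# render the four channels of a ground truth; uses current RNG state
renderChannels <- function(truth) {
  cfg <- truth@config
  px <- cfg@pixelSizeUm
  dimPx <- cfg@imageSizePx
  nr <- dimPx[2]; nc <- dimPx[1]
  im <- cfg@intensityModel
  cl <- truth@cells
  cxp <- cl$x_um / px + 1; cyp <- cl$y_um / px + 1
  rxp <- cl$nucleus_r_um / sqrt(cl$aspect) / px
  ryp <- cl$nucleus_r_um * sqrt(cl$aspect) / px
  soft <- 0.8 / px
  blob <- function(sel, extraUm, m) {
    img <- matrix(0, nr, nc)
    if (any(sel))
      .c_render_blobs(img, cxp[sel], cyp[sel],
                      rxp[sel] + extraUm / px, ryp[sel] + extraUm / px,
                      cl$theta[sel], stats::rnorm(sum(sel), m$fgMean, m$fgSd), soft)
    img
  }
  finalize <- function(img, m) .c_finalize_channel(img, m$bgMean, m$bgSd)

  dapi <- finalize(blob(rep(TRUE, nrow(cl)), 0, im$DAPI), im$DAPI)

  # soft islet shape field in [0,1]; insulin (diffuse fill and per-cell
  # beta signal alike) is confined to the islet, so the field multiplies
  # the whole insulin foreground
  sfield <- matrix(0, nr, nc)
  for (id in seq_along(truth@islets)) {
    isl <- truth@islets[[id]]
    if (isl$label != "ICI") next
    j0 <- max(1L, umToIdx(isl$cx - isl$maxR - 3, px))
    j1 <- min(nc, umToIdx(isl$cx + isl$maxR + 3, px))
    i0 <- max(1L, umToIdx(isl$cy - isl$maxR - 3, px))
    i1 <- min(nr, umToIdx(isl$cy + isl$maxR + 3, px))
    xs <- idxToUm(j0:j1, px) - isl$cx
    ys <- idxToUm(i0:i1, px) - isl$cy
    rho <- sqrt(outer(ys^2, xs^2, "+"))
    th <- atan2(matrix(ys, length(ys), length(xs)),
                matrix(xs, length(ys), length(xs), byrow = TRUE))
    s <- pmin(1, pmax(0, (isletRadiusAt(isl, th) - rho) / 1.6 + 0.5))
    sub <- sfield[i0:i1, j0:j1]
    sfield[i0:i1, j0:j1] <- pmax(sub, s)
  }
  insBlob <- blob(cl$insulin_pos, 2.0, im$INS)
  insBlob[insBlob < im$INS$isletFill] <- im$INS$isletFill
  ins <- finalize(sfield * insBlob, im$INS)
  rm(insBlob, sfield)

  cd68 <- finalize(blob(cl$cd68_pos, 2.5, im$CD68), im$CD68)
  hla2 <- finalize(blob(cl$hla2_pos, 2.5, im$HLAII), im$HLAII)

  channelStack(list(DAPI = dapi, INS = ins, CD68 = cd68, HLAII = hla2), px)
}

#' Generate one synthetic tissue section
#'
#' Runs the full generator - islet placement, cell sampling with zone-wise
#' marker structure, and (optionally) rendering of the four channels
#' (DAPI/Hoechst, INS, CD68, HLAII) under the configured intensity model.
#' The result is a pure function of the configuration: the same config
#' yields bit-identical pixels and tables.
#'
#' @param config a \linkS4class{TissueConfig}.
#' @param render if FALSE, skip image rendering (ground truth only), which
#'   is much faster for statistics-level work.
#' @return list with \code{stack} (a \linkS4class{ChannelStack}, or NULL
#'   when \code{render = FALSE}) and \code{truth}
#'   (a \linkS4class{GroundTruthTissue}).
#' @examples
#' tt <- generateTissue(tissueConfig(imageSizePx = c(600, 600), nIslets = 1,
#'                                   seed = 3), render = FALSE)
#' tt$truth
#' @export
generateTissue <- function(config, render = TRUE) {
  validObject(config)
  px <- config@pixelSizeUm
  islets <- withSeed(childSeed(config@seed, 1), sampleIsletPolygons(config))
  mask <- isletMaskFromList(islets, config@imageSizePx, px)
  smp <- withSeed(childSeed(config@seed, 2), sampleCells(config, islets, mask))
  isletTable <- if (length(islets)) data.frame(
    islet_id = seq_along(islets),
    label = vapply(islets, `[[`, character(1), "label"),
    cx_um = vapply(islets, `[[`, numeric(1), "cx"),
    cy_um = vapply(islets, `[[`, numeric(1), "cy"),
    mean_radius_um = vapply(islets, `[[`, numeric(1), "r0"),
    area_um2 = vapply(islets, function(i) polyArea(i$poly), numeric(1)))
  else data.frame(islet_id = integer(0), label = character(0),
                  cx_um = numeric(0), cy_um = numeric(0),
                  mean_radius_um = numeric(0), area_um2 = numeric(0))
  truth <- new("GroundTruthTissue", cells = smp$cells, islets = islets,
               isletTable = isletTable, tissueRect = tissueRectOf(config),
               config = config)
  stack <- if (render)
    withSeed(childSeed(config@seed, 3), renderChannels(truth)) else NULL
  list(stack = stack, truth = truth)
}

#' Rasterize the true islet shapes of a ground truth
#'
#' @param truth a \linkS4class{GroundTruthTissue}.
#' @return integer matrix of islet ids (0 outside).
#' @export
trueIsletMask <- function(truth)
  isletMaskFromList(truth@islets, truth@config@imageSizePx,
                    truth@config@pixelSizeUm)
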