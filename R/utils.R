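## internal helpers: units, RNG scoping, thresholding, small geometry

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a local RNG state seeded by `seed`, restoring the caller's
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# splittable child seeds: deterministic, spread across the 31-bit range
childSeed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + k * 7919) %% 2147483629)
}

# physical um (0-based pixel-centre convention) <-> 1-based matrix index
umToIdx <- function(u, px) as.integer(round(u / px) + 1)
idxToUm <- function(i, px) (i - 1) * px

# triangle threshold on a 0..255 histogram of image values
triangleThreshold <- function(x, nbins = 256) {
  h <- as.double(tabulate(pmin(pmax(as.integer(x) + 1L, 1L), nbins), nbins))
  pk <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  # take the longer tail
  if ((hi - pk) >= (pk - lo)) { a <- pk; b <- hi } else { a <- pk; b <- lo }
  if (a == b) return(a - 1)
  idx <- seq(a, b, by = if (b > a) 1 else -1)
  # perpendicular distance from (i, h[i]) to the line (a,h[a])-(b,h[b])
  dx <- (b - a); dy <- as.double(h[b] - h[a])
  d <- abs(dy * (idx - a) - dx * (h[idx] - h[a])) / sqrt(dx^2 + dy^2)
  idx[which.max(d)] - 1  # 0-based intensity
}

# shoelace polygon area; poly = matrix with columns x, y
polyArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# points-in-polygon (closed boundary counts as inside, up to numeric eps)
pointsInPolygon <- function(pts, poly) {
  as.logical(mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]),
                          as.matrix(pts)))
}

# clamp + integerise to 8-bit
asUint8 <- function(m) {
  m <- round(m)
  m[m < 0] <- 0; m[m > 255] <- 255
  storage.mode(m) <- "integer"
  m
}

# nearest-seed distance transform on an integer label matrix; returns
# dist (px, centre-to-centre) and nearest seed label
nearestSeed <- function(labels, maxDistPx = -1) {
  storage.mode(labels) <- "integer"
  .c_nearest_seed(labels, maxDistPx, TRUE)
}

# label-only variant: pixels farther than maxDistPx from any seed get 0;
# skips allocating the distance matrix
nearestSeedLabel <- function(labels, maxDistPx) {
  storage.mode(labels) <- "integer"
  .c_nearest_seed(labels, maxDistPx, FALSE)$label
}

# separable Gaussian blur, sigma in pixels
gaussBlur <- function(m, sigmaPx) {
  storage.mode(m) <- "double"
  .c_gauss_blur(m, sigmaPx)
}

# boundary pixels of labelled regions: pixels with a 4-neighbour of a
# different label; returns data.frame(i, j, label)
labelBoundaries <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  b <- matrix(FALSE, nr, nc)
  fg <- lab > 0L
  b[-nr, ] <- b[-nr, ] | (fg[-nr, ] & lab[-nr, ] != lab[-1, ])
  b[-1, ]  <- b[-1, ]  | (fg[-1, ]  & lab[-1, ]  != lab[-nr, ])
  b[, -nc] <- b[, -nc] | (fg[, -nc] & lab[, -nc] != lab[, -1])
  b[, -1]  <- b[, -1]  | (fg[, -1]  & lab[, -1]  != lab[, -nc])
  b[1, ] <- b[1, ] | fg[1, ]; b[nr, ] <- b[nr, ] | fg[nr, ]
  b[, 1] <- b[, 1] | fg[, 1]; b[, nc] <- b[, nc] | fg[, nc]
  idx <- which(b, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], label = lab[idx])
}

# md5 of a file, NA-safe
fileHash <- function(path) unname(tools::md5sum(path))

# raster boundary convention: a region's continuous boundary runs a small
# fixed offset outside the outermost in-region pixel centres. 0.25 px is
# the empirical mean gap between a smooth boundary and the nearest interior
# pixel centre on this grid; distance-band and dilation cuts subtract it so
# pixel-counted areas match analytic discs/annuli to well within 1%.
.edgeOffsetPx <- 0.25
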