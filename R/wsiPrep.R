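#' Tile an image into non-overlapping 224 x 224 patches
#'
#' Cuts a full grid of non-overlapping tiles anchored at the top-left corner
#' (0-based, row-major, half-open extents); partial border tiles are
#' discarded, so the tile count is `floor(H/size) * floor(W/size)`. When the
#' source resolution is supplied, the image is first resampled (bilinear) to
#' the target resolution of 0.5 micrometers per pixel.
#'
#' @param image H x W x 3 numeric array in \[0, 255\].
#' @param tileSize tile side length (default 224).
#' @param micronsPerPixel optional source resolution; when given, the image
#'   is rescaled by `micronsPerPixel / targetMpp` before tiling.
#' @param targetMpp target resolution (default 0.5).
#' @return list of tiles, each a list with `pixels` (tileSize^2 x 3 array)
#'   and `origin` = c(row, col) in 0-based pixel coordinates of the
#'   (possibly resampled) image. An image smaller than one tile yields an
#'   empty list.
#' @export
tileImage <- function(image, tileSize = 224L, micronsPerPixel = NULL,
                      targetMpp = 0.5) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  if (!is.null(micronsPerPixel) && micronsPerPixel != targetMpp) {
    f <- micronsPerPixel / targetMpp
    w <- round(dim(image)[1] * f); h <- round(dim(image)[2] * f)
    img <- EBImage::resize(EBImage::Image(image / 255, colormode = "Color"),
                           w = w, h = h)
    image <- as.array(img) * 255
    image[] <- pmin(255, pmax(0, image))
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  nr <- H %/% tileSize; nc <- W %/% tileSize
  tiles <- list()
  for (i in seq_len(nr) - 1L) for (j in seq_len(nc) - 1L) {
    px <- image[i * tileSize + seq_len(tileSize),
                j * tileSize + seq_len(tileSize), , drop = FALSE]
    tiles <- c(tiles, list(list(pixels = px,
                                origin = c(row = i * tileSize, col = j * tileSize))))
  }
  tiles
}

tileGray <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

#' Fraction of edge pixels in a tile
#'
#' Runs the Canny detector (Gaussian smoothing, Sobel gradients, non-maximum
#' suppression, hysteresis with the given 8-bit thresholds) on the grayscale
#' tile and returns the fraction of pixels marked as edges.
#'
#' @param tile list with `pixels` (H x W x 3, \[0, 255\]) or a bare array.
#' @param cannyLow,cannyHigh hysteresis thresholds on 8-bit gradient
#'   magnitude.
#' @return proportion in \[0, 1\].
#' @export
edgeFraction <- function(tile, cannyLow = 50, cannyHigh = 150) {
  px <- if (is.list(tile)) tile$pixels else tile
  mean(cannyEdges(tileGray(px), low = cannyLow, high = cannyHigh))
}

#' Filter background and blurry tiles by edge content
#'
#' A tile is rejected when its edge percentage (`edgeFraction * 100`) is at
#' or below `edgeThreshold` (default 2): uniform background and heavily
#' blurred tiles have little edge content, while in-focus tissue does.
#'
#' @param tiles list of tiles (each with `pixels`).
#' @param edgeThreshold rejection threshold on the edge percentage.
#' @param cannyLow,cannyHigh passed to [edgeFraction()].
#' @return list with `kept` (surviving tiles) and `log` (data.frame:
#'   `tile`, `edge_pct`, `kept`).
#' @export
filterPatches <- function(tiles, edgeThreshold = 2, cannyLow = 50,
                          cannyHigh = 150) {
  stopifnot(edgeThreshold >= 0)
  pct <- vapply(tiles, edgeFraction, 0, cannyLow = cannyLow,
                cannyHigh = cannyHigh) * 100
  keep <- pct > edgeThreshold
  list(kept = tiles[keep],
       log = data.frame(tile = seq_along(tiles), edge_pct = pct, kept = keep))
}

#' Standardize tile brightness
#'
#' Linear luminance rescaling mapping the 90th-percentile luminance to 240
#' (clipped to \[0, 255\]), so differently exposed slides share a brightness
#' scale. Idempotent within one intensity level. A fully black tile is
#' returned unchanged with a warning.
#'
#' @param tile list with `pixels` or a bare H x W x 3 array in \[0, 255\].
#' @param target luminance value the 90th percentile is mapped to.
#' @return same structure as the input, with rescaled pixels.
#' @export
standardizeBrightness <- function(tile, target = 240) {
  px <- if (is.list(tile)) tile$pixels else tile
  p90 <- quantile(tileGray(px), 0.9, names = FALSE)
  if (p90 < 1) {
    warning("near-black tile: brightness left unchanged")
    return(tile)
  }
  out <- px * (target / p90)
  out[] <- pmin(255, pmax(0, out))
  if (is.list(tile)) { tile$pixels <- out; tile } else out
}

rgbToOd <- function(px) {
  # pixels x 3 matrix of optical densities
  m <- cbind(as.numeric(px[, , 1]), as.numeric(px[, , 2]), as.numeric(px[, , 3]))
  -log10((m + 1) / 256)
}

odToRgb <- function(od, dims) {
  m <- pmin(255, pmax(0, round(256 * 10^(-od) - 1)))
  array(m, dim = dims)
}

# exact nonnegative least squares for 2 stains, vectorized over pixels:
# solve the unconstrained 2x2 system, then clamp-and-resolve per stain
nnls2 <- function(S, od) {
  StS <- crossprod(S)
  C <- solve(StS, t(S) %*% t(od))             # 2 x pixels
  s11 <- sum(S[, 1]^2); s22 <- sum(S[, 2]^2)
  neg1 <- C[1, ] < 0; neg2 <- C[2, ] < 0
  C[1, neg1] <- 0
  C[2, neg1] <- pmax(0, (od[neg1, , drop = FALSE] %*% S[, 2]) / s22)
  C[2, neg2] <- 0
  C[1, neg2] <- pmax(0, (od[neg2, , drop = FALSE] %*% S[, 1]) / s11)
  C
}

#' Fit a Macenko stain model to a tile
#'
#' Macenko stain estimation: convert RGB to optical density
#' `OD = -log10((I + 1) / 256)`, discard pixels that are not above
#' `odThreshold` in every channel, take the top-2 singular directions of the
#' remaining OD cloud, project the pixels into that plane, and take the
#' directions at the extreme angle percentiles as the stain vectors. Columns
#' are ordered so hematoxylin (larger blue-channel OD) comes first, vectors
#' are clamped nonnegative and normalized, concentrations are recovered by
#' exact two-variable nonnegative least squares, and the per-stain 99th
#' percentile concentration is stored.
#'
#' @param tile list with `pixels` or a bare H x W x 3 array in \[0, 255\].
#' @param odThreshold minimum per-channel optical density for a pixel to
#'   count as tissue (default 0.15).
#' @param anglePercentile robust extreme-angle percentile (default 1).
#' @param minTissuePixels minimum number of tissue pixels (default 100).
#' @return A [StainModel-class].
#' @export
macenkoFit <- function(tile, odThreshold = 0.15, anglePercentile = 1,
                       minTissuePixels = 100L) {
  px <- if (is.list(tile)) tile$pixels else tile
  od <- rgbToOd(px)
  tissue <- od[rowSums(od > odThreshold) == 3L, , drop = FALSE]
  if (nrow(tissue) < minTissuePixels)
    stop("insufficient tissue: only ", nrow(tissue),
         " pixels above the OD threshold")
  V <- svd(tissue, nu = 0, nv = 2)$v
  for (j in 1:2) if (sum(tissue %*% V[, j]) < 0) V[, j] <- -V[, j]
  proj <- tissue %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- quantile(phi, c(anglePercentile, 100 - anglePercentile) / 100,
                 names = FALSE)
  v1 <- V %*% c(cos(qs[1]), sin(qs[1]))
  v2 <- V %*% c(cos(qs[2]), sin(qs[2]))
  S <- cbind(pmax(v1, 0), pmax(v2, 0))
  S <- sweep(S, 2, sqrt(colSums(S^2)), "/")
  if (S[3, 2] > S[3, 1]) S <- S[, 2:1]        # hematoxylin first
  C <- nnls2(S, tissue)
  new("StainModel", stainMatrix = S,
      maxConcentrations = apply(C, 1, quantile, 0.99, names = FALSE))
}

#' Normalize a tile to a reference stain model
#'
#' Recovers the tile's stain concentrations under its fitted model, rescales
#' them by `reference max / fitted max` per stain, re-renders with the
#' reference stain matrix and inverts the optical-density transform, clipping
#' to \[0, 255\].
#'
#' @param tile list with `pixels` or a bare array.
#' @param fitted [StainModel-class] fitted to this tile (or its slide).
#' @param reference target [StainModel-class] (default
#'   [referenceStainModel()]).
#' @return same structure as the input, with normalized pixels.
#' @export
macenkoApply <- function(tile, fitted, reference = referenceStainModel()) {
  stopifnot(is(fitted, "StainModel"), is(reference, "StainModel"))
  if (any(fitted@maxConcentrations <= 0))
    stop("fitted model has a zero maximum concentration")
  px <- if (is.list(tile)) tile$pixels else tile
  od <- rgbToOd(px)
  C <- nnls2(fitted@stainMatrix, od)
  C <- C * (reference@maxConcentrations / fitted@maxConcentrations)
  out <- odToRgb(t(reference@stainMatrix %*% C), dim(px))
  if (is.list(tile)) { tile$pixels <- out; tile } else out
}

#' Reference stain model shipped with the package
#'
#' The documented normalization target. The reference uses the balanced
#' stain vectors (all channels absorb appreciably) rather than the classical
#' H&E vectors: eosin's near-zero red optical density would place pure-eosin
#' pixels of a normalized tile below the per-channel tissue threshold, making
#' re-fitting of already-normalized tiles unstable. Reference concentrations
#' are a typical tissue-tile 99th percentile.
#'
#' @return A [StainModel-class].
#' @export
referenceStainModel <- function() {
  new("StainModel", stainMatrix = balancedStainVectors(),
      maxConcentrations = c(1.2, 0.9))
}

#' Embed kept tiles into patch feature vectors
#'
#' Applies an embedder function to each tile and stacks the results in tile
#' order, yielding the feature block of a [PatchBag-class]. The deep feature
#' extractor used at full scale is a pluggable seam here; two embedders ship
#' with the package: `"identity-pool"` (per-channel mean and sd, 6 features)
#' and any user function mapping a tile to a fixed-length numeric vector.
#' Bags that already arrive in feature form bypass this stage entirely
#' ("synthetic passthrough").
#'
#' @param tiles list of tiles (each with `pixels`).
#' @param embedder `"identity-pool"` or a function(tile) -> numeric vector.
#' @return n_tiles x D numeric matrix.
#' @export
embedPatches <- function(tiles, embedder = "identity-pool") {
  f <- if (is.function(embedder)) embedder
  else if (identical(embedder, "identity-pool")) {
    function(tile) {
      px <- if (is.list(tile)) tile$pixels else tile
      c(apply(px, 3, mean), apply(px, 3, sd))
    }
  } else stop("unknown embedder")
  rows <- lapply(tiles, function(tl) as.numeric(f(tl)))
  lens <- lengths(rows)
  if (length(unique(lens)) > 1)
    stop("embedder output length differs across tiles")
  do.call(rbind, rows)
}
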