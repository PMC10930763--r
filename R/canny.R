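# Canny edge detection on an 8-bit grayscale matrix. No installed R package
# provides a Canny detector, so the classic pipeline is implemented here:
# optional Gaussian smoothing, Sobel gradients, 4-sector non-maximum
# suppression, and double-threshold hysteresis. Gradient magnitude uses the
# L1 norm |gx| + |gy|, so `low`/`high` are on the familiar 8-bit scale, and
# no prefilter is applied by default (the common Canny convention: smoothing
# is the caller's choice). A 2-pixel image border is excluded: gradients
# there are undefined without padding assumptions.

shiftMat <- function(m, dr, dc, fill = 0) {
  n <- matrix(fill, nrow(m), ncol(m))
  rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
  cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
  n[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  n
}

gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

convSep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in -r:r) out <- out + k[i + r + 1L] * shiftMat(m, i, 0, fill = NA)
  out[is.na(out)] <- 0
  out2 <- matrix(0, nrow(m), ncol(m))
  for (j in -r:r) out2 <- out2 + k[j + r + 1L] * shiftMat(out, 0, j, fill = NA)
  out2[is.na(out2)] <- 0
  out2
}

cannyEdges <- function(gray, low = 50, high = 150, sigma = 0) {
  g <- if (sigma > 0) convSep(gray, gaussKernel1d(sigma)) else gray
  # Sobel
  gx <- (shiftMat(g, 0, -1) - shiftMat(g, 0, 1)) * 2 +
    (shiftMat(g, -1, -1) - shiftMat(g, -1, 1)) +
    (shiftMat(g, 1, -1) - shiftMat(g, 1, 1))
  gy <- (shiftMat(g, -1, 0) - shiftMat(g, 1, 0)) * 2 +
    (shiftMat(g, -1, -1) - shiftMat(g, 1, -1)) +
    (shiftMat(g, -1, 1) - shiftMat(g, 1, 1))
  mag <- abs(gx) + abs(gy)
  b <- 2L                                   # exclude undefined border gradients
  mag[c(seq_len(b), nrow(mag) - seq_len(b) + 1L), ] <- 0
  mag[, c(seq_len(b), ncol(mag) - seq_len(b) + 1L)] <- 0
  ang <- atan2(gy, gx)
  # quantize direction into 4 sectors and suppress non-maxima
  sector <- (round(ang / (pi / 4)) %% 4)
  nbr <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (sct in 0:3) {
    d <- nbr[[as.character(sct)]]
    m1 <- shiftMat(mag, d[1], d[2])
    m2 <- shiftMat(mag, -d[1], -d[2])
    keep <- keep | (sector == sct & mag >= m1 & mag >= m2)
  }
  magNms <- mag * keep
  strong <- magNms >= high
  weak <- magNms >= low
  # hysteresis: grow strong edges through connected weak pixels
  repeat {
    grown <- strong
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) grown <- grown | shiftMat(strong, dr, dc)
    grown <- grown & weak
    if (all(grown == strong)) break
    strong <- grown
  }
  strong
}
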