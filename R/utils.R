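## Internal helpers: condition classes, seeded evaluation, geometry and
## interpolation primitives shared across modules.

## Signal a classed error so callers can condition on the failure mode
## (e.g. tryCatch(..., degenerateHistogramError = ...)).
stopWith <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "phageNucProfilerError", "error", "condition"),
    list(message = message, call = call)
  ))
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hasSeed) {
      oldSeed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive a per-stage/per-scene seed from a global one by a fixed counter
## scheme; kept below 2^31 - 1 so it is always a valid R integer seed.
deriveSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(counter)) %% 2147483629 + 1)
}

## All user-facing coordinates are 0-based (row, col) with pixel-center
## semantics; matrices are addressed 1-based internally.
rcToIndex <- function(rc, dim) {
  as.integer((rc[, 2L]) * dim[1L] + rc[, 1L] + 1L)
}

indexToRc <- function(idx, dim) {
  idx0 <- as.integer(idx) - 1L
  cbind(row = idx0 %% dim[1L], col = idx0 %/% dim[1L])
}

## Bilinear interpolation of `img` at 0-based subpixel (row, col) positions,
## clamped to the image domain.
bilinearSample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(rows, 0), nr - 1)
  c <- pmin(pmax(cols, 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(c), nc - 2); c0 <- pmax(c0, 0)
  fr <- r - r0
  fc <- c - c0
  i00 <- img[cbind(r0 + 1, c0 + 1)]
  i10 <- img[cbind(r0 + 2, c0 + 1)]
  i01 <- img[cbind(r0 + 1, c0 + 2)]
  i11 <- img[cbind(r0 + 2, c0 + 2)]
  i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
}

## Minimum distance between two 2-D segments (a0-a1, b0-b1); used for the
## spherocylinder overlap test.
segmentDistance <- function(a0, a1, b0, b1) {
  pointSegDist <- function(p, s0, s1) {
    d <- s1 - s0
    l2 <- sum(d * d)
    t <- if (l2 == 0) 0 else max(0, min(1, sum((p - s0) * d) / l2))
    sqrt(sum((p - (s0 + t * d))^2))
  }
  segsIntersect <- function(p1, p2, p3, p4) {
    ccw <- function(a, b, c) {
      (c[2] - a[2]) * (b[1] - a[1]) - (b[2] - a[2]) * (c[1] - a[1])
    }
    d1 <- ccw(p3, p4, p1); d2 <- ccw(p3, p4, p2)
    d3 <- ccw(p1, p2, p3); d4 <- ccw(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (segsIntersect(a0, a1, b0, b1)) return(0)
  min(
    pointSegDist(a0, b0, b1), pointSegDist(a1, b0, b1),
    pointSegDist(b0, a0, a1), pointSegDist(b1, a0, a1)
  )
}

## Gaussian blur that degrades gracefully on images smaller than the
## default kernel support.
safeGblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  radius <- 2 * ceiling(3 * sigma) + 1
  maxRadius <- min(dim(m)) - !(min(dim(m)) %% 2)
  radius <- min(radius, maxRadius)
  if (radius < 3) return(m)
  out <- EBImage::gblur(m, sigma = sigma, radius = radius)
  matrix(EBImage::imageData(out), nrow(m), ncol(m))
}

## Run-length encode a sorted vector of 1-based linear pixel indices as
## (start, length) pairs; the plain-text sidecar format for masks.
rleEncodeIndices <- function(idx) {
  idx <- sort(as.integer(idx))
  if (length(idx) == 0L) return(matrix(integer(0), ncol = 2L))
  breaks <- which(diff(idx) != 1L)
  starts <- idx[c(1L, breaks + 1L)]
  ends <- idx[c(breaks, length(idx))]
  cbind(start = starts, length = ends - starts + 1L)
}

rleDecodeIndices <- function(runs) {
  runs <- matrix(as.integer(unlist(runs)), ncol = 2L, byrow = is.list(runs))
  if (nrow(runs) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(runs)), function(i) {
    seq.int(runs[i, 1L], length.out = runs[i, 2L])
  }))
}

## Largest connected component (8-connectivity) of a logical matrix;
## returns a logical matrix of the same shape, or NULL if empty.
largestComponent <- function(bw) {
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(bw), ncol(bw))
  if (max(lab) == 0L) return(NULL)
  areas <- tabulate(lab[lab > 0L])
  lab == which.max(areas)
}

## Perimeter and circularity of a single-component logical mask. The
## perimeter is the chain-code contour length (orthogonal steps count 1,
## diagonal steps sqrt(2)), which keeps 4*pi*area/perimeter^2 close to 1
## for digital disks and well below 1 for elongated blobs; the raw
## boundary-pixel count would overestimate circularity for rods.
maskShape <- function(bw) {
  area <- sum(bw)
  oc <- EBImage::ocontour(EBImage::bwlabel(bw))[[1L]]
  if (is.null(oc) || nrow(oc) < 3L) {
    return(list(area = area, perimeter = 0, circularity = NA_real_))
  }
  steps <- rbind(oc[-1L, , drop = FALSE], oc[1L, , drop = FALSE]) - oc
  perim <- sum(sqrt(rowSums(steps^2)))
  list(area = area, perimeter = perim,
       circularity = 4 * pi * area / perim^2)
}

## Crop helper: local logical mask of an ROI within its bounding box plus
## the 0-based offsets needed to map local coordinates back to the frame.
roiBox <- function(roi) {
  rc <- indexToRc(roi@pixels, roi@imageDim)
  r0 <- min(rc[, 1L]); r1 <- max(rc[, 1L])
  c0 <- min(rc[, 2L]); c1 <- max(rc[, 2L])
  mask <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  mask[cbind(rc[, 1L] - r0 + 1L, rc[, 2L] - c0 + 1L)] <- TRUE
  list(r0 = r0, c0 = c0, rows = (r0:r1) + 1L, cols = (c0:c1) + 1L,
       mask = mask)
}
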