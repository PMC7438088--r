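#' Segment round cells in a grayscale frame
#'
#' Robust segmentation for bright, roughly circular cells on a darker
#' background: background subtraction (median), Gaussian smoothing, a
#' global Otsu threshold, hole filling, connected-component labeling, and
#' a distance-map watershed to split touching objects. Objects touching
#' the image border and objects below \code{minPixels} are discarded.
#'
#' The global threshold is refined from the raw Otsu value to the midpoint
#' of the background and foreground class means, which centers the boundary
#' on the half-height of the (symmetric) cell edge profile and keeps the
#' measured radius accurate to a fraction of a pixel.
#'
#' @param frame Numeric matrix (grayscale image, any positive range).
#' @param pixelSize Pixel size, um/pixel.
#' @param sigma Gaussian smoothing sigma, px.
#' @param minPixels Minimum object size kept, px.
#' @param splitTouching Run the watershed split of touching objects.
#' @param frameIndex Frame index stored in the result.
#' @return A \code{\link{labeledMask}}. An empty or blank frame yields a
#'   mask with zero objects.
#' @export
segmentCells <- function(frame, pixelSize = 0.2, sigma = 1,
                         minPixels = 50, splitTouching = TRUE,
                         frameIndex = 1L) {
  stopifnot(is.matrix(frame))
  rng <- range(frame)
  if (diff(rng) < .Machine$double.eps)  # blank frame
    return(labeledMask(matrix(0L, nrow(frame), ncol(frame)),
                       pixelSize, frameIndex))
  img <- (frame - rng[1]) / diff(rng)
  img <- img - stats::median(img)
  img[img < 0] <- 0
  if (max(img) <= 0)
    return(labeledMask(matrix(0L, nrow(frame), ncol(frame)),
                       pixelSize, frameIndex))
  img <- img / max(img)
  sm <- EBImage::gblur(img, sigma = sigma)
  th0 <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  # refine to the midpoint of the plateau levels, sampled away from the
  # edge ring (erode/dilate): centers the boundary on the half-height of
  # a symmetric edge profile, keeping the radius sub-pixel accurate
  bw0 <- sm > th0
  brush <- EBImage::makeBrush(5, "disc")
  inner <- EBImage::erode(bw0, brush)
  outer <- EBImage::dilate(bw0, brush)
  th <- if (any(inner > 0) && any(outer == 0))
    (mean(sm[inner > 0]) + mean(sm[outer == 0])) / 2 else th0
  bw <- EBImage::fillHull(sm > th)
  lab <- if (splitTouching)
    EBImage::watershed(EBImage::distmap(bw), tolerance = 2)
  else EBImage::bwlabel(bw)
  lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"
  # drop border-touching and tiny objects, relabel contiguously
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  counts <- tabulate(lab[lab > 0L])
  drop <- union(setdiff(border, 0L), which(counts < minPixels))
  if (length(drop)) lab[lab %in% drop] <- 0L
  keep <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(keep))
    lab[] <- match(lab, keep, nomatch = 0L)
  labeledMask(lab, pixelSize, frameIndex)
}

# Ordered boundary polygon of one labeled object, simplified by
# Douglas-Peucker; returns list(P = perimeter, A = shoelace area) in px.
.boundaryPolygon <- function(bin, eps = 1) {
  oc <- EBImage::ocontour(EBImage::Image(bin))[[1]]
  n <- nrow(oc)
  if (n < 4) return(NULL)
  dp <- function(pts, eps) {
    m <- nrow(pts)
    if (m <= 2) return(pts)
    a <- pts[1, ]; b <- pts[m, ]; ab <- b - a
    L <- sqrt(sum(ab^2))
    d <- if (L == 0)
      sqrt(rowSums((pts - matrix(a, m, 2, byrow = TRUE))^2))
    else abs((pts[, 1] - a[1]) * ab[2] - (pts[, 2] - a[2]) * ab[1]) / L
    i <- which.max(d)
    if (d[i] <= eps) return(pts[c(1, m), , drop = FALSE])
    left <- dp(pts[1:i, , drop = FALSE], eps)
    rbind(left[-nrow(left), , drop = FALSE],
          dp(pts[i:m, , drop = FALSE], eps))
  }
  # split the closed contour at the point farthest from the start
  d0 <- sqrt(rowSums((oc - matrix(oc[1, ], n, 2, byrow = TRUE))^2))
  k <- which.max(d0)
  p1 <- dp(oc[1:k, , drop = FALSE], eps)
  p2 <- dp(rbind(oc[k:n, , drop = FALSE], oc[1, , drop = FALSE]), eps)
  poly <- rbind(p1[-nrow(p1), , drop = FALSE],
                p2[-nrow(p2), , drop = FALSE])
  x <- poly[, 1]; y <- poly[, 2]
  P <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  A <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  list(P = P, A = A)
}

#' Circularity (isoperimetric quotient) of a mask object
#'
#' Circularity is computed as 4 pi A / P^2 on a simplified polygon fitted
#' to the traced object boundary (Douglas-Peucker, default tolerance 1
#' px), which removes the rasterization staircase so that disks score
#' near 1 and squares near pi/4. The score is clipped to at most 1 and is
#' invariant under rotation and (asymptotically) scaling.
#'
#' @param bin Logical or 0/1 matrix containing a single object.
#' @param eps Douglas-Peucker tolerance, px.
#' @return Circularity in (0, 1], or NA for degenerate (< 4 boundary
#'   point) objects.
#' @examples
#' m <- matrix(0L, 60, 60); m[20:40, 20:40] <- 1L
#' circularity(m)  # ~ pi/4
#' @export
circularity <- function(bin, eps = 1) {
  if (sum(bin > 0) == 0) stop("object area must be positive")
  bp <- .boundaryPolygon(bin > 0, eps)
  if (is.null(bp) || bp$P <= 0 || bp$A <= 0) return(NA_real_)
  min(1, 4 * pi * bp$A / bp$P^2)
}

#' Per-object shape metrics of a labeled mask
#'
#' Computes, per labeled object: pixel area (um^2), perimeter from the
#' simplified boundary polygon plus the half-pixel boundary offset (um),
#' equivalent-circle radius a = sqrt(area / pi) (um), circularity (see
#' \code{\link{circularity}}), ellipse aspect ratio (major/minor axis
#' from image moments), and centroid (um).
#'
#' @param mask A \code{\link{labeledMask}}.
#' @return A data.frame, one row per object.
#' @export
shapeMetrics <- function(mask) {
  stopifnot(is(mask, "LabeledMask"))
  lab <- mask@labels
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  px <- mask@pixelSize
  if (!length(ids))
    return(data.frame(cell_id = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), radius_um = numeric(),
                      circularity = numeric(), aspect_ratio = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      frame = integer()))
  mom <- EBImage::computeFeatures.moment(lab)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                       dimnames = list(NULL, names(mom)))
  rows <- lapply(ids, function(id) {
    bin <- lab == id
    npx <- sum(bin)
    bp <- .boundaryPolygon(bin)
    if (is.null(bp)) return(NULL)  # degenerate object, skipped
    major <- mom[id, "m.majoraxis"]
    ecc <- mom[id, "m.eccentricity"]
    minor <- major * sqrt(1 - ecc^2)
    data.frame(cell_id = id, area_um2 = npx * px^2,
               perimeter_um = (bp$P + pi) * px,
               radius_um = sqrt(npx / pi) * px,
               circularity = min(1, 4 * pi * bp$A / bp$P^2),
               aspect_ratio = if (minor > 0) major / minor else Inf,
               x_um = mom[id, "m.cx"] * px, y_um = mom[id, "m.cy"] * px,
               frame = mask@frame)
  })
  do.call(rbind, rows)
}

#' Equivalent radius and spherical volume per cell
#'
#' Equivalent-circle radius a = sqrt(area / pi) from the projected mask
#' area, and the sphere-assumption volume V = (4/3) pi a^3.
#'
#' @param mask A \code{\link{labeledMask}}.
#' @return A data.frame with cell_id, radius_um, volume_m3.
#' @export
radiusAndVolume <- function(mask) {
  sm <- shapeMetrics(mask)
  data.frame(cell_id = sm$cell_id, radius_um = sm$radius_um,
             volume_m3 = 4 / 3 * pi * (sm$radius_um * 1e-6)^3,
             frame = sm$frame)
}

#' Link cell detections across frames into trajectories
#'
#' Greedy nearest-centroid linking: detections in consecutive frames are
#' matched closest-first under a maximum displacement gate; unmatched
#' detections start new tracks and tracks without a match end. Cells are
#' near-stationary in the osmotic assay, so the default gate is 10
#' px/frame.
#'
#' @param masks A list of \code{\link{labeledMask}} (>= 2 frames) in
#'   temporal order.
#' @param maxDisplacement Maximum centroid displacement between frames,
#'   px.
#' @return A data.frame with track_id, frame, cell_id (label within the
#'   frame), x_um, y_um, radius_um.
#' @export
trackCells <- function(masks, maxDisplacement = 10) {
  if (length(masks) < 2) stop("need at least 2 frames to track")
  px <- masks[[1]]@pixelSize
  gate <- maxDisplacement * px
  dets <- lapply(seq_along(masks), function(i) {
    sm <- shapeMetrics(masks[[i]])
    if (nrow(sm)) sm$frame <- i
    sm
  })
  tracks <- list()  # each: list(pts = data.frame, active = TRUE)
  for (i in seq_along(dets)) {
    d <- dets[[i]]
    activeIdx <- which(vapply(tracks, function(t) t$active, logical(1)))
    used <- rep(FALSE, if (is.null(d)) 0 else nrow(d))
    if (length(activeIdx) && !is.null(d) && nrow(d)) {
      last <- t(vapply(tracks[activeIdx], function(t) {
        p <- t$pts[nrow(t$pts), ]; c(p$x_um, p$y_um)
      }, numeric(2)))
      D <- outer(seq_len(nrow(last)), seq_len(nrow(d)),
                 Vectorize(function(a, b)
                   sqrt((last[a, 1] - d$x_um[b])^2 +
                        (last[a, 2] - d$y_um[b])^2)))
      repeat {
        m <- which(D == min(D), arr.ind = TRUE)[1, ]
        if (D[m[1], m[2]] > gate) break
        ti <- activeIdx[m[1]]
        tracks[[ti]]$pts <- rbind(tracks[[ti]]$pts, d[m[2], ])
        used[m[2]] <- TRUE
        D[m[1], ] <- Inf; D[, m[2]] <- Inf
        if (all(!is.finite(D))) break
      }
      matched <- vapply(activeIdx, function(ti)
        tracks[[ti]]$pts$frame[nrow(tracks[[ti]]$pts)] == i, logical(1))
      for (ti in activeIdx[!matched]) tracks[[ti]]$active <- FALSE
    } else if (length(activeIdx)) {
      for (ti in activeIdx) tracks[[ti]]$active <- FALSE
    }
    if (!is.null(d) && nrow(d))
      for (j in which(!used))
        tracks[[length(tracks) + 1]] <- list(pts = d[j, ], active = TRUE)
  }
  out <- do.call(rbind, lapply(seq_along(tracks), function(k) {
    p <- tracks[[k]]$pts
    data.frame(track_id = k, frame = p$frame, cell_id = p$cell_id,
               x_um = p$x_um, y_um = p$y_um, radius_um = p$radius_um)
  }))
  out[order(out$track_id, out$frame), ]
}

#' Gate a feature table down to single cells
#'
#' Removes rows failing any enabled gate (area bounds, aspect ratio,
#' focus, intensity range) and reports per-gate removal counts. Gating is
#' idempotent.
#'
#' @param metrics A feature data.frame (from \code{\link{shapeMetrics}},
#'   optionally augmented with \code{focus} and \code{total_intensity}
#'   columns).
#' @param gate A \code{\link{gateConfig}}.
#' @return The filtered data.frame, with a \code{"removed"} attribute
#'   holding per-gate counts.
#' @export
gateSingleCells <- function(metrics, gate = gateConfig()) {
  stopifnot(is(gate, "GateConfig"))
  keep <- rep(TRUE, nrow(metrics))
  removed <- c(fragment = 0L, cluster = 0L, aspect = 0L, focus = 0L,
               intensity = 0L)
  small <- metrics$area_um2 < gate@minArea
  removed["fragment"] <- sum(small & keep); keep <- keep & !small
  big <- metrics$area_um2 > gate@maxArea
  removed["cluster"] <- sum(big & keep); keep <- keep & !big
  elong <- metrics$aspect_ratio > gate@maxAspect
  removed["aspect"] <- sum(elong & keep); keep <- keep & !elong
  if (!is.na(gate@minFocus) && "focus" %in% names(metrics)) {
    soft <- metrics$focus < gate@minFocus
    removed["focus"] <- sum(soft & keep); keep <- keep & !soft
  }
  if (!all(is.na(gate@intensityRange)) &&
      "total_intensity" %in% names(metrics)) {
    oor <- metrics$total_intensity < gate@intensityRange[1] |
      metrics$total_intensity > gate@intensityRange[2]
    removed["intensity"] <- sum(oor & keep, na.rm = TRUE)
    keep <- keep & !oor
  }
  out <- metrics[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Sharpness score of an image region
#'
#' Variance-of-Laplacian style focus metric used by the optional focus
#' gate: the variance of the 4-neighbour Laplacian within the region.
#'
#' @param image Numeric matrix.
#' @param bin Optional logical mask restricting the region.
#' @return A non-negative sharpness score.
#' @export
focusScore <- function(image, bin = NULL) {
  n <- nrow(image); m <- ncol(image)
  lap <- 4 * image[2:(n - 1), 2:(m - 1)] -
    image[1:(n - 2), 2:(m - 1)] - image[3:n, 2:(m - 1)] -
    image[2:(n - 1), 1:(m - 2)] - image[2:(n - 1), 3:m]
  if (!is.null(bin)) lap <- lap[bin[2:(n - 1), 2:(m - 1)]]
  stats::var(as.vector(lap))
}

#' Size-normalized marker intensity
#'
#' Total in-mask intensity divided by mask area (a.u./um^2); when a
#' control-group mean is supplied the value is additionally reported
#' normalized to it, so the control group averages 1 by construction.
#'
#' @param image Numeric matrix (fluorescence channel).
#' @param mask A \code{\link{labeledMask}} aligned with the image.
#' @param controlMean Optional control-group mean per-area intensity.
#' @return A data.frame with cell_id, total_intensity,
#'   intensity_per_um2 and (when \code{controlMean} is given)
#'   norm_intensity.
#' @export
normalizedIntensity <- function(image, mask, controlMean = NULL) {
  stopifnot(is(mask, "LabeledMask"))
  if (!all(dim(image) == dim(mask@labels)))
    stop("image and mask dimensions differ")
  lab <- mask@labels
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  px2 <- mask@pixelSize^2
  out <- do.call(rbind, lapply(ids, function(id) {
    tot <- sum(image[lab == id])
    area <- sum(lab == id) * px2
    data.frame(cell_id = id, total_intensity = tot,
               intensity_per_um2 = tot / area)
  }))
  if (!is.null(controlMean)) {
    if (controlMean == 0) stop("control mean intensity is zero")
    out$norm_intensity <- out$intensity_per_um2 / controlMean
  }
  out
}

#' Nuclear colocalization similarity score
#'
#' Log-transformed Pearson correlation of in-mask pixel intensities
#' between two aligned channels (Fisher z transform atanh(rho)),
#' symmetric in channel order. Large positive scores indicate nuclear
#' translocation of the marker. A constant channel has undefined
#' correlation and yields an NA score with a flag.
#'
#' @param channelA,channelB Numeric matrices (aligned channels).
#' @param mask A \code{\link{labeledMask}}; the score is computed per
#'   labeled object.
#' @param rhoCap Correlations are clipped to +/- this value before the
#'   log transform so perfectly identical channels give a large finite
#'   score.
#' @return A data.frame with cell_id, rho, similarity, flag.
#' @export
nuclearSimilarity <- function(channelA, channelB, mask,
                              rhoCap = 1 - 1e-6) {
  stopifnot(is(mask, "LabeledMask"))
  if (!all(dim(channelA) == dim(channelB)) ||
      !all(dim(channelA) == dim(mask@labels)))
    stop("channels and mask dimensions differ")
  lab <- mask@labels
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (!length(ids)) stop("mask is empty")
  do.call(rbind, lapply(ids, function(id) {
    a <- channelA[lab == id]; b <- channelB[lab == id]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      return(data.frame(cell_id = id, rho = NA_real_,
                        similarity = NA_real_, flag = "constant_channel"))
    rho <- stats::cor(a, b)
    data.frame(cell_id = id, rho = rho,
               similarity = atanh(max(-rhoCap, min(rhoCap, rho))),
               flag = "")
  }))
}
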