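#' Simulate measured volume traces for a cell population
#'
#' Forward-simulates each cell of a population through the osmotic
#' protocol with its per-step Lp truths and applies multiplicative
#' measurement noise on the radius (volume noise is the cube), emulating
#' segmentation jitter at 0.5 Hz sampling.
#'
#' @param population A data.frame from \code{\link{samplePopulation}}
#'   (columns lp_hyper, lp_hypo, radius_um, phir). When the protocol has
#'   more steps than hyper/hypo, lp_hyper is recycled.
#' @param protocol An \code{\link{OsmoticProtocol}}.
#' @param radiusNoiseCV Coefficient of variation of the per-frame
#'   multiplicative radius noise (0 = noiseless).
#' @param seed Integer seed.
#' @param constants A \code{\link{modelConstants}}.
#' @param samplingInterval Sampling interval, s.
#' @return A list with \code{traces} (named list of
#'   \code{CellVolumeTrace}) and \code{truth} (the population table).
#' @export
makeVolumeTraces <- function(population, protocol = defaultProtocol(),
                             radiusNoiseCV = 0, seed = 1,
                             constants = modelConstants(),
                             samplingInterval = 2) {
  set.seed(seed)
  labels <- stepLabels(protocol)
  traces <- lapply(seq_len(nrow(population)), function(i) {
    p <- population[i, ]
    Lp <- vapply(labels, function(l) {
      if (startsWith(l, "hypo") && !is.na(p$lp_hypo)) p$lp_hypo
      else p$lp_hyper
    }, numeric(1))
    tr <- simulateVolumeResponse(
      cellParams(Lp = unname(Lp), phir = p$phir,
                 refRadius = p$radius_um * 1e-6),
      protocol, constants, samplingInterval, cellId = p$cell_id)
    if (radiusNoiseCV > 0) {
      eps <- stats::rnorm(length(tr@volume), 0, radiusNoiseCV)
      tr@volume <- tr@volume * (1 + eps)^3
    }
    tr
  })
  names(traces) <- population$cell_id
  list(traces = traces, truth = population)
}

#' Render a synthetic image sequence of round cells
#'
#' Draws each cell as a bright disk with a soft (sigmoidal) edge on a
#' noisy background, placed without overlap, one frame per time point.
#' Radii may shrink/swell over frames when per-frame radii are supplied.
#' This emulates the appearance of round cells in DIC-like frames well
#' enough to exercise segmentation and tracking; it makes no attempt at
#' real DIC optics.
#'
#' @param radii_um Either a numeric vector (one static radius per cell)
#'   or a matrix cells x frames of radii in um.
#' @param nFrames Number of frames when \code{radii_um} is a vector.
#' @param pixelSize Pixel size, um/pixel.
#' @param fieldSize Field side length, px.
#' @param background Background level in [0, 1).
#' @param noiseSD SD of additive Gaussian pixel noise.
#' @param edgeWidth Soft-edge width, px.
#' @param margin Minimum spacing between cell edges and to the border,
#'   px.
#' @param seed Integer seed.
#' @return A list with \code{frames} (list of numeric matrices) and
#'   \code{truth} (data.frame cell_id, frame, x_px, y_px, radius_um).
#'   Raises an error when the requested cells cannot be placed.
#' @export
renderFrameSequence <- function(radii_um, nFrames = 1, pixelSize = 0.2,
                                fieldSize = 512, background = 0.1,
                                noiseSD = 0.02, edgeWidth = 1.5,
                                margin = 8, seed = 1) {
  if (is.matrix(radii_um)) {
    R <- radii_um
  } else {
    R <- matrix(radii_um, nrow = length(radii_um), ncol = nFrames)
  }
  nc <- nrow(R); nf <- ncol(R)
  set.seed(seed)
  rpx <- R / pixelSize
  rmax <- apply(rpx, 1, max)
  # random non-overlapping placement with retry
  centers <- matrix(NA_real_, nc, 2)
  for (i in seq_len(nc)) {
    ok <- FALSE
    for (try in 1:500) {
      cx <- stats::runif(1, rmax[i] + margin, fieldSize - rmax[i] - margin)
      cy <- stats::runif(1, rmax[i] + margin, fieldSize - rmax[i] - margin)
      if (i == 1 || all(sqrt((centers[seq_len(i - 1), 1] - cx)^2 +
                             (centers[seq_len(i - 1), 2] - cy)^2) >
                        rmax[seq_len(i - 1)] + rmax[i] + margin)) {
        centers[i, ] <- c(cx, cy); ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place ", nc, " cells in a ", fieldSize,
                  " px field without overlap; enlarge the field")
  }
  xg <- matrix(seq_len(fieldSize), fieldSize, fieldSize)
  yg <- t(xg)
  frames <- vector("list", nf)
  truth <- list()
  for (f in seq_len(nf)) {
    img <- matrix(background, fieldSize, fieldSize)
    for (i in seq_len(nc)) {
      d <- sqrt((xg - centers[i, 1])^2 + (yg - centers[i, 2])^2)
      img <- img + 0.8 / (1 + exp((d - rpx[i, f]) / edgeWidth))
      truth[[length(truth) + 1]] <-
        data.frame(cell_id = i, frame = f, x_px = centers[i, 1],
                   y_px = centers[i, 2], radius_um = R[i, f])
    }
    img <- img + matrix(stats::rnorm(fieldSize^2, 0, noiseSD),
                        fieldSize, fieldSize)
    frames[[f]] <- pmin(pmax(img, 0), 1)
  }
  list(frames = frames, truth = do.call(rbind, truth))
}

#' Generate star-like masks with controlled circularity ordering
#'
#' Polar shapes r(theta) = a (1 + amplitude * cos(k theta)): amplitude 0
#' gives disks, increasing amplitude gives increasingly lobed shapes with
#' strictly lower circularity, emulating cells developing radial
#' processes.
#'
#' @param n Number of masks.
#' @param amplitude Protrusion amplitude in [0, 1).
#' @param k Number of lobes.
#' @param radius_px Base radius a, px.
#' @param seed Seed for random rotation of each shape.
#' @return A list of \code{\link{labeledMask}} (one object each).
#' @export
makeShapeMasks <- function(n, amplitude = 0, k = 5, radius_px = 45,
                           seed = 1) {
  stopifnot(n >= 1)
  if (amplitude >= 1)
    stop("amplitude must be < 1 (the shape self-intersects at r <= 0)")
  set.seed(seed)
  side <- ceiling(2 * radius_px * (1 + amplitude)) + 21
  c0 <- (side + 1) / 2
  xg <- matrix(seq_len(side), side, side); yg <- t(xg)
  lapply(seq_len(n), function(i) {
    rot <- stats::runif(1, 0, 2 * pi)
    th <- atan2(yg - c0, xg - c0)
    r <- sqrt((xg - c0)^2 + (yg - c0)^2)
    bin <- r <= radius_px * (1 + amplitude * cos(k * (th - rot)))
    labeledMask(matrix(as.integer(bin), side, side), pixelSize = 0.2,
                frame = i)
  })
}

#' Generate synthetic Hertz force-indentation curves
#'
#' Forward Hertz curves with a flat pre-contact baseline region, a
#' contact-point offset along the displacement axis, and additive
#' Gaussian force noise scaled to the maximum force.
#'
#' @param E Elastic modulus truths, Pa (one curve per value).
#' @param tipRadius Tip radius, m.
#' @param maxIndent Maximum indentation beyond contact, m.
#' @param contactOffset Contact-point offset(s), m (recycled).
#' @param baselineLength Length of the pre-contact baseline region, m.
#' @param noiseSD Force noise SD as a fraction of the maximum force.
#' @param nPoints Samples per curve.
#' @param nu Poisson ratio used for generation.
#' @param seed Integer seed.
#' @return A named list of \code{\link{forceCurve}}; each carries a
#'   \code{"truth"} attribute with the generating E and contact offset.
#' @export
makeForceCurves <- function(E, tipRadius = 3e-6, maxIndent = 1e-6,
                            contactOffset = 0, baselineLength = 1e-7,
                            noiseSD = 0, nPoints = 400, nu = 0.5,
                            seed = 1) {
  stopifnot(all(E > 0))
  set.seed(seed)
  off <- rep_len(contactOffset, length(E))
  out <- lapply(seq_along(E), function(i) {
    z0 <- baselineLength + off[i]
    z <- seq(0, z0 + maxIndent, length.out = nPoints)
    delta <- pmax(0, z - z0)
    Fr <- hertzForce(E[i], delta, tipRadius, nu)
    if (noiseSD > 0)
      Fr <- Fr + stats::rnorm(nPoints, 0, noiseSD * max(Fr))
    cv <- forceCurve(z, Fr, tipRadius)
    attr(cv, "truth") <- list(E = E[i], contact = z0)
    cv
  })
  names(out) <- sprintf("curve_%03d", seq_along(E))
  out
}

#' Generate a correlated two-channel image pair with a mask
#'
#' Two Gaussian random fields whose in-mask pixelwise Pearson correlation
#' targets \code{rho}, plus a centered disk mask, emulating a marker
#' channel and a nuclear stain for colocalization scoring.
#'
#' @param rho Target correlation in [-1, 1].
#' @param size Image side length, px.
#' @param maskRadius Radius of the disk mask, px.
#' @param seed Integer seed.
#' @return A list with \code{channelA}, \code{channelB} (matrices) and
#'   \code{mask} (a \code{\link{labeledMask}}).
#' @export
makeChannelPair <- function(rho, size = 128, maskRadius = size / 3,
                            seed = 1) {
  if (rho < -1 || rho > 1) stop("rho must lie in [-1, 1]")
  set.seed(seed)
  A <- matrix(stats::rnorm(size^2), size, size)
  Nind <- matrix(stats::rnorm(size^2), size, size)
  B <- rho * A + sqrt(1 - rho^2) * Nind
  c0 <- (size + 1) / 2
  xg <- matrix(seq_len(size), size, size); yg <- t(xg)
  bin <- (xg - c0)^2 + (yg - c0)^2 <= maskRadius^2
  list(channelA = A, channelB = B,
       mask = labeledMask(matrix(as.integer(bin), size, size)))
}
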