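# Shared fixtures: small rasterized shapes and canned traces, all built in
# code at test time.

rasterDisk <- function(r, side = 2 * r + 21, cx = (side + 1) / 2,
                       cy = cx) {
  xg <- matrix(seq_len(side), side, side)
  yg <- t(xg)
  matrix(as.integer((xg - cx)^2 + (yg - cy)^2 <= r^2), side, side)
}

rasterSquare <- function(s, side = s + 20) {
  m <- matrix(0L, side, side)
  i0 <- (side - s) %/% 2 + 1
  m[i0:(i0 + s - 1), i0:(i0 + s - 1)] <- 1L
  m
}

# Two overlapping disks (a doublet / fused pair).
rasterDoublet <- function(r, sep = round(1.2 * r), side = 2 * r + sep + 21) {
  xg <- matrix(seq_len(side), side, side)
  yg <- t(xg)
  c1 <- (side - sep) / 2; c2 <- c1 + sep
  cy <- side / 2
  bin <- ((xg - c1)^2 + (yg - cy)^2 <= r^2) |
         ((xg - c2)^2 + (yg - cy)^2 <= r^2)
  matrix(as.integer(bin), side, side)
}

# Exponential relaxation trace towards a known plateau ratio.
plateauTrace <- function(ratio, Vr = 3e-15, tau = 40, duration = 300,
                         dt = 2, label = "hyper") {
  tt <- seq(0, duration, dt)
  V <- Vr * (ratio + (1 - ratio) * exp(-tt / tau))
  cellVolumeTrace("synthcell", tt, V, rep(label, length(tt)))
}

untreatedParams <- function(Lp = 7.2e-14, phir = 0.6)
  cellParams(Lp = Lp, phir = phir, refRadius = 9.1e-6)

# Radii (um) of planted single cells: normal draw truncated to the
# single-cell size range so every planted single passes the size gates.
singleCellRadii <- function(n, mean = 9.1, sd = 1.3, lo = 6, hi = 13) {
  out <- numeric(0)
  while (length(out) < n) {
    r <- rnorm(2 * n, mean, sd)
    out <- c(out, r[r > lo & r < hi])
  }
  out[seq_len(n)]
}
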