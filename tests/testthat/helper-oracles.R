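# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation.

# L1 (city-block) distance to the mask complement by value iteration over
# the lattice; the complement includes everything outside the array.
# Independent of the erosion-based shell code.
l1DistanceToComplement <- function(mask) {
  d <- dim(mask)
  pd <- d + 2L
  pmask <- array(FALSE, pd)
  pmask[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)] <- mask
  dist <- array(0, pd)
  dist[pmask] <- Inf
  shift <- function(a, dx, dy, dz) {
    out <- array(Inf, dim(a))
    sx <- max(1, 1 + dx):min(pd[1], pd[1] + dx)
    sy <- max(1, 1 + dy):min(pd[2], pd[2] + dy)
    sz <- max(1, 1 + dz):min(pd[3], pd[3] + dz)
    out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
    out
  }
  repeat {
    upd <- pmin(dist,
                shift(dist, 1, 0, 0) + 1, shift(dist, -1, 0, 0) + 1,
                shift(dist, 0, 1, 0) + 1, shift(dist, 0, -1, 0) + 1,
                shift(dist, 0, 0, 1) + 1, shift(dist, 0, 0, -1) + 1)
    if (identical(upd, dist)) break
    dist <- upd
  }
  dist[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)]
}

# brute-force mean Euclidean distance from each TRUE pixel of `region` to
# the nearest TRUE pixel of `points` (2D), in pixels
bruteForceMeanNearest <- function(points, region) {
  pc <- which(points, arr.ind = TRUE)
  rc <- which(region, arr.ind = TRUE)
  dmin <- rep(Inf, nrow(rc))
  for (v in seq_len(nrow(pc)))
    dmin <- pmin(dmin, sqrt((rc[, 1] - pc[v, 1])^2 + (rc[, 2] - pc[v, 2])^2))
  mean(dmin)
}

# one-way ANOVA from first principles (sums of squares), as the
# independent reference for the oneway.test-based implementation
handAnova <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# trapezoid-rule convolution oracle for the extended Kety model on a fine
# time grid (recursive update, exact for the trapezoid rule), vectorised
# over parameter draws. times in seconds; rates per minute.
trapzKetyOracle <- function(ktrans, ve, vp, aif, times, dtSec = 0.01) {
  nD <- length(ktrans)
  kep <- ktrans / ve
  tmax <- max(times)
  grid <- seq(aif@onsetTime, tmax, by = dtSec)
  cpGrid <- aifConcentration(aif, grid)
  dtMin <- dtSec / 60
  decay <- exp(-kep * dtMin)
  out <- matrix(0, nD, length(times))
  # frame times mapped onto grid indices (times are multiples of dtSec)
  frameIdx <- round((times - aif@onsetTime) / dtSec) + 1
  J <- rep(0, nD)
  hit <- which(frameIdx == 1)
  if (length(hit)) out[, hit] <- 0
  for (g in 2:length(grid)) {
    J <- J * decay + dtMin / 2 * (cpGrid[g] + cpGrid[g - 1] * decay)
    hit <- which(frameIdx == g)
    if (length(hit)) out[, hit] <- J
  }
  cpT <- aifConcentration(aif, times)
  res <- matrix(0, nD, length(times))
  for (i in seq_len(nD)) res[i, ] <- vp[i] * cpT + ktrans[i] * out[i, ]
  res[, times < aif@onsetTime] <- 0
  res
}

# wrap a matrix of per-voxel concentration curves (voxels x frames) as a
# ConcentrationSeries on an n x 1 x 1 grid
curvesAsConcentration <- function(curves, acq, relaxivity = 3.9) {
  n <- nrow(curves); nf <- ncol(curves)
  conc <- array(0, c(n, 1, 1, nf))
  conc[, 1, 1, ] <- curves
  new("ConcentrationSeries", conc = conc,
      valid = array(TRUE, c(n, 1, 1, nf)),
      baselineR1 = array(1000 / 1800, c(n, 1, 1)),
      relaxivity = relaxivity, frameTimes = tumorquant::frameTimes(acq),
      acq = acq)
}

# test-local stepwise studentized-range procedure, written independently
# (recursive formulation) to cross-check the package's iterative one
snkOracle <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  means <- sort(tapply(values, groups, mean))
  k <- length(means)
  n <- table(groups)
  nh <- k / sum(1 / n)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfW <- length(values) - k
  mse <- ssw / dfW
  sig <- matrix(NA, k, k)
  testSpan <- function(i, j) {
    # returns TRUE if span i..j significant; recursion enforces containment
    r <- j - i + 1
    if (r < 2) return(FALSE)
    q <- (means[j] - means[i]) / sqrt(mse / nh)
    own <- stats::ptukey(q, r, dfW, lower.tail = FALSE) < alpha
    if (r == k) return(own)
    # blocked unless some strictly containing span is significant chain up
    containers <- list()
    if (i > 1) containers <- c(containers, list(c(i - 1, j)))
    if (j < k) containers <- c(containers, list(c(i, j + 1)))
    anyContainerSig <- any(vapply(containers, function(ij)
      testSpan(ij[1], ij[2]), logical(1)))
    own && anyContainerSig
  }
  pairs <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    pairs[[length(pairs) + 1]] <- data.frame(
      group1 = names(means)[i], group2 = names(means)[j],
      significant = testSpan(i, j))
  do.call(rbind, pairs)
}
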