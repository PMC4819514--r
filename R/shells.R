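#' @include AllClasses.R
NULL

# shift a 3D logical array by (dx, dy, dz), filling with FALSE
shift3d <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (!length(sx) || !length(sy) || !length(sz)) return(out)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# neighbour offsets of the 3D structuring element (excluding the centre)
seOffsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6"  = nz == 1,
    "18" = nz >= 1 & nz <= 2,
    "26" = nz >= 1,
    stop("connectivity must be 6, 18 or 26"))
  as.matrix(g[keep, , drop = FALSE])
}

# one binary erosion: a voxel survives iff all its structuring-element
# neighbours (outside the array counts as background) are in the mask
erodeOnce <- function(mask, offsets) {
  out <- mask
  for (r in seq_len(nrow(offsets))) {
    out <- out & shift3d(mask, -offsets[r, 1], -offsets[r, 2], -offsets[r, 3])
    if (!any(out)) break
  }
  out
}

#' Segment a tumor mask into single-voxel-thick concentric shells
#'
#' Iterated binary erosion of the 3D tumor mask: shell k is the set of
#' voxels removed at erosion step k, so shell 1 is the outermost voxel
#' layer and indices increase inward until the mask is exhausted. Every
#' in-mask voxel receives exactly one shell index and voxel count is
#' conserved. Erosion is lattice-based (voxel anisotropy is ignored).
#'
#' @param mask non-empty 3D logical array
#' @param connectivity structuring element: 6 (faces), 18 (faces + edges)
#'   or 26 (full neighbourhood)
#' @return a [ShellLabeling-class]
#' @examples
#' cube <- array(TRUE, c(3, 3, 3))
#' sl <- erodeShells(cube)        # 26 surface voxels + 1 centre voxel
#' table(shellIndex(sl)[cube])
#' @export
erodeShells <- function(mask, connectivity = 6L) {
  if (length(dim(mask)) != 3L) stop("mask must be 3D")
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  offsets <- seOffsets(connectivity)
  shellIdx <- array(0L, dim(mask))
  cur <- mask
  k <- 0L
  while (any(cur)) {
    k <- k + 1L
    nxt <- erodeOnce(cur, offsets)
    shellIdx[cur & !nxt] <- k
    cur <- nxt
  }
  new("ShellLabeling", shellIndex = shellIdx, nShells = k,
      connectivity = as.integer(connectivity))
}

#' Split a shelled tumor into periphery and core Ktrans averages
#'
#' Accumulates shells outermost-first until the cumulative voxel count
#' first reaches one third of the in-mask voxels; those shells are the
#' tumor periphery (outer one-third of voxels) and the remaining shells the
#' core (inner two-thirds). Returns the mean Ktrans of fit-OK voxels in
#' each set. The split is resolved at whole-shell granularity.
#'
#' @param shells a [ShellLabeling-class]
#' @param pk a [PKParameterMap-class] on the same grid
#' @return a list with `peripheryKtrans`, `coreKtrans` (NA with a warning
#'   when every shell fell in the periphery), `peripheryShells` (indices),
#'   and per-set fit-OK voxel counts
#' @export
peripheryCoreSplit <- function(shells, pk) {
  stopifnot(is(shells, "ShellLabeling"), is(pk, "PKParameterMap"))
  si <- shells@shellIndex
  if (!identical(dim(si), dim(pk@ktrans)))
    stop("shells and parameter map must share one grid")
  counts <- tabulate(si[si > 0L], nbins = shells@nShells)
  nTot <- sum(counts)
  cum <- cumsum(counts)
  kSplit <- which(cum >= nTot / 3)[1]
  periShells <- seq_len(kSplit)
  inPeri <- si > 0L & si <= kSplit
  inCore <- si > kSplit
  okP <- inPeri & pk@fitOk
  okC <- inCore & pk@fitOk
  peri <- if (any(okP)) mean(pk@ktrans[okP]) else NA_real_
  core <- if (any(inCore)) {
    if (any(okC)) mean(pk@ktrans[okC]) else NA_real_
  } else {
    warning("no core voxels: every shell fell in the periphery")
    NA_real_
  }
  list(peripheryKtrans = peri, coreKtrans = core,
       peripheryShells = periShells,
       nPeriphery = sum(okP), nCore = sum(okC))
}

#' Per-shell voxel counts and Ktrans summaries
#'
#' @param shells a [ShellLabeling-class]
#' @param pk a [PKParameterMap-class] on the same grid
#' @return a data.frame with one row per shell: voxel count, fit-OK count,
#'   mean and median Ktrans over fit-OK voxels
#' @export
shellSummary <- function(shells, pk) {
  si <- shells@shellIndex
  do.call(rbind, lapply(seq_len(shells@nShells), function(k) {
    inK <- si == k
    okK <- inK & pk@fitOk
    data.frame(shell = k, nVoxels = sum(inK), nFitOk = sum(okK),
               meanKtrans = if (any(okK)) mean(pk@ktrans[okK]) else NA_real_,
               medianKtrans = if (any(okK)) stats::median(pk@ktrans[okK]) else NA_real_)
  }))
}
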