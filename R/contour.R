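# Moore boundary tracing. The perimeter convention of the whole package is
# defined here: the closed 8-connected contour through boundary-pixel
# centers, axial steps counting 1 and diagonal steps sqrt(2). Thin structures
# are traced out-and-back (a 1 x k line has perimeter 2(k-1)); an isolated
# pixel has a degenerate two-vertex contour and is assigned perimeter 1.

# Clockwise neighbor order starting north: N NE E SE S SW W NW
.mooreDirs <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                       1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                     ncol = 2L, byrow = TRUE)

# Trace one 8-connected component. `mask` is a logical matrix containing the
# component (possibly among others); tracing starts at the component's first
# pixel in raster-scan (row-major) order and follows only pixels of value
# TRUE, so callers pass a mask of the single component. Returns a closed
# (row, col) matrix with first vertex == last vertex.
mooreTraceComponent <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  # first TRUE pixel in row-major order
  idx <- which(t(mask))
  if (!length(idx)) return(matrix(integer(), ncol = 2L))
  r0 <- (idx[1L] - 1L) %/% W + 1L
  c0 <- (idx[1L] - 1L) %% W + 1L
  fg <- function(r, c) r >= 1L && r <= H && c >= 1L && c <= W && mask[r, c]

  hasNb <- FALSE
  for (k in 1:8)
    if (fg(r0 + .mooreDirs[k, 1L], c0 + .mooreDirs[k, 2L])) { hasNb <- TRUE; break }
  if (!hasNb)
    return(matrix(c(r0, c0, r0, c0), ncol = 2L, byrow = TRUE))

  npix <- sum(mask)
  maxSteps <- 8L * npix + 8L
  path <- matrix(NA_integer_, nrow = maxSteps + 1L, ncol = 2L)
  path[1L, ] <- c(r0, c0)
  np <- 1L
  curR <- r0; curC <- c0
  # initial backtrack: the W neighbor, guaranteed background because the
  # start pixel is first in raster order
  backDir <- 7L
  firstMove <- -1L
  repeat {
    entry <- 0L
    for (s in 1:8) {
      k <- (backDir - 1L + s) %% 8L + 1L
      nr <- curR + .mooreDirs[k, 1L]
      nc <- curC + .mooreDirs[k, 2L]
      if (fg(nr, nc)) { entry <- k; break }
    }
    if (entry == 0L) break  # unreachable for components with >= 2 pixels
    # Jacob's stopping criterion: back at the start, about to repeat the
    # first move
    if (curR == r0 && curC == c0 && entry == firstMove) break
    if (firstMove < 0L) firstMove <- entry
    nr <- curR + .mooreDirs[entry, 1L]
    nc <- curC + .mooreDirs[entry, 2L]
    np <- np + 1L
    if (np > maxSteps) break  # safety net; cannot trigger for valid masks
    path[np, ] <- c(nr, nc)
    # new backtrack points to the last background neighbor examined, i.e. the
    # neighbor scanned just before the hit
    kprev <- (entry - 2L) %% 8L + 1L
    pr <- curR + .mooreDirs[kprev, 1L]
    pc <- curC + .mooreDirs[kprev, 2L]
    dr <- pr - nr; dc <- pc - nc
    backDir <- which(.mooreDirs[, 1L] == dr & .mooreDirs[, 2L] == dc)
    curR <- nr; curC <- nc
  }
  path <- path[seq_len(np), , drop = FALSE]
  if (any(path[np, ] != path[1L, ])) path <- rbind(path, path[1L, ])
  path
}

# Length of a closed contour under the package perimeter convention.
contourLength <- function(path) {
  if (nrow(path) < 2L) return(0)
  d <- diff(path)
  steps <- abs(d[, 1L]) + abs(d[, 2L])
  sum(ifelse(steps == 2L, sqrt(2), 1)[steps > 0L])
}

# 8-connected component labeling: 4-connected pass (EBImage::bwlabel) then
# union of labels that touch diagonally.
label8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  # diagonal adjacencies between distinct 4-connected labels
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # NW-SE pairs
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]   # NE-SW pairs
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1L]); rb <- find(pairs[i, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  newId <- match(root, sort(unique(root)))
  lab[lab > 0L] <- newId[lab[lab > 0L]]
  lab
}

# Trace every labeled component, working in per-component bounding boxes.
# Returns a list of closed contours in full-raster coordinates, one per
# label 1..max(lab).
traceAllComponents <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(list())
  idx <- which(lab > 0L)
  H <- nrow(lab)
  ri <- (idx - 1L) %% H + 1L
  ci <- (idx - 1L) %/% H + 1L
  byLab <- split(seq_along(idx), lab[idx])
  lapply(seq_len(n), function(k) {
    sel <- byLab[[as.character(k)]]
    r <- ri[sel]; c <- ci[sel]
    r0 <- min(r); c0 <- min(c)
    sub <- matrix(FALSE, max(r) - r0 + 1L, max(c) - c0 + 1L)
    sub[cbind(r - r0 + 1L, c - c0 + 1L)] <- TRUE
    path <- mooreTraceComponent(sub)
    path[, 1L] <- path[, 1L] + r0 - 1L
    path[, 2L] <- path[, 2L] + c0 - 1L
    path
  })
}

# Renumber positive labels 1..n in raster-scan (row-major) order of each
# component's first pixel.
relabelRasterOrder <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  ri <- (idx - 1L) %% H + 1L
  ci <- (idx - 1L) %/% H + 1L
  rasterPos <- (ri - 1L) * W + ci
  firstPos <- tapply(rasterPos, lab[idx], min)
  labIds <- as.integer(names(firstPos))
  ord <- order(firstPos)
  mapping <- integer(max(labIds))
  mapping[labIds[ord]] <- seq_along(ord)
  lab[idx] <- mapping[lab[idx]]
  lab
}
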