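# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: quadrature on a fine grid, brute-force
# pixel loops, complete enumeration, and a hand-written Lance-Williams
# recursion.

# --- band integration -------------------------------------------------

# Trapezoidal-baseline band area of an analytic spectrum f(wn), computed
# by trapezoid quadrature on a grid `factor` times finer than `step`.
oracle_band_area <- function(f, lo, hi, anchor_hw, step, factor = 50) {
  x <- seq(lo, hi, by = step / factor)
  y <- f(x)
  xl <- x[x <= lo + anchor_hw]; if (!length(xl)) xl <- x[1]
  xr <- x[x >= hi - anchor_hw]; if (!length(xr)) xr <- x[length(x)]
  al <- mean(f(xl)); ar <- mean(f(xr))
  mxl <- mean(xl); mxr <- mean(xr)
  base <- if (mxr > mxl) al + (ar - al) / (mxr - mxl) * (x - mxl) else al
  yc <- y - base
  sum((yc[-1] + yc[-length(yc)]) / 2 * diff(x))
}

# Quadrature check of the integration step alone: the baseline anchors
# are means over the spectrum's own channels *by definition*, so they
# are reproduced from the coarse grid; the corrected analytic spectrum
# is then integrated on a grid `factor` times finer.
oracle_band_area_quadrature <- function(f, lo, hi, anchor_hw, wn_coarse,
                                        factor = 50) {
  win <- wn_coarse[wn_coarse >= lo & wn_coarse <= hi]
  left <- win[win <= lo + anchor_hw];  if (!length(left)) left <- win[1]
  right <- win[win >= hi - anchor_hw]
  if (!length(right)) right <- win[length(win)]
  al <- mean(f(left)); ar <- mean(f(right))
  xl <- mean(left); xr <- mean(right)
  step <- (win[2] - win[1]) / factor
  x <- seq(lo, hi, by = step)
  yc <- f(x) - (al + (ar - al) / (xr - xl) * (x - xl))
  sum((yc[-1] + yc[-length(yc)]) / 2 * diff(x))
}

# --- morphological erosion --------------------------------------------

# Pixel-by-pixel neighborhood check; out-of-bounds counts as background.
erode_bf <- function(region, r) {
  nr <- nrow(region); nc <- ncol(region)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, , drop = FALSE]
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!region[i, j]) next
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      ii <- i + offs$dx[k]; jj <- j + offs$dy[k]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !region[ii, jj]) {
        ok <- FALSE
        break
      }
    }
    out[i, j] <- ok
  }
  out
}

# --- Mann-Whitney -----------------------------------------------------

# Exact two-sided p by complete enumeration of the C(n1+n2, n1) equally
# likely assignments of ranks to the first sample (tie-free data only).
# Returns the full U distribution so callers can reuse it.
mw_enum_distribution <- function(n1, n2) {
  combos <- utils::combn(n1 + n2, n1)
  u <- colSums(matrix(combos, nrow = n1)) - n1 * (n1 + 1) / 2
  u
}

mw_enum_p <- function(x, y, dist_u = NULL) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(dist_u)) dist_u <- mw_enum_distribution(n1, n2)
  lower <- mean(dist_u <= u_obs)
  upper <- mean(dist_u >= u_obs)
  min(1, 2 * min(lower, upper))
}

# --- Ward clustering --------------------------------------------------

# Hand-written Lance-Williams Ward recursion on squared Euclidean
# distances.  Returns merges in hclust convention (negative = leaf) with
# rows sorted ascending, plus merge heights.  Ties broken by the lowest
# (i, j) active-cluster index pair.
lw_ward_bf <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))^2
  active <- seq_len(n)            # current cluster ids (1..n leaves)
  code <- -seq_len(n)             # hclust codes of active clusters
  size <- rep(1, n)
  merges <- matrix(NA_real_, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(active)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- D[active[i], active[j]]
      if (d < best[1]) best <- c(d, i, j)
    }
    i <- best[2]; j <- best[3]
    ai <- active[i]; aj <- active[j]
    heights[step] <- best[1]
    merges[step, ] <- sort(c(code[i], code[j]))
    # Lance-Williams Ward update against every other active cluster
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      ak <- active[k]
      ni <- size[ai]; nj <- size[aj]; nk <- size[ak]
      dnew <- ((ni + nk) * D[ai, ak] + (nj + nk) * D[aj, ak] -
                 nk * D[ai, aj]) / (ni + nj + nk)
      D[ai, ak] <- D[ak, ai] <- dnew
    }
    size[ai] <- size[ai] + size[aj]
    code[i] <- step
    active <- active[-j]
    code <- code[-j]
  }
  list(merge = merges, height = heights)
}

# canonical form of an hclust tree for comparison
hclust_canonical <- function(hc) {
  list(merge = t(apply(hc$merge, 1, sort)), height = hc$height)
}

# --- small fixtures ---------------------------------------------------

# fast low-resolution phantom configuration for plumbing tests
tiny_config <- function(seed = 1L, noise_sigma = 0, drift_scale = 0,
                        wn_step = 4, ...) {
  phantom_config(ncol = 12, heights = c(MO = 3, GR = 3, PY = 3, MU = 3),
                 margin = 1, wn_step = wn_step, noise_sigma = noise_sigma,
                 drift_order = 2, drift_scale = drift_scale, seed = seed,
                 ...)
}

# well-separated narrow-band composition: no overlap between any two
# registry windows, so closed-form truncated areas equal the measured
# (baseline-corrected) areas to high accuracy
narrow_layer_bands <- function() {
  comp <- data.frame(
    name = c("a1658", "b1635", "ch2924", "ch2958", "p1080", "p1240",
             "c1740", "m1420"),
    center = c(1658, 1635, 2924, 2958, 1080, 1240, 1740, 1420),
    width = c(2.5, 2.5, 3, 3, 3, 3, 3, 3))
  amp <- c(a1658 = 0.9, b1635 = 0.3, ch2924 = 0.45, ch2958 = 0.3,
           p1080 = 0.3, p1240 = 0.26, c1740 = 0.1, m1420 = 0.2)
  lapply(setNames(c("GR", "PY", "MU", "MO"), c("GR", "PY", "MU", "MO")),
         function(ly) lapply(comp$name, function(nm) {
           i <- match(nm, comp$name)
           band_model(comp$center[i], comp$width[i], amp[[nm]], name = nm)
         }))
}
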