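# trapezoid-rule weights for an (ascending, possibly nonuniform) axis
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need >= 2 points for trapezoid rule", call. = FALSE)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2L) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

# channel indices of window / anchor sub-windows; validates resolution
band_channels <- function(wavenumbers, band) {
  if (band$lo < min(wavenumbers) || band$hi > max(wavenumbers))
    stop("band '", band$name, "' window [", band$lo, ", ", band$hi,
         "] outside spectral axis range [", min(wavenumbers), ", ",
         max(wavenumbers), "]", call. = FALSE)
  win <- which(wavenumbers >= band$lo & wavenumbers <= band$hi)
  if (length(win) < 2L)
    stop("band '", band$name,
         "' window contains fewer than 2 channels at this resolution",
         call. = FALSE)
  left <- win[wavenumbers[win] <= band$lo + band$anchor_hw]
  if (!length(left)) left <- win[1L]
  right <- win[wavenumbers[win] >= band$hi - band$anchor_hw]
  if (!length(right)) right <- win[length(win)]
  list(win = win, left = left, right = right)
}

# Core kernel: spectra as (npix x nchan) matrix -> per-pixel band value.
# Baseline: straight line through (mean wn_left, mean A_left) and
# (mean wn_right, mean A_right); subtracted before area/height.
integrate_band_matrix <- function(spectra, wavenumbers, band) {
  ch <- band_channels(wavenumbers, band)
  xw <- wavenumbers[ch$win]
  xl <- mean(wavenumbers[ch$left])
  xr <- mean(wavenumbers[ch$right])
  Al <- if (length(ch$left) == 1L) spectra[, ch$left]
        else rowMeans(spectra[, ch$left, drop = FALSE])
  Ar <- if (length(ch$right) == 1L) spectra[, ch$right]
        else rowMeans(spectra[, ch$right, drop = FALSE])
  slope <- if (xr > xl) (Ar - Al) / (xr - xl) else rep(0, nrow(spectra))
  # corrected[i, j] = A[i, j] - (Al[i] + slope[i] * (x[j] - xl))
  corrected <- spectra[, ch$win, drop = FALSE] - outer(Al, rep(1, length(xw))) -
    outer(slope, xw - xl)
  if (band$mode == "area") {
    drop(corrected %*% trapz_weights(xw))
  } else {
    apply(corrected, 1L, max)
  }
}

#' Integrate one absorption band with trapezoidal baseline correction
#'
#' Quantifies one band or massif of a single spectrum.  A straight
#' baseline is drawn between the mean absorbances of the two anchor
#' sub-windows at the edges of the integration window (each anchored at
#' the mean wavenumber of its sub-window) and subtracted.  In `"area"`
#' mode the trapezoid-rule integral of the corrected spectrum over the
#' window is returned (AU·cm^-1; may be negative — negative corrected
#' areas are retained, not clipped, since silent clipping would bias
#' group means).  In `"height"` mode the maximum of the corrected
#' spectrum within the window is returned (AU).
#'
#' Because the baseline is linear in the spectrum, integration is linear,
#' and any affine-in-wavenumber component of the spectrum integrates to
#' exactly zero.
#'
#' @param absorbance numeric vector, one spectrum.
#' @param wavenumbers matching ascending axis, cm^-1.
#' @param band a [band_definition()].
#' @return scalar band value.
#' @examples
#' wn <- seq(900, 4000, by = 4)
#' s <- exp(-(wn - 1658)^2 / (2 * 10^2))      # unit-height Gaussian band
#' integrate_band(s, wn, band_definition("amideI", 1598, 1718))
#' # ~ 10 * sqrt(2*pi) = 25.07 AU cm-1
#' @export
integrate_band <- function(absorbance, wavenumbers, band) {
  stopifnot(inherits(band, "band_definition"))
  if (length(absorbance) != length(wavenumbers))
    stop("spectrum and axis lengths differ", call. = FALSE)
  integrate_band_matrix(matrix(absorbance, nrow = 1L), wavenumbers, band)[1L]
}

#' Evaluate a biochemical parameter over a whole map
#'
#' Integrates the numerator band (and denominator band, for ratio
#' parameters) at every pixel of a [spectral_map()] and returns the
#' resulting [chemical_map()].  Ratio pixels whose denominator magnitude
#' falls below `denom_floor` are marked invalid (`NA` value, `FALSE` in
#' the validity mask) — never `NaN`/`Inf`.
#'
#' @param map a [spectral_map()].
#' @param spec a [parameter_spec()], or a parameter name to look up in
#'   `registry`.
#' @param registry registry used when `spec` is a name.
#' @param denom_floor smallest denominator magnitude (AU·cm^-1, or AU in
#'   height mode) considered valid for ratios.  Default 1e-3.
#' @param tissue optional logical matrix restricting validity to tissue
#'   pixels (see [tissue_mask()]).
#' @return a [chemical_map()].
#' @export
compute_parameter <- function(map, spec, registry = parameter_registry(),
                              denom_floor = 1e-3, tissue = NULL) {
  stopifnot(inherits(map, "spectral_map"))
  if (is.character(spec)) {
    if (is.null(registry[[spec]]))
      stop("unknown parameter name '", spec, "'", call. = FALSE)
    spec <- registry[[spec]]
  }
  stopifnot(inherits(spec, "parameter_spec"))
  d <- dim(map$absorbance)
  m <- cube_matrix(map)
  num <- integrate_band_matrix(m, map$wavenumbers, spec$numerator)
  if (is.null(spec$denominator)) {
    vals <- num
    valid <- rep(TRUE, length(vals))
    units <- if (spec$numerator$mode == "area") "AU.cm-1" else "AU"
  } else {
    den <- integrate_band_matrix(m, map$wavenumbers, spec$denominator)
    valid <- abs(den) >= denom_floor
    vals <- rep(NA_real_, length(num))
    vals[valid] <- num[valid] / den[valid]
    units <- ""
  }
  if (!is.null(tissue)) valid <- valid & as.vector(tissue)
  vals[!valid] <- NA_real_
  chemical_map(matrix(vals, d[1], d[2]), matrix(valid, d[1], d[2]),
               parameter = spec$name, units = units)
}

#' Tissue/background segmentation by amide I intensity
#'
#' A pixel is tissue iff its baseline-corrected integrated amide I
#' absorbance is at least `threshold`.  With `threshold = 0` every pixel
#' is tissue.
#'
#' @param map a [spectral_map()].
#' @param threshold AU·cm^-1, `>= 0`.
#' @param band the band used for segmentation; defaults to the registry's
#'   amide I definition.
#' @return logical matrix, `TRUE` for tissue.
#' @export
tissue_mask <- function(map, threshold = 1,
                        band = default_bands()[["1658"]]) {
  stopifnot(inherits(map, "spectral_map"), threshold >= 0)
  d <- dim(map$absorbance)
  a <- integrate_band_matrix(cube_matrix(map), map$wavenumbers, band)
  out <- matrix(a >= threshold, d[1], d[2])
  if (!any(out))
    warning("tissue threshold ", threshold,
            " is above the map's maximum amide I area; empty tissue mask",
            call. = FALSE)
  out
}
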