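#' Absorption band model
#'
#' One spectral component of a phantom layer: a Gaussian (default) or
#' Lorentzian line centred at `center` with scale `width` (the Gaussian
#' standard deviation, or Lorentzian half-width at half-maximum) and peak
#' absorbance `amplitude`.
#'
#' @param center band centre, cm^-1.
#' @param width line width parameter, cm^-1, `> 0`.
#' @param amplitude peak absorbance, AU, `>= 0`.
#' @param name optional band name.
#' @return list of class `band_model`.
#' @export
band_model <- function(center, width, amplitude, name = as.character(center)) {
  if (width <= 0) stop("band width must be > 0", call. = FALSE)
  if (amplitude < 0) stop("band amplitude must be >= 0", call. = FALSE)
  structure(list(name = name, center = center, width = width,
                 amplitude = amplitude),
            class = "band_model")
}

# line profile evaluated on the axis (unit amplitude)
band_profile <- function(band, wn, lineshape = "gaussian") {
  if (lineshape == "gaussian") {
    exp(-(wn - band$center)^2 / (2 * band$width^2))
  } else {
    band$width^2 / ((wn - band$center)^2 + band$width^2)
  }
}

#' Closed-form area of a (truncated) model band
#'
#' Analytic integral of a unit-amplitude-scaled band over `[lo, hi]`:
#' `amplitude * width * sqrt(2*pi) * (Phi((hi-c)/w) - Phi((lo-c)/w))` for
#' Gaussians, `amplitude * width * (atan((hi-c)/w) - atan((lo-c)/w))` for
#' Lorentzians.  Used as the independent ground truth for integration
#' oracles.
#'
#' @param band a [band_model()].
#' @param lo,hi integration limits, cm^-1 (default the whole line).
#' @param lineshape `"gaussian"` or `"lorentzian"`.
#' @return area, AU·cm^-1.
#' @export
band_area <- function(band, lo = -Inf, hi = Inf, lineshape = "gaussian") {
  if (lineshape == "gaussian") {
    band$amplitude * band$width * sqrt(2 * pi) *
      (stats::pnorm((hi - band$center) / band$width) -
         stats::pnorm((lo - band$center) / band$width))
  } else {
    band$amplitude * band$width *
      (atan((hi - band$center) / band$width) -
         atan((lo - band$center) / band$width))
  }
}

#' Default spectral composition of the phantom layers
#'
#' Each cellular layer's noiseless spectrum is a sum of Gaussian bands at
#' the wavenumbers quantified by the default [parameter_registry()]:
#' amide I alpha-helix (1658) and beta-sheet (1635) components, the C-H
#' stretching bands of the lipid massif (2852, 2873, 2924, 2958), the
#' phosphate bands (1080, 1240), the carbonyl ester band (1740), and the
#' CH2/CH3 bending bands of the 1360-1480 massif (1382, 1400, 1440,
#' 1465).  Amplitudes vary mildly between layers (protein densest in the
#' granular layer, lipid richest in the molecular layer), with magnitudes
#' in the 0.1-1 AU range typical of 12-um brain cryosections measured in
#' transflection.
#'
#' @return named list (`GR`, `PY`, `MU`, `MO`) of lists of
#'   [band_model()]s.
#' @export
default_layer_bands <- function() {
  comp <- data.frame(
    name   = c("a1658", "b1635", "ch2852", "ch2873", "ch2924", "ch2958",
               "p1080", "p1240", "c1740", "m1382", "m1400", "m1440",
               "m1465"),
    center = c(1658, 1635, 2852, 2873, 2924, 2958,
               1080, 1240, 1740, 1382, 1400, 1440, 1465),
    width  = c(12, 9, 9, 8, 10, 9, 16, 14, 9, 10, 9, 12, 9),
    GR = c(0.95, 0.32, 0.20, 0.14, 0.40, 0.26, 0.30, 0.26, 0.10,
           0.14, 0.12, 0.22, 0.16),
    PY = c(0.90, 0.30, 0.22, 0.15, 0.44, 0.28, 0.30, 0.26, 0.10,
           0.14, 0.12, 0.22, 0.16),
    MU = c(0.80, 0.28, 0.24, 0.16, 0.48, 0.30, 0.28, 0.25, 0.10,
           0.13, 0.12, 0.21, 0.16),
    MO = c(0.85, 0.30, 0.26, 0.17, 0.50, 0.32, 0.28, 0.25, 0.10,
           0.13, 0.12, 0.21, 0.16))
  lapply(setNames(c("GR", "PY", "MU", "MO"), c("GR", "PY", "MU", "MO")),
         function(ly) {
           lapply(seq_len(nrow(comp)), function(i)
             band_model(comp$center[i], comp$width[i], comp[[ly]][i],
                        name = comp$name[i]))
         })
}

#' Multiplicative group x layer effects on band amplitudes
#'
#' An effect map lists multiplicative factors applied to the amplitude of
#' one model band in one layer for one group, encoding which biochemical
#' anomalies a phantom cohort carries.
#'
#' @param entries data.frame with columns `group` (`"N"`/`"K"` or a
#'   subgroup label), `layer` (`GR`/`PY`/`MU`/`MO`), `center` (band
#'   centre, cm^-1), `factor` (`> 0`).
#' @return data.frame of class `effect_map`.
#' @export
effect_map <- function(entries) {
  entries <- as.data.frame(entries)
  need <- c("group", "layer", "center", "factor")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("effect map missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(entries$factor <= 0))
    stop("effect factors must be > 0", call. = FALSE)
  bad <- setdiff(unique(entries$layer), .hippo_layers)
  if (length(bad))
    stop("unknown layer(s) in effect map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  class(entries) <- c("effect_map", "data.frame")
  entries
}

#' The default kindled-group effect map
#'
#' Encodes, as +/-15% amplitude factors on the K group, the direction of
#' every layer-wise anomaly the pipeline is expected to detect:
#' an elevated beta-sheet component (1635) in the molecular layer, an
#' elevated 1080 phosphate band in the granular and pyramidal layers, a
#' reduced 1240 phosphate band in the multiform and molecular layers, an
#' elevated carbonyl ester band (1740) in all layers, a reduced
#' 1360-1480 CH-bending massif in all layers, and an elevated C-H
#' stretching (lipid) massif in the pyramidal layer.  Magnitudes are free
#' parameters of the phantom (the underlying study reports significance,
#' not effect sizes); +/-15% is the package default.
#'
#' @param up,down multiplicative factors for increased / decreased bands
#'   (defaults 1.15 and 0.85).
#' @return an [effect_map()].
#' @export
default_effect_map <- function(up = 1.15, down = 0.85) {
  all_l <- .hippo_layers
  massif_down <- expand.grid(layer = all_l,
                             center = c(1382, 1400, 1440, 1465),
                             stringsAsFactors = FALSE)
  massif_down$factor <- down
  rows <- rbind(
    data.frame(layer = "MO", center = 1635, factor = up),
    data.frame(layer = c("GR", "PY"), center = 1080, factor = up),
    data.frame(layer = c("MU", "MO"), center = 1240, factor = down),
    data.frame(layer = all_l, center = 1740, factor = up),
    massif_down,
    data.frame(layer = "PY", center = c(2852, 2873, 2924, 2958),
               factor = up))
  rows$group <- "K"
  effect_map(rows[, c("group", "layer", "center", "factor")])
}

#' Phantom configuration
#'
#' Geometry, spectral axis, and noise model of a synthetic layered
#' hippocampal section.  The section is a stack of horizontal laminae
#' (molecular, granular, pyramidal, multiform, from top) on a background
#' border, mimicking the banded architecture of the dentate gyrus /
#' cornu ammonis region at 25 um pixels.  The default geometry gives
#' every layer comfortably more pixels than the QC minima of
#' [default_pixel_minima()] even after 1-pixel border erosion
#' (GR 144, PY 192, MU and MO 384 post-erosion pixels).
#'
#' The spectral axis spans 900-4000 cm^-1 in 4 cm^-1 steps by default
#' (an 8 cm^-1 instrument resolution digitised on the usual 2x finer
#' grid).  Noise is additive i.i.d. Gaussian on absorbance; baseline
#' drift is a per-pixel random polynomial in the scaled wavenumber.
#'
#' @param ncol image width in pixels.
#' @param heights named integer vector of stripe heights (rows) for
#'   `MO`, `GR`, `PY`, `MU` (top to bottom).
#' @param margin background border width, rows/cols.
#' @param wn_start,wn_stop,wn_step wavenumber grid, cm^-1.
#' @param noise_sigma additive noise standard deviation, AU.
#' @param drift_order,drift_scale baseline-drift polynomial order and
#'   coefficient standard deviation (AU); order 0 with scale 0 disables
#'   drift.
#' @param layer_bands spectral composition, see [default_layer_bands()].
#' @param lineshape `"gaussian"` (default) or `"lorentzian"`.
#' @param seed integer RNG seed.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(ncol = 50,
                           heights = c(MO = 10, GR = 5, PY = 6, MU = 10),
                           margin = 2,
                           wn_start = 900, wn_stop = 4000, wn_step = 4,
                           noise_sigma = 0.01,
                           drift_order = 2, drift_scale = 0.005,
                           layer_bands = default_layer_bands(),
                           lineshape = c("gaussian", "lorentzian"),
                           seed = 1L) {
  lineshape <- match.arg(lineshape)
  if (wn_step <= 0) stop("wavenumber step must be > 0", call. = FALSE)
  if (wn_stop <= wn_start) stop("empty wavenumber range", call. = FALSE)
  if (noise_sigma < 0 || drift_scale < 0)
    stop("noise/drift scales must be >= 0", call. = FALSE)
  miss <- setdiff(.hippo_layers, names(heights))
  if (length(miss))
    stop("stripe heights missing for layer(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  zero <- names(heights)[heights < 1]
  if (length(zero))
    stop("layer(s) with zero pixels in configured geometry: ",
         paste(zero, collapse = ", "), call. = FALSE)
  if (ncol - 2 * margin < 1)
    stop("image too narrow for the configured margin", call. = FALSE)
  wn <- seq(wn_start, wn_stop, by = wn_step)
  for (ly in names(layer_bands))
    for (b in layer_bands[[ly]])
      if (b$center < wn_start || b$center > wn_stop)
        stop("band '", b$name, "' centre ", b$center,
             " outside the spectral axis", call. = FALSE)
  structure(list(ncol = ncol, heights = heights, margin = margin,
                 wavenumbers = wn, noise_sigma = noise_sigma,
                 drift_order = drift_order, drift_scale = drift_scale,
                 layer_bands = layer_bands, lineshape = lineshape,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# stripe-geometry label image
phantom_geometry <- function(config) {
  stripe_order <- c("MO", "GR", "PY", "MU")
  h <- config$heights[stripe_order]
  nrow <- 2L * config$margin + sum(h)
  labels <- matrix(0L, nrow, config$ncol)
  legend <- setNames(seq_along(stripe_order), stripe_order)
  r <- config$margin
  cols <- (config$margin + 1L):(config$ncol - config$margin)
  for (ly in stripe_order) {
    labels[(r + 1L):(r + h[[ly]]), cols] <- legend[[ly]]
    r <- r + h[[ly]]
  }
  layer_mask(labels, legend)
}

# apply group effects to one layer's band list
apply_effects <- function(bands, effects, group, layer) {
  if (is.null(effects)) return(bands)
  sel <- effects[effects$group == group & effects$layer == layer, ,
                 drop = FALSE]
  if (!nrow(sel)) return(bands)
  centers <- vapply(bands, `[[`, 0, "center")
  for (i in seq_len(nrow(sel))) {
    hit <- which(abs(centers - sel$center[i]) < 1e-6)
    if (!length(hit)) {
      warning("effect on centre ", sel$center[i], " in layer ", layer,
              " matches no model band; ignored", call. = FALSE)
      next
    }
    for (j in hit) bands[[j]]$amplitude <- bands[[j]]$amplitude * sel$factor[i]
  }
  bands
}

#' Generate a hyperspectral tissue phantom
#'
#' Builds one synthetic section for one animal: every tissue pixel's
#' spectrum is the sum of its layer's [band_model()]s (amplitudes scaled
#' by the applicable [effect_map()] factors for `group`), plus per-pixel
#' polynomial baseline drift and additive Gaussian noise.  Background
#' pixels carry only noise and drift.  The returned ground truth
#' tabulates, for every default registry band window and layer, the
#' closed-form (noiseless, effect-scaled) integrated area of the model
#' bands within that window.
#'
#' @param config a [phantom_config()].
#' @param effects an [effect_map()] or `NULL`.
#' @param group group label whose effects apply (`"N"` or `"K"`).
#' @param animal_id id recorded in the map metadata.
#' @param registry registry whose band windows define the ground-truth
#'   table.
#' @return list of class `phantom`: `map` ([spectral_map()]), `mask`
#'   ([layer_mask()]), `ground_truth` (data.frame `layer`, `band`,
#'   `area`), `config`, `group`.
#' @export
make_phantom <- function(config = phantom_config(), effects = NULL,
                         group = "N", animal_id = NA_character_,
                         registry = parameter_registry()) {
  stopifnot(inherits(config, "phantom_config"))
  if (!group %in% c("N", "K") &&
      !(is.data.frame(effects) && group %in% effects$group))
    stop("group must be 'N', 'K', or a group present in the effect map",
         call. = FALSE)
  mask <- phantom_geometry(config)
  wn <- config$wavenumbers
  nchan <- length(wn)
  npix <- length(mask$labels)

  set.seed(config$seed)

  # layer spectra with effects applied
  eff_bands <- lapply(setNames(.hippo_layers, .hippo_layers), function(ly)
    apply_effects(config$layer_bands[[ly]], effects, group, ly))
  layer_spec <- vapply(.hippo_layers, function(ly) {
    Reduce(`+`, lapply(eff_bands[[ly]], function(b)
      b$amplitude * band_profile(b, wn, config$lineshape)),
      accumulate = FALSE, init = numeric(nchan))
  }, numeric(nchan))  # nchan x 4

  spectra <- matrix(0, npix, nchan)
  for (ly in .hippo_layers) {
    idx <- which(as.vector(mask$labels) == mask$legend[[ly]])
    if (length(idx))
      spectra[idx, ] <- matrix(layer_spec[, ly], length(idx), nchan,
                               byrow = TRUE)
  }

  if (config$drift_scale > 0 && config$drift_order >= 0) {
    u <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
    basis <- t(vapply(0:config$drift_order, function(k) u^k,
                      numeric(nchan)))           # (order+1) x nchan
    coef <- matrix(rnorm(npix * (config$drift_order + 1L),
                         sd = config$drift_scale),
                   npix, config$drift_order + 1L)
    spectra <- spectra + coef %*% basis
  }
  if (config$noise_sigma > 0)
    spectra <- spectra + matrix(rnorm(npix * nchan,
                                      sd = config$noise_sigma),
                                npix, nchan)

  d <- dim(mask$labels)
  map <- spectral_map(array(spectra, c(d[1], d[2], nchan)), wn,
                      animal_id = animal_id, group = group,
                      pixel_size_um = 25)

  # closed-form ground truth per registry band window
  reg_bands <- list()
  for (p in registry) {
    reg_bands[[p$numerator$name]] <- p$numerator
    if (!is.null(p$denominator))
      reg_bands[[p$denominator$name]] <- p$denominator
  }
  gt <- do.call(rbind, lapply(.hippo_layers, function(ly) {
    data.frame(layer = ly,
               band = names(reg_bands),
               area = vapply(reg_bands, function(rb)
                 sum(vapply(eff_bands[[ly]], band_area, 0,
                            lo = rb$lo, hi = rb$hi,
                            lineshape = config$lineshape)),
                 0),
               stringsAsFactors = FALSE)
  }))
  rownames(gt) <- NULL

  structure(list(map = map, mask = mask, ground_truth = gt,
                 config = config, group = group),
            class = "phantom")
}

#' Noiseless parameter ground truth of a phantom
#'
#' Converts a phantom's band-level ground truth into per-layer parameter
#' values: window area for absolute parameters, window-area ratio for
#' ratio parameters.
#'
#' @param phantom a [make_phantom()] result.
#' @param registry the registry used to build it.
#' @return data.frame `layer`, `parameter`, `value`.
#' @export
ground_truth_parameters <- function(phantom,
                                    registry = parameter_registry()) {
  gt <- phantom$ground_truth
  do.call(rbind, lapply(.hippo_layers, function(ly) {
    g <- gt[gt$layer == ly, ]
    a <- setNames(g$area, g$band)
    data.frame(layer = ly,
               parameter = names(registry),
               value = vapply(registry, function(p) {
                 if (is.null(p$denominator)) a[[p$numerator$name]]
                 else a[[p$numerator$name]] / a[[p$denominator$name]]
               }, 0),
               stringsAsFactors = FALSE)
  }))
}
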