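#' Band definition for integration
#'
#' Describes how one absorption band or massif is quantified: a closed
#' integration window `[lo, hi]` (cm^-1), the half-width of the baseline
#' anchor sub-windows at each window edge, and whether the band is
#' quantified as baseline-corrected area (default) or peak height.
#'
#' The trapezoidal baseline is the straight line joining the mean
#' absorbance in `[lo, lo + anchor_hw]` to the mean absorbance in
#' `[hi - anchor_hw, hi]` (anchored at the mean wavenumber of each
#' sub-window); see [integrate_band()].
#'
#' @param name band name, e.g. `"1740"` or `"2800-3000"`.
#' @param lo,hi integration window bounds, cm^-1, `lo < hi`.
#' @param anchor_hw baseline anchor half-width, cm^-1, `>= 0`.  With 0,
#'   the single channel nearest each edge anchors the baseline.
#' @param mode `"area"` (AU·cm^-1) or `"height"` (AU).
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, lo, hi, anchor_hw = 8,
                            mode = c("area", "height")) {
  mode <- match.arg(mode)
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stop("band window requires lo < hi", call. = FALSE)
  if (anchor_hw < 0)
    stop("anchor half-width must be >= 0", call. = FALSE)
  structure(list(name = name, lo = lo, hi = hi, anchor_hw = anchor_hw,
                 mode = mode),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s [%g, %g] cm-1, anchors +/-%g, %s\n",
              x$name, x$lo, x$hi, x$anchor_hw, x$mode))
  invisible(x)
}

#' Biochemical parameter specification
#'
#' A parameter is either one band's integrated intensity or the ratio of
#' two bands' intensities.
#'
#' @param name parameter name.
#' @param numerator a [band_definition()].
#' @param denominator a [band_definition()] or `NULL` for an absolute
#'   parameter.
#' @param description free-text biochemical meaning.
#' @return An object of class `parameter_spec`.
#' @export
parameter_spec <- function(name, numerator, denominator = NULL,
                           description = "") {
  stopifnot(inherits(numerator, "band_definition"))
  if (!is.null(denominator)) stopifnot(inherits(denominator, "band_definition"))
  structure(list(name = name, numerator = numerator,
                 denominator = denominator, description = description),
            class = "parameter_spec")
}

#' @export
print.parameter_spec <- function(x, ...) {
  cat(sprintf("<parameter> %s = %s%s\n", x$name, x$numerator$name,
              if (is.null(x$denominator)) ""
              else paste0(" / ", x$denominator$name)))
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  invisible(x)
}

#' Default integration windows for the standard band panel
#'
#' Single bands use a +/-24 cm^-1 window around the nominal centre;
#' massifs use their conventional printed ranges; the amide I
#' sub-components (1635 beta-sheet, 1658 alpha-helix) and the 2924/2955
#' CH stretches use narrower windows so the paired sub-bands stay
#' disjoint.  Anchor half-widths are 8 cm^-1 (4 for the narrow
#' sub-bands).  All of this is overridable: pass a modified band set to
#' [parameter_registry()], or drop in instrument-specific limits via
#' [read_registry()].
#'
#' @return named list of [band_definition()]s.
#' @export
default_bands <- function() {
  b <- list(
    band_definition("1658",      1634, 1682, 8),
    band_definition("1635n",     1627, 1643, 4),
    band_definition("1658n",     1650, 1666, 4),
    band_definition("2800-3000", 2800, 3000, 8),
    band_definition("2924n",     2912, 2936, 4),
    band_definition("2955n",     2943, 2967, 4),
    band_definition("1080",      1056, 1104, 8),
    band_definition("1240",      1216, 1264, 8),
    band_definition("1360-1480", 1360, 1480, 8),
    band_definition("1740",      1716, 1764, 8))
  setNames(b, vapply(b, `[[`, "", "name"))
}

#' The default biochemical parameter registry
#'
#' Builds the standard panel of 17 parameters quantified in layer-wise
#' FT-IR analyses of brain tissue: 6 absolute band/massif intensities and
#' 11 intensity ratios.
#'
#' | parameter | meaning |
#' |---|---|
#' | `1658` | amide I; protein distribution |
#' | `1635/1658` | beta-sheet / alpha-helix ratio (protein secondary structure) |
#' | `2800-3000` | C-H stretching massif; lipid distribution |
#' | `2924/2955` | CH2/CH3 stretch ratio; acyl chain length/branching/saturation |
#' | `1080`, `1240` | phosphate bands; nucleic acids, phospholipids, phosphorylated carbohydrates |
#' | `1360-1480` | CH2/CH3 bending massif; lipids, cholesterol and its esters |
#' | `1740` | carbonyl ester band; phospholipids, cholesterol esters, ketone bodies |
#' | nine ratios | each band/massif relative to protein (`/1658`) and to lipid (`/2800-3000`) |
#'
#' @param bands named list of [band_definition()]s to use instead of the
#'   defaults; must contain the band names referenced by the panel.
#' @param mode integration mode applied to every band, `"area"` (default)
#'   or `"height"`.
#' @return Named list of [parameter_spec()]s (class
#'   `parameter_registry`).
#' @export
parameter_registry <- function(bands = default_bands(),
                               mode = c("area", "height")) {
  mode <- match.arg(mode)
  if (mode != "area")
    bands <- lapply(bands, function(b) { b$mode <- mode; b })
  g <- function(nm) {
    if (is.null(bands[[nm]]))
      stop("band '", nm, "' missing from band set", call. = FALSE)
    bands[[nm]]
  }
  specs <- list(
    parameter_spec("1658", g("1658"), NULL, "protein distribution (amide I)"),
    parameter_spec("1635/1658", g("1635n"), g("1658n"),
                   "beta-sheet to alpha-helix ratio"),
    parameter_spec("2800-3000", g("2800-3000"), NULL, "lipid distribution"),
    parameter_spec("2924/2955", g("2924n"), g("2955n"),
                   "lipid saturation / chain length and branching"),
    parameter_spec("1080", g("1080"), NULL,
                   "phosphate-containing compounds"),
    parameter_spec("1240", g("1240"), NULL,
                   "phosphate-containing compounds"),
    parameter_spec("1360-1480", g("1360-1480"), NULL,
                   "lipids, cholesterol and cholesterol esters"),
    parameter_spec("1740", g("1740"), NULL,
                   "phospholipids, cholesterol esters, ketone bodies"),
    parameter_spec("2800-3000/1658", g("2800-3000"), g("1658"),
                   "lipid to protein"),
    parameter_spec("1080/1658", g("1080"), g("1658"),
                   "phosphates to protein"),
    parameter_spec("1240/1658", g("1240"), g("1658"),
                   "phosphates to protein"),
    parameter_spec("1740/1658", g("1740"), g("1658"),
                   "carbonyl esters to protein"),
    parameter_spec("1360-1480/1658", g("1360-1480"), g("1658"),
                   "methyl/methylene compounds to protein"),
    parameter_spec("1080/2800-3000", g("1080"), g("2800-3000"),
                   "phosphates to lipid"),
    parameter_spec("1240/2800-3000", g("1240"), g("2800-3000"),
                   "phosphates to lipid"),
    parameter_spec("1740/2800-3000", g("1740"), g("2800-3000"),
                   "carbonyl esters to lipid"),
    parameter_spec("1360-1480/2800-3000", g("1360-1480"), g("2800-3000"),
                   "methyl/methylene compounds to lipid"))
  structure(setNames(specs, vapply(specs, `[[`, "", "name")),
            class = c("parameter_registry", "list"))
}

#' @export
print.parameter_registry <- function(x, ...) {
  cat(sprintf("<parameter_registry> %d parameters\n", length(x)))
  for (p in x)
    cat(sprintf("  %-22s %s\n", p$name, p$description))
  invisible(x)
}

#' Read / write a parameter registry as JSON
#'
#' Serialises every band window, anchor width, and mode so a study can
#' drop in its own integration limits (e.g. instrument-specific baseline
#' points) without touching code.
#'
#' @param registry a [parameter_registry()].
#' @param path JSON file path.
#' @return `read_registry()` returns a `parameter_registry`.
#' @export
write_registry <- function(registry, path) {
  ser_band <- function(b) b[c("name", "lo", "hi", "anchor_hw", "mode")]
  out <- lapply(unname(registry), function(p) {
    list(name = p$name, description = p$description,
         numerator = ser_band(p$numerator),
         denominator = if (is.null(p$denominator)) NULL
                       else ser_band(p$denominator))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  raw <- jsonlite::read_json(path)
  de_band <- function(b) band_definition(b$name, b$lo, b$hi, b$anchor_hw,
                                         b$mode)
  specs <- lapply(raw, function(p)
    parameter_spec(p$name, de_band(p$numerator),
                   if (is.null(p$denominator)) NULL
                   else de_band(p$denominator),
                   p$description %||% ""))
  structure(setNames(specs, vapply(specs, `[[`, "", "name")),
            class = c("parameter_registry", "list"))
}
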