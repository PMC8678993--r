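#' Hyperspectral absorbance map
#'
#' Container for one FT-IR chemical-mapping acquisition: an absorbance cube
#' indexed by (row, col, wavenumber channel) together with its calibrated
#' wavenumber axis and acquisition metadata.  If the supplied axis is
#' descending (some instruments store interferogram-order axes) it is
#' re-sorted ascending, the cube channels are permuted accordingly, and
#' `metadata$resorted` is set to `TRUE`.
#'
#' @param absorbance numeric 3-d array, `dim = c(nrow, ncol, nchan)`, in
#'   absorbance units (AU).  All values must be finite.
#' @param wavenumbers numeric vector of length `nchan`, cm^-1, strictly
#'   monotonic (ascending or descending; stored ascending).
#' @param animal_id character scalar identifier.
#' @param group group label, conventionally `"N"` (control) or `"K"`
#'   (kindled/stimulated).
#' @param pixel_size_um nominal pixel edge length in micrometres.
#' @param metadata optional named list of additional metadata.
#'
#' @return An object of class `spectral_map`: a list with elements
#'   `absorbance`, `wavenumbers`, `metadata`.
#' @seealso [read_map()], [write_map()], [make_phantom()]
#' @export
spectral_map <- function(absorbance, wavenumbers, animal_id = NA_character_,
                         group = NA_character_, pixel_size_um = 25,
                         metadata = list()) {
  if (!is.array(absorbance) || length(dim(absorbance)) != 3L)
    stop("`absorbance` must be a 3-d array (row, col, channel)", call. = FALSE)
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != dim(absorbance)[3L])
    stop("wavenumber axis length (", length(wavenumbers),
         ") does not match cube channel count (", dim(absorbance)[3L], ")",
         call. = FALSE)
  if (!all(is.finite(absorbance)))
    stop("absorbance cube contains non-finite values", call. = FALSE)
  d <- diff(wavenumbers)
  resorted <- FALSE
  if (all(d < 0)) {
    ord <- rev(seq_along(wavenumbers))
    wavenumbers <- wavenumbers[ord]
    absorbance <- absorbance[, , ord, drop = FALSE]
    resorted <- TRUE
  } else if (!all(d > 0)) {
    stop("wavenumber axis must be strictly monotonic", call. = FALSE)
  }
  md <- c(list(animal_id = animal_id, group = group,
               pixel_size_um = pixel_size_um, resorted = resorted),
          metadata)
  structure(list(absorbance = absorbance, wavenumbers = wavenumbers,
                 metadata = md),
            class = "spectral_map")
}

#' @export
print.spectral_map <- function(x, ...) {
  d <- dim(x$absorbance)
  cat(sprintf(
    "<spectral_map> %d x %d pixels, %d channels (%.0f-%.0f cm-1)\n",
    d[1], d[2], d[3], min(x$wavenumbers), max(x$wavenumbers)))
  cat(sprintf("  animal: %s  group: %s  pixel: %s um\n",
              x$metadata$animal_id, x$metadata$group,
              format(x$metadata$pixel_size_um)))
  invisible(x)
}

#' @export
dim.spectral_map <- function(x) dim(x$absorbance)

# flatten cube to (npix x nchan) matrix, pixels in column-major (R) order
cube_matrix <- function(map) {
  d <- dim(map$absorbance)
  matrix(map$absorbance, nrow = d[1] * d[2], ncol = d[3])
}

#' Cellular-layer label mask
#'
#' Integer label image assigning each pixel of a paired [spectral_map()] to
#' one of the hippocampal cellular layers (granular GR, pyramidal PY,
#' multiform MU, molecular MO) or to background (label 0).
#'
#' @param labels integer matrix; 0 is background, positive integers are
#'   layers listed in `legend`.
#' @param legend named integer vector mapping layer names to label values,
#'   e.g. `c(GR = 1, PY = 2, MU = 3, MO = 4)`.  Every nonzero label present
#'   in `labels` must appear in the legend.
#'
#' @return An object of class `layer_mask`.
#' @export
layer_mask <- function(labels, legend) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  legend <- setNames(as.integer(legend), names(legend))
  if (is.null(names(legend)) || any(!nzchar(names(legend))))
    stop("legend must be a named integer vector", call. = FALSE)
  if (anyDuplicated(legend) || anyDuplicated(names(legend)))
    stop("legend labels and names must be unique", call. = FALSE)
  present <- setdiff(unique(as.vector(labels)), 0L)
  orphan <- setdiff(present, legend)
  if (length(orphan))
    stop("mask labels missing from legend: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  structure(list(labels = labels, legend = legend), class = "layer_mask")
}

#' @export
print.layer_mask <- function(x, ...) {
  cat(sprintf("<layer_mask> %d x %d pixels\n",
              nrow(x$labels), ncol(x$labels)))
  for (nm in names(x$legend))
    cat(sprintf("  %-10s label %d: %d px\n", nm, x$legend[[nm]],
                sum(x$labels == x$legend[[nm]])))
  invisible(x)
}

# logical image of one layer's pixels
layer_region <- function(mask, layer) {
  if (!layer %in% names(mask$legend))
    stop("layer '", layer, "' not present in mask legend", call. = FALSE)
  mask$labels == mask$legend[[layer]]
}

check_mask_pairing <- function(map, mask) {
  dm <- dim(map$absorbance)[1:2]
  if (!identical(dm, dim(mask$labels)))
    stop("mask extents (", paste(dim(mask$labels), collapse = "x"),
         ") do not match map extents (", paste(dm, collapse = "x"), ")",
         call. = FALSE)
  invisible(TRUE)
}

#' 2-D chemical map of one biochemical parameter
#'
#' Result of evaluating a [parameter_spec()] at every pixel of a
#' [spectral_map()]: a value image plus a validity mask.  Invalid pixels
#' (ratio denominators below the floor, non-tissue pixels) carry `NA` in
#' `values` and `FALSE` in `valid`; they are never silently zero.
#'
#' @param values numeric matrix (AU·cm^-1, AU, or dimensionless ratio).
#' @param valid logical matrix, same extents.
#' @param parameter parameter name.
#' @param units unit string.
#' @return An object of class `chemical_map`.
#' @export
chemical_map <- function(values, valid, parameter, units = "") {
  values <- as.matrix(values)
  valid <- as.matrix(valid)
  if (!identical(dim(values), dim(valid)))
    stop("values/valid extents differ", call. = FALSE)
  if (any(!is.finite(values[valid])))
    stop("chemical map contains non-finite values flagged as valid",
         call. = FALSE)
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid, parameter = parameter,
                 units = units),
            class = "chemical_map")
}

#' @export
print.chemical_map <- function(x, ...) {
  cat(sprintf("<chemical_map> '%s' %d x %d px, %d valid (%s)\n",
              x$parameter, nrow(x$values), ncol(x$values), sum(x$valid),
              if (nzchar(x$units)) x$units else "dimensionless"))
  invisible(x)
}

#' @export
#' @importFrom graphics image
plot.chemical_map <- function(x, ...) {
  image(t(x$values[nrow(x$values):1, , drop = FALSE]), axes = FALSE,
        main = x$parameter, ...)
  invisible(x)
}

#' Validate a tidy table of daily seizure logs
#'
#' Seizure logs are stored tidily: one row per animal-day with clonic and
#' tonic seizure intensity scores and durations.  Intensities follow the
#' two behavioral scales used for electroshock seizures: tonic 0-3
#' (0 none, 3 complete hind-limb extension) and clonic on a modified
#' Racine-type scale, by default 0-`clonic_max`.
#'
#' @param logs data.frame with columns `animal_id`, `day`,
#'   `clonic_intensity`, `clonic_duration_s`, `tonic_intensity`,
#'   `tonic_duration_s`.
#' @param days expected number of daily records per animal (default 21).
#' @param clonic_max maximum clonic intensity score (default 5).
#' @return the validated data.frame, invisibly classed `seizure_logs`.
#' @export
validate_logs <- function(logs, days = 21, clonic_max = 5) {
  logs <- as.data.frame(logs)
  need <- c("animal_id", "day", "clonic_intensity", "clonic_duration_s",
            "tonic_intensity", "tonic_duration_s")
  miss <- setdiff(need, names(logs))
  if (length(miss))
    stop("seizure log missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(logs) == 0L)
    stop("seizure log table is empty", call. = FALSE)
  cnt <- table(logs$animal_id)
  bad <- names(cnt)[cnt != days]
  if (length(bad))
    stop("animals with != ", days, " daily records: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!all(logs$tonic_intensity %in% 0:3))
    stop("tonic intensity outside {0,1,2,3}", call. = FALSE)
  if (!all(logs$clonic_intensity %in% 0:clonic_max))
    stop("clonic intensity outside 0..", clonic_max, call. = FALSE)
  if (any(logs$clonic_duration_s < 0) || any(logs$tonic_duration_s < 0))
    stop("negative seizure duration", call. = FALSE)
  class(logs) <- unique(c("seizure_logs", class(logs)))
  invisible(logs)
}

#' Study manifest
#'
#' Registry of one study: one row per animal with its group label and the
#' paths of its map, mask, and seizure-log files.  Animal ids must be
#' unique (one hippocampal section per brain).
#'
#' @param entries data.frame with columns `animal_id`, `group`, and
#'   optionally `map`, `mask`, `log` (file paths).
#' @return An object of class `study_manifest` with attribute
#'   `group_counts`.
#' @export
study_manifest <- function(entries) {
  entries <- as.data.frame(entries)
  need <- c("animal_id", "group")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("manifest missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- entries$animal_id[duplicated(entries$animal_id)]
  if (length(dup))
    stop("duplicate animal ids in manifest: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  counts <- table(entries$group)
  structure(entries,
            group_counts = setNames(as.integer(counts), names(counts)),
            class = c("study_manifest", "data.frame"))
}

#' @export
print.study_manifest <- function(x, ...) {
  gc <- attr(x, "group_counts")
  cat(sprintf("<study_manifest> %d samples (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(gc), gc), collapse = ", ")))
  invisible(x)
}

#' Per-group sample counts of a manifest
#'
#' @param manifest a [study_manifest()].
#' @return named integer vector of per-group counts with attribute
#'   `total`.
#' @export
manifest_counts <- function(manifest) {
  gc <- attr(manifest, "group_counts")
  attr(gc, "total") <- sum(gc)
  gc
}
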