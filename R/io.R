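#' Read and write hyperspectral map containers
#'
#' The canonical on-disk container is a plain-text file with a one-line
#' JSON header followed by a CSV matrix:
#'
#' * line 1: a JSON object with fields `format` (`"hippospec-map"`),
#'   `version` (1), `nrow`, `ncol`, `nchan`, `metadata` (animal id, group,
#'   pixel size), and `wavenumbers` (the full axis, cm^-1, full `%.17g`
#'   precision);
#' * lines 2..: one CSV row per pixel in column-major order, `nchan`
#'   absorbance values each, written with 17 significant digits so the
#'   write -> read round trip is bit-exact.
#'
#' Descending axes in the header are accepted and re-sorted ascending on
#' read (flagged in `metadata$resorted`).
#'
#' @param map a [spectral_map()].
#' @param path file path.
#' @return `read_map()` returns a [spectral_map()]; `write_map()` returns
#'   `path` invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "spectral_map"))
  d <- dim(map$absorbance)
  header <- jsonlite::toJSON(
    list(format = "hippospec-map", version = 1L,
         nrow = d[1], ncol = d[2], nchan = d[3],
         metadata = map$metadata[c("animal_id", "group", "pixel_size_um")],
         wavenumbers = map$wavenumbers),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  m <- cube_matrix(map)
  txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, con)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path))
    stop("map file not found: ", path, call. = FALSE)
  header_line <- readLines(path, n = 1L)
  hdr <- tryCatch(jsonlite::fromJSON(header_line),
                  error = function(e) NULL)
  if (is.null(hdr) || !identical(hdr$format, "hippospec-map"))
    stop("not a hippospec map container (bad or missing header): ", path,
         call. = FALSE)
  for (f in c("nrow", "ncol", "nchan", "wavenumbers"))
    if (is.null(hdr[[f]]))
      stop("map container missing header field '", f, "': ", path,
           call. = FALSE)
  m <- as.matrix(data.table::fread(path, skip = 1L, header = FALSE,
                                   colClasses = "numeric"))
  if (nrow(m) != hdr$nrow * hdr$ncol || ncol(m) != hdr$nchan)
    stop(sprintf(
      "map payload shape %dx%d does not match header (%d pixels x %d channels)",
      nrow(m), ncol(m), hdr$nrow * hdr$ncol, hdr$nchan), call. = FALSE)
  cube <- array(m, dim = c(hdr$nrow, hdr$ncol, hdr$nchan))
  md <- hdr$metadata
  spectral_map(cube, hdr$wavenumbers,
               animal_id = md$animal_id %||% NA_character_,
               group = md$group %||% NA_character_,
               pixel_size_um = md$pixel_size_um %||% NA_real_)
}

#' Read and write layer masks
#'
#' Masks are stored as a whitespace-separated integer grid (one text line
#' per image row) with the layer legend in a JSON sidecar at
#' `<path>.legend.json` mapping layer names to label values.
#'
#' @param mask a [layer_mask()].
#' @param path grid file path; the legend sidecar path is derived.
#' @return `read_mask()` returns a [layer_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "layer_mask"))
  txt <- apply(mask$labels, 1L, paste, collapse = " ")
  writeLines(txt, path)
  jsonlite::write_json(as.list(mask$legend), paste0(path, ".legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop("mask file not found: ", path, call. = FALSE)
  legend_path <- paste0(path, ".legend.json")
  if (!file.exists(legend_path))
    stop("mask legend sidecar not found: ", legend_path, call. = FALSE)
  rows <- strsplit(trimws(readLines(path)), "\\s+")
  n <- lengths(rows)
  if (length(unique(n)) != 1L)
    stop("ragged mask grid in ", path, call. = FALSE)
  labels <- matrix(as.integer(unlist(rows)), nrow = length(rows),
                   byrow = TRUE)
  legend <- unlist(jsonlite::read_json(legend_path))
  layer_mask(labels, legend)
}

#' Read and write seizure logs
#'
#' Tidy CSV, one row per animal-day; see [validate_logs()] for the schema
#' and scale bounds that are enforced on read.
#'
#' @param logs validated seizure-log data.frame.
#' @param path CSV path.
#' @param days,clonic_max validation settings, see [validate_logs()].
#' @return `read_logs()` returns the validated data.frame.
#' @export
write_logs <- function(logs, path) {
  data.table::fwrite(as.data.frame(logs), path)
  invisible(path)
}

#' @rdname write_logs
#' @export
read_logs <- function(path, days = 21, clonic_max = 5) {
  if (!file.exists(path))
    stop("seizure log file not found: ", path, call. = FALSE)
  logs <- as.data.frame(data.table::fread(path))
  validate_logs(logs, days = days, clonic_max = clonic_max)
}

#' Read and write the study manifest
#'
#' CSV with columns `animal_id`, `group`, `map`, `mask`, `log`; file paths
#' are resolved relative to the manifest's directory.  Reading validates
#' id uniqueness and (when `check_files = TRUE`) that every referenced
#' file exists.
#'
#' @param manifest a [study_manifest()].
#' @param path CSV path.
#' @param check_files verify that referenced files exist (default `TRUE`).
#' @return `read_manifest()` returns a [study_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(as.data.frame(manifest), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path))
    stop("manifest file not found: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path))
  man <- study_manifest(df)
  base <- dirname(normalizePath(path))
  for (col in intersect(c("map", "mask", "log"), names(man))) {
    p <- as.character(man[[col]])
    present <- !is.na(p) & nzchar(p)
    abs <- ifelse(present & !grepl("^(/|[A-Za-z]:)", p),
                  file.path(base, p), p)
    abs[!present] <- NA_character_
    man[[col]] <- abs
    if (check_files) {
      missing <- present & !file.exists(abs)
      if (any(missing))
        stop("manifest references missing ", col, " file(s) for animal(s): ",
             paste(man$animal_id[missing], collapse = ", "), call. = FALSE)
    }
  }
  man
}
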