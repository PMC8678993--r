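# Euclidean-disc structuring element of integer radius r:
# offsets (dx, dy) with dx^2 + dy^2 <= r^2 (r = 1 is the 4-neighbour cross).
disc_kernel <- function(r) {
  stopifnot(r >= 1)
  off <- seq(-r, r)
  outer(off, off, function(dx, dy) as.numeric(dx^2 + dy^2 <= r^2))
}

# Binary erosion with background (FALSE) padding outside the image, so
# regions touching the image edge erode there too.  EBImage::erode pads
# by replication; pad with a background frame first to get the intended
# semantics.
erode_region <- function(region, radius) {
  stopifnot(is.matrix(region), radius >= 0)
  if (radius == 0) return(region)
  r <- as.integer(radius)
  padded <- matrix(0, nrow(region) + 2L * r, ncol(region) + 2L * r)
  padded[(r + 1L):(r + nrow(region)), (r + 1L):(r + ncol(region))] <-
    as.numeric(region)
  er <- EBImage::erode(padded, disc_kernel(r))
  er[(r + 1L):(r + nrow(region)), (r + 1L):(r + ncol(region))] > 0.5
}

#' Extract a cellular layer's pixel values from a chemical map
#'
#' Selects the valid pixels of `cmap` whose mask label equals `layer`,
#' after morphological erosion of the layer region by `erosion` pixels
#' (Euclidean disc; pixels outside the image count as background).
#' Erosion implements the protocol of avoiding points at the borders of
#' the cellular layers.
#'
#' @param cmap a [chemical_map()].
#' @param mask the paired [layer_mask()].
#' @param layer layer name present in the mask legend.
#' @param erosion erosion radius in pixels, `>= 0` (default 1).
#' @return list with `values` (numeric vector, possibly empty) and
#'   `n` (its length).
#' @export
extract_layer_pixels <- function(cmap, mask, layer, erosion = 1) {
  stopifnot(inherits(cmap, "chemical_map"), inherits(mask, "layer_mask"))
  if (!identical(dim(cmap$values), dim(mask$labels)))
    stop("chemical map and mask extents differ", call. = FALSE)
  region <- layer_region(mask, layer)
  region <- erode_region(region, erosion)
  keep <- region & cmap$valid
  values <- cmap$values[keep]
  list(values = values, n = length(values))
}

#' Per-animal summary of one layer's pixel values
#'
#' The per-animal statistic carried into group comparisons is the
#' arithmetic mean of the layer's pixel values.  The QC flag records
#' whether the pixel count reaches the configured minimum for the layer;
#' animals failing QC are excluded from comparisons.
#'
#' @param values numeric vector of pixel values.
#' @param min_count minimum acceptable pixel count.
#' @return list with `mean`, `n`, `qc_pass`.
#' @export
summarize_animal <- function(values, min_count = 1) {
  if (length(values) == 0L)
    return(list(mean = NA_real_, n = 0L, qc_pass = FALSE))
  list(mean = mean(values), n = length(values),
       qc_pass = length(values) >= min_count)
}

#' Default per-layer minimum pixel counts
#'
#' Layer-wise minima applied as QC on per-animal means: 120 (GR), 150
#' (PY), and 300 (MU, MO; "several hundred" interpreted as 300).
#' @return named integer vector.
#' @export
default_pixel_minima <- function() {
  c(GR = 120L, PY = 150L, MU = 300L, MO = 300L)
}

#' Layer-wise per-animal summaries for a set of parameters
#'
#' Runs [compute_parameter()], [extract_layer_pixels()], and
#' [summarize_animal()] for every parameter x layer combination of one
#' animal's map, reusing each band's per-pixel integral across the
#' parameters that share it.
#'
#' @param map the animal's [spectral_map()].
#' @param mask the paired [layer_mask()].
#' @param registry a [parameter_registry()].
#' @param layers layers to summarise (default GR, PY, MU, MO).
#' @param erosion border-exclusion radius in pixels.
#' @param min_pixels named per-layer pixel minima, see
#'   [default_pixel_minima()].
#' @param denom_floor ratio denominator floor, see [compute_parameter()].
#' @param tissue optional tissue mask (logical matrix).
#' @return data.frame with one row per parameter x layer: `animal_id`,
#'   `group`, `layer`, `parameter`, `mean`, `n_pixels`, `qc_pass`.
#' @export
layer_summaries <- function(map, mask, registry = parameter_registry(),
                            layers = c("GR", "PY", "MU", "MO"),
                            erosion = 1,
                            min_pixels = default_pixel_minima(),
                            denom_floor = 1e-3, tissue = NULL) {
  stopifnot(inherits(map, "spectral_map"), inherits(mask, "layer_mask"))
  check_mask_pairing(map, mask)
  d <- dim(map$absorbance)
  m <- cube_matrix(map)

  # integrate each distinct band once
  band_list <- list()
  for (p in registry) {
    band_list[[p$numerator$name]] <- p$numerator
    if (!is.null(p$denominator))
      band_list[[p$denominator$name]] <- p$denominator
  }
  areas <- lapply(band_list, function(b)
    integrate_band_matrix(m, map$wavenumbers, b))

  # eroded layer regions (shared across parameters)
  regions <- lapply(setNames(layers, layers), function(ly)
    erode_region(layer_region(mask, ly), erosion))

  rows <- vector("list", length(registry) * length(layers))
  i <- 0L
  for (p in registry) {
    num <- areas[[p$numerator$name]]
    if (is.null(p$denominator)) {
      vals <- num
      valid <- rep(TRUE, length(num))
    } else {
      den <- areas[[p$denominator$name]]
      valid <- abs(den) >= denom_floor
      vals <- ifelse(valid, num / den, NA_real_)
    }
    if (!is.null(tissue)) valid <- valid & as.vector(tissue)
    for (ly in layers) {
      keep <- as.vector(regions[[ly]]) & valid
      s <- summarize_animal(vals[keep],
                            min_count = min_pixels[[ly]] %||% 1L)
      i <- i + 1L
      rows[[i]] <- data.frame(animal_id = map$metadata$animal_id,
                              group = map$metadata$group,
                              layer = ly, parameter = p$name,
                              mean = s$mean, n_pixels = s$n,
                              qc_pass = s$qc_pass,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Mann-Whitney U test between two samples
#'
#' Rank-sum comparison of two groups of per-animal values.  The U
#' statistic is computed from rank sums with midranks for ties.  The
#' two-sided p-value is exact (complete enumeration of rank assignments)
#' when both samples have at most `exact_max` observations and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction is used.  The direction compares the first
#' group's median against the second's.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @param exact_max largest per-group size for which the exact
#'   distribution is used (default 9).
#' @return list of class `mw_result`: `n1`, `n2`, `U`, `p`, `direction`
#'   (`"up"`, `"down"`, `"none"`), `significant`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided", alpha = 0.05,
                         exact_max = 9) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must contain at least one value", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L

  if (length(unique(c(x, y))) == 1L) {
    # completely degenerate: all values identical in both groups
    return(structure(list(n1 = n1, n2 = n2, U = n1 * n2 / 2, p = 1,
                          direction = "none", significant = FALSE,
                          method = "degenerate"),
                     class = "mw_result"))
  }

  use_exact <- n1 <= exact_max && n2 <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = use_exact,
                correct = TRUE))
  U <- unname(wt$statistic)  # R's W for x vs y equals U of the first group
  p <- min(wt$p.value, 1)
  mx <- median(x); my <- median(y)
  direction <- if (mx > my) "up" else if (mx < my) "down" else "none"
  structure(list(n1 = n1, n2 = n2, U = U, p = p, direction = direction,
                 significant = p < alpha,
                 method = if (use_exact) "exact" else "normal"),
            class = "mw_result")
}

#' @export
print.mw_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney: n1=%d n2=%d U=%.1f p=%.4g (%s) %s%s\n",
              x$n1, x$n2, x$U, x$p, x$method, x$direction,
              if (x$significant) " *" else ""))
  invisible(x)
}

# group pairs evaluated for each grouping scheme
grouping_pairs <- function(grouping) {
  switch(grouping,
    group  = list(c("K", "N")),
    clonic = list(c("CS", "N"), c("LCS", "N"), c("CS", "LCS")),
    tonic  = list(c("TS", "N"), c("LTS", "N"), c("TS", "LTS")),
    stop("unknown grouping '", grouping, "'", call. = FALSE))
}

#' Run all group comparisons over a layer-summary table
#'
#' For every requested group pair and every parameter x layer present in
#' `summaries`, compares the QC-passing per-animal means by
#' [mann_whitney()].  Raw p-values drive the default significance flag at
#' `alpha` (one test per comparison, matching a per-comparison 5% level);
#' a Benjamini-Hochberg adjusted column `p_bh` is reported alongside for
#' transparency but does not affect the flag.
#'
#' @param summaries a [layer_summaries()] table (rows from several
#'   animals combined), with a `group` column carrying the labels named
#'   in `pairs`.
#' @param pairs list of 2-vectors of group labels to compare, or a
#'   grouping scheme name: `"group"` (K vs N), `"clonic"` (CS/LCS vs N
#'   and CS vs LCS), `"tonic"` (TS/LTS vs N and TS vs LTS).
#' @param alpha significance level (default 0.05).
#' @param min_n smallest per-group animal count required to run a test
#'   (default 1).
#' @return data.frame, one row per parameter x layer x pair:
#'   `parameter`, `layer`, `group1`, `group2`, `n1`, `n2`, `U`, `p`,
#'   `p_bh`, `direction`, `significant`.
#' @export
run_comparisons <- function(summaries, pairs = "group", alpha = 0.05,
                            min_n = 1) {
  if (is.character(pairs) && length(pairs) == 1L)
    pairs <- grouping_pairs(pairs)
  present <- unique(summaries$group)
  for (pr in pairs) {
    unknown <- setdiff(pr, present)
    if (length(unknown))
      stop("group label(s) absent from summaries: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  ok <- summaries$qc_pass & is.finite(summaries$mean)
  summaries <- summaries[ok, , drop = FALSE]
  combos <- unique(summaries[, c("parameter", "layer")])
  rows <- list()
  for (pr in pairs) {
    for (k in seq_len(nrow(combos))) {
      sub <- summaries[summaries$parameter == combos$parameter[k] &
                         summaries$layer == combos$layer[k], ]
      xv <- sub$mean[sub$group == pr[1]]
      yv <- sub$mean[sub$group == pr[2]]
      if (length(xv) < min_n || length(yv) < min_n) next
      r <- mann_whitney(xv, yv, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = combos$parameter[k], layer = combos$layer[k],
        group1 = pr[1], group2 = pr[2], n1 = r$n1, n2 = r$n2,
        U = r$U, p = r$p, direction = r$direction,
        significant = r$significant, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no comparable parameter x layer x pair combinations", call. = FALSE)
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$p, method = "BH")
  out[, c("parameter", "layer", "group1", "group2", "n1", "n2", "U",
          "p", "p_bh", "direction", "significant")]
}
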