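#' Simulate a complete phantom study
#'
#' Generates a kindled-vs-control cohort: `n_k` stimulated (K) and `n_n`
#' control (N) animals, each with its own tissue phantom, plus daily
#' seizure logs for the K animals with planted severity tiers.  Animal-
#' to-animal biological variability is modelled as an independent
#' log-normal factor on each band's amplitude (coefficient of variation
#' `animal_cv`, applied identically across that animal's layers); the K
#' group's phantoms additionally carry the [effect_map()] factors.
#'
#' A single `seed` drives everything: it is fanned out into per-animal
#' phantom seeds and a seizure-log seed, so the same seed always yields
#' the same study.
#'
#' @param n_k,n_n animals per group (defaults 16 stimulated, 10 control).
#' @param config base [phantom_config()] shared by all animals.
#' @param effects an [effect_map()] applied to the K group (or `NULL`
#'   for a null study).
#' @param seizure_config a [seizure_sim_config()]; its cohort size must
#'   equal `n_k`.
#' @param animal_cv between-animal coefficient of variation of band
#'   amplitudes (default 0.05).
#' @param seed master seed.
#' @param dir if non-`NULL`, the study is written to this directory
#'   (maps, masks, logs, `manifest.csv`) instead of being kept in
#'   memory.
#' @return If `dir` is `NULL`: a list of class `phantom_study` with
#'   `manifest` ([study_manifest()]), `maps`, `masks` (named lists),
#'   `logs`, `ground_truth` (named list of per-animal band-area tables),
#'   `seizure_truth`.  Otherwise the path of the written manifest.
#' @export
simulate_study <- function(n_k = 16, n_n = 10,
                           config = phantom_config(),
                           effects = default_effect_map(),
                           seizure_config = seizure_sim_config(),
                           animal_cv = 0.05, seed = 1L, dir = NULL) {
  if (sum(seizure_config$clonic_tiers$n) != n_k)
    stop("seizure config cohort size (",
         sum(seizure_config$clonic_tiers$n),
         ") must equal n_k (", n_k, ")", call. = FALSE)
  set.seed(seed)
  n <- n_k + n_n
  ids <- c(sprintf("K%02d", seq_len(n_k)), sprintf("N%02d", seq_len(n_n)))
  groups <- c(rep("K", n_k), rep("N", n_n))
  phantom_seeds <- sample.int(.Machine$integer.max - 1L, n)
  seizure_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  # per animal x band jitter factors, drawn up front under the master seed
  nb <- length(config$layer_bands[[1]])
  jitter <- matrix(exp(rnorm(n * nb, sd = animal_cv)), n, nb)

  maps <- masks <- gts <- setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- phantom_seeds[i]
    cfg$layer_bands <- lapply(cfg$layer_bands, function(bands) {
      for (j in seq_along(bands))
        bands[[j]]$amplitude <- bands[[j]]$amplitude * jitter[i, j]
      bands
    })
    ph <- make_phantom(cfg, effects = effects, group = groups[i],
                       animal_id = ids[i])
    maps[[i]] <- ph$map
    masks[[i]] <- ph$mask
    gts[[i]] <- ph$ground_truth
  }

  sc <- seizure_config
  sc$seed <- seizure_seed
  sim <- make_seizure_logs(sc, id_prefix = "K")

  man <- study_manifest(data.frame(animal_id = ids, group = groups,
                                   stringsAsFactors = FALSE))
  study <- structure(list(manifest = man, maps = maps, masks = masks,
                          logs = sim$logs, ground_truth = gts,
                          seizure_truth = sim$truth, seed = seed),
                     class = "phantom_study")
  if (is.null(dir)) return(study)
  write_study(study, dir)
}

#' Write a phantom study to disk
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "phantom_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- as.data.frame(study$manifest)
  man$map <- file.path(dir, paste0(man$animal_id, ".map.txt"))
  man$mask <- file.path(dir, paste0(man$animal_id, ".mask.txt"))
  log_path <- file.path(dir, "seizure_logs.csv")
  man$log <- ifelse(man$group == "K", log_path, NA_character_)
  for (i in seq_len(nrow(man))) {
    write_map(study$maps[[man$animal_id[i]]], man$map[i])
    write_mask(study$masks[[man$animal_id[i]]], man$mask[i])
  }
  write_logs(study$logs, log_path)
  gt <- do.call(rbind, lapply(names(study$ground_truth), function(id)
    cbind(animal_id = id, study$ground_truth[[id]])))
  data.table::fwrite(gt, file.path(dir, "ground_truth_bands.tsv"),
                     sep = "\t")
  data.table::fwrite(study$seizure_truth,
                     file.path(dir, "seizure_truth.csv"))
  path <- file.path(dir, "manifest.csv")
  # manifest stores paths relative to its own directory
  rel <- man
  for (col in c("map", "mask", "log")) rel[[col]] <- basename(rel[[col]])
  write_manifest(study_manifest(rel), path)
  invisible(path)
}

#' Analysis configuration
#'
#' Collects every tunable of the analysis chain so nothing is hard-coded
#' in [run_study()].
#'
#' @param registry [parameter_registry()] to quantify.
#' @param erosion layer border-exclusion radius, pixels.
#' @param min_pixels per-layer pixel minima ([default_pixel_minima()]).
#' @param alpha significance level.
#' @param denom_floor ratio denominator floor (AU·cm^-1).
#' @param tissue_threshold amide I area threshold separating tissue from
#'   background (AU·cm^-1); `NULL` disables tissue masking.
#' @param k_clonic,k_tonic severity cluster counts.
#' @param standardize,dialect clustering options, see [ward_cluster()].
#' @return list of class `run_config`.
#' @export
run_config <- function(registry = parameter_registry(), erosion = 1,
                       min_pixels = default_pixel_minima(), alpha = 0.05,
                       denom_floor = 1e-3, tissue_threshold = 1,
                       k_clonic = 3, k_tonic = 2, standardize = TRUE,
                       dialect = "ward.D") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (erosion < 0) stop("erosion must be >= 0", call. = FALSE)
  structure(list(registry = registry, erosion = erosion,
                 min_pixels = min_pixels, alpha = alpha,
                 denom_floor = denom_floor,
                 tissue_threshold = tissue_threshold,
                 k_clonic = k_clonic, k_tonic = k_tonic,
                 standardize = standardize, dialect = dialect),
            class = "run_config")
}

# iterate animals of an in-memory study or a manifest on disk
study_animals <- function(x) {
  if (inherits(x, "phantom_study")) {
    man <- x$manifest
    list(manifest = man,
         get = function(id) list(map = x$maps[[id]], mask = x$masks[[id]]),
         logs = x$logs)
  } else if (is.character(x) && length(x) == 1L) {
    man <- read_manifest(x)
    log_paths <- unique(stats::na.omit(man$log))
    logs <- if (length(log_paths))
      do.call(rbind, lapply(log_paths, function(p)
        as.data.frame(data.table::fread(p)))) else NULL
    list(manifest = man,
         get = function(id) {
           row <- man[man$animal_id == id, ]
           list(map = read_map(row$map), mask = read_mask(row$mask))
         },
         logs = logs)
  } else {
    stop("`x` must be a phantom_study or a manifest path", call. = FALSE)
  }
}

#' Run the full analysis chain on a study
#'
#' Executes quantification, layer-wise summarisation, K-vs-N
#' comparisons, seizure-severity clustering, and subgroup comparisons on
#' an in-memory [simulate_study()] object or a manifest path.  The run
#' is deterministic given its inputs (no randomness is used after data
#' generation).
#'
#' Subgroup comparisons relabel the stimulated animals by their clonic
#' (CS / ICS / LCS) or tonic (TS / LTS) severity subgroup and compare
#' severe and light subgroups against controls and against each other;
#' intermediate clonic animals (ICS) take part in the clustering but not
#' in the severe-vs-light comparisons.
#'
#' @param x a `phantom_study` or the path of a manifest CSV.
#' @param config a [run_config()].
#' @return list of class `study_result`: `summaries` (per animal x layer
#'   x parameter), `comparisons` (named list of comparison tables:
#'   `group`, and `clonic`/`tonic` when logs are available), `subgroups`
#'   (assignment data.frame or `NULL`), `clustering` (list with the two
#'   [ward_cluster()] objects), `qc` (QC report list).
#' @export
run_study <- function(x, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  src <- study_animals(x)
  man <- src$manifest

  summaries <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    id <- man$animal_id[i]
    a <- src$get(id)
    if (is.null(a$map) || is.null(a$mask))
      stop("study stage 'quantify': missing map or mask for animal ", id,
           call. = FALSE)
    tissue <- if (is.null(config$tissue_threshold)) NULL
              else tissue_mask(a$map, config$tissue_threshold)
    summaries[[i]] <- layer_summaries(
      a$map, a$mask, registry = config$registry,
      erosion = config$erosion, min_pixels = config$min_pixels,
      denom_floor = config$denom_floor, tissue = tissue)
  }
  summaries <- do.call(rbind, summaries)

  comparisons <- list(
    group = run_comparisons(summaries, "group", alpha = config$alpha))

  subgroups <- NULL
  clustering <- NULL
  if (!is.null(src$logs)) {
    sg <- assign_subgroups(src$logs, k_clonic = config$k_clonic,
                           k_tonic = config$k_tonic,
                           standardize = config$standardize,
                           dialect = config$dialect)
    subgroups <- sg$assignment
    clustering <- list(clonic = sg$clonic, tonic = sg$tonic)

    relabel <- function(col) {
      lab <- subgroups[[col]][match(summaries$animal_id,
                                    subgroups$animal_id)]
      ifelse(summaries$group == "N", "N", lab)
    }
    for (scheme in c("clonic", "tonic")) {
      s2 <- summaries
      s2$group <- relabel(paste0(scheme, "_subgroup"))
      s2 <- s2[!is.na(s2$group), , drop = FALSE]
      comparisons[[scheme]] <- run_comparisons(s2, scheme,
                                               alpha = config$alpha)
    }
  }

  qc_fail <- summaries[!summaries$qc_pass,
                       c("animal_id", "layer", "parameter", "n_pixels")]
  qc <- list(
    n_animals = nrow(man),
    group_counts = as.list(manifest_counts(man)),
    excluded = qc_fail,
    n_excluded = nrow(qc_fail),
    config = list(erosion = config$erosion,
                  min_pixels = as.list(config$min_pixels),
                  alpha = config$alpha, denom_floor = config$denom_floor,
                  tissue_threshold = config$tissue_threshold,
                  k_clonic = config$k_clonic, k_tonic = config$k_tonic,
                  standardize = config$standardize,
                  dialect = config$dialect))

  structure(list(summaries = summaries, comparisons = comparisons,
                 subgroups = subgroups, clustering = clustering, qc = qc),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d animals, %d summaries, %d comparison table(s)\n",
              x$qc$n_animals, nrow(x$summaries), length(x$comparisons)))
  for (nm in names(x$comparisons)) {
    tab <- x$comparisons[[nm]]
    cat(sprintf("  %s: %d comparisons, %d significant at alpha = %g\n",
                nm, nrow(tab), sum(tab$significant), x$qc$config$alpha))
  }
  invisible(x)
}

#' Write a study result bundle to disk
#'
#' Exports the per-animal summaries and every comparison table as TSV,
#' the subgroup assignment as CSV, both dendrograms as merge-list TSV
#' plus Newick, and the QC report as JSON.
#'
#' @param result a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(result$summaries,
                     file.path(dir, "layer_summaries.tsv"), sep = "\t")
  for (nm in names(result$comparisons))
    data.table::fwrite(result$comparisons[[nm]],
                       file.path(dir, paste0("comparisons_", nm, ".tsv")),
                       sep = "\t")
  if (!is.null(result$subgroups)) {
    data.table::fwrite(result$subgroups, file.path(dir, "subgroups.csv"))
    for (nm in names(result$clustering))
      write_dendrogram(result$clustering[[nm]],
                       file.path(dir, paste0("dendrogram_", nm, ".tsv")),
                       newick = file.path(dir,
                                          paste0("dendrogram_", nm, ".nwk")))
  }
  jsonlite::write_json(result$qc, file.path(dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  invisible(dir)
}
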