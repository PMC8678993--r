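#' Seizure-log simulation configuration
#'
#' Defines a cohort of stimulated animals whose daily seizure records are
#' drawn around planted severity tiers, independently for clonic and
#' tonic seizures.  Each tier sets the mean and dispersion of the daily
#' intensity score and of the daily seizure duration.  Daily intensities
#' are rounded and clamped to their behavioral scale: tonic 0-3, clonic
#' 0-`clonic_max` (a modified Racine-type scale, 0-5 by default);
#' durations are truncated at 0.
#'
#' The default tiers plant three clonic severity levels (severe /
#' intermediate / light: 5, 5, and 6 animals) and two tonic levels
#' (severe / light: 7 and 9 animals) in a 16-animal cohort, with daily
#' means separated by many within-tier standard deviations so cumulative
#' features cluster cleanly.  Tonic tier membership is assigned by a
#' seeded permutation, so clonic and tonic severities are not aligned
#' animal by animal.
#'
#' @param days stimulation days (default 21).
#' @param clonic_tiers,tonic_tiers data.frames with columns `label`,
#'   `n`, `intensity_mean`, `intensity_sd`, `duration_mean`,
#'   `duration_sd` (durations in seconds).  Tier `n` must sum to the
#'   same total in both tables.
#' @param clonic_max maximum clonic intensity score (default 5).
#' @param seed integer RNG seed.
#' @return list of class `seizure_sim_config`.
#' @export
seizure_sim_config <- function(
    days = 21,
    clonic_tiers = data.frame(
      label = c("severe", "intermediate", "light"),
      n = c(5L, 5L, 6L),
      intensity_mean = c(4.2, 2.2, 0.4), intensity_sd = c(0.5, 0.5, 0.4),
      duration_mean = c(70, 35, 5), duration_sd = c(10, 8, 3)),
    tonic_tiers = data.frame(
      label = c("severe", "light"),
      n = c(7L, 9L),
      intensity_mean = c(2.3, 0.4), intensity_sd = c(0.4, 0.3),
      duration_mean = c(20, 3), duration_sd = c(5, 2)),
    clonic_max = 5,
    seed = 1L) {
  if (days < 1) stop("days must be >= 1", call. = FALSE)
  for (tiers in list(clonic = clonic_tiers, tonic = tonic_tiers)) {
    need <- c("label", "n", "intensity_mean", "intensity_sd",
              "duration_mean", "duration_sd")
    miss <- setdiff(need, names(tiers))
    if (length(miss))
      stop("tier table missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (any(tiers$n < 1))
      stop("every tier needs at least one animal", call. = FALSE)
    if (any(tiers$intensity_sd < 0) || any(tiers$duration_sd < 0))
      stop("tier dispersions must be >= 0", call. = FALSE)
    if (any(tiers$duration_mean < 0))
      stop("tier duration means must be >= 0", call. = FALSE)
  }
  if (sum(clonic_tiers$n) != sum(tonic_tiers$n))
    stop("clonic and tonic tier sizes must sum to the same cohort size",
         call. = FALSE)
  structure(list(days = as.integer(days), clonic_tiers = clonic_tiers,
                 tonic_tiers = tonic_tiers, clonic_max = clonic_max,
                 seed = as.integer(seed)),
            class = "seizure_sim_config")
}

# daily integer scores: normal draw, rounded, clamped to [0, max]
draw_scores <- function(n, mean, sd, max) {
  pmin(pmax(round(rnorm(n, mean, sd)), 0), max)
}

# daily durations: normal draw truncated at 0
draw_durations <- function(n, mean, sd) {
  pmax(rnorm(n, mean, sd), 0)
}

#' Simulate seizure logs with planted severity clusters
#'
#' Generates one 21-day (configurable) daily record per animal.  Animals
#' are assigned to the configured clonic tiers in blocks and to the tonic
#' tiers by a seeded random permutation of the same cohort.  Tier
#' membership is returned as ground truth for validating the severity
#' clustering downstream.
#'
#' @param config a [seizure_sim_config()].
#' @param id_prefix prefix for generated animal ids (default `"K"`).
#' @return list with `logs` (tidy data.frame, one row per animal-day,
#'   validated by [validate_logs()]) and `truth` (data.frame
#'   `animal_id`, `clonic_tier`, `tonic_tier`).
#' @export
make_seizure_logs <- function(config = seizure_sim_config(),
                              id_prefix = "K") {
  stopifnot(inherits(config, "seizure_sim_config"))
  set.seed(config$seed)
  n <- sum(config$clonic_tiers$n)
  ids <- sprintf("%s%02d", id_prefix, seq_len(n))
  clonic_tier <- rep(config$clonic_tiers$label, config$clonic_tiers$n)
  tonic_tier <- rep(config$tonic_tiers$label, config$tonic_tiers$n)[
    sample.int(n)]

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ct <- config$clonic_tiers[config$clonic_tiers$label == clonic_tier[i], ]
    tt <- config$tonic_tiers[config$tonic_tiers$label == tonic_tier[i], ]
    rows[[i]] <- data.frame(
      animal_id = ids[i],
      day = seq_len(config$days),
      clonic_intensity = draw_scores(config$days, ct$intensity_mean,
                                     ct$intensity_sd, config$clonic_max),
      clonic_duration_s = draw_durations(config$days, ct$duration_mean,
                                         ct$duration_sd),
      tonic_intensity = draw_scores(config$days, tt$intensity_mean,
                                    tt$intensity_sd, 3),
      tonic_duration_s = draw_durations(config$days, tt$duration_mean,
                                        tt$duration_sd),
      stringsAsFactors = FALSE)
  }
  logs <- do.call(rbind, rows)
  rownames(logs) <- NULL
  logs <- validate_logs(logs, days = config$days,
                        clonic_max = config$clonic_max)
  truth <- data.frame(animal_id = ids, clonic_tier = clonic_tier,
                      tonic_tier = tonic_tier, stringsAsFactors = FALSE)
  list(logs = logs, truth = truth)
}
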