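#' Cumulative seizure features per animal
#'
#' Sums the daily intensity scores and durations of one seizure type over
#' the whole stimulation period (21 days by default), independently for
#' clonic and tonic seizures.  These two cumulative features per animal
#' are the input of the severity clustering.
#'
#' @param logs tidy seizure-log table (see [validate_logs()]).
#' @param type `"clonic"` or `"tonic"`.
#' @return data.frame with one row per animal: `animal_id`,
#'   `cum_intensity`, `cum_duration_s`, ordered by first appearance in
#'   `logs`.
#' @export
cumulative_features <- function(logs, type = c("clonic", "tonic")) {
  type <- match.arg(type)
  logs <- as.data.frame(logs)
  ic <- paste0(type, "_intensity")
  dc <- paste0(type, "_duration_s")
  if (!all(c("animal_id", ic, dc) %in% names(logs)))
    stop("log table lacks the columns for seizure type '", type, "'",
         call. = FALSE)
  ids <- unique(logs$animal_id)
  out <- data.frame(
    animal_id = ids,
    cum_intensity = vapply(ids, function(a)
      sum(logs[[ic]][logs$animal_id == a]), 0),
    cum_duration_s = vapply(ids, function(a)
      sum(logs[[dc]][logs$animal_id == a]), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ward hierarchical clustering of seizure-behavior features
#'
#' Agglomerative clustering of animals on their cumulative seizure
#' intensity and duration, using Ward's minimum-variance criterion in the
#' classic dialect: the Lance-Williams Ward update applied to pairwise
#' *squared* Euclidean distances (`ward.D` on squared distances, the
#' convention of classic statistical packages).  The alternative dialect
#' (`ward.D2` on distances) is available via `dialect`.
#'
#' Because intensity scores and durations (seconds) are incommensurate,
#' the two features are z-score standardized before clustering by
#' default; a zero-variance feature is left centred at 0.
#'
#' @param features data.frame from [cumulative_features()] (columns
#'   `animal_id`, `cum_intensity`, `cum_duration_s`).
#' @param k number of clusters to cut, `1 <= k <= n`.
#' @param standardize z-score the features first (default `TRUE`).
#' @param dialect `"ward.D"` (squared Euclidean; default) or
#'   `"ward.D2"`.
#' @param labels optional character vector of severity labels, most to
#'   least severe, of length `k`; clusters are labelled in decreasing
#'   order of mean raw cumulative intensity (ties broken by mean
#'   cumulative duration, then lowest member index).  Defaults to
#'   `"C1" > "C2" > ...`.
#' @return list of class `ward_clustering`: `hclust` (the tree; `NULL`
#'   for n = 1), `merges` (data.frame of merge steps with heights),
#'   `assignment` (data.frame `animal_id`, `cluster`, `subgroup`),
#'   `k`, `dialect`, `standardize`.
#' @export
ward_cluster <- function(features, k, standardize = TRUE,
                         dialect = c("ward.D", "ward.D2"), labels = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(features))
  n <- nrow(features)
  if (k < 1 || k > n)
    stop("k must satisfy 1 <= k <= n (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  X <- as.matrix(features[, c("cum_intensity", "cum_duration_s")])
  rownames(X) <- features$animal_id
  if (standardize) {
    X <- apply(X, 2L, function(col) {
      s <- sd(col)
      if (is.na(s) || s == 0) col - mean(col) else (col - mean(col)) / s
    })
    if (n == 1L) X <- matrix(0, 1L, 2L, dimnames = list(features$animal_id))
  }

  if (n == 1L) {
    assignment <- data.frame(animal_id = features$animal_id, cluster = 1L,
                             stringsAsFactors = FALSE)
    hc <- NULL
    merges <- data.frame(a = integer(), b = integer(), height = numeric(),
                         size = integer())
  } else {
    d <- dist(X)
    if (dialect == "ward.D") d <- d^2
    hc <- hclust(d, method = dialect)
    if (all(hc$height == 0))
      warning("all merge heights are zero (identical feature vectors); ",
              "cluster assignment is determined by tie-breaking only",
              call. = FALSE)
    cl <- cutree(hc, k = k)
    assignment <- data.frame(animal_id = features$animal_id,
                             cluster = unname(cl),
                             stringsAsFactors = FALSE)
    # merge sizes: number of leaves in each newly formed cluster
    sizes <- integer(n - 1L)
    for (i in seq_len(n - 1L)) {
      s <- 0L
      for (j in hc$merge[i, ]) s <- s + if (j < 0) 1L else sizes[j]
      sizes[i] <- s
    }
    merges <- data.frame(a = hc$merge[, 1], b = hc$merge[, 2],
                         height = hc$height, size = sizes)
  }

  # severity ordering: decreasing mean raw cumulative intensity
  raw <- as.matrix(features[, c("cum_intensity", "cum_duration_s")])
  stats <- lapply(sort(unique(assignment$cluster)), function(cl) {
    idx <- which(assignment$cluster == cl)
    list(cluster = cl, mi = mean(raw[idx, 1]), md = mean(raw[idx, 2]),
         first = min(idx))
  })
  ord <- order(-vapply(stats, `[[`, 0, "mi"),
               -vapply(stats, `[[`, 0, "md"),
               vapply(stats, `[[`, 0, "first"))
  if (is.null(labels)) labels <- paste0("C", seq_len(k))
  if (length(labels) != k)
    stop("need exactly k = ", k, " severity labels", call. = FALSE)
  lab_of <- setNames(labels, vapply(stats, `[[`, 0, "cluster")[ord])
  assignment$subgroup <- unname(lab_of[as.character(assignment$cluster)])

  structure(list(hclust = hc, merges = merges, assignment = assignment,
                 k = k, dialect = dialect, standardize = standardize),
            class = "ward_clustering")
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("<ward_clustering> %d animals, k = %d (%s%s)\n",
              nrow(x$assignment), x$k, x$dialect,
              if (x$standardize) ", standardized" else ""))
  print(table(x$assignment$subgroup))
  invisible(x)
}

#' Assign clonic and tonic severity subgroups
#'
#' Runs the severity clustering independently on the clonic and tonic
#' cumulative features of the same animals: the clonic tree is cut at
#' k = 3 into severe / intermediate / light clonic seizures (CS, ICS,
#' LCS) and the tonic tree at k = 2 into severe / light tonic seizures
#' (TS, LTS).  Labels are ordered by cluster-mean cumulative intensity
#' (highest = severe).
#'
#' @param logs tidy seizure-log table covering the stimulated animals.
#' @param k_clonic,k_tonic cluster counts (defaults 3 and 2).
#' @param standardize,dialect passed to [ward_cluster()].
#' @return list with `assignment` (data.frame `animal_id`,
#'   `clonic_subgroup`, `tonic_subgroup`), `clonic` and `tonic`
#'   (the two [ward_cluster()] objects).
#' @export
assign_subgroups <- function(logs, k_clonic = 3, k_tonic = 2,
                             standardize = TRUE, dialect = "ward.D") {
  fc <- cumulative_features(logs, "clonic")
  ft <- cumulative_features(logs, "tonic")
  if (!setequal(fc$animal_id, ft$animal_id))
    stop("clonic and tonic features cover different animal sets",
         call. = FALSE)
  clonic_labels <- switch(as.character(k_clonic),
                          "3" = c("CS", "ICS", "LCS"),
                          "2" = c("CS", "LCS"), NULL)
  tonic_labels <- if (k_tonic == 2) c("TS", "LTS") else NULL
  wc <- ward_cluster(fc, k_clonic, standardize = standardize,
                     dialect = dialect, labels = clonic_labels)
  wt <- ward_cluster(ft, k_tonic, standardize = standardize,
                     dialect = dialect, labels = tonic_labels)
  assignment <- data.frame(
    animal_id = fc$animal_id,
    clonic_subgroup = wc$assignment$subgroup,
    tonic_subgroup = wt$assignment$subgroup[
      match(fc$animal_id, wt$assignment$animal_id)],
    stringsAsFactors = FALSE)
  list(assignment = assignment, clonic = wc, tonic = wt)
}

#' Export a dendrogram
#'
#' Writes the merge list as TSV (`a`, `b`, `height`, `size`; negative
#' indices are leaves, positive indices earlier merges, following the
#' `hclust` convention) and, optionally, the tree in Newick format with
#' merge heights as node depths for external viewers.
#'
#' @param clustering a [ward_cluster()] result.
#' @param path output TSV path.
#' @param newick optional Newick output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(clustering, path, newick = NULL) {
  stopifnot(inherits(clustering, "ward_clustering"))
  data.table::fwrite(clustering$merges, path, sep = "\t")
  if (!is.null(newick)) {
    if (is.null(clustering$hclust))
      stop("single-leaf clustering has no tree to serialise", call. = FALSE)
    phy <- ape::as.phylo(clustering$hclust)
    ape::write.tree(phy, file = newick)
  }
  invisible(path)
}
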