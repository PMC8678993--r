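feat <- function(intensity, duration = rep(0, length(intensity)),
                 ids = sprintf("K%02d", seq_along(intensity))) {
  data.frame(animal_id = ids, cum_intensity = intensity,
             cum_duration_s = duration)
}

test_that("k = n puts every animal in its own cluster", {
  f <- feat(c(1, 5, 9, 13), c(10, 20, 30, 40))
  wc <- ward_cluster(f, k = 4)
  expect_equal(sort(unique(wc$assignment$cluster)), 1:4)
  expect_equal(anyDuplicated(wc$assignment$cluster), 0)
})

test_that("1-D features {0, 1, 10} at k = 2 isolate the outlier", {
  f <- feat(c(0, 1, 10))
  wc <- ward_cluster(f, k = 2, standardize = FALSE)
  cl <- wc$assignment$cluster
  expect_equal(cl[1], cl[2])
  expect_false(cl[3] == cl[1])
  # {0,1} merge first, at the lowest height
  expect_setequal(-c(wc$merges$a[1], wc$merges$b[1]), c(1, 2))
  expect_true(all(diff(wc$merges$height) >= 0))
})

test_that("merge heights are non-decreasing (Ward reducibility)", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    f <- feat(rnorm(n), rnorm(n))
    wc <- ward_cluster(f, k = 2)
    expect_true(all(diff(wc$merges$height) >= -1e-12))
  }
})

test_that("clustering is permutation-invariant on tie-free inputs", {
  set.seed(42)
  for (i in 1:15) {
    n <- 8
    f <- feat(rnorm(n), rnorm(n))
    wc1 <- ward_cluster(f, k = 3)
    perm <- sample.int(n)
    wc2 <- ward_cluster(f[perm, ], k = 3)
    expect_equal(sort(wc1$merges$height), sort(wc2$merges$height),
                 tolerance = 1e-9)
    # same partition: severity labels are order-independent
    lab1 <- setNames(wc1$assignment$subgroup, wc1$assignment$animal_id)
    lab2 <- setNames(wc2$assignment$subgroup, wc2$assignment$animal_id)
    expect_identical(lab1[sort(names(lab1))], lab2[sort(names(lab2))])
  }
})

test_that("the k = 2 cut matches an exhaustive-partition WSS check", {
  # greedy Ward's k = 2 cut should achieve a within-cluster sum of squares
  # no worse than any 2-partition achievable by the Ward merge path; check
  # against the global optimum over all 2-partitions on tiny sets
  wss2 <- function(X, grp) {
    sum(vapply(unique(grp), function(g) {
      Y <- X[grp == g, , drop = FALSE]
      sum(scale(Y, scale = FALSE)^2)
    }, 0))
  }
  set.seed(43)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    X <- matrix(rnorm(2 * n), n, 2)
    f <- feat(X[, 1], X[, 2])
    wc <- ward_cluster(f, k = 2, standardize = FALSE)
    got <- wss2(X, wc$assignment$cluster)
    best <- Inf
    for (code in 1:(2^(n - 1) - 1)) {
      grp <- as.integer(intToBits(code))[1:n]
      best <- min(best, wss2(X, grp))
    }
    # Ward is greedy: allow it to be at or above the optimum, but it must
    # be a genuine 2-partition and close to optimal on separated data
    expect_gte(got + 1e-9, best)
    expect_equal(length(unique(wc$assignment$cluster)), 2)
  }
})

test_that("planted two-tier logs are recovered exactly at k = 2", {
  tiers2 <- data.frame(label = c("hi", "lo"), n = c(5L, 5L),
                       intensity_mean = c(2.4, 0.3),
                       intensity_sd = c(0.3, 0.3),
                       duration_mean = c(25, 3), duration_sd = c(4, 2))
  for (s in 1:10) {
    cfg <- seizure_sim_config(clonic_tiers = data.frame(
      label = c("a", "b"), n = c(5L, 5L), intensity_mean = c(4, 1),
      intensity_sd = 0.4, duration_mean = c(60, 10), duration_sd = 5),
      tonic_tiers = tiers2, seed = s)
    sim <- make_seizure_logs(cfg)
    f <- cumulative_features(sim$logs, "tonic")
    wc <- ward_cluster(f, k = 2)
    tab <- table(wc$assignment$cluster,
                 sim$truth$tonic_tier[match(wc$assignment$animal_id,
                                            sim$truth$animal_id)])
    expect_equal(sum(apply(tab, 1, max)), 10)  # pure clusters
  }
})

test_that("three planted clonic tiers map onto CS/ICS/LCS in severity order", {
  sim <- make_seizure_logs(seizure_sim_config(seed = 7))
  sg <- assign_subgroups(sim$logs)
  merged <- merge(sg$assignment, sim$truth)
  expect_true(all(merged$clonic_subgroup[merged$clonic_tier == "severe"] == "CS"))
  expect_true(all(merged$clonic_subgroup[merged$clonic_tier == "intermediate"] == "ICS"))
  expect_true(all(merged$clonic_subgroup[merged$clonic_tier == "light"] == "LCS"))
  expect_true(all(merged$tonic_subgroup[merged$tonic_tier == "severe"] == "TS"))
  expect_true(all(merged$tonic_subgroup[merged$tonic_tier == "light"] == "LTS"))

  # severity ordering invariant on cumulative intensity
  f <- cumulative_features(sim$logs, "clonic")
  by_lab <- split(f$cum_intensity[match(sg$assignment$animal_id,
                                        f$animal_id)],
                  sg$assignment$clonic_subgroup)
  expect_gte(mean(by_lab$CS), mean(by_lab$ICS))
  expect_gte(mean(by_lab$ICS), mean(by_lab$LCS))
})

test_that("degenerate and edge inputs are handled deterministically", {
  f1 <- feat(5)
  wc1 <- ward_cluster(f1, k = 1)
  expect_equal(nrow(wc1$merges), 0)
  expect_equal(wc1$assignment$cluster, 1L)

  expect_error(ward_cluster(feat(c(1, 2)), k = 3), "k must satisfy")

  same <- feat(rep(3, 5), rep(8, 5))
  expect_warning(wc <- ward_cluster(same, k = 2), "identical")
  expect_equal(length(wc$assignment$subgroup), 5)
  # deterministic: repeated runs give the same labels
  expect_warning(wc2 <- ward_cluster(same, k = 2), "identical")
  expect_identical(wc$assignment, wc2$assignment)
})

test_that("dendrograms export as merge-list TSV and Newick", {
  f <- feat(c(0, 1, 4, 9), c(1, 0, 2, 5))
  wc <- ward_cluster(f, k = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(wc, tsv, newick = nwk)
  merges <- read.delim(tsv)
  expect_equal(nrow(merges), 3)
  expect_named(merges, c("a", "b", "height", "size"))
  phy <- ape::read.tree(nwk)
  expect_equal(sort(phy$tip.label), sort(f$animal_id))
})
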