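test_that("standardized columns have mean 0 and unit n-1 SD", {
  idx <- compute_indices(
    simulate_yield_pairs(sim_preset("paper_heat_clusters", seed = 5)))
  z <- standardize_indices(idx)
  expect_equal(unname(colMeans(z)), rep(0, 9), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 9), tolerance = 1e-12)
  expect_equal(rownames(z), idx$genotype)
})

test_that("two observations standardize to +-1/sqrt(2)", {
  two <- stresskit:::new_yield_pair_table(
    tibble::tibble(genotype = c("A", "B"), Yp = c(100, 200),
                   Ys = c(60, 80)), stress = "heat")
  z <- standardize_indices(compute_indices(two))
  expect_equal(abs(unname(z)),
               matrix(sqrt(2) / 2, 2, 9), tolerance = 1e-12)
})

test_that("zero-variance columns are refused by name", {
  idx <- compute_indices(
    simulate_yield_pairs(sim_preset("paper_heat_clusters", seed = 5)))
  idx$TOL <- 3
  expect_error(standardize_indices(idx), "zero-variance column.*TOL")
})

test_that("PCA of two perfectly correlated variables is rank one", {
  set.seed(2)
  a <- rnorm(20)
  z <- scale(cbind(x = a, y = 2 * a + 1))
  p <- pca_indices(z)
  expect_equal(unname(p$eigenvalues), c(2, 0), tolerance = 1e-12)
  expect_equal(unname(p$variance_explained), c(100, 0), tolerance = 1e-10)
})

test_that("PCA eigenvalues match an independent characteristic-polynomial solve", {
  set.seed(17)
  z <- matrix(rnorm(12), nrow = 4, ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  p <- pca_indices(z)
  expect_equal(unname(p$eigenvalues),
               charpoly_eigenvalues_3x3(cor(z)), tolerance = 1e-9)
})

test_that("PCA contributions, eigenvalue sum and sign convention hold", {
  idx <- compute_indices(
    simulate_yield_pairs(sim_preset("paper_sni_clusters", seed = 9)))
  p <- pca_indices(standardize_indices(idx))
  expect_equal(unname(colSums(p$contributions)), rep(100, 9),
               tolerance = 1e-6)
  expect_equal(sum(p$eigenvalues), 9, tolerance = 1e-9)
  expect_true(all(p$loadings["Ys", ] >= 0))
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_error(pca_indices(matrix(c(1, NA, 2, 3, 4, 5), 3)), "non-finite")
})

test_that("Ward recovers well-separated zero-noise blobs exactly", {
  cfg <- cluster_sim_config(group_sizes = c(4, 3, 5, 2),
                            mean_ysi = c(0.8, 0.6, 0.4, 0.2),
                            mean_yp = c(150, 220, 300, 260),
                            sd_yp = 0, sd_ysi = 0, seed = 1)
  pairs <- simulate_yield_pairs(cfg)
  # jitter minutely so no column is constant, keeping blobs separated
  set.seed(1)
  pairs$Yp <- pairs$Yp + rnorm(14, 0, 1e-3)
  pairs$Ys <- pairs$Ys + rnorm(14, 0, 1e-3)
  z <- standardize_indices(compute_indices(pairs))
  cl <- ward_cluster(z, k = 4)
  expect_true(same_partition(cl$assignment, attr(pairs, "true_group")))
  expect_equal(sort(cl$cluster_sizes), c(2, 3, 4, 5))
})

test_that("merge heights never decrease along the agglomeration", {
  z <- standardize_indices(compute_indices(
    simulate_yield_pairs(sim_preset("paper_heat_clusters", seed = 12))))
  cl <- ward_cluster(z, 4)
  expect_true(all(diff(cl$merge_history$height) >= -1e-12))
  expect_error(ward_cluster(z, 0), "k must")
  expect_error(ward_cluster(z, nrow(z)), "k must")
})

test_that("duplicating every point preserves the cluster structure", {
  z <- standardize_indices(compute_indices(
    simulate_yield_pairs(sim_preset("paper_heat_clusters", seed = 4))))
  cl1 <- ward_cluster(z, 4)
  z2 <- rbind(z, z)
  rownames(z2) <- c(paste0(rownames(z), "_1"), paste0(rownames(z), "_2"))
  cl2 <- ward_cluster(z2, 4)
  # each duplicate pair lands together and the partition doubles in size
  expect_true(same_partition(cl2$assignment,
                             rep(cl1$assignment, 2)))
  expect_equal(sort(cl2$cluster_sizes), sort(2L * cl1$cluster_sizes))
})

test_that("labelling follows the GMP / SSI / YSI rule on constructed extremes", {
  idx <- tibble::tibble(
    genotype = c("A", "B", "C", "D"),
    Ys = c(150, 20, 90, 60), Yp = c(200, 180, 150, 170),
    STI = c(1.2, 0.1, 0.5, 0.4), TOL = c(50, 160, 60, 110),
    GMP = c(170, 60, 116, 100), MP = c(175, 100, 120, 115),
    HARM = c(168, 36, 112, 88), SSI = c(0.4, 1.6, 0.7, 1.1),
    YSI = c(0.75, 0.11, 0.60, 0.35))
  cl <- structure(list(
    assignment = setNames(1:4, idx$genotype),
    merge_history = NULL, cluster_sizes = rep(1L, 4), labels = NULL,
    k = 4L, hclust = NULL), class = "cluster_result")
  lab <- label_clusters(cl, idx)
  expect_equal(unname(lab$labels[as.character(1:4)]),
               c("tolerant", "susceptible", "moderately_tolerant",
                 "moderately_susceptible"))

  tie <- idx
  tie$GMP <- c(170, 170, 116, 100)
  expect_error(label_clusters(cl, tie), "tie in mean GMP")
  cl3 <- cl
  cl3$k <- 3L
  expect_error(label_clusters(cl3, idx), "k = 4")
})

test_that("planted partitions are recovered across seeds on both presets", {
  for (preset in c("paper_heat_clusters", "paper_sni_clusters")) {
    hits <- 0
    for (s in 1:20) {
      res <- classify_preset(preset, seed = s)
      hits <- hits + same_partition(res$clusters$assignment,
                                    attr(res$pairs, "true_group"))
    }
    expect_gte(hits, 18)
  }
})

test_that("cluster profiles average replicate means within clusters", {
  # 8 genotypes, 2 planted clusters, hand-checkable means
  trial <- tibble::tibble(
    genotype = rep(sprintf("G%d", 1:8), each = 2),
    environment = "SI", replicate = rep(1:2, 8), trait = "GY",
    value = c(10, 12, 14, 16, 11, 13, 15, 17,   # G1..G4 -> cluster 1
              30, 32, 34, 36, 31, 33, 35, 37))  # G5..G8 -> cluster 2
  cl <- structure(list(
    assignment = setNames(rep(1:2, each = 4), sprintf("G%d", 1:8)),
    merge_history = NULL, cluster_sizes = c(4L, 4L), labels = NULL,
    k = 2L, hclust = NULL), class = "cluster_result")
  prof <- cluster_profile(cl, trial, "GY")
  expect_equal(prof$mean[prof$cluster == 1], mean(c(11, 15, 12, 16)))
  expect_equal(prof$mean[prof$cluster == 2], mean(c(31, 35, 32, 36)))
  expect_equal(prof$letters, c("a", "b"))  # far apart -> separated

  const <- trial
  const$value <- 9
  prof0 <- cluster_profile(cl, const, "GY")
  expect_equal(prof0$mean, c(9, 9))
  expect_equal(prof0$letters, c("a", "a"))
  expect_error(cluster_profile(cl, trial, "PH"), "available: GY")
})

test_that("zero-noise planted data profile to the planted group means", {
  cfg <- sim_preset("paper_heat_clusters", seed = 1)
  cfg$sd_yp <- 0
  cfg$sd_ysi <- 0
  pairs <- simulate_yield_pairs(cfg)
  grp <- attr(pairs, "true_group")
  trial <- tibble::tibble(
    genotype = rep(pairs$genotype, each = 2),
    environment = "SI", replicate = rep(1:2, nrow(pairs)), trait = "GY",
    value = rep(pairs$Ys, each = 2))
  cl <- structure(list(
    assignment = setNames(grp, pairs$genotype),
    merge_history = NULL, cluster_sizes = as.integer(table(grp)),
    labels = NULL, k = 4L, hclust = NULL), class = "cluster_result")
  prof <- cluster_profile(cl, trial, "GY")
  planted <- cfg$mean_yp * cfg$mean_ysi
  expect_equal(prof$mean[order(prof$cluster)], planted, tolerance = 1e-9)
})

test_that("dendrograms export as parseable newick text", {
  res <- classify_preset("paper_heat_clusters", seed = 2)
  nwk <- dendrogram_newick(res$clusters)
  expect_match(nwk, ";$")
  expect_equal(lengths(regmatches(nwk, gregexpr("G[0-9]+", nwk))), 43)
  skip_if_not_installed("ape")
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), sort(res$pairs$genotype))
})
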