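# Independent brute-force oracles used by the unit tests. These deliberately
# re-derive results from definitions (enumeration, textbook formulas,
# characteristic polynomials) rather than calling the code paths they check.

# Exhaustive Ward minimum-variance agglomeration: at every step merge the
# pair of clusters whose fusion least increases the total within-cluster sum
# of squares. Returns the merge sequence as member sets plus the ESS
# increase of each merge.
ward_oracle <- function(x) {
  x <- as.matrix(x)
  ess <- function(members) {
    xm <- x[members, , drop = FALSE]
    ctr <- colMeans(xm)
    sum(sweep(xm, 2, ctr)^2)
  }
  clusters <- lapply(seq_len(nrow(x)), identity)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merges[[length(merges) + 1]] <- list(
      a = sort(clusters[[best[1]]]),
      b = sort(clusters[[best[2]]]),
      delta_ess = best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# Member sets of every merge step of an hclust object.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  members <- function(i) {
    if (i < 0) return(-i)
    sets[[i]]$all
  }
  for (s in seq_len(nrow(hc$merge))) {
    a <- sort(members(hc$merge[s, 1]))
    b <- sort(members(hc$merge[s, 2]))
    sets[[s]] <- list(a = a, b = b, all = sort(c(a, b)),
                      height = hc$height[s])
  }
  sets
}

# TRUE if two cluster assignments are the same partition up to relabelling.
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Eigenvalues of a symmetric 3x3 matrix via its characteristic polynomial,
# solved with polyroot (independent of LAPACK's eigen).
charpoly_eigenvalues_3x3 <- function(m) {
  stopifnot(nrow(m) == 3, ncol(m) == 3)
  tr <- sum(diag(m))
  minors <- (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) +
    (m[1, 1] * m[3, 3] - m[1, 3] * m[3, 1]) +
    (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2])
  dt <- det(m)
  # lambda^3 - tr lambda^2 + minors lambda - det = 0
  roots <- polyroot(c(-dt, minors, -tr, 1))
  sort(Re(roots), decreasing = TRUE)
}

# Balanced two-way ANOVA sums of squares from cell/marginal means
# (textbook decomposition; a x b cells, r replicates).
anova2_oracle <- function(value, fa, fb) {
  fa <- as.character(fa)
  fb <- as.character(fb)
  grand <- mean(value)
  ma <- tapply(value, fa, mean)
  mb <- tapply(value, fb, mean)
  mab <- tapply(value, list(fa, fb), mean)
  a <- length(ma)
  b <- length(mb)
  r <- length(value) / (a * b)
  ss_a <- b * r * sum((ma - grand)^2)
  ss_b <- a * r * sum((mb - grand)^2)
  inter <- outer(ma, rep(1, b)) + outer(rep(1, a), mb)
  ss_ab <- r * sum((mab - inter + grand)^2)
  ss_e <- sum((value - mab[cbind(fa, fb)])^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_e = ss_e,
       ss_total = sum((value - grand)^2))
}

# Minimal long trial table for unit tests.
toy_trial <- function() {
  tibble::tibble(
    genotype = rep(c("A", "B", "C"), each = 8),
    environment = rep(rep(c("N2", "SNI"), each = 4), 3),
    replicate = rep(c(1L, 1L, 2L, 2L), 6),
    trait = rep(c("GY", "PH"), 12),
    value = c(100, 30, 120, 32, 40, 20, 60, 22,
              80, 28, 80, 30, 50, 18, 40, 20,
              120, 33, 120, 35, 70, 25, 60, 23))
}

# Run the full classification chain on a preset, returning the labelled
# clustering and the pairs it came from.
classify_preset <- function(preset, seed, k = 4) {
  pairs <- simulate_yield_pairs(sim_preset(preset, seed = seed))
  idx <- compute_indices(pairs)
  z <- standardize_indices(idx)
  cl <- label_clusters(ward_cluster(z, k), idx)
  list(pairs = pairs, indices = idx, z = z, clusters = cl)
}

# Size of the tolerant-labelled cluster.
tolerant_count <- function(cl) {
  tol_id <- as.integer(names(which(cl$labels == "tolerant")))
  sum(cl$assignment == tol_id)
}
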