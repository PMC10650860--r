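test_that("two-way ANOVA matches the textbook cell-mean decomposition", {
  set.seed(7)
  grid <- expand.grid(genotype = c("A", "B"), environment = c("N2", "SI"),
                      replicate = 1:2, stringsAsFactors = FALSE)
  trial <- tibble::tibble(
    genotype = grid$genotype, environment = grid$environment,
    replicate = grid$replicate, trait = "GY",
    value = round(runif(8, 50, 150), 1))
  res <- two_way_anova(trial, "GY")
  o <- anova2_oracle(trial$value, trial$genotype, trial$environment)
  expect_equal(res$sumsq[res$term == "genotype"], o$ss_a, tolerance = 1e-9)
  expect_equal(res$sumsq[res$term == "environment"], o$ss_b,
               tolerance = 1e-9)
  expect_equal(res$sumsq[res$term == "genotype:environment"], o$ss_ab,
               tolerance = 1e-9)
  expect_equal(res$sumsq[res$term == "residual"], o$ss_e, tolerance = 1e-9)
  expect_equal(sum(res$df), nrow(trial) - 1)
})

test_that("the sums of squares decompose the total on simulated data", {
  trial <- simulate_trial(sim_preset("demo_yield", seed = 11))
  res <- two_way_anova(trial, "GY")
  total <- sum((trial$value[trial$trait == "GY"] -
                  mean(trial$value[trial$trait == "GY"]))^2)
  expect_equal(sum(res$sumsq), total, tolerance = 1e-9 * total)
  expect_true(all(res$sumsq >= 0))
})

test_that("degenerate ANOVA inputs are handled as specified", {
  const <- toy_trial()
  const$value <- 5
  res <- two_way_anova(const, "GY")
  expect_equal(res$sumsq, rep(0, 4), tolerance = 1e-20)
  expect_true(all(is.na(res$statistic)))

  # zero noise, distinct treatment means: all variation is environmental
  cfg <- trial_sim_config(
    treatment_means = list(GY = c(N2 = 150, SI = 80)),
    n_genotypes = 4, n_replicates = 2, seed = 1)
  res0 <- two_way_anova(simulate_trial(cfg), "GY")
  expect_gt(res0$sumsq[res0$term == "environment"], 0)
  expect_equal(res0$sumsq[res0$term == "residual"], 0, tolerance = 1e-9)

  unb <- toy_trial()[-1, ]
  expect_error(two_way_anova(unb, "GY"), "unbalanced")
  one_rep <- toy_trial()
  one_rep <- one_rep[one_rep$replicate == 1, ]
  expect_error(two_way_anova(one_rep, "GY"), "residual degrees")
})

test_that("heritability variance components agree with stats::aov", {
  set.seed(21)
  trial <- tibble::tibble(
    genotype = rep(sprintf("G%02d", 1:12), each = 3),
    environment = "SI", replicate = rep(1:3, 12), trait = "GY",
    value = rep(runif(12, 80, 120), each = 3) + rnorm(36, 0, 5))
  h <- broad_sense_heritability(trial, "SI", "GY")
  fit <- summary(stats::aov(value ~ factor(genotype), data = trial))[[1]]
  ms_g <- fit["factor(genotype)", "Mean Sq"]
  ms_e <- fit["Residuals", "Mean Sq"]
  expect_equal(h$sigma2_e, ms_e, tolerance = 1e-9)
  expect_equal(h$sigma2_g, max(0, (ms_g - ms_e) / 3), tolerance = 1e-9)
  expect_equal(h$H2, h$sigma2_g / (h$sigma2_g + ms_e / 3),
               tolerance = 1e-12)
})

test_that("heritability limits: perfect repeatability and null signal", {
  noiseless <- tibble::tibble(
    genotype = rep(c("A", "B", "C"), each = 2), environment = "N2",
    replicate = rep(1:2, 3), trait = "GY",
    value = rep(c(100, 120, 140), each = 2))
  expect_equal(broad_sense_heritability(noiseless, "N2", "GY")$H2, 1)

  set.seed(31)
  null <- tibble::tibble(
    genotype = rep(sprintf("G%03d", 1:200), each = 2), environment = "N2",
    replicate = rep(1:2, 200), trait = "GY",
    value = 100 + rnorm(400, 0, 4))
  expect_lt(broad_sense_heritability(null, "N2", "GY")$H2, 0.2)

  single <- noiseless[noiseless$replicate == 1, ]
  expect_error(broad_sense_heritability(single, "N2", "GY"),
               "2 replicates")
})

test_that("percent change is the signed relative difference", {
  expect_equal(percent_change(100, 50), -50)
  expect_equal(percent_change(80, 80), 0)
  expect_equal(percent_change(20.26, 22.19), 100 * (22.19 - 20.26) / 20.26)
  expect_equal(percent_change(20.26, 22.19), 9.526, tolerance = 1e-4)
  expect_error(percent_change(0, 10), "non-zero")
})

test_that("pearson_matrix matches the covariance-definition oracle", {
  x <- c(1.2, 3.4, 2.2, 5.9, 4.1)
  y <- c(2.0, 2.9, 2.5, 7.3, 3.8)
  w <- c(9.1, 4.4, 6.3, 1.0, 5.5)
  brute_r <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  m <- pearson_matrix(tibble::tibble(x = x, y = y, w = w))
  expect_equal(m$r["x", "y"], brute_r(x, y), tolerance = 1e-12)
  expect_equal(m$r["x", "w"], brute_r(x, w), tolerance = 1e-12)
  expect_equal(m$r["y", "w"], brute_r(y, w), tolerance = 1e-12)
  # p-value from the t transform, checked against cor.test
  expect_equal(m$p["x", "y"], stats::cor.test(x, y)$p.value,
               tolerance = 1e-12)
})

test_that("pearson_matrix is symmetric, unit-diagonal, scale-equivariant", {
  idx <- compute_indices(
    simulate_yield_pairs(sim_preset("paper_heat_clusters", seed = 3)))
  m <- pearson_matrix(idx)
  expect_equal(m$r, t(m$r))
  expect_equal(unname(diag(m$r)), rep(1, ncol(m$r)))
  num <- idx[setdiff(names(idx), "genotype")]
  resc <- as.data.frame(Map(function(col, a, b) a * col + b, num,
                            c(2, -3, 1, 0.5, 4, 1, 2, -1, 10),
                            c(1, 0, -2, 5, 0, 3, 0, 1, -4)))
  m2 <- pearson_matrix(resc)
  signs <- sign(c(2, -3, 1, 0.5, 4, 1, 2, -1, 10))
  expect_equal(unname(m2$r), unname(m$r * outer(signs, signs)),
               tolerance = 1e-10)
})

test_that("degenerate correlation inputs give NA or errors", {
  z <- tibble::tibble(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2))
  m <- pearson_matrix(z)
  expect_true(is.na(m$r["a", "b"]))
  expect_equal(m$r["a", "a"], 1)
  expect_error(pearson_matrix(tibble::tibble(a = 1:2, b = 2:1)),
               "fewer than 3")
})

test_that("the two-panel correlation layout places each stress in a triangle", {
  heat <- pearson_matrix(compute_indices(
    simulate_yield_pairs(sim_preset("paper_heat_clusters", seed = 1))))
  comb <- pearson_matrix(compute_indices(
    simulate_yield_pairs(sim_preset("paper_sni_clusters", seed = 1))))
  panel <- format_pearson_panel(heat, comb)
  expect_equal(panel$variable, colnames(heat$r))
  expect_equal(panel$YSI[panel$variable == "SSI"], "-1.00 **")  # lower
  expect_equal(panel$SSI[panel$variable == "YSI"], "-1.00 **")  # upper
})

test_that("treatment summaries compute means and percent changes", {
  trial <- toy_trial()
  out <- treatment_summary(trial, baseline = "N2")
  gy_n2 <- mean(trial$value[trial$trait == "GY" &
                              trial$environment == "N2"])
  gy_sni <- mean(trial$value[trial$trait == "GY" &
                               trial$environment == "SNI"])
  row <- out[out$trait == "GY" & out$environment == "SNI", ]
  expect_equal(row$mean, gy_sni)
  expect_equal(row$pct_change, 100 * (gy_sni - gy_n2) / gy_n2)
  expect_true(is.na(out$pct_change[out$environment == "N2"][1]))
})
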