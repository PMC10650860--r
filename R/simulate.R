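#' Configuration for a synthetic multi-environment trial
#'
#' Defines an additive genotype + treatment + GxE + residual model per trait:
#' \deqn{y_{ger} = \mu_{te} + G_g + (GE)_{ge} + \varepsilon_{ger}}
#' with \eqn{G \sim N(0, \sigma_g^2)}, \eqn{GE \sim N(0, \sigma_{ge}^2)} and
#' \eqn{\varepsilon \sim N(0, \sigma_e^2)}, all in the trait's own units.
#' Incomplete-block structure is not modelled; no downstream stage uses it.
#'
#' @param treatment_means Named list: trait -> named numeric vector of
#'   per-environment means (environments from [trial_environments], a subset
#'   is allowed). Units are trait-specific (g/plot, cm, %, mg/kg, mm, mm2).
#' @param n_genotypes Number of genotypes (default 43, the collection size).
#' @param n_replicates Replicates per genotype x environment cell (default 2).
#' @param sd_genotype,sd_gxe,sd_residual Standard deviations of the genotype
#'   main effect, GxE interaction and residual. Either a single number used
#'   for every trait or a named vector per trait. All must be >= 0.
#' @param seed Integer seed; identical configurations give identical tables.
#'
#' @return An object of class `trial_sim_config`.
#' @seealso [simulate_trial()], [sim_preset()]
#' @export
trial_sim_config <- function(treatment_means, n_genotypes = 43,
                             n_replicates = 2, sd_genotype = 0,
                             sd_gxe = 0, sd_residual = 0, seed = 1L) {
  stopifnot(is.list(treatment_means), length(treatment_means) > 0)
  traits <- names(treatment_means)
  if (is.null(traits) || any(traits == "")) {
    stop("treatment_means must be a named list (trait -> env means)",
         call. = FALSE)
  }
  for (tr in traits) {
    m <- treatment_means[[tr]]
    if (is.null(names(m)) || !all(names(m) %in% trial_environments)) {
      stop("treatment_means[['", tr, "']] must be named with environment ",
           "labels from: ", paste(trial_environments, collapse = ", "),
           call. = FALSE)
    }
    if (!all(is.finite(m))) stop("non-finite treatment mean for ", tr,
                                 call. = FALSE)
  }
  expand_sd <- function(x, what) {
    if (any(x < 0)) stop(what, " must be >= 0", call. = FALSE)
    if (length(x) == 1 && is.null(names(x))) {
      return(setNames(rep(x, length(traits)), traits))
    }
    if (!all(traits %in% names(x))) {
      stop(what, " must be scalar or named per trait", call. = FALSE)
    }
    x[traits]
  }
  structure(list(
    n_genotypes = as.integer(n_genotypes),
    n_replicates = as.integer(n_replicates),
    treatment_means = treatment_means,
    sd_genotype = expand_sd(sd_genotype, "sd_genotype"),
    sd_gxe = expand_sd(sd_gxe, "sd_gxe"),
    sd_residual = expand_sd(sd_residual, "sd_residual"),
    seed = as.integer(seed)
  ), class = "trial_sim_config")
}

#' Configuration for cluster-structured yield pairs
#'
#' Genotypes fall into groups; within group `c`, potential yield is drawn as
#' `Yp ~ N(mean_yp[c], sd_yp^2)` truncated to be positive and the yield
#' stability ratio as `YSI ~ N(mean_ysi[c], sd_ysi^2)` truncated to
#' (0.01, 1.2); the stress yield is `Ys = Yp * YSI`. Truncation clamps
#' out-of-range draws (rather than resampling) so the number of random draws
#' is independent of the values, preserving seed reproducibility.
#'
#' @param group_sizes Positive integer group sizes; their sum is the number
#'   of genotypes.
#' @param mean_ysi Per-group mean yield stability index, in (0, 1).
#' @param mean_yp Per-group mean potential yield (g/plot), > 0.
#' @param sd_yp,sd_ysi Within-group standard deviations (g/plot and
#'   dimensionless); defaults 12 and 0.03.
#' @param stress Stress class of the pairs: `"heat"` or `"combined"`.
#' @param seed Integer seed.
#'
#' @return An object of class `cluster_sim_config`.
#' @seealso [simulate_yield_pairs()], [sim_preset()]
#' @export
cluster_sim_config <- function(group_sizes, mean_ysi, mean_yp,
                               sd_yp = 12, sd_ysi = 0.03,
                               stress = c("heat", "combined"), seed = 1L) {
  stress <- match.arg(stress)
  k <- length(group_sizes)
  if (k == 0 || any(group_sizes < 1) ||
      any(group_sizes != round(group_sizes))) {
    stop("group_sizes must be positive integers", call. = FALSE)
  }
  if (length(mean_ysi) != k || length(mean_yp) != k) {
    stop("mean_ysi and mean_yp must match the number of groups (", k, ")",
         call. = FALSE)
  }
  if (any(mean_ysi <= 0 | mean_ysi >= 1)) {
    stop("group mean YSI must lie in (0, 1)", call. = FALSE)
  }
  if (any(mean_yp <= 0)) stop("group mean Yp must be > 0", call. = FALSE)
  if (sd_yp < 0 || sd_ysi < 0) stop("SDs must be >= 0", call. = FALSE)
  structure(list(
    group_sizes = as.integer(group_sizes),
    mean_ysi = as.numeric(mean_ysi),
    mean_yp = as.numeric(mean_yp),
    sd_yp = sd_yp, sd_ysi = sd_ysi,
    stress = stress, seed = as.integer(seed)
  ), class = "cluster_sim_config")
}

#' Named simulation presets
#'
#' Three ready-made configurations used throughout the documentation and
#' validation suite:
#' \describe{
#'   \item{`paper_protein`}{A 43-genotype, 2-replicate protein trial with
#'     per-treatment means 20.26 (N1), 20.26 (N2), 22.19 (SI) and
#'     21.94 (SNI) percent, residual SD 0.5, genotype SD 0.35 and GxE SD
#'     0.2 (entry-mean heritability around 0.5, i.e. medium).}
#'   \item{`paper_heat_clusters`}{43 heat-stress yield pairs in four planted
#'     groups of sizes 11, 5, 12 and 15 with group mean YSI
#'     (0.55, 0.65, 0.35, 0.22) and group mean Yp (280, 190, 310, 215)
#'     g/plot; within-group SDs 12 g/plot and 0.03. The 11-member group is
#'     the tolerant one (highest Ys/STI/GMP/MP/HARM), the 12-member group
#'     has the highest Yp and TOL, the 15-member group the highest SSI.}
#'   \item{`paper_sni_clusters`}{43 combined heat-drought pairs in groups of
#'     sizes 22, 2, 12 and 7 with group mean YSI (0.50, 0.70, 0.28, 0.15)
#'     and group mean Yp (250, 170, 320, 260) g/plot, same SDs.}
#' }
#' Group separations are several within-group SDs so the planted partition
#' is recoverable; the dispersions are fixtures chosen for that purpose, not
#' field estimates.
#'
#' @param name One of `"paper_protein"`, `"paper_heat_clusters"`,
#'   `"paper_sni_clusters"`.
#' @param seed Integer seed stored in the returned config.
#'
#' @return A `trial_sim_config` or `cluster_sim_config`.
#' @examples
#' pairs <- simulate_yield_pairs(sim_preset("paper_heat_clusters", seed = 7))
#' table(attr(pairs, "true_group"))
#' @export
sim_preset <- function(name, seed = 1L) {
  switch(
    name,
    paper_protein = trial_sim_config(
      treatment_means = list(
        protein = c(N1 = 20.26, N2 = 20.26, SI = 22.19, SNI = 21.94)),
      n_genotypes = 43, n_replicates = 2,
      sd_genotype = 0.35, sd_gxe = 0.2, sd_residual = 0.5, seed = seed),
    paper_heat_clusters = cluster_sim_config(
      group_sizes = c(11, 5, 12, 15),
      mean_ysi = c(0.55, 0.65, 0.35, 0.22),
      mean_yp = c(280, 190, 310, 215),
      sd_yp = 12, sd_ysi = 0.03, stress = "heat", seed = seed),
    paper_sni_clusters = cluster_sim_config(
      group_sizes = c(22, 2, 12, 7),
      mean_ysi = c(0.50, 0.70, 0.28, 0.15),
      mean_yp = c(250, 170, 320, 260),
      sd_yp = 12, sd_ysi = 0.03, stress = "combined", seed = seed),
    demo_yield = trial_sim_config(
      treatment_means = list(
        GY = c(N1 = 180, N2 = 190, SI = 95, SNI = 85),
        PH = c(N1 = 58, N2 = 60, SI = 30, SNI = 29)),
      n_genotypes = 43, n_replicates = 2,
      sd_genotype = c(GY = 15, PH = 4), sd_gxe = c(GY = 8, PH = 2),
      sd_residual = c(GY = 12, PH = 3), seed = seed),
    stop("unknown preset: ", name, call. = FALSE)
  )
}

#' Simulate a multi-environment trial table
#'
#' Draws the additive model of [trial_sim_config()] with R's default
#' Mersenne-Twister generator seeded from `config$seed`, in a fixed draw
#' order (per trait: genotype effects, then GxE effects, then residuals), so
#' identical configurations always give identical tables. Negative simulated
#' values of non-percentage traits are truncated at 0 (percentage traits are
#' additionally capped at 100) and the truncation count is reported via a
#' message.
#'
#' @param config A `trial_sim_config`.
#'
#' @return A validated `trial_table` with genotypes `G01`, `G02`, ...
#' @examples
#' trial <- simulate_trial(sim_preset("paper_protein", seed = 1))
#' dplyr::count(trial, environment)
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_sim_config"))
  set.seed(config$seed)
  g <- config$n_genotypes
  r <- config$n_replicates
  geno <- sprintf("G%02d", seq_len(g))
  out <- vector("list", length(config$treatment_means))
  n_trunc <- 0L
  for (i in seq_along(config$treatment_means)) {
    tr <- names(config$treatment_means)[i]
    mu <- config$treatment_means[[i]]
    envs <- names(mu)
    G <- stats::rnorm(g, 0, config$sd_genotype[[tr]])
    GE <- matrix(stats::rnorm(g * length(envs), 0, config$sd_gxe[[tr]]),
                 nrow = g, ncol = length(envs))
    grid <- expand.grid(replicate = seq_len(r), environment = envs,
                        genotype_i = seq_len(g), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    eps <- stats::rnorm(nrow(grid), 0, config$sd_residual[[tr]])
    ei <- match(grid$environment, envs)
    value <- mu[ei] + G[grid$genotype_i] + GE[cbind(grid$genotype_i, ei)] +
      eps
    low <- value < 0
    value[low] <- 0
    n_trunc <- n_trunc + sum(low)
    if (tr %in% percent_traits) {
      high <- value > 100
      value[high] <- 100
      n_trunc <- n_trunc + sum(high)
    }
    out[[i]] <- tibble::tibble(
      genotype = geno[grid$genotype_i],
      environment = grid$environment,
      replicate = as.integer(grid$replicate),
      trait = tr,
      value = unname(value))
  }
  if (n_trunc > 0) {
    message("simulate_trial: ", n_trunc,
            " value(s) truncated to the valid range")
  }
  validate_trial_table(dplyr::bind_rows(out))
}

#' Simulate cluster-structured yield pairs
#'
#' Draws per-genotype (Yp, Ys) pairs from the grouped model of
#' [cluster_sim_config()]. The planted group of each genotype is stored in
#' the `true_group` attribute for recovery scoring.
#'
#' @param config A `cluster_sim_config`.
#'
#' @return A `yield_pair_table` with attributes `yp_bar`, `ys_bar`, `stress`
#'   and `true_group` (integer vector of planted group ids).
#' @examples
#' pairs <- simulate_yield_pairs(sim_preset("paper_sni_clusters", seed = 3))
#' head(pairs)
#' @export
simulate_yield_pairs <- function(config) {
  stopifnot(inherits(config, "cluster_sim_config"))
  set.seed(config$seed)
  n <- sum(config$group_sizes)
  group <- rep(seq_along(config$group_sizes), times = config$group_sizes)
  yp <- stats::rnorm(n, config$mean_yp[group], config$sd_yp)
  ysi <- stats::rnorm(n, config$mean_ysi[group], config$sd_ysi)
  yp <- pmax(yp, 0.01)                 # truncate, do not resample
  ysi <- pmin(pmax(ysi, 0.01), 1.2)
  df <- tibble::tibble(
    genotype = sprintf("G%02d", seq_len(n)),
    Yp = yp,
    Ys = yp * ysi)
  new_yield_pair_table(df, stress = config$stress, true_group = group)
}
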