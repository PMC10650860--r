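#' Two-way ANOVA for a trial trait
#'
#' Fits the fixed-effects general linear model
#' `value ~ genotype + environment + genotype:environment` on one trait of a
#' balanced trial and partitions the total sum of squares into genotype,
#' environment, interaction and residual components, with F tests against
#' the residual mean square. Only balanced designs (equal replicates in
#' every genotype x environment cell) are supported; unbalanced input is an
#' error rather than a silent sums-of-squares-type choice.
#'
#' @param trial A `trial_table`.
#' @param trait Trait name to analyse.
#' @param environments Optional subset of environments to include (default:
#'   all present for the trait).
#'
#' @return An `anova_result` tibble with columns `term` (genotype,
#'   environment, genotype:environment, residual), `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`. With constant data all SS are 0 and the F
#'   statistics are `NA`.
#' @examples
#' trial <- simulate_trial(sim_preset("paper_protein", seed = 1))
#' two_way_anova(trial, "protein")
#' @export
two_way_anova <- function(trial, trait, environments = NULL) {
  trial <- validate_trial_table(trial)
  sub <- trial[trial$trait == trait, ]
  if (!is.null(environments)) {
    sub <- sub[sub$environment %in% environments, ]
  }
  if (nrow(sub) == 0) stop("trait not found: ", trait, call. = FALSE)
  counts <- table(sub$genotype, sub$environment)
  if (any(counts < 1)) {
    stop("empty genotype x environment cell(s); every cell needs >= 1 ",
         "observation", call. = FALSE)
  }
  if (length(unique(as.vector(counts))) != 1) {
    stop("unbalanced design: unequal replicates per cell are not supported",
         call. = FALSE)
  }
  df <- data.frame(
    value = sub$value,
    genotype = factor(sub$genotype),
    environment = factor(sub$environment))
  if (nlevels(df$genotype) < 2 || nlevels(df$environment) < 2) {
    stop("two-way ANOVA needs >= 2 genotypes and >= 2 environments",
         call. = FALSE)
  }
  if (nrow(df) - nlevels(df$genotype) * nlevels(df$environment) < 1) {
    stop("zero residual degrees of freedom: add replicates", call. = FALSE)
  }
  fit <- stats::aov(value ~ genotype * environment, data = df)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  out <- tibble::tibble(
    term = c("genotype", "environment", "genotype:environment", "residual"),
    df = tab[match(c("genotype", "environment", "genotype:environment",
                     "Residuals"), terms), "Df"],
    sumsq = tab[match(c("genotype", "environment", "genotype:environment",
                        "Residuals"), terms), "Sum Sq"],
    meansq = tab[match(c("genotype", "environment", "genotype:environment",
                         "Residuals"), terms), "Mean Sq"])
  # zap floating-point dust so degenerate inputs report exact zeros
  tol_ss <- 1e-12 * sum(df$value^2)
  zap <- out$sumsq < tol_ss
  out$sumsq[zap] <- 0
  out$meansq[zap] <- 0
  ms_err <- out$meansq[out$term == "residual"]
  stat <- out$meansq / ms_err
  stat[out$term == "residual"] <- NA_real_
  # constant data: 0/0 -> NaN; report NA
  stat[!is.finite(stat)] <- NA_real_
  pval <- ifelse(is.na(stat), NA_real_,
                 stats::pf(stat, out$df, out$df[out$term == "residual"],
                           lower.tail = FALSE))
  out$statistic <- stat
  out$p.value <- pval
  class(out) <- c("anova_result", class(out))
  out
}

#' Broad-sense heritability on an entry-mean basis
#'
#' Within one environment, fits the balanced one-way genotype ANOVA and
#' estimates the variance components as
#' \eqn{\hat\sigma^2_e = MS_{error}} and
#' \eqn{\hat\sigma^2_g = \max(0, (MS_{genotype} - MS_{error})/r)}, giving
#' \deqn{H^2 = \frac{\hat\sigma^2_g}{\hat\sigma^2_g + \hat\sigma^2_e / r}}
#' with `r` replicates. Negative genotypic-variance estimates are truncated
#' at 0, so `H^2` lies in \[0, 1\]. The balanced sums of squares are
#' computed directly from the cell means (equivalent to `stats::aov`).
#'
#' @param trial A `trial_table`.
#' @param environment Environment label to analyse within.
#' @param trait Trait name.
#'
#' @return A `heritability_result` tibble (one row) with columns
#'   `environment`, `trait`, `sigma2_g`, `sigma2_e`, `replicates`, `H2`.
#'   `H2` is `NA` when both variance components are estimated as 0.
#' @examples
#' trial <- simulate_trial(sim_preset("paper_protein", seed = 1))
#' broad_sense_heritability(trial, "SI", "protein")
#' @export
broad_sense_heritability <- function(trial, environment, trait) {
  trial <- validate_trial_table(trial)
  sub <- trial[trial$trait == trait & trial$environment == environment, ]
  if (nrow(sub) == 0) {
    stop("no data for trait ", trait, " in environment ", environment,
         call. = FALSE)
  }
  counts <- table(sub$genotype)
  if (length(counts) < 2) stop(">= 2 genotypes required", call. = FALSE)
  if (length(unique(as.vector(counts))) != 1) {
    stop("unbalanced replication across genotypes is not supported",
         call. = FALSE)
  }
  r <- unname(counts[1])
  if (r < 2) {
    stop(">= 2 replicates required: residual variance is inestimable ",
         "with a single replicate", call. = FALSE)
  }
  g <- length(counts)
  means <- tapply(sub$value, sub$genotype, mean)
  grand <- mean(sub$value)
  ss_g <- r * sum((means - grand)^2)
  ss_e <- sum((sub$value - means[sub$genotype])^2)
  ms_g <- ss_g / (g - 1)
  ms_e <- ss_e / (g * (r - 1))
  sigma2_g <- max(0, (ms_g - ms_e) / r)
  denom <- sigma2_g + ms_e / r
  h2 <- if (denom == 0) NA_real_ else sigma2_g / denom
  out <- tibble::tibble(
    environment = environment, trait = trait,
    sigma2_g = sigma2_g, sigma2_e = ms_e,
    replicates = as.integer(r), H2 = h2)
  class(out) <- c("heritability_result", class(out))
  out
}

#' Signed percent change of a stress mean relative to a normal baseline
#'
#' @param mean_normal Baseline (normal-treatment) mean; must be non-zero.
#' @param mean_stress Stress-treatment mean, same units.
#'
#' @return `100 * (mean_stress - mean_normal) / mean_normal`.
#' @examples
#' percent_change(100, 50)      # -50
#' percent_change(20.26, 22.19) # +9.53
#' @export
percent_change <- function(mean_normal, mean_stress) {
  if (any(!is.finite(mean_normal)) || any(mean_normal == 0)) {
    stop("mean_normal must be finite and non-zero", call. = FALSE)
  }
  100 * (mean_stress - mean_normal) / mean_normal
}

#' Pearson correlation matrix with significance stars
#'
#' Product-moment correlations between every pair of numeric columns, with
#' two-sided p-values from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on `n - 2`
#' degrees of freedom and the usual star coding: `**` for p < 0.01, `*` for
#' p < 0.05, empty otherwise. Correlations of magnitude 1 (to within 1e-12)
#' are reported with p = 0 and `**`, matching the printed convention for
#' exact linear dependencies even though the t statistic degenerates.
#' Zero-variance columns give `NA` entries.
#'
#' @param table A data frame; non-numeric columns (e.g. `genotype`) are
#'   dropped. At least 3 complete observations are required per column pair.
#'
#' @return A `pearson_matrix` list with components `r` (correlations, unit
#'   diagonal), `p` (p-values), `stars` (character matrix), `n` (pairwise
#'   complete counts).
#' @examples
#' idx <- compute_indices(simulate_yield_pairs(sim_preset("paper_heat_clusters")))
#' m <- pearson_matrix(idx)
#' m$r["SSI", "YSI"] # -1
#' @export
pearson_matrix <- function(table) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (ncol(num) < 2) stop(">= 2 numeric columns required", call. = FALSE)
  p <- ncol(num)
  x <- as.matrix(num)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  pv <- r
  nm <- matrix(NA_integer_, p, p, dimnames = dimnames(r))
  for (i in seq_len(p)) {
    for (j in seq_len(i)) {
      ok <- is.finite(x[, i]) & is.finite(x[, j])
      n <- sum(ok)
      nm[i, j] <- nm[j, i] <- n
      if (n < 3) {
        stop("fewer than 3 complete observations for pair ",
             colnames(x)[i], "/", colnames(x)[j], call. = FALSE)
      }
      if (i == j) {
        r[i, j] <- 1
        pv[i, j] <- 0
        next
      }
      if (stats::sd(x[ok, i]) == 0 || stats::sd(x[ok, j]) == 0) next
      rij <- stats::cor(x[ok, i], x[ok, j])
      r[i, j] <- r[j, i] <- rij
      if (abs(rij) >= 1 - 1e-12) {
        pij <- 0
      } else {
        tstat <- rij * sqrt((n - 2) / (1 - rij^2))
        pij <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
      }
      pv[i, j] <- pv[j, i] <- pij
    }
  }
  stars <- matrix("", p, p, dimnames = dimnames(r))
  stars[!is.na(pv) & pv < 0.05] <- "*"
  stars[!is.na(pv) & pv < 0.01] <- "**"
  diag(stars) <- ""
  structure(list(r = r, p = pv, stars = stars, n = nm),
            class = "pearson_matrix")
}

#' Formatted correlation panel
#'
#' Renders a [pearson_matrix()] as a tibble of `"r star"` strings (e.g.
#' `"-1.00 **"`). When a second matrix is supplied, the first fills the
#' upper triangle and the second the lower triangle, mirroring the printed
#' two-panel layout for two stress conditions.
#'
#' @param upper A `pearson_matrix` (fills the upper triangle and diagonal).
#' @param lower Optional second `pearson_matrix` on the same variables.
#' @param digits Decimal places for r (default 2).
#' @return A tibble with a `variable` column and one column per variable.
#' @export
format_pearson_panel <- function(upper, lower = NULL, digits = 2) {
  stopifnot(inherits(upper, "pearson_matrix"))
  vars <- colnames(upper$r)
  fmt <- function(m) {
    out <- matrix(sprintf(paste0("%.", digits, "f"), m$r),
                  nrow(m$r), ncol(m$r))
    out <- matrix(trimws(paste(out, m$stars)), nrow(out), ncol(out),
                  dimnames = dimnames(m$r))
    out[is.na(m$r)] <- "NA"
    out
  }
  panel <- fmt(upper)
  diag(panel) <- "1"
  if (!is.null(lower)) {
    stopifnot(inherits(lower, "pearson_matrix"),
              identical(colnames(lower$r), vars))
    lo <- fmt(lower)
    panel[lower.tri(panel)] <- lo[lower.tri(lo)]
  }
  tibble::as_tibble(cbind(tibble::tibble(variable = vars),
                          as.data.frame(panel)))
}

#' Treatment percent-change summary for a trial
#'
#' For each trait, computes treatment means (averaging replicates and
#' genotypes) and the signed percent change of each stress treatment
#' relative to a normal baseline environment.
#'
#' @param trial A `trial_table`.
#' @param baseline Normal environment used as reference (default `"N2"`).
#'
#' @return A tibble with columns `trait`, `environment`, `mean`,
#'   `pct_change` (`NA` for the baseline itself).
#' @export
treatment_summary <- function(trial, baseline = "N2") {
  trial <- validate_trial_table(trial)
  if (!baseline %in% trial$environment) {
    stop("baseline environment ", baseline, " absent from trial",
         call. = FALSE)
  }
  means <- trial |>
    dplyr::group_by(.data$trait, .data$environment) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop")
  base <- means[means$environment == baseline, c("trait", "mean")]
  names(base)[2] <- "base_mean"
  out <- dplyr::left_join(means, base, by = "trait")
  out$pct_change <- ifelse(
    out$environment == baseline, NA_real_,
    percent_change(out$base_mean, out$mean))
  out$base_mean <- NULL
  out
}
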