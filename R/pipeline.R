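#' Read a pipeline configuration file
#'
#' YAML key/value config driving [run_pipeline()]. Recognised keys:
#' `seed` (integer), one of `preset` (a [sim_preset()] name) or `trial`
#' (path to a long-format trial CSV), `normal_env` (default `"N2"`),
#' `trait` (yield trait to pair, default `"GY"`), `k` (clusters, default 4),
#' `profile_traits` (traits for the cluster profile), `out_dir`.
#'
#' @param path Path to a YAML file.
#' @return A named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key/value mapping",
                          call. = FALSE)
  cfg
}

pipeline_defaults <- list(seed = 1L, normal_env = "N2", trait = "GY",
                          k = 4L, profile_traits = NULL)

cluster_presets <- c("paper_heat_clusters", "paper_sni_clusters")

#' Run the full analysis pipeline and write a report bundle
#'
#' End-to-end chain over either a simulation preset or a trial CSV:
#' stress-index tables, the correlation panel with significance stars, the
#' PCA summary (eigenvalues, percent variance, per-variable contributions),
#' the labelled Ward clustering, a cluster trait profile (trial input), the
#' two-way ANOVA / heritability / percent-change summaries (trial input),
#' and a Markdown report. Every output file starts with `#` comment lines
#' recording the package version, seed and a config hash, so reruns with an
#' identical configuration are byte-identical.
#'
#' For trial input, each stress environment (`SI`, `SNI`) present in the
#' trial is paired with `normal_env`; a missing stress environment is
#' skipped with a message rather than an error.
#'
#' @param config A named list (see [read_pipeline_config()]) or path to a
#'   YAML config file.
#' @param out_dir Output directory (created if needed); overrides
#'   `config$out_dir`.
#' @param dry_run If `TRUE`, validate the configuration, print the planned
#'   steps, and write nothing.
#'
#' @return Invisibly, a list with the computed objects (`indices`,
#'   `clusters`, `pca`, ... keyed by stress class where relevant) and
#'   `files`, the paths written. A dry run returns the plan (character
#'   vector) invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, dry_run = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  cfg <- utils::modifyList(pipeline_defaults, config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  has_preset <- !is.null(cfg$preset)
  has_trial <- !is.null(cfg$trial)
  if (has_preset == has_trial) {
    stop("config must name exactly one of `preset` or `trial`",
         call. = FALSE)
  }
  if (has_preset && !cfg$preset %in% c(cluster_presets, "paper_protein",
                                       "demo_yield")) {
    stop("unknown preset: ", cfg$preset, call. = FALSE)
  }
  if (treatment_class(cfg$normal_env) != "normal") {
    stop("normal_env must be N1 or N2", call. = FALSE)
  }

  hash_cfg <- cfg[setdiff(names(cfg), "out_dir")]
  hash <- rlang::hash(hash_cfg[order(names(hash_cfg))])
  header <- c(
    paste0("stresskit ", as.character(utils::packageVersion("stresskit"))),
    paste0("seed: ", cfg$seed),
    paste0("config: ", hash))

  plan <- character(0)
  note <- function(x) plan <<- c(plan, x)
  if (has_preset && cfg$preset %in% cluster_presets) {
    note(paste0("simulate yield pairs from preset ", cfg$preset,
                " (seed ", cfg$seed, ")"))
    note("compute stress indices; correlation panel; PCA; Ward clustering")
  } else if (has_preset) {
    note(paste0("simulate trial from preset ", cfg$preset,
                " (seed ", cfg$seed, ")"))
    note("ANOVA, heritability and treatment summaries; index chain per stress environment")
  } else {
    note(paste0("read trial CSV ", cfg$trial))
    note("ANOVA, heritability and treatment summaries; index chain per stress environment")
  }
  note(paste0("write bundle to ", cfg$out_dir %||% "<out_dir>"))
  if (dry_run) {
    cat("run_pipeline plan:\n", paste0("  - ", plan, collapse = "\n"),
        "\n", sep = "")
    return(invisible(plan))
  }
  if (is.null(cfg$out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  out_path <- function(name) {
    p <- file.path(cfg$out_dir, name)
    files <<- c(files, p)
    p
  }
  results <- list(config = cfg, config_hash = hash)

  run_index_chain <- function(pairs, tag) {
    idx <- compute_indices(pairs)
    write_index_csv(idx, out_path(paste0("indices_", tag, ".csv")), header)
    cm <- pearson_matrix(idx)
    write_csv_with_header(format_pearson_panel(cm),
                          out_path(paste0("table1_corr_", tag, ".csv")),
                          header)
    z <- standardize_indices(idx)
    pca <- pca_indices(z)
    write_csv_with_header(format_pca_table(pca),
                          out_path(paste0("table2_pca_", tag, ".csv")),
                          header)
    cl <- label_clusters2(ward_cluster(z, k = cfg$k), idx)
    write_csv_with_header(cluster_assignments(cl),
                          out_path(paste0("clusters_", tag, ".csv")),
                          header)
    writeLines(c(paste0("# ", header), dendrogram_newick(cl)),
               out_path(paste0("dendrogram_", tag, ".nwk")))
    list(indices = idx, correlation = cm, pca = pca, clusters = cl)
  }

  if (has_preset && cfg$preset %in% cluster_presets) {
    pairs <- simulate_yield_pairs(sim_preset(cfg$preset, seed = cfg$seed))
    tag <- attr(pairs, "stress")
    results[[tag]] <- run_index_chain(pairs, tag)
  } else {
    trial <- if (has_preset) {
      simulate_trial(sim_preset(cfg$preset, seed = cfg$seed))
    } else {
      read_trial_csv(cfg$trial)
    }
    results$trial <- trial
    write_csv_with_header(treatment_summary(trial, cfg$normal_env),
                          out_path("treatment_summary.csv"), header)
    traits <- unique(trial$trait)
    anovas <- dplyr::bind_rows(lapply(traits, function(tr) {
      a <- two_way_anova(trial, tr)
      a$trait <- tr
      a[, c("trait", setdiff(names(a), "trait"))]
    }))
    write_csv_with_header(anovas, out_path("anova.csv"), header)
    results$anova <- anovas
    envs <- unique(trial$environment)
    h2 <- dplyr::bind_rows(lapply(traits, function(tr) {
      dplyr::bind_rows(lapply(envs, function(e) {
        broad_sense_heritability(trial, e, tr)
      }))
    }))
    write_csv_with_header(h2, out_path("heritability.csv"), header)
    results$heritability <- h2
    for (stress_env in c("SI", "SNI")) {
      if (!stress_env %in% envs || !cfg$trait %in% traits) {
        message("skipping ", stress_env,
                ": environment or trait absent from trial")
        next
      }
      pairs <- pair_yields(trial, cfg$normal_env, stress_env,
                           trait = cfg$trait)
      tag <- treatment_class(stress_env)
      results[[tag]] <- run_index_chain(pairs, tag)
      if (!is.null(cfg$profile_traits)) {
        prof <- cluster_profile(results[[tag]]$clusters, trial,
                                cfg$profile_traits,
                                environment = stress_env)
        write_csv_with_header(prof,
                              out_path(paste0("table3_profile_", tag,
                                              ".csv")), header)
        results[[tag]]$profile <- prof
      }
    }
  }

  report <- c(
    "# stresskit report", "",
    paste0("- package version: ",
           as.character(utils::packageVersion("stresskit"))),
    paste0("- seed: ", cfg$seed),
    paste0("- config hash: ", hash),
    paste0("- input: ", if (has_preset) paste0("preset ", cfg$preset) else
      cfg$trial),
    "", "## Outputs", "",
    paste0("- ", basename(files)))
  for (tag in intersect(c("heat", "combined"), names(results))) {
    cl <- results[[tag]]$clusters
    pca <- results[[tag]]$pca
    counts <- table(factor(cl$labels[as.character(cl$assignment)],
                           levels = tolerance_levels))
    report <- c(report, "",
                paste0("## ", tag, " stress classification"), "",
                paste0("- stress intensity: ",
                       signif(attr(results[[tag]]$indices, "si"), 4)),
                paste0("- cumulative variance of first two PCA dimensions: ",
                       sprintf("%.2f%%", pca$cumulative_variance[2])),
                paste0("- ", names(counts), ": ", as.integer(counts),
                       " genotypes"))
  }
  writeLines(report, out_path("report.md"))
  results$files <- files
  invisible(results)
}

# Label clusters when k = 4; otherwise leave unlabelled (pipeline helper).
label_clusters2 <- function(clusters, idx) {
  if (clusters$k == 4) label_clusters(clusters, idx) else clusters
}

#' Table-2-style PCA summary
#'
#' Variables x dimensions contribution table with appended `Eigenvalue`,
#' `Variance explained (%)` and `Cumulative variance (%)` rows, for the
#' first `dims` dimensions.
#'
#' @param pca A `pca_result`.
#' @param dims Number of leading dimensions (default 3).
#' @return A tibble with a `row` column followed by `Dim.1`, `Dim.2`, ...
#' @export
format_pca_table <- function(pca, dims = 3) {
  stopifnot(inherits(pca, "pca_result"))
  dims <- min(dims, length(pca$eigenvalues))
  contrib <- pca$contributions[, seq_len(dims), drop = FALSE]
  body <- as.data.frame(rbind(
    contrib,
    Eigenvalue = pca$eigenvalues[seq_len(dims)],
    `Variance explained (%)` = pca$variance_explained[seq_len(dims)],
    `Cumulative variance (%)` = pca$cumulative_variance[seq_len(dims)]))
  tibble::as_tibble(cbind(tibble::tibble(row = rownames(body)), body))
}
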