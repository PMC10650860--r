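#' @importFrom rlang .data %||%
#' @importFrom stats var sd cor qt qtukey pf pt qtukey setNames na.omit
#' @importFrom utils modifyList
NULL

#' Trial environment labels
#'
#' The four environments of the two-season trial design: `N1` and `N2` are
#' normal winter sowings of seasons one and two, `SI` is late sowing with
#' full irrigation (terminal heat stress) and `SNI` is late sowing with
#' irrigation withheld from flowering (combined heat-drought stress).
#'
#' @format A character vector of length four.
#' @export
trial_environments <- c("N1", "N2", "SI", "SNI")

#' Treatment class of an environment
#'
#' @param environment Character vector of environment labels
#'   (see [trial_environments]).
#'
#' @return Character vector with values `"normal"`, `"heat"` or `"combined"`.
#' @examples
#' treatment_class(c("N1", "SI", "SNI"))
#' @export
treatment_class <- function(environment) {
  cls <- c(N1 = "normal", N2 = "normal", SI = "heat", SNI = "combined")
  bad <- setdiff(unique(environment), names(cls))
  if (length(bad) > 0) {
    stop("unknown environment label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(names(cls), collapse = ", "),
         call. = FALSE)
  }
  unname(cls[environment])
}

# Traits whose values are percentages and must lie in [0, 100].
percent_traits <- c("protein", "HI")

#' Validate a long-format trial table
#'
#' Checks the structural invariants of the long trial format: required
#' columns, known environment labels, positive integer replicates, unique
#' (genotype, environment, replicate, trait) keys, non-negative measurement
#' values and percentage traits (`protein`, `HI`) inside \[0, 100\].
#' Violations are reported with the offending row numbers.
#'
#' @param trial A data frame with columns `genotype`, `environment`,
#'   `replicate`, `trait`, `value`.
#'
#' @return The validated table as a tibble with class `trial_table`,
#'   invisibly usable anywhere a data frame is.
#' @export
validate_trial_table <- function(trial) {
  required <- c("genotype", "environment", "replicate", "trait", "value")
  missing_cols <- setdiff(required, names(trial))
  if (length(missing_cols) > 0) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trial <- tibble::as_tibble(trial)[required]
  trial$genotype <- as.character(trial$genotype)
  trial$environment <- as.character(trial$environment)
  trial$trait <- as.character(trial$trait)

  fail_rows <- function(ok, what) {
    if (!all(ok)) {
      rows <- which(!ok)
      stop("invalid trial table: ", what, " (row",
           if (length(rows) > 1) "s" else "", " ",
           paste(utils::head(rows, 10), collapse = ", "),
           if (length(rows) > 10) ", ..." else "", ")", call. = FALSE)
    }
  }

  fail_rows(trial$environment %in% trial_environments,
            "unknown environment label")
  if (!is.numeric(trial$replicate)) {
    stop("invalid trial table: replicate column is not numeric",
         call. = FALSE)
  }
  fail_rows(is.finite(trial$replicate) & trial$replicate >= 1 &
              trial$replicate == round(trial$replicate),
            "replicate must be a positive integer")
  if (!is.numeric(trial$value)) {
    stop("invalid trial table: value column is not numeric", call. = FALSE)
  }
  fail_rows(is.finite(trial$value), "non-finite value")
  fail_rows(trial$value >= 0, "negative measurement value")
  pct <- trial$trait %in% percent_traits
  fail_rows(!pct | trial$value <= 100, "percentage trait above 100")

  key <- paste(trial$genotype, trial$environment, trial$replicate,
               trial$trait, sep = "\r")
  fail_rows(!duplicated(key),
            "duplicate (genotype, environment, replicate, trait) key")

  trial$replicate <- as.integer(trial$replicate)
  class(trial) <- c("trial_table", class(trial))
  trial
}

#' Read a long-format trial CSV
#'
#' The expected file is comma-separated UTF-8 with a mandatory header row and
#' decimal points, columns `genotype,environment,replicate,trait,value`.
#' Differently named columns can be mapped via `schema`. Lines starting with
#' `#` are treated as comments.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping standard column
#'   names to the names used in the file, e.g.
#'   `c(genotype = "entry", value = "obs")`.
#'
#' @return A validated `trial_table` tibble.
#' @seealso [write_trial_csv()], [validate_trial_table()]
#' @export
read_trial_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                         progress = FALSE)
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == "")) {
      stop("schema must be a named character vector", call. = FALSE)
    }
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src) > 0) {
      stop("schema names column(s) absent from file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (std in names(schema)) {
      names(raw)[names(raw) == schema[[std]]] <- std
    }
  }
  for (col in c("replicate", "value")) {
    if (col %in% names(raw) && !is.numeric(raw[[col]])) {
      bad <- which(!is.na(raw[[col]]) &
                     is.na(suppressWarnings(as.numeric(raw[[col]]))))
      stop("non-numeric ", col, " in ", path,
           if (length(bad) > 0) paste0(" (row ", bad[1], ")") else "",
           call. = FALSE)
    }
  }
  validate_trial_table(raw)
}

#' Write a trial table to CSV
#'
#' @param trial A `trial_table` (or compatible data frame).
#' @param path Output path.
#' @param header Optional character vector written as `#`-prefixed comment
#'   lines before the data (used by the pipeline to record seeds/config).
#'
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path, header = NULL) {
  trial <- validate_trial_table(trial)
  write_csv_with_header(trial, path, header)
}

# Shared CSV writer: optional '#' comment header, then readr::write_csv body.
write_csv_with_header <- function(x, path, header = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header) > 0) {
    writeLines(paste0("# ", header), con)
  }
  body <- readr::format_csv(x)
  writeLines(sub("\n$", "", body), con, sep = "\n")
  invisible(path)
}

#' Pair replicate-mean yields of a normal and a stress environment
#'
#' For every genotype observed in both environments, computes the
#' replicate-mean yield under the normal environment (`Yp`) and under the
#' stress environment (`Ys`), within the same trait (grain yield by
#' default). Genotypes missing from either environment are dropped with a
#' warning, as are genotypes with `Yp <= 0` (their susceptibility indices
#' would be undefined). The across-genotype means of the retained `Yp` and
#' `Ys` are carried as attributes `yp_bar` / `ys_bar`.
#'
#' @param trial A `trial_table`.
#' @param normal_env Normal environment label (`"N1"` or `"N2"`).
#' @param stress_env Stress environment label (`"SI"` or `"SNI"`).
#' @param trait Trait to pair; default `"GY"` (grain yield, g/plot).
#'
#' @return A `yield_pair_table`: tibble with columns `genotype`, `Yp`, `Ys`,
#'   attributes `yp_bar`, `ys_bar` (population means, g/plot) and `stress`
#'   (`"heat"` or `"combined"`).
#' @examples
#' trial <- tibble::tibble(
#'   genotype = rep("A", 4), environment = rep(c("N2", "SNI"), each = 2),
#'   replicate = c(1, 2, 1, 2), trait = "GY", value = c(100, 120, 40, 60))
#' pair_yields(trial, "N2", "SNI")
#' @export
pair_yields <- function(trial, normal_env, stress_env, trait = "GY") {
  trial <- validate_trial_table(trial)
  if (treatment_class(normal_env) != "normal") {
    stop("normal_env must be a normal environment (N1 or N2), got ",
         normal_env, call. = FALSE)
  }
  if (treatment_class(stress_env) == "normal") {
    stop("stress_env must be a stress environment (SI or SNI), got ",
         stress_env, call. = FALSE)
  }
  sub <- trial[trial$trait == trait &
                 trial$environment %in% c(normal_env, stress_env), ]
  if (!normal_env %in% sub$environment) {
    stop("environment ", normal_env, " absent for trait ", trait,
         call. = FALSE)
  }
  if (!stress_env %in% sub$environment) {
    stop("environment ", stress_env, " absent for trait ", trait,
         call. = FALSE)
  }
  means <- sub |>
    dplyr::group_by(.data$genotype, .data$environment) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "environment", values_from = "value")
  incomplete <- is.na(means[[normal_env]]) | is.na(means[[stress_env]])
  if (any(incomplete)) {
    warning(sum(incomplete), " genotype(s) missing in one environment ",
            "dropped: ", paste(means$genotype[incomplete], collapse = ", "),
            call. = FALSE)
    means <- means[!incomplete, ]
  }
  zero_yp <- means[[normal_env]] <= 0
  if (any(zero_yp)) {
    warning(sum(zero_yp), " genotype(s) with non-positive normal yield ",
            "excluded from index computation: ",
            paste(means$genotype[zero_yp], collapse = ", "), call. = FALSE)
    means <- means[!zero_yp, ]
  }
  if (nrow(means) == 0) {
    stop("no genotype observed in both environments", call. = FALSE)
  }
  out <- tibble::tibble(genotype = means$genotype,
                        Yp = means[[normal_env]],
                        Ys = means[[stress_env]])
  new_yield_pair_table(out,
                       stress = treatment_class(stress_env),
                       normal_env = normal_env, stress_env = stress_env)
}

# Constructor shared by pair_yields() and simulate_yield_pairs().
new_yield_pair_table <- function(df, stress, normal_env = NA_character_,
                                 stress_env = NA_character_,
                                 true_group = NULL) {
  out <- tibble::as_tibble(df)
  stopifnot(all(c("genotype", "Yp", "Ys") %in% names(out)))
  attr(out, "yp_bar") <- mean(out$Yp)
  attr(out, "ys_bar") <- mean(out$Ys)
  attr(out, "stress") <- stress
  attr(out, "normal_env") <- normal_env
  attr(out, "stress_env") <- stress_env
  if (!is.null(true_group)) attr(out, "true_group") <- true_group
  class(out) <- c("yield_pair_table", class(out))
  out
}

#' Population mean yields of a yield-pair table
#'
#' @param pairs A `yield_pair_table`.
#' @return Named numeric vector `c(yp_bar = ..., ys_bar = ...)` (g/plot).
#' @export
pair_means <- function(pairs) {
  c(yp_bar = attr(pairs, "yp_bar"), ys_bar = attr(pairs, "ys_bar"))
}
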