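#' Stress intensity
#'
#' The population-level severity of a stress episode,
#' \eqn{SI = 1 - \bar{Y}_s / \bar{Y}_p}, where \eqn{\bar{Y}_p} and
#' \eqn{\bar{Y}_s} are the across-genotype mean yields under the normal and
#' the stress environment. `SI = 0` means no yield penalty, `SI = 1` total
#' loss.
#'
#' @param yp_bar Across-genotype mean yield under normal conditions
#'   (g/plot); must be > 0.
#' @param ys_bar Across-genotype mean yield under stress (g/plot).
#'
#' @return The dimensionless stress intensity.
#' @examples
#' stress_intensity(80, 48) # 0.4
#' @export
stress_intensity <- function(yp_bar, ys_bar) {
  if (!is.finite(yp_bar) || yp_bar <= 0) {
    stop("yp_bar must be a positive finite number", call. = FALSE)
  }
  1 - ys_bar / yp_bar
}

# Canonical column order of the wide index table.
index_columns <- c("Ys", "Yp", "STI", "TOL", "GMP", "MP", "HARM",
                   "SSI", "YSI")

#' Compute stress tolerance indices for a set of yield pairs
#'
#' Given per-genotype replicate-mean yields under normal (`Yp`) and stress
#' (`Ys`) conditions, computes the seven classical indices:
#' \describe{
#'   \item{STI}{stress tolerance index \eqn{Y_{pi} Y_{si} / \bar{Y}_p^2}
#'     (Fernandez); the denominator is the squared population mean.}
#'   \item{TOL}{tolerance \eqn{Y_{pi} - Y_{si}} (g/plot).}
#'   \item{GMP}{geometric mean productivity \eqn{\sqrt{Y_{pi} Y_{si}}}.}
#'   \item{MP}{mean productivity \eqn{(Y_{pi} + Y_{si})/2}.}
#'   \item{HARM}{harmonic mean \eqn{2 Y_{pi} Y_{si}/(Y_{pi} + Y_{si})}.}
#'   \item{SSI}{stress susceptibility index
#'     \eqn{(1 - Y_{si}/Y_{pi})/SI} (Fischer-Maurer).}
#'   \item{YSI}{yield stability index \eqn{Y_{si}/Y_{pi}}.}
#' }
#' The identities `TOL = Yp - Ys`, `GMP^2 = MP * HARM`,
#' `HARM <= GMP <= MP` and `YSI + SI * SSI = 1` hold exactly.
#'
#' @param pairs A `yield_pair_table` (see [pair_yields()],
#'   [simulate_yield_pairs()]). All `Yp` must be > 0.
#' @param allow_zero_si If the stress intensity is 0 (no stress), SSI is
#'   undefined; by default this is an error. With `allow_zero_si = TRUE`
#'   the SSI column is returned as `NA`.
#'
#' @return An `index_table`: tibble with columns `genotype`, `Ys`, `Yp`,
#'   `STI`, `TOL`, `GMP`, `MP`, `HARM`, `SSI`, `YSI`, and attributes `si`
#'   (stress intensity) and `stress` (carried over from `pairs`).
#' @examples
#' pairs <- simulate_yield_pairs(sim_preset("paper_heat_clusters"))
#' head(compute_indices(pairs))
#' @export
compute_indices <- function(pairs, allow_zero_si = FALSE) {
  stopifnot(all(c("genotype", "Yp", "Ys") %in% names(pairs)))
  if (any(!is.finite(pairs$Yp)) || any(!is.finite(pairs$Ys))) {
    stop("non-finite yields in pairs", call. = FALSE)
  }
  if (any(pairs$Yp <= 0)) {
    stop("all Yp must be > 0; drop such genotypes first (see pair_yields)",
         call. = FALSE)
  }
  yp_bar <- attr(pairs, "yp_bar") %||% mean(pairs$Yp)
  ys_bar <- attr(pairs, "ys_bar") %||% mean(pairs$Ys)
  si <- stress_intensity(yp_bar, ys_bar)
  ysi <- pairs$Ys / pairs$Yp
  if (si == 0) {
    if (!allow_zero_si) {
      stop("stress intensity is 0 (no stress): SSI undefined; ",
           "set allow_zero_si = TRUE to return SSI as NA", call. = FALSE)
    }
    ssi <- rep(NA_real_, nrow(pairs))
  } else {
    ssi <- (1 - ysi) / si
  }
  out <- tibble::tibble(
    genotype = pairs$genotype,
    Ys = pairs$Ys,
    Yp = pairs$Yp,
    STI = pairs$Yp * pairs$Ys / yp_bar^2,
    TOL = pairs$Yp - pairs$Ys,
    GMP = sqrt(pairs$Yp * pairs$Ys),
    MP = (pairs$Yp + pairs$Ys) / 2,
    HARM = 2 * pairs$Yp * pairs$Ys / (pairs$Yp + pairs$Ys),
    SSI = ssi,
    YSI = ysi)
  attr(out, "si") <- si
  attr(out, "yp_bar") <- yp_bar
  attr(out, "ys_bar") <- ys_bar
  attr(out, "stress") <- attr(pairs, "stress")
  class(out) <- c("index_table", class(out))
  out
}

#' Read / write a wide index CSV
#'
#' Wide format: columns `genotype,Ys,Yp,STI,TOL,GMP,MP,HARM,SSI,YSI`;
#' `#`-prefixed lines are comments. The stress intensity is recomputed from
#' the Yp/Ys columns on read.
#'
#' @param path File path.
#' @param indices An `index_table`.
#' @param header Optional comment lines for the writer.
#' @return `read_index_csv()` an `index_table`; `write_index_csv()` the
#'   path, invisibly.
#' @export
read_index_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                         progress = FALSE)
  need <- c("genotype", index_columns)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("index CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(raw[need])
  attr(out, "yp_bar") <- mean(out$Yp)
  attr(out, "ys_bar") <- mean(out$Ys)
  attr(out, "si") <- stress_intensity(mean(out$Yp), mean(out$Ys))
  class(out) <- c("index_table", class(out))
  out
}

#' @rdname read_index_csv
#' @export
write_index_csv <- function(indices, path, header = NULL) {
  stopifnot(all(c("genotype", index_columns) %in% names(indices)))
  write_csv_with_header(indices[, c("genotype", index_columns)], path,
                        header)
}
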