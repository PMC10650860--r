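#' Post-hoc mean separation with letter groups (LSD or Duncan)
#'
#' Compares a set of group means against an ANOVA error mean square and
#' assigns compact letter groups: means that do not differ significantly
#' share a letter, letters assigned from the largest mean downwards ("a"
#' first).
#'
#' For `method = "LSD"` every pair is compared against the single threshold
#' \deqn{LSD = t_{1-\alpha/2,\,df} \sqrt{2\,MS_e / r}.}
#' For `method = "Duncan"` (multiple range test) the critical range for two
#' means `p` steps apart in the ranking is
#' \deqn{R_p = q\big((1-\alpha)^{p-1};\, p,\, df\big)\sqrt{MS_e / r}}
#' with `q` the studentized-range quantile; adjacent means (`p = 2`) face
#' the same threshold as the LSD, wider spans a larger one.
#'
#' @param group_means Named numeric vector of group means (names become the
#'   group labels; unnamed vectors are labelled by position).
#' @param ms_error Error mean square from the ANOVA; `>= 0`.
#' @param df_error Error degrees of freedom; `>= 1`.
#' @param r Common group size (number of observations behind each mean).
#'   For mildly unequal sizes pass the harmonic mean.
#' @param method `"LSD"` or `"Duncan"`.
#' @param alpha Significance level (default 0.05).
#'
#' @return A `mean_separation` tibble with columns `group`, `mean`,
#'   `letters`, ordered by decreasing mean. With `ms_error = 0` any two
#'   unequal means are declared different.
#' @examples
#' mean_separation(c(A = 10, B = 9.9, C = 5), ms_error = 4.5,
#'                 df_error = 12, r = 2, method = "LSD")
#' @export
mean_separation <- function(group_means, ms_error, df_error, r,
                            method = c("LSD", "Duncan"), alpha = 0.05) {
  method <- match.arg(method)
  if (df_error < 1) stop("df_error must be >= 1", call. = FALSE)
  if (ms_error < 0) stop("ms_error must be >= 0", call. = FALSE)
  if (r <= 0) stop("r must be > 0", call. = FALSE)
  k <- length(group_means)
  if (k < 1) stop("no group means supplied", call. = FALSE)
  if (is.null(names(group_means))) {
    names(group_means) <- as.character(seq_len(k))
  }
  ord <- order(group_means, decreasing = TRUE)
  m <- group_means[ord]

  # critical difference for two means `span` apart in the ranked sequence
  crit <- if (method == "LSD") {
    lsd <- stats::qt(1 - alpha / 2, df_error) * sqrt(2 * ms_error / r)
    function(span) lsd
  } else {
    se <- sqrt(ms_error / r)
    function(span) stats::qtukey((1 - alpha)^(span - 1), span, df_error) * se
  }
  differ <- function(i, j) {            # i < j in ranked order
    gap <- m[i] - m[j]
    if (ms_error == 0) return(gap > 0)
    gap > crit(j - i + 1)
  }

  # sweep: for each start, extend to the longest run of non-different means;
  # keep only runs not contained in an earlier one, then letter them
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !differ(i, j + 1)) j <- j + 1
    contained <- length(runs) > 0 &&
      any(vapply(runs, function(rg) rg[1] <= i && rg[2] >= j, logical(1)))
    if (!contained) runs[[length(runs) + 1]] <- c(i, j)
  }
  if (length(runs) > 26) {
    stop("more than 26 letter groups required", call. = FALSE)
  }
  lab <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(runs, function(rg) rg[1] <= i && rg[2] >= i,
                                logical(1)))], collapse = "")
  }, character(1))

  out <- tibble::tibble(group = names(m), mean = unname(m), letters = lab)
  class(out) <- c("mean_separation", class(out))
  out
}
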