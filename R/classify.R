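#' Z-standardize the index columns
#'
#' Centres and scales each of the nine index columns (`Ys`, `Yp`, `STI`,
#' `TOL`, `GMP`, `MP`, `HARM`, `SSI`, `YSI`) to mean 0 and standard
#' deviation 1 (n - 1 denominator), putting g/plot-scaled yields and
#' dimensionless ratios on commensurate scales for PCA and Ward clustering.
#'
#' @param index_table An `index_table` (see [compute_indices()]), or any
#'   data frame carrying the nine columns and a `genotype` column.
#'
#' @return Numeric matrix (genotypes x 9) with genotype row names.
#' @export
standardize_indices <- function(index_table) {
  missing_cols <- setdiff(index_columns, names(index_table))
  if (length(missing_cols) > 0) {
    stop("index table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(index_table[index_columns])
  if (any(!is.finite(x))) stop("non-finite index values", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(index_columns[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- scale(x)
  dimnames(z) <- list(index_table$genotype, index_columns)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Correlation-matrix PCA of the stress indices
#'
#' Eigendecomposition of the correlation matrix of the (standardized) index
#' columns. Eigenvalues sum to the number of variables; the percent variance
#' of dimension `k` is `100 * lambda_k / p`; the contribution of variable
#' `j` to dimension `k` is `100 * e_jk^2`, the squared unit-eigenvector
#' loading, so contributions sum to 100 within each dimension. Eigenvector
#' signs are fixed so the `Ys` loading is non-negative on every dimension
#' (eigenvectors are sign-ambiguous; this makes biplots reproducible).
#'
#' @param z Standardized matrix from [standardize_indices()] (any numeric
#'   matrix with >= 3 rows works; columns are the variables).
#'
#' @return A `pca_result` list: `eigenvalues`, `variance_explained` (%),
#'   `cumulative_variance` (%), `contributions` (variables x dimensions, %),
#'   `loadings` (unit eigenvectors), `scores` (observations x dimensions).
#' @examples
#' idx <- compute_indices(simulate_yield_pairs(sim_preset("paper_heat_clusters")))
#' p <- pca_indices(standardize_indices(idx))
#' p$cumulative_variance[2] # first two dimensions, percent
#' @export
pca_indices <- function(z) {
  z <- as.matrix(z)
  if (any(!is.finite(z))) stop("non-finite entries", call. = FALSE)
  if (nrow(z) < 3) stop(">= 3 observations required", call. = FALSE)
  p <- ncol(z)
  C <- stats::cor(z)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)          # clip tiny negative roundoff
  vecs <- eig$vectors
  ys_row <- match("Ys", colnames(z))
  for (k in seq_len(p)) {
    anchor <- if (!is.na(ys_row)) vecs[ys_row, k] else vecs[1, k]
    if (anchor < 0) vecs[, k] <- -vecs[, k]
  }
  dn <- list(colnames(z), paste0("Dim.", seq_len(p)))
  dimnames(vecs) <- dn
  structure(list(
    eigenvalues = setNames(vals, dn[[2]]),
    variance_explained = setNames(100 * vals / p, dn[[2]]),
    cumulative_variance = setNames(cumsum(100 * vals / p), dn[[2]]),
    contributions = 100 * vecs^2,
    loadings = vecs,
    scores = scale(z, center = TRUE, scale = FALSE) %*% vecs
  ), class = "pca_result")
}

#' Ward hierarchical clustering of genotypes
#'
#' Agglomerative clustering of the standardized index rows under Ward's
#' minimum-variance criterion (squared-Euclidean objective; `hclust` method
#' `"ward.D2"` on Euclidean distances, Lance-Williams updates), with the
#' dendrogram cut into `k` groups. At each merge the criterion picks the
#' pair of clusters whose fusion least increases the total within-cluster
#' sum of squares; the merge height equals the square root of twice that
#' increase.
#'
#' @param z Standardized matrix from [standardize_indices()].
#' @param k Number of clusters to cut (default 4).
#'
#' @return A `cluster_result` list: `assignment` (named integer vector,
#'   cluster ids 1..k in order of first appearance), `merge_history` (tibble
#'   `step`, `a`, `b`, `height` in `hclust` merge encoding),
#'   `cluster_sizes`, `labels` (`NULL` until [label_clusters()]), `k`, and
#'   the underlying `hclust` object.
#' @export
ward_cluster <- function(z, k = 4) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n", call. = FALSE)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  assignment <- stats::cutree(hc, k = k)
  if (!is.null(rownames(z))) names(assignment) <- rownames(z)
  structure(list(
    assignment = assignment,
    merge_history = tibble::tibble(
      step = seq_len(n - 1),
      a = hc$merge[, 1], b = hc$merge[, 2],
      height = hc$height),
    cluster_sizes = as.integer(table(assignment)),
    labels = NULL,
    k = as.integer(k),
    hclust = hc
  ), class = "cluster_result")
}

# The four tolerance categories, most to least tolerant.
tolerance_levels <- c("tolerant", "moderately_tolerant",
                      "moderately_susceptible", "susceptible")

#' Label four clusters by tolerance class
#'
#' Applies a fixed rule to name the `k = 4` clusters from their mean index
#' values: the cluster with the highest mean GMP is `tolerant`; among the
#' remaining three, the one with the highest mean SSI is `susceptible`; of
#' the last two, the one with the higher mean YSI is `moderately_tolerant`
#' and the other `moderately_susceptible`. Exact ties in any of these
#' ranking statistics are an error (label manually in that case).
#'
#' @param clusters A `cluster_result` with `k = 4`.
#' @param index_table The `index_table` the clustering was computed from
#'   (same genotypes).
#'
#' @return The `cluster_result` with `labels`: a named character vector
#'   mapping cluster id to tolerance class, each class used exactly once.
#' @export
label_clusters <- function(clusters, index_table) {
  stopifnot(inherits(clusters, "cluster_result"))
  if (clusters$k != 4) {
    stop("tolerance labelling is defined for k = 4 clusters", call. = FALSE)
  }
  if (!all(names(clusters$assignment) %in% index_table$genotype)) {
    stop("clustered genotypes absent from index table", call. = FALSE)
  }
  idx <- index_table[match(names(clusters$assignment),
                           index_table$genotype), ]
  cl <- clusters$assignment
  stat <- function(col) tapply(idx[[col]], cl, mean)
  gmp <- stat("GMP"); ssi <- stat("SSI"); ysi <- stat("YSI")
  ids <- as.integer(names(gmp))

  pick_max <- function(x, cand, what) {
    x <- x[as.character(cand)]
    top <- cand[x == max(x)]
    if (length(top) > 1) {
      stop("tie in mean ", what, " between clusters ",
           paste(top, collapse = " and "),
           ": assign labels manually", call. = FALSE)
    }
    top
  }
  tol <- pick_max(gmp, ids, "GMP")
  rest <- setdiff(ids, tol)
  sus <- pick_max(ssi, rest, "SSI")
  rest <- setdiff(rest, sus)
  mtol <- pick_max(ysi, rest, "YSI")
  msus <- setdiff(rest, mtol)

  labels <- setNames(rep(NA_character_, 4), as.character(ids))
  labels[as.character(c(tol, mtol, msus, sus))] <-
    c("tolerant", "moderately_tolerant", "moderately_susceptible",
      "susceptible")
  clusters$labels <- labels
  clusters
}

#' Genotype-to-class assignment table
#'
#' @param clusters A labelled `cluster_result`.
#' @return Tibble with columns `genotype`, `cluster`, `label`.
#' @export
cluster_assignments <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_result"))
  out <- tibble::tibble(
    genotype = names(clusters$assignment),
    cluster = unname(clusters$assignment))
  out$label <- if (is.null(clusters$labels)) NA_character_ else
    unname(clusters$labels[as.character(out$cluster)])
  out
}

#' Per-cluster trait profile with Duncan letter groups
#'
#' For each requested trait, averages replicates within genotype, then
#' genotypes within cluster, and separates the cluster means with Duncan's
#' multiple range test at `alpha = 0.05` (error mean square from the
#' one-way cluster ANOVA on genotype means; harmonic-mean cluster size for
#' unequal clusters).
#'
#' @param clusters A (labelled) `cluster_result` covering every genotype in
#'   `trial`.
#' @param trial A `trial_table` with the genotypes of the clustering.
#' @param traits Character vector of traits to profile.
#' @param environment Optional single environment to restrict to.
#' @param method Mean-separation method (default `"Duncan"`).
#' @param alpha Significance level (default 0.05).
#'
#' @return Tibble with columns `trait`, `cluster`, `label`, `mean`,
#'   `letters`, ordered by trait then decreasing mean.
#' @export
cluster_profile <- function(clusters, trial, traits, environment = NULL,
                            method = "Duncan", alpha = 0.05) {
  stopifnot(inherits(clusters, "cluster_result"))
  trial <- validate_trial_table(trial)
  if (!is.null(environment)) {
    trial <- trial[trial$environment %in% environment, ]
  }
  avail <- unique(trial$trait)
  missing_tr <- setdiff(traits, avail)
  if (length(missing_tr) > 0) {
    stop("trait(s) absent from trial: ",
         paste(missing_tr, collapse = ", "),
         "; available: ", paste(sort(avail), collapse = ", "),
         call. = FALSE)
  }
  asg <- clusters$assignment
  not_in <- setdiff(unique(trial$genotype), names(asg))
  if (length(not_in) > 0) {
    stop("genotype(s) without cluster assignment: ",
         paste(utils::head(not_in, 5), collapse = ", "), call. = FALSE)
  }
  out <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    gm <- trial[trial$trait == tr, ] |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
    gm$cluster <- asg[gm$genotype]
    sizes <- table(gm$cluster)
    cm <- tapply(gm$value, gm$cluster, mean)
    # one-way ANOVA of genotype means across clusters
    grand <- mean(gm$value)
    ss_w <- sum((gm$value - cm[as.character(gm$cluster)])^2)
    df_w <- nrow(gm) - length(cm)
    if (df_w < 1) stop("not enough genotypes for within-cluster error",
                       call. = FALSE)
    ms_w <- ss_w / df_w
    r_h <- length(sizes) / sum(1 / as.numeric(sizes))  # harmonic mean size
    sep <- mean_separation(setNames(as.numeric(cm), names(cm)),
                           ms_error = ms_w, df_error = df_w, r = r_h,
                           method = method, alpha = alpha)
    sep$trait <- tr
    sep$cluster <- as.integer(sep$group)
    sep$label <- if (is.null(clusters$labels)) NA_character_ else
      unname(clusters$labels[sep$group])
    out[[ti]] <- sep[, c("trait", "cluster", "label", "mean", "letters")]
  }
  dplyr::bind_rows(out)
}

#' Export a dendrogram as nested newick-style text
#'
#' @param clusters A `cluster_result`.
#' @param digits Decimal places for branch heights.
#' @return A single newick string (leaf names, merge heights as labels).
#' @export
dendrogram_newick <- function(clusters, digits = 4) {
  stopifnot(inherits(clusters, "cluster_result"))
  hc <- clusters$hclust
  labs <- hc$labels %||% as.character(seq_len(length(hc$order)))
  node <- function(i) {
    if (i < 0) return(labs[-i])
    paste0("(", node(hc$merge[i, 1]), ",", node(hc$merge[i, 2]), "):",
           format(round(hc$height[i], digits), trim = TRUE))
  }
  paste0(node(nrow(hc$merge)), ";")
}
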