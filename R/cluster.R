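# Pattern discovery: log transform of skewed markers, Ward clustering on
# squared Euclidean distances, per-feature one-way ANOVA across clusters.

#' Log-transform skewed feature columns
#'
#' Replaces each value x by `log(x + epsilon)`. The small offset keeps
#' zero-valued densities (e.g. absent giant cells in perituberal cortex)
#' finite while preserving rank order. Columns already transformed are
#' tracked in the `transform_log` attribute and a second application is an
#' error.
#'
#' @param df data.frame.
#' @param columns character vector of column names to transform; all must
#'   be nonnegative.
#' @param epsilon offset added before the log, default 1e-3.
#' @return `df` with the named columns transformed and the
#'   `transform_log` attribute extended.
#' @export
log_skew_transform <- function(df, columns, epsilon = 1e-3) {
  done <- attr(df, "transform_log")
  again <- intersect(columns, done)
  if (length(again) > 0L)
    stop("column(s) already log-transformed: ",
         paste(again, collapse = ", "), call. = FALSE)
  missing <- setdiff(columns, names(df))
  if (length(missing) > 0L)
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (cl in columns) {
    if (any(df[[cl]] < 0, na.rm = TRUE))
      stop("negative values in column ", cl, call. = FALSE)
    df[[cl]] <- log(df[[cl]] + epsilon)
  }
  attr(df, "transform_log") <- c(done, columns)
  df
}

#' Ward hierarchical clustering of marker features
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' squared Euclidean distances. Features are z-standardised first (by
#' default), so percentage-scale and count-scale markers contribute
#' comparably to the distance; merge heights are then guaranteed
#' nondecreasing. Cluster labels come from cutting the tree at `k`
#' clusters; `k = NULL` picks the cut automatically at the largest gap
#' between successive merge heights (see \code{\link{select_k}}).
#'
#' @param df data.frame holding the feature columns (transform skewed
#'   columns first with \code{\link{log_skew_transform}}).
#' @param columns feature columns to cluster on.
#' @param k number of clusters, or `NULL` for automatic selection.
#' @param standardize z-score each column before computing distances.
#' @return list with `labels` (integer vector, 1..k, renumbered in order
#'   of first appearance), `k`, `tree` (an \code{\link[stats]{hclust}}
#'   object), and `data` (the matrix clustered).
#' @export
ward_cluster <- function(df, columns = c("ps6_pct", "smi32_density",
                                         "vimentin_density"),
                         k = 3L, standardize = TRUE) {
  missing <- setdiff(columns, names(df))
  if (length(missing) > 0L)
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[, columns, drop = FALSE])
  if (anyNA(m)) stop("missing values in clustered columns", call. = FALSE)
  n <- nrow(m)
  if (!is.null(k) && n < k)
    stop("need at least k samples", call. = FALSE)
  if (standardize) {
    m <- apply(m, 2, function(x) {
      s <- sd(x)
      if (s > 0) (x - mean(x)) / s else x - mean(x)
    })
    m <- matrix(m, nrow = n, dimnames = list(NULL, columns))
  }
  # ward.D on squared Euclidean distances is the classic Ward criterion
  tree <- hclust(dist(m)^2, method = "ward.D")
  if (is.null(k)) k <- select_k(tree)
  raw <- cutree(tree, k = k)
  first <- unique(raw)
  labels <- match(raw, first)
  list(labels = labels, k = as.integer(k), tree = tree, data = m)
}

#' Select the cluster count from the dendrogram
#'
#' Mojena's stopping rule: the natural partition keeps every merge whose
#' height stays within `mean(h) + c * sd(h)` of the height distribution
#' and cuts above the first height that jumps beyond it, giving
#' `k = 1 + (number of heights above the threshold)`. The constant
#' `c = 1.25` follows Milligan and Cooper's comparative study of stopping
#' rules. A naive cut at the single largest height gap is biased toward
#' two clusters under Ward's method, whose final merge height grows with
#' cluster size even without structure; flagging heights that are
#' outlying relative to the whole height distribution is robust to that.
#'
#' @param tree an \code{\link[stats]{hclust}} object.
#' @param k_max largest cluster count considered, default 10.
#' @param const threshold constant, default 1.25.
#' @return integer cluster count (at least 2 when `n >= 2`).
#' @export
select_k <- function(tree, k_max = 10L, const = 1.25) {
  h <- tree$height
  n <- length(h) + 1L
  if (length(h) < 2L) return(min(2L, n))
  thr <- mean(h) + const * sd(h)
  k <- sum(h > thr) + 1L
  as.integer(min(max(k, 2L), k_max, n))
}

#' Per-feature one-way ANOVA across cluster labels
#'
#' For each feature, a one-way ANOVA of feature ~ cluster identifies which
#' markers discriminate the clusters.
#'
#' @param df data.frame with the feature columns.
#' @param labels cluster membership, one per row of `df`.
#' @param columns features to test; defaults to every numeric column.
#' @return data.frame with one row per feature: `feature`, `f_statistic`,
#'   `df_between`, `df_within`, `p_value`.
#' @export
anova_feature_discrimination <- function(df, labels, columns = NULL) {
  if (length(labels) != nrow(df))
    stop("labels must match rows of df", call. = FALSE)
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L))
    stop("every group needs at least 2 samples", call. = FALSE)
  if (is.null(columns))
    columns <- names(df)[vapply(df, is.numeric, logical(1))]
  res <- lapply(columns, function(cl) {
    fit <- aov(df[[cl]] ~ g)
    tab <- summary(fit)[[1]]
    data.frame(feature = cl, f_statistic = tab[1, "F value"],
               df_between = tab[1, "Df"], df_within = tab[2, "Df"],
               p_value = tab[1, "Pr(>F)"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
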