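# Dynamic time warping and trajectory clustering.

#' Dynamic-time-warping distance between two series
#'
#' Classic exact dynamic-programming DTW with absolute-difference local
#' cost, symmetric steps and no band constraint. Zero for identical series
#' and symmetric in its arguments; note DTW does not satisfy the triangle
#' inequality, so the pairwise matrix is a dissimilarity, not a metric.
#'
#' @param a,b non-empty numeric series (possibly different lengths).
#' @return the non-negative alignment cost.
#' @examples
#' dtw_distance(c(0, 0, 0), c(1, 1, 1))  # 3
#' dtw_distance(1:5, 1:5)                # 0
#' @export
dtw_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0)
    stop("DTW is undefined for empty series")
  if (anyNA(a) || anyNA(b)) stop("series must not contain missing values")
  dtw_dist_cpp(a, b)
}

#' Pairwise DTW distance matrix
#'
#' @param trajectories list of non-empty numeric series.
#' @param scale z-score each series first (recommended when series of
#'   different physical quantities are clustered together).
#' @return a symmetric matrix of DTW distances.
#' @export
dtw_distance_matrix <- function(trajectories, scale = FALSE) {
  stopifnot(is.list(trajectories), length(trajectories) >= 1)
  if (scale) trajectories <- lapply(trajectories, zscore_series)
  lens <- lengths(trajectories)
  if (any(lens == 0)) stop("DTW is undefined for empty series")
  trajectories <- lapply(trajectories, as.numeric)
  d <- dtw_pairwise_cpp(trajectories)
  dimnames(d) <- list(names(trajectories), names(trajectories))
  d
}

zscore_series <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Cluster lineage trajectories by DTW + average linkage
#'
#' Agglomerative hierarchical clustering with average linkage on the
#' pairwise DTW distance matrix, cut at `k` clusters. Used to validate the
#' threshold-based deletion calls: deleted and non-deleted lineages form
#' well-separated trajectory families (fluorescence decay versus steady
#' signal, declining versus steady elongation rate).
#'
#' @param trajectories list of numeric series (one per lineage).
#' @param k number of clusters (1 <= k <= number of series).
#' @param scale z-score each series before computing distances (default
#'   `TRUE`, making channels of different units commensurate).
#' @return a list with `labels` (integer cluster per series, numbered by
#'   first appearance), `hclust` (the dendrogram object) and `dist`
#'   (the DTW distance matrix).
#' @examples
#' fam1 <- replicate(4, cumsum(rnorm(20, 0.2)), simplify = FALSE)
#' fam2 <- replicate(4, cumsum(rnorm(20, -0.2)), simplify = FALSE)
#' cl <- cluster_lineages(c(fam1, fam2), k = 2)
#' cl$labels
#' @export
cluster_lineages <- function(trajectories, k, scale = TRUE) {
  n <- length(trajectories)
  if (k > n) stop("`k` must not exceed the number of trajectories")
  if (k < 1) stop("`k` must be at least 1")
  d <- dtw_distance_matrix(trajectories, scale = scale)
  hc <- hclust(as.dist(d), method = "average")
  raw <- cutree(hc, k = k)
  # renumber clusters by order of first appearance (deterministic contract)
  labels <- match(raw, unique(raw))
  list(labels = labels, hclust = hc, dist = d)
}
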