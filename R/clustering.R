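# Lower/higher memory-functioning partitions: exact 1-D two-means on a
# model coefficient, or Ward's method on the five raw trial scores.

new_lc_clusters <- function(labels, values, method, extra = list()) {
  labels <- factor(labels, levels = c("lower", "higher"))
  sizes <- table(labels)
  structure(c(list(
    labels = labels,
    sizes = c(lower = unname(sizes[["lower"]]),
              higher = unname(sizes[["higher"]])),
    method = method
  ), extra), class = "lc_clusters")
}

#' @export
print.lc_clusters <- function(x, ...) {
  cat("Two-cluster partition (", x$method, ")\n", sep = "")
  cat(sprintf("  lower : n = %d", x$sizes[["lower"]]))
  if (!is.null(x$ranges)) {
    cat(sprintf(", range %.3g..%.3g", x$ranges$lower[1], x$ranges$lower[2]))
  }
  cat("\n")
  cat(sprintf("  higher: n = %d", x$sizes[["higher"]]))
  if (!is.null(x$ranges)) {
    cat(sprintf(", range %.3g..%.3g", x$ranges$higher[1], x$ranges$higher[2]))
  }
  cat("\n")
  invisible(x)
}

#' Exact two-means clustering of a scalar coefficient
#'
#' Globally optimal 2-cluster partition of a scalar sample minimising the
#' within-cluster sum of squares. Optimal 1-D clusters are contiguous in
#' sorted order, so the optimum is found by exhaustively scanning the
#' `n - 1` contiguous split points; the result is deterministic (no
#' iterative seeding). Ties between equal-cost splits are broken toward the
#' more balanced partition, then the lower split index.
#'
#' @param values scalar values (e.g. fitted `B3` per subject), `n >= 2`,
#'   not all identical.
#' @return An object of class `"lc_clusters"` with per-subject `labels`
#'   (`lower`/`higher`, in input order), `sizes`, `centers` (cluster
#'   means), `ranges` (min-max per cluster; they never overlap) and
#'   `within_ss`.
#' @examples
#' two_means_1d(c(1, 2, 9, 10))
#' @export
two_means_1d <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (diff(range(values)) == 0) {
    stop("all values identical: no cluster structure", call. = FALSE)
  }
  n <- length(values)
  o <- order(values)
  s <- values[o]
  # prefix sums give each contiguous segment's SS in O(1)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  seg_ss <- function(i, j) { # within-SS of s[i..j]
    m <- j - i + 1
    sum_ <- cs[j] - if (i > 1) cs[i - 1] else 0
    sum2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    sum2 - sum_^2 / m
  }
  k <- seq_len(n - 1)
  costs <- vapply(k, function(i) seg_ss(1, i) + seg_ss(i + 1, n), 0.0)
  tol <- 1e-10 * max(1, abs(min(costs)))
  best <- k[costs <= min(costs) + tol]
  bal <- abs(best - n / 2)
  best <- best[bal == min(bal)]
  split <- min(best)

  labels <- rep("higher", n)
  labels[o[seq_len(split)]] <- "lower"
  low <- s[seq_len(split)]
  high <- s[(split + 1):n]
  new_lc_clusters(labels, values, "two-means", list(
    centers = c(lower = mean(low), higher = mean(high)),
    ranges = list(lower = range(low), higher = range(high)),
    within_ss = min(costs),
    split_index = split,
    values = values
  ))
}

#' Ward clustering of the five trial scores
#'
#' Agglomerative hierarchical clustering with Ward's minimum-variance
#' criterion (Lance-Williams update; classic Ward on squared Euclidean
#' distances, i.e. `hclust(method = "ward.D2")` on Euclidean distance),
#' cut at 2 clusters. Clusters are named `lower`/`higher` by the grand
#' mean of their trial scores. Trials share units (words), so scores are
#' clustered raw by default; `standardize = TRUE` scales each trial column
#' first.
#'
#' @param trial_matrix numeric matrix, subjects in rows, one column per
#'   trial (typically 5).
#' @param standardize scale columns to unit variance before clustering.
#' @return An `"lc_clusters"` object; `centers` holds the per-cluster mean
#'   trial profile and `hclust` the full agglomeration tree.
#' @export
ward_trials <- function(trial_matrix, standardize = FALSE) {
  X <- as.matrix(trial_matrix)
  if (nrow(X) < 2) stop("need at least 2 subjects", call. = FALSE)
  if (any(!is.finite(X))) stop("trial scores must be finite", call. = FALSE)
  Xc <- if (standardize) scale(X) else X
  hc <- stats::hclust(stats::dist(Xc), method = "ward.D2")
  cut <- stats::cutree(hc, k = 2)
  labels <- label_clusters(cut, rowMeans(X))
  cent <- rbind(lower = colMeans(X[labels == "lower", , drop = FALSE]),
                higher = colMeans(X[labels == "higher", , drop = FALSE]))
  new_lc_clusters(labels, rowMeans(X), "ward-trials",
                  list(centers = cent, hclust = hc))
}

#' Name two clusters lower/higher memory functioning
#'
#' Maps an arbitrary 2-level partition onto the `lower`/`higher` naming
#' convention: `higher` is the cluster whose mean of the clustered
#' variable is greater. Stable under permutation of the input order. An
#' exact tie of means cannot be named automatically and raises an error.
#'
#' @param partition a 2-level factor/vector of cluster assignments.
#' @param values the scalar each subject was (or summarises being)
#'   clustered on, same length as `partition`.
#' @return A factor with levels `lower`, `higher`, in input order.
#' @export
label_clusters <- function(partition, values) {
  f <- factor(partition)
  if (nlevels(f) != 2) stop("exactly two clusters are required",
                            call. = FALSE)
  if (length(values) != length(f)) {
    stop("values must match the partition length", call. = FALSE)
  }
  m <- tapply(values, f, mean)
  if (m[1] == m[2]) {
    stop("cluster means are exactly tied; lower/higher naming is undefined",
         call. = FALSE)
  }
  higher_level <- names(m)[which.max(m)]
  factor(ifelse(as.character(f) == higher_level, "higher", "lower"),
         levels = c("lower", "higher"))
}
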