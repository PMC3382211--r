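# Two-group Fisher linear discriminant analysis with the display
# conventions used for clinical boundary values: scores scaled to unit
# pooled within-group variance, size-weighted grand centroid at zero, and
# a fixed boundary between the two group centroids.

#' Bartlett's chi-square approximation for Wilks' lambda
#'
#' `chi2 = -(N - 1 - (p + g)/2) * ln(lambda)` with `df = p * (g - 1)`,
#' the large-sample test that Wilks' lambda differs from 1.
#'
#' @param lambda Wilks' lambda in (0, 1].
#' @param n total sample size `N`.
#' @param p number of predictors.
#' @param g number of groups (default 2).
#' @return The chi-square statistic.
#' @examples
#' bartlett_chi2(0.534, 74, 1)  # ~44.86
#' @export
bartlett_chi2 <- function(lambda, n, p, g = 2) {
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]",
                                      call. = FALSE)
  -(n - 1 - (p + g) / 2) * log(lambda)
}

#' Fit a two-group linear discriminant function
#'
#' Canonical discriminant weights proportional to
#' `S_pooled^-1 (mean_a - mean_b)`, rescaled so the pooled within-group
#' variance of the discriminant scores is exactly 1, signed so the first
#' (reference) group has the larger centroid. The constant `C0` places the
#' size-weighted grand centroid at score 0. The boundary value `Y_b` is
#' the unweighted midpoint of the two group centroids (`"weighted"` uses
#' the size-weighted midpoint, i.e. score 0); scores `>= Y_b` classify as
#' the reference group. Separation is summarised by Wilks'
#' `lambda = |W| / |T|` (within over total cross-products) and Bartlett's
#' chi-square.
#'
#' @param group_a reference-group predictor matrix (or vector if
#'   univariate), `n_a x p`.
#' @param group_b comparison-group predictor matrix, `n_b x p`.
#' @param groups character of length 2 naming the groups; the first is the
#'   reference ("healthy-like") side.
#' @param boundary `"midpoint"` (default) or `"weighted"`.
#' @return An object of class `"lc_lda"`: `coefficients` (`C0` then one
#'   weight per predictor), `boundary`, `wilks_lambda`, `chi2`, `df`,
#'   `p_value`, `centroids`, `n_per_group` and the training
#'   classification report.
#' @export
fit_lda <- function(group_a, group_b, groups = c("control", "patient"),
                    boundary = c("midpoint", "weighted")) {
  boundary <- match.arg(boundary)
  A <- as.matrix(group_a)
  B <- as.matrix(group_b)
  if (ncol(A) != ncol(B)) stop("groups must share predictors", call. = FALSE)
  p <- ncol(A)
  preds <- colnames(A)
  if (is.null(preds)) preds <- paste0("x", seq_len(p))
  n_a <- nrow(A); n_b <- nrow(B); N <- n_a + n_b
  if (n_a < p + 2 || n_b < p + 2) {
    stop(sprintf("each group needs at least p + 2 = %d subjects", p + 2),
         call. = FALSE)
  }
  ma <- colMeans(A); mb <- colMeans(B)
  grand <- (n_a * ma + n_b * mb) / N
  Wa <- crossprod(sweep(A, 2, ma))
  Wb <- crossprod(sweep(B, 2, mb))
  W <- Wa + Wb
  S <- W / (N - 2)                       # pooled within-group covariance
  w_raw <- try(solve(S, ma - mb), silent = TRUE)
  if (inherits(w_raw, "try-error") || any(!is.finite(w_raw))) {
    qr_S <- qr(S)
    bad <- preds[setdiff(seq_len(p), qr_S$pivot[seq_len(qr_S$rank)])]
    stop("pooled within-group covariance is singular (collinear ",
         "predictors: ", paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  denom2 <- drop(t(w_raw) %*% S %*% w_raw)
  if (denom2 <= 0) {
    stop("group means coincide; the discriminant direction is undefined",
         call. = FALSE)
  }
  w <- w_raw / sqrt(denom2)
  if (drop(crossprod(w, ma - mb)) < 0) w <- -w
  C0 <- -drop(crossprod(w, grand))
  cent <- c(drop(crossprod(w, ma)) + C0, drop(crossprod(w, mb)) + C0)
  names(cent) <- groups
  Yb <- if (boundary == "midpoint") mean(cent) else 0

  Bscat <- n_a * tcrossprod(ma - grand) + n_b * tcrossprod(mb - grand)
  Tm <- W + Bscat
  lambda <- det(W) / det(Tm)
  lambda <- min(max(lambda, .Machine$double.eps), 1)
  chi2 <- bartlett_chi2(lambda, N, p)
  df <- p
  coefs <- c(C0 = C0, stats::setNames(as.numeric(w), preds))

  model <- structure(list(
    coefficients = coefs,
    boundary = Yb,
    boundary_type = boundary,
    wilks_lambda = lambda,
    chi2 = chi2,
    df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
    centroids = cent,
    n_per_group = stats::setNames(c(n_a, n_b), groups),
    groups = groups,
    predictors = preds
  ), class = "lc_lda")
  model$training <- rbind(
    classification_report(model, A, groups[1]),
    classification_report(model, B, groups[2])
  )
  model
}

#' Build a discriminant model from published coefficients
#'
#' Wraps an externally reported discriminant function (constant, weights,
#' boundary value) as an `"lc_lda"` object so that [classify()],
#' [verify_holdout()] and [threshold_from_function()] can be applied to
#' it. Separation statistics are unknown for such functions and stored as
#' `NA`.
#'
#' @param c0 the constant term.
#' @param weights named (or unnamed) predictor weights.
#' @param boundary the boundary value `Y_b`.
#' @inheritParams fit_lda
#' @export
discriminant_function <- function(c0, weights, boundary,
                                  groups = c("control", "patient")) {
  preds <- names(weights)
  if (is.null(preds)) preds <- paste0("x", seq_along(weights))
  structure(list(
    coefficients = c(C0 = unname(c0),
                     stats::setNames(as.numeric(weights), preds)),
    boundary = boundary,
    boundary_type = "published",
    wilks_lambda = NA_real_, chi2 = NA_real_, df = length(weights),
    p_value = NA_real_,
    centroids = NULL, n_per_group = NULL,
    groups = groups, predictors = preds
  ), class = "lc_lda")
}

#' @export
print.lc_lda <- function(x, digits = 3, ...) {
  cat("Linear discriminant function (", paste(x$groups, collapse = " vs "),
      ")\n", sep = "")
  cat("  y =", format(round(x$coefficients[["C0"]], digits)))
  for (p in x$predictors) {
    w <- x$coefficients[[p]]
    cat(sprintf(" %s %s*%s", ifelse(w >= 0, "+", "-"),
                format(round(abs(w), digits)), p))
  }
  cat("\n")
  cat("  boundary Y_b =", format(round(x$boundary, digits)),
      sprintf("(scores >= Y_b classify as %s)\n", x$groups[1]))
  if (is.finite(x$wilks_lambda)) {
    cat(sprintf("  Wilks' lambda = %.3f, chi2(%d) = %.3f, P = %.3g\n",
                x$wilks_lambda, x$df, x$chi2, x$p_value))
  }
  invisible(x)
}

#' Classify predictor vectors with a discriminant model
#'
#' Computes `y = C0 + sum(C_i x_i)` and labels a case as the reference
#' group iff `y >= Y_b` (the boundary is inclusive on the healthy side).
#'
#' @param model an `"lc_lda"` object.
#' @param x a predictor vector, or a matrix/data frame with one row per
#'   case and columns matching the model's predictors.
#' @return A data frame with `score` and `label`.
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "lc_lda"))
  p <- length(model$predictors)
  if (is.null(dim(x))) {
    # a bare vector is one case for a p-variate model, or p = 1 cases
    if (p > 1 && length(x) != p) {
      stop(sprintf("expected %d predictor(s), got %d", p, length(x)),
           call. = FALSE)
    }
    X <- matrix(x, ncol = p, byrow = TRUE)
  } else {
    X <- as.matrix(x)
  }
  if (ncol(X) != length(model$predictors)) {
    stop(sprintf("expected %d predictor(s), got %d",
                 length(model$predictors), ncol(X)), call. = FALSE)
  }
  w <- model$coefficients[model$predictors]
  score <- drop(X %*% w) + model$coefficients[["C0"]]
  label <- factor(ifelse(score >= model$boundary, model$groups[1],
                         model$groups[2]), levels = model$groups)
  data.frame(score = score, label = label)
}

# One row of counts-correct bookkeeping for a group of known membership.
classification_report <- function(model, X, true_group) {
  cl <- classify(model, X)
  n <- nrow(cl)
  correct <- sum(cl$label == true_group)
  data.frame(group = true_group, n = n, correct = correct,
             incorrect = n - correct,
             percent_correct = 100 * correct / n)
}

#' Invert a univariate discriminant function at its boundary
#'
#' For a univariate function `y = c0 + c1 * predictor` with boundary
#' `Y_b`, the predictor-space cutoff is `(Y_b - c0) / c1`. With `c1 > 0`,
#' predictor values below the cutoff classify as impaired: this turns a
#' discriminant function into a clinical cutoff on `B3` or `B4` directly.
#'
#' @param c0 constant term.
#' @param c1 univariate weight (nonzero).
#' @param boundary boundary value `Y_b` on the score scale.
#' @return The predictor cutoff.
#' @examples
#' threshold_from_function(-4.518, 0.937, 0.958)  # ~5.84 words
#' @export
threshold_from_function <- function(c0, c1, boundary) {
  if (!is.finite(c1) || c1 == 0) {
    stop("degenerate discriminant function: c1 must be nonzero",
         call. = FALSE)
  }
  (boundary - c0) / c1
}

#' Classify a held-out cluster and report agreement
#'
#' Applies [classify()] to every row of a hold-out sample and reports how
#' many match an expected label — the verification step applied to the
#' non-training clusters (e.g. the lower memory-functioning cluster of
#' controls).
#'
#' @param model an `"lc_lda"` object.
#' @param holdout predictor matrix/vector of held-out cases.
#' @param expected_label the label agreement is counted against; must be
#'   one of the model's groups.
#' @return A list with the per-case `classification` data frame, `n`,
#'   `n_match` and `percent_match`.
#' @export
verify_holdout <- function(model, holdout, expected_label) {
  stopifnot(inherits(model, "lc_lda"))
  if (!expected_label %in% model$groups) {
    stop("expected_label must be one of: ",
         paste(model$groups, collapse = ", "), call. = FALSE)
  }
  cl <- classify(model, holdout)
  n <- nrow(cl)
  if (n == 0) stop("holdout is empty", call. = FALSE)
  m <- sum(cl$label == expected_label)
  list(classification = cl, n = n, expected_label = expected_label,
       n_match = m, percent_match = 100 * m / n)
}

#' Per-trial comparison of two groups
#'
#' Two-sided pooled-variance (equal-variance) independent-samples t-test
#' for each column (trial) of two group matrices.
#'
#' @param group_a,group_b numeric matrices with identical columns.
#' @return A data frame with one row per trial: group means, `t`, `df`
#'   and `p_value`.
#' @export
compare_group_means <- function(group_a, group_b) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  if (ncol(A) != ncol(B)) stop("groups must share columns", call. = FALSE)
  if (nrow(A) < 2 || nrow(B) < 2) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  cols <- colnames(A)
  if (is.null(cols)) cols <- paste0("t", seq_len(ncol(A)))
  out <- lapply(seq_len(ncol(A)), function(j) {
    a <- A[, j]; b <- B[, j]
    if (stats::var(a) + stats::var(b) == 0) {
      stop("zero pooled variance in column ", cols[j], call. = FALSE)
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(trial = cols[j], mean_a = mean(a), mean_b = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  do.call(rbind, out)
}
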