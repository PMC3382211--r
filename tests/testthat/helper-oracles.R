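# Independent oracles and small fixture builders used across the suite.

# Finite-difference asymptotic SEs: numerical Jacobian of the model at the
# optimum, s^2 (J'J)^-1 with s^2 = SS_res/(n-3). Independent of the
# analytic Jacobian inside the package.
fd_asymptotic_se <- function(params, trials, ss_res, h = 1e-6) {
  n <- length(trials)
  J <- matrix(0, n, 3)
  for (j in 1:3) {
    up <- params; dn <- params
    up[j] <- up[j] + h; dn[j] <- dn[j] - h
    J[, j] <- (evaluate_model(up, trials) - evaluate_model(dn, trials)) /
      (2 * h)
  }
  s2 <- if (n > 3) ss_res / (n - 3) else 0
  sqrt(diag(s2 * solve(crossprod(J))))
}

# Total within-cluster SSE of a labelled partition of a matrix.
partition_sse <- function(X, labels) {
  s <- 0
  for (g in unique(labels)) {
    M <- X[labels == g, , drop = FALSE]
    s <- s + sum(sweep(M, 2, colMeans(M))^2)
  }
  s
}

# Exhaustive search over all 2-partitions of the rows of X for the
# minimum total within-cluster SSE (feasible for n <= ~12).
best_bipartition <- function(X) {
  n <- nrow(X)
  best <- Inf
  bestlab <- NULL
  for (m in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(m))[1:n]
    if (length(unique(lab)) < 2) next
    s <- partition_sse(X, lab)
    if (s < best - 1e-10) {
      best <- s
      bestlab <- lab
    }
  }
  list(labels = bestlab, sse = best)
}

same_partition <- function(a, b) {
  length(unique(paste(a, b))) == 2
}

# Brute-force Fisher direction on 2-D data: scan projection angles on a
# 1-degree grid maximising the between/within variance ratio.
grid_lda_direction <- function(A, B) {
  angles <- (0:179) * pi / 180
  ratio <- vapply(angles, function(th) {
    w <- c(cos(th), sin(th))
    sa <- drop(A %*% w); sb <- drop(B %*% w)
    between <- (mean(sa) - mean(sb))^2
    within <- (sum((sa - mean(sa))^2) + sum((sb - mean(sb))^2)) /
      (length(sa) + length(sb) - 2)
    between / within
  }, 0.0)
  th <- angles[which.max(ratio)]
  c(cos(th), sin(th))
}
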