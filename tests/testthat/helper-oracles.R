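# Independent reference implementations used as oracles. These deliberately
# recompute everything from first principles (no calls into the package
# internals beyond plain arithmetic) so they stay independent of the code
# paths they check.

# Exhaustive Kennard-Stone: recomputes all pairwise distances at every step.
ksReference <- function(X, k) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- -Inf
  sel <- c(1L, 2L)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (d(i, j) > best) {
        best <- d(i, j)
        sel <- c(i, j)
      }
    }
  }
  while (length(sel) < k) {
    rem <- setdiff(seq_len(n), sel)
    md <- vapply(rem, function(r) {
      min(vapply(sel, function(s) d(r, s), numeric(1L)))
    }, numeric(1L))
    sel <- c(sel, rem[which.max(md)])
  }
  sel
}

# Deflation-free PLS1 reference via the Krylov-subspace formulation:
# with s = X'y, the k-component PLS solution is the least-squares fit
# restricted to span{s, (X'X)s, ..., (X'X)^(k-1) s}. Scaling/centring is
# redone here from scratch.
plsKrylovPredict <- function(X, y, k, Xnew) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  yb <- mean(y)
  yc <- y - yb
  s <- drop(crossprod(Xs, yc))
  XtX <- crossprod(Xs)
  K <- matrix(0, ncol(X), k)
  v <- s
  for (j in seq_len(k)) {
    K[, j] <- v / sqrt(sum(v^2))
    v <- drop(XtX %*% K[, j])
  }
  K <- qr.Q(qr(K))  # orthonormal basis of the same Krylov subspace
  M <- crossprod(K, XtX %*% K)
  b <- drop(K %*% solve(M, crossprod(K, s)))
  Xn <- sweep(sweep(Xnew, 2L, mu), 2L, sdv, `/`)
  drop(Xn %*% b) + yb
}

# Ordinary least squares (with intercept) on the autoscaled variables.
olsPredict <- function(X, y, Xnew) {
  fit <- lm(y ~ ., data = as.data.frame(X))
  unname(predict(fit, newdata = as.data.frame(Xnew)))
}

# Noiseless quadratic baseline + narrow peaks fixture for baseline recovery.
baselineFixture <- function(n = 400) {
  wn <- seq(800, 1800, length.out = n)
  t <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
  true <- 0.3 + 0.1 * t + 0.15 * t^2
  peaks <- Reduce(`+`, lapply(c(1000, 1250, 1600), function(c0) {
    0.8 * exp(-log(2) * ((wn - c0) / 6)^2)
  }))
  list(wn = wn, true = true, y = true + peaks)
}
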