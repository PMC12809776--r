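# Scalar slice samplers and convergence diagnostics for the Gibbs sampler.

# Slice sampler on a bounded interval (shrinkage only; no stepping out
# needed because the support is finite). logf need not be normalised.
slice_bounded <- function(x0, logf, lower, upper, max_shrink = 200L) {
  y <- logf(x0) - stats::rexp(1L)
  l <- lower; r <- upper
  for (i in seq_len(max_shrink)) {
    x1 <- stats::runif(1L, l, r)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
  }
  x0 # numerically stuck; keep current value
}

# Neal's stepping-out slice sampler on the real line.
slice_stepout <- function(x0, logf, w = 1, m = 50L, max_shrink = 200L) {
  y <- logf(x0) - stats::rexp(1L)
  u <- stats::runif(1L)
  l <- x0 - w * u
  r <- l + w
  j <- floor(m * stats::runif(1L)); k <- m - 1L - j
  while (j > 0L && logf(l) > y) { l <- l - w; j <- j - 1L }
  while (k > 0L && logf(r) > y) { r <- r + w; k <- k - 1L }
  for (i in seq_len(max_shrink)) {
    x1 <- stats::runif(1L, l, r)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
  }
  x0
}

# Split-R-hat (Gelman et al.): x is an iterations x chains matrix.
split_rhat <- function(x) {
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1L):n, , drop = FALSE])
  mns <- colMeans(xs)
  vars <- apply(xs, 2L, stats::var)
  W <- mean(vars)
  B <- half * stats::var(mns)
  if (W < 1e-12) return(if (B < 1e-12) 1 else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Effective sample size from chain autocovariances (Geyer's initial
# positive sequence, applied to chains pooled after centring).
ess_basic <- function(x) {
  n <- nrow(x); C <- ncol(x)
  if (n < 4L) return(NA_real_)
  acsum <- 0
  for (c in seq_len(C)) {
    v <- x[, c] - mean(x[, c])
    if (stats::sd(v) < 1e-12) next
    ac <- stats::acf(v, lag.max = min(n - 1L, 200L), plot = FALSE,
                     demean = FALSE)$acf[, 1L, 1L]
    rho <- ac / ac[1L]
    # sum consecutive pairs until a pair sum goes non-positive
    s <- 0
    t <- 2L
    while (t + 1L <= length(rho)) {
      pair <- rho[t] + rho[t + 1L]
      if (pair <= 0) break
      s <- s + pair
      t <- t + 2L
    }
    acsum <- acsum + s
  }
  tau <- 1 + 2 * acsum / C
  max(1, n * C / max(tau, 1e-12))
}

# Apply a diagnostic over a draws array [iter, dim, chain].
diag_over <- function(arr, fun) {
  apply(arr, 2L, function(sl) fun(as.matrix(sl)))
}
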