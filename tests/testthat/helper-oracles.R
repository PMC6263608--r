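# Independent oracles used across the suite. These share no code with the
# package implementation: the classical NIPALS oracle uses the covariance
# form of the weight vector, the LWPLS oracle is a straight transliteration
# of the weighted component loop using a dense eigensolver, and the OLS
# oracle solves the normal equations.

ols_fit_predict <- function(X, y, Xq) {
  Xi <- cbind(1, X)
  beta <- solve(crossprod(Xi), crossprod(Xi, y))
  drop(cbind(1, Xq) %*% beta)
}

# Classical covariance-maximising NIPALS: w_k = X_k' y_k / ||X_k' y_k||.
nipals_classic <- function(X, y, K) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  W <- P <- matrix(0, ncol(X), K)
  b <- numeric(K)
  for (k in seq_len(K)) {
    v <- drop(crossprod(Xc, yc))
    w <- v / sqrt(sum(v^2))
    t_k <- drop(Xc %*% w)
    tt <- sum(t_k^2)
    p <- drop(crossprod(Xc, t_k)) / tt
    bk <- sum(yc * t_k) / tt
    W[, k] <- w; P[, k] <- p; b[k] <- bk
    Xc <- Xc - tcrossprod(t_k, p)
    yc <- yc - bk * t_k
  }
  list(W = W, P = P, b = b)
}

nipals_classic_predict <- function(X, y, K, xq) {
  m <- nipals_classic(X, y, K)
  xc <- xq - colMeans(X)
  yhat <- mean(y)
  for (k in seq_len(K)) {
    t_q <- sum(xc * m$W[, k])
    yhat <- yhat + t_q * m$b[k]
    xc <- xc - t_q * m$P[, k]
  }
  yhat
}

# Straight transliteration of the weighted component loop, with the weight
# vector taken from a dense eigendecomposition of X_k' O y_k y_k' O X_k
# (not the closed form used by the implementation).
lwpls_transliterate <- function(X, y, xq, phi, K) {
  N <- nrow(X)
  d <- rowSums(sweep(X, 2, xq)^2)
  sigma_d <- sqrt(mean((d - mean(d))^2))
  omega <- if (sigma_d <= max(d) * 1e-12) rep(1, N) else exp(-d * phi / sigma_d)
  O <- diag(omega, N)
  xbar <- drop(crossprod(X, omega)) / sum(omega)
  ybar <- sum(omega * y) / sum(omega)
  Xk <- sweep(X, 2, xbar)
  yk <- y - ybar
  xqk <- xq - xbar
  yhat <- ybar
  for (k in seq_len(K)) {
    A <- crossprod(Xk, O %*% yk) %*% crossprod(yk, O %*% Xk)
    if (sum(abs(A)) < 1e-20) break
    ev <- eigen(A, symmetric = TRUE)
    w <- ev$vectors[, 1]
    # the eigenvector is sign-ambiguous; estimates are invariant, but align
    # for readability
    if (sum(w * drop(crossprod(Xk, omega * yk))) < 0) w <- -w
    t_k <- drop(Xk %*% w)
    t_q <- sum(xqk * w)
    tot <- sum(omega * t_k^2)
    p <- drop(crossprod(Xk, omega * t_k)) / tot
    d_k <- sum(omega * yk * t_k) / tot
    yhat <- yhat + t_q * d_k
    Xk <- Xk - tcrossprod(t_k, p)
    yk <- yk - t_k * d_k
    xqk <- xqk - t_q * p
  }
  yhat
}

# Dominant periodogram frequency (Hz) of an evenly sampled series.
periodogram_peak <- function(x, fs) {
  sp <- stats::spec.pgram(stats::ts(x - mean(x), frequency = fs),
                          taper = 0, plot = FALSE, detrend = FALSE)
  sp$freq[which.max(sp$spec)]
}

rand_problem <- function(n, m, seed) {
  set.seed(seed)
  list(X = matrix(stats::rnorm(n * m), n, m), y = stats::rnorm(n),
       xq = stats::rnorm(m))
}

# Training rows all exactly equidistant from the query: forces the
# sigma_d = 0 uniform-weight path.
equidistant_problem <- function(n, m, seed, radius = 2) {
  set.seed(seed)
  xq <- stats::rnorm(m)
  U <- t(vapply(seq_len(n), function(i) {
    v <- stats::rnorm(m); v / sqrt(sum(v^2))
  }, numeric(m)))
  list(X = sweep(radius * U, 2, xq, "+"), y = stats::rnorm(n), xq = xq)
}
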