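#' Partial least squares regression via the eigenvalue NIPALS algorithm
#'
#' Fits a PLS model with `K` latent variables by sequential deflation. At
#' each step the weight vector `w_k` is the leading eigenvector of the
#' rank-one matrix `X_k' y_k y_k' X_k`, which is available in closed form as
#' the normalised covariance vector `X_k' y_k / ||X_k' y_k||`; the latent
#' score is `t_k = X_k w_k`, the loading `p_k = X_k' t_k / (t_k' t_k)` and
#' the regression coefficient `b_k = y_k' t_k / (t_k' t_k)`, after which
#' both blocks are deflated (`X_{k+1} = X_k - t_k p_k'`,
#' `y_{k+1} = y_k - b_k t_k`).
#'
#' Inputs are mean-centered internally. No variance scaling is applied by
#' default because the intended inputs (R-R intervals) share a common unit;
#' set `autoscale = TRUE` to divide columns by their standard deviation.
#'
#' @param X numeric matrix, N samples by M variables.
#' @param y numeric response vector of length N.
#' @param K number of latent variables, `K <= min(N - 1, M)`.
#' @param autoscale divide columns of `X` (and `y`) by their SD after
#'   centering.
#' @param allow_early_stop if `TRUE`, a deflated block whose input-output
#'   covariance vanishes before `K` components stops fitting quietly and the
#'   model keeps the components found so far (useful on noiseless data whose
#'   relation is exhausted early); if `FALSE` (default) this is an error
#'   naming the achieved rank.
#' @return an object of class `pls_model` with elements `K`, `weights`
#'   (M x K), `loadings` (M x K), `coef` (length K), `x_center`, `y_center`,
#'   `x_scale`, `y_scale`.
#' @seealso [predict.pls_model()], [lwpls_estimate()]
#' @export
fit_pls <- function(X, y, K, autoscale = FALSE, allow_early_stop = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  N <- nrow(X); M <- ncol(X)
  stopifnot(N >= 1, M >= 1, length(y) == N)
  if (anyNA(X) || anyNA(y)) stop("X and y must not contain missing values")
  if (K < 1 || K > min(N - 1, M))
    stop(sprintf("K must satisfy 1 <= K <= min(N - 1, M) = %d", min(N - 1, M)))

  x_center <- colMeans(X)
  y_center <- mean(y)
  x_scale <- rep(1, M)
  y_scale <- 1
  Xc <- sweep(X, 2, x_center)
  yc <- y - y_center
  if (autoscale) {
    x_scale <- apply(Xc, 2, stats::sd)
    x_scale[x_scale == 0] <- 1
    y_scale <- stats::sd(yc)
    if (y_scale == 0) y_scale <- 1
    Xc <- sweep(Xc, 2, x_scale, "/")
    yc <- yc / y_scale
  }
  if (all(abs(Xc) < .Machine$double.eps * 1e2))
    stop("X has no non-constant column; nothing to fit")

  Wm <- matrix(0, M, K)
  Pm <- matrix(0, M, K)
  b <- numeric(K)
  scale_ref <- sqrt(sum(Xc^2)) * sqrt(sum(yc^2)) + .Machine$double.eps
  k_done <- 0L
  for (k in seq_len(K)) {
    v <- drop(crossprod(Xc, yc))               # X_k' y_k: top eigvec direction
    nv <- sqrt(sum(v^2))
    if (nv <= 1e-12 * scale_ref || all(abs(Xc) < 1e-12 * scale_ref)) {
      if (allow_early_stop) break
      stop(sprintf(
        "degenerate deflated block before reaching K = %d components (achieved rank %d)",
        K, k_done))
    }
    w <- v / nv                                 # sign: w'(X'y) = ||X'y|| >= 0
    t_k <- drop(Xc %*% w)
    tt <- sum(t_k^2)
    p <- drop(crossprod(Xc, t_k)) / tt
    bk <- sum(yc * t_k) / tt
    Wm[, k] <- w
    Pm[, k] <- p
    b[k] <- bk
    Xc <- Xc - tcrossprod(t_k, p)
    yc <- yc - bk * t_k
    k_done <- k
  }
  if (k_done == 0L) stop("no PLS component could be extracted")
  structure(
    list(K = k_done,
         weights = Wm[, seq_len(k_done), drop = FALSE],
         loadings = Pm[, seq_len(k_done), drop = FALSE],
         coef = b[seq_len(k_done)],
         x_center = x_center, y_center = y_center,
         x_scale = x_scale, y_scale = y_scale),
    class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' Applies the stored centering (and scaling, if any), then projects the
#' query through the component sequence: `t_qk = x_qk' w_k`, accumulating
#' `yhat = ybar + sum_k t_qk b_k`, with query deflation
#' `x_{q,k+1} = x_qk - t_qk p_k`.
#'
#' @param object a `pls_model`.
#' @param newdata numeric vector of length M, or an N x M matrix.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  Xq <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(Xq) != length(object$x_center))
    stop(sprintf("query has %d variables; model expects %d",
                 ncol(Xq), length(object$x_center)))
  Xq <- sweep(sweep(Xq, 2, object$x_center), 2, object$x_scale, "/")
  yhat <- rep(0, nrow(Xq))
  for (k in seq_len(object$K)) {
    t_q <- drop(Xq %*% object$weights[, k])
    yhat <- yhat + t_q * object$coef[k]
    Xq <- Xq - tcrossprod(t_q, object$loadings[, k])
  }
  drop(object$y_center + yhat * object$y_scale)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d latent variable(s), %d input variable(s)\n",
              x$K, length(x$x_center)))
  invisible(x)
}

#' Similarity weights between stored samples and a query
#'
#' Computes, for each stored sample `x_n`, the squared Euclidean distance
#' `d_n = (x_n - x_q)'(x_n - x_q)` to the query (no square root) and the
#' localisation weight `omega_n = exp(-d_n * phi / sigma_d)` where `sigma_d`
#' is the standard deviation of the distances. Small `phi` makes similarity
#' fall off steeply with distance; large `phi` makes it fall off gradually.
#'
#' When all distances are equal (`sigma_d = 0`, e.g. a constant training
#' buffer) the weights are set to 1 uniformly and flagged, which reduces the
#' locally weighted fit to an ordinary PLS fit.
#'
#' @param X numeric matrix of stored samples (N x M).
#' @param xq query vector of length M.
#' @param phi localisation parameter, `phi > 0` (dimensionless).
#' @param sd_type `"population"` (divide by N, default) or `"sample"`
#'   convention for `sigma_d`.
#' @return list with `omega` (weights in (0, 1]), `d` (squared distances),
#'   `sigma_d`, and `uniform` (`TRUE` when the `sigma_d = 0` path was taken).
#' @export
compute_similarity <- function(X, xq, phi,
                               sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  X <- as.matrix(X)
  xq <- as.numeric(xq)
  stopifnot(ncol(X) == length(xq), phi > 0)
  diffs <- sweep(X, 2, xq)
  d <- rowSums(diffs^2)
  sigma_d <- if (sd_type == "population") {
    sqrt(mean((d - mean(d))^2))
  } else {
    stats::sd(d)
  }
  # treat a spread at float-noise level relative to the distances as zero,
  # so e.g. exactly equidistant samples take the uniform-weight path
  if (!is.finite(sigma_d) || sigma_d <= max(d) * 1e-12) {
    return(list(omega = rep(1, nrow(X)), d = d, sigma_d = 0, uniform = TRUE))
  }
  list(omega = exp(-d * phi / sigma_d), d = d, sigma_d = sigma_d,
       uniform = FALSE)
}

#' Just-in-time locally weighted PLS estimate
#'
#' Builds a local PLS model around the query and returns its prediction,
#' then discards the model (the call is stateless). Samples are weighted by
#' [compute_similarity()]; the weighted means
#' `xbar_m = sum_n omega_n x_nm / sum_n omega_n` and
#' `ybar = sum_n omega_n y_n / sum_n omega_n` center the blocks, the
#' estimate starts at `ybar`, and each component adds `t_qk d_k` with
#' `w_k = X_k' O y_k / ||X_k' O y_k||` (the leading eigenvector of the
#' rank-one weighted covariance matrix), `t_k = X_k w_k`,
#' `t_qk = x_qk' w_k`, `p_k = X_k' O t_k / (t_k' O t_k)`,
#' `d_k = y_k' O t_k / (t_k' O t_k)`, followed by deflation of `X_k`, `y_k`
#' and the query. With uniform weights the estimate coincides with an
#' ordinary PLS prediction.
#'
#' @param X stored input samples (N x M).
#' @param y stored outputs (length N).
#' @param xq query vector (length M).
#' @param phi localisation parameter (> 0).
#' @param K number of latent variables, `K <= min(N - 1, M)`.
#' @param sd_type convention for the distance SD, see [compute_similarity()].
#' @return scalar estimate.
#' @export
lwpls_estimate <- function(X, y, xq, phi, K,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  xq <- as.numeric(xq)
  N <- nrow(X); M <- ncol(X)
  stopifnot(N >= 2, length(y) == N, length(xq) == M,
            K >= 1, K <= min(N - 1, M))

  sim <- compute_similarity(X, xq, phi, sd_type)
  # estimates are invariant to a constant rescaling of the weights, so use
  # the max-normalised form exp(-(d - min d) phi / sigma_d): identical
  # estimate, no underflow for strongly localised phi
  omega <- if (sim$uniform) sim$omega else
    exp(-(sim$d - min(sim$d)) * phi / sim$sigma_d)
  sw <- sum(omega)
  xbar <- drop(crossprod(X, omega)) / sw
  ybar <- sum(omega * y) / sw

  Xk <- sweep(X, 2, xbar)
  yk <- y - ybar
  xqk <- xq - xbar
  yhat <- ybar
  scale_ref <- sqrt(sum(Xk^2)) * sqrt(sum(yk^2)) + .Machine$double.eps
  for (k in seq_len(K)) {
    v <- drop(crossprod(Xk, omega * yk))
    nv <- sqrt(sum(v^2))
    if (nv <= 1e-12 * scale_ref) break     # relation exhausted; estimate final
    w <- v / nv
    t_k <- drop(Xk %*% w)
    t_q <- sum(xqk * w)
    tot <- sum(omega * t_k^2)
    if (tot <= 0) {
      warning("degenerate weighted design (t' Omega t = 0); ",
              "returning the estimate accumulated so far")
      break
    }
    p <- drop(crossprod(Xk, omega * t_k)) / tot
    d_k <- sum(omega * yk * t_k) / tot
    yhat <- yhat + t_q * d_k
    Xk <- Xk - tcrossprod(t_k, p)
    yk <- yk - t_k * d_k
    xqk <- xqk - t_q * p
  }
  yhat
}

#' Serialise a PLS model to JSON
#'
#' Round-trip exact: numbers are written at full precision.
#'
#' @param model a `pls_model`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
pls_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "pls_model"))
  cols <- function(m) lapply(seq_len(ncol(m)), function(k) m[, k])
  payload <- list(
    K = model$K,
    weights = cols(model$weights),
    loadings = cols(model$loadings),
    coef = model$coef,
    x_center = model$x_center,
    y_center = model$y_center,
    x_scale = model$x_scale,
    y_scale = model$y_scale)
  js <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore a PLS model from JSON
#'
#' @param json JSON string or path to a file written by [pls_to_json()].
#' @return a `pls_model`.
#' @export
pls_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  as_mat <- function(m) {
    # stored as a list of column vectors; jsonlite may simplify it to a
    # row-per-column matrix
    m <- if (is.list(m)) do.call(cbind, m) else t(as.matrix(m))
    storage.mode(m) <- "double"
    unname(m)
  }
  structure(
    list(K = as.integer(obj$K),
         weights = as_mat(obj$weights),
         loadings = as_mat(obj$loadings),
         coef = as.numeric(obj$coef),
         x_center = as.numeric(obj$x_center),
         y_center = as.numeric(obj$y_center),
         x_scale = as.numeric(obj$x_scale),
         y_scale = as.numeric(obj$y_scale)),
    class = "pls_model")
}
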