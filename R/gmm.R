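# Full-covariance Gaussian mixture fitted by EM with k-means++-style
# initialization and multiple restarts.  Dimensions here are small (three
# principal components), so a plain R implementation is adequate.

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- x[sample.int(n, 1), , drop = FALSE]
  for (i in seq_len(k - 1)) {
    d2 <- apply(x, 1, function(r) min(colSums((t(centers) - r)^2)))
    if (all(d2 == 0)) {
      centers <- rbind(centers, x[sample.int(n, 1), , drop = FALSE])
    } else {
      centers <- rbind(centers, x[sample.int(n, 1, prob = d2), , drop = FALSE])
    }
  }
  centers
}

log_mvnorm <- function(x, mu, sigma) {
  d <- ncol(x)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(sigma + diag(1e-6 * mean(diag(sigma)) + 1e-12, d))
  xc <- sweep(x, 2, mu)
  z <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

gmm_em_once <- function(x, k, max_iter, tol, reg) {
  n <- nrow(x); d <- ncol(x)
  centers <- kmeanspp_centers(x, k)
  km <- suppressWarnings(kmeans(x, centers = centers, iter.max = 50))
  mu <- km$centers
  w <- pmax(tabulate(km$cluster, k), 1) / n
  w <- w / sum(w)
  sig <- lapply(seq_len(k), function(j) {
    pts <- x[km$cluster == j, , drop = FALSE]
    s <- if (nrow(pts) > d) stats::cov(pts) else stats::cov(x)
    s + diag(reg, d)
  })
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lg <- vapply(seq_len(k),
                 function(j) log(w[j]) + log_mvnorm(x, mu[j, ], sig[[j]]),
                 numeric(n))
    m <- apply(lg, 1, max)
    lse <- m + log(rowSums(exp(lg - m)))
    resp <- exp(lg - lse)
    ll <- sum(lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
    nk <- colSums(resp)
    for (j in seq_len(k)) {
      if (nk[j] < 1e-8) {                    # re-seed an emptied component
        far <- which.min(lse)
        mu[j, ] <- x[far, ]
        sig[[j]] <- stats::cov(x) + diag(reg, d)
        w[j] <- 1 / n
        next
      }
      mu[j, ] <- colSums(resp[, j] * x) / nk[j]
      xc <- sweep(x, 2, mu[j, ])
      sig[[j]] <- crossprod(xc * sqrt(resp[, j])) / nk[j] + diag(reg, d)
      w[j] <- nk[j] / n
    }
    w <- w / sum(w)
  }
  cluster <- max.col(lg, ties.method = "first")
  list(loglik = ll_old, weights = w, means = mu, covariances = sig,
       responsibilities = resp, cluster = cluster)
}

#' Fit a full-covariance Gaussian mixture by EM
#'
#' @param x Numeric matrix (observations x dimensions).
#' @param k Number of components.
#' @param restarts Independent k-means++ initializations; the fit with the
#'   best log-likelihood is kept.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @param seed RNG seed controlling initialization (restored on exit).
#' @return List with `weights`, `means`, `covariances`, `cluster` (hard
#'   argmax-responsibility assignment, ties to the lowest index),
#'   `responsibilities`, `loglik`, `k`, `seed`.
#' @export
fit_gmm <- function(x, k, restarts = 10, max_iter = 300, tol = 1e-8,
                    seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < k)
    stop("model degeneracy: fewer observations (", nrow(x),
         ") than mixture components (", k, "); reduce n_clusters")
  reg <- 1e-6 * mean(apply(x, 2, var)) + 1e-12
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- gmm_em_once(x, k, max_iter, tol, reg)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  best$k <- k
  best$seed <- seed
  best
}

# evaluate-with-seed helper: runs code under a fixed RNG state and restores
# the caller's state afterwards, so library code never perturbs user RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
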