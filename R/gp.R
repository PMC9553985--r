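# Laplace-approximate Gaussian-process classification with a squared-
# exponential kernel; regularised kernel-logistic (IRLS) fallback.
#
# Standard Laplace scheme: Newton iterations on the latent posterior mode
# with the logistic likelihood, predictive latent mean/variance from the
# mode, and the probit-style squashing of the latent Gaussian into a
# predictive probability.

.sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

seKernel <- function(A, B, lengthscale, sigma2 = 1) {
  sigma2 * exp(-.sqdist(A, B) / (2 * lengthscale^2))
}

# deterministic median-distance heuristic on an evenly spaced subsample
medianLengthscale <- function(X, maxPoints = 200L) {
  n <- nrow(X)
  idx <- unique(round(seq(1L, n, length.out = min(n, maxPoints))))
  D2 <- .sqdist(X[idx, , drop = FALSE], X[idx, , drop = FALSE])
  d <- sqrt(D2[upper.tri(D2)])
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Newton iterations for the latent posterior mode; y in {-1, 1}
gpLaplaceFit <- function(K, y, maxIter = 50L, tol = 1e-8) {
  n <- length(y)
  t01 <- (y + 1) / 2
  f <- numeric(n)
  objOld <- -Inf
  for (iter in seq_len(maxIter)) {
    pi <- .sigmoid(f)
    W <- pi * (1 - pi)
    sw <- sqrt(W)
    B <- diag(n) + (sw %o% sw) * K
    L <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(L)) return(NULL)
    b <- W * f + (t01 - pi)
    v <- backsolve(L, forwardsolve(t(L), sw * (K %*% b)))
    a <- b - sw * v
    f <- drop(K %*% a)
    obj <- -0.5 * sum(a * f) + sum(stats::plogis(y * f, log.p = TRUE))
    if (!is.finite(obj)) return(NULL)
    if (abs(obj - objOld) < tol * (1 + abs(obj))) break
    objOld <- obj
  }
  pi <- .sigmoid(f)
  sw <- sqrt(pi * (1 - pi))
  B <- diag(n) + (sw %o% sw) * K
  L <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  list(f = f, grad = t01 - pi, sw = sw, L = L, converged = TRUE)
}

# kernel-logistic fallback: IRLS on alpha with ridge penalty lambda/2 a'Ka
klogisticFit <- function(K, y, lambda = 1e-2, maxIter = 100L, tol = 1e-8) {
  n <- length(y)
  t01 <- (y + 1) / 2
  alpha <- numeric(n)
  f <- numeric(n)
  for (iter in seq_len(maxIter)) {
    pi <- .sigmoid(f)
    W <- pmax(pi * (1 - pi), 1e-10)
    z <- f + (t01 - pi) / W
    M <- K + diag(lambda / W)
    alphaNew <- tryCatch(solve(M, z), error = function(e) NULL)
    if (is.null(alphaNew)) break
    fNew <- drop(K %*% alphaNew)
    if (max(abs(fNew - f)) < tol * (1 + max(abs(f)))) { alpha <- alphaNew; f <- fNew; break }
    alpha <- alphaNew; f <- fNew
  }
  list(alpha = alpha, f = f)
}

# predictive probabilities for either fit
gpPredict <- function(fit, Ktrain, Kstar, kss, method) {
  if (method == "gp_laplace") {
    fmean <- drop(Kstar %*% fit$grad)
    V <- forwardsolve(t(fit$L), t(Kstar) * fit$sw)
    fvar <- pmax(kss - colSums(V^2), 1e-12)
    .sigmoid(fmean / sqrt(1 + pi * fvar / 8))
  } else {
    .sigmoid(drop(Kstar %*% fit$alpha))
  }
}
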