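#' Gaussian process regression engine
#'
#' Shared GPR machinery used both for multiband LAI retrieval (D input bands)
#' and for 1-D time-series gap-filling (D = 1, input = acquisition day).
#' The covariance is the anisotropic (ARD) squared-exponential kernel
#' \deqn{k(x_i, x_j) = \sigma_s^2 \exp(-\tfrac12 \sum_b ((x_{ib}-x_{jb})/\sigma_b)^2)}
#' with output variance \eqn{\sigma_s^2}, per-dimension lengthscales
#' \eqn{\sigma_b} and observation noise variance \eqn{\sigma_n^2}. The inverse
#' lengthscale of a band measures that band's relevance to the prediction.
#'
#' @name gpr-engine
NULL

#' GPR hyperparameters
#'
#' @param sigma_s2 output (signal) variance, > 0
#' @param lengthscales per-input-dimension lengthscale vector, all > 0
#' @param sigma_n2 noise variance, >= 0
#' @return list of class \code{GPRHyperparams}
#' @export
gprHyperparams <- function(sigma_s2, lengthscales, sigma_n2) {
  stopifnot(is.numeric(sigma_s2), length(sigma_s2) == 1, sigma_s2 > 0,
            all(lengthscales > 0), sigma_n2 >= 0)
  structure(list(sigma_s2 = as.numeric(sigma_s2),
                 lengthscales = as.numeric(lengthscales),
                 sigma_n2 = as.numeric(sigma_n2)),
            class = "GPRHyperparams")
}

#' Squared-exponential (ARD) kernel matrix
#'
#' @param Xa M x D matrix (a vector is treated as a one-column matrix)
#' @param Xb P x D matrix
#' @param theta a \code{\link{gprHyperparams}} object with D lengthscales
#' @return M x P covariance matrix
#' @examples
#' th <- gprHyperparams(1, 1, 0)
#' seKernel(0, 1, th)   # exp(-0.5)
#' @export
seKernel <- function(Xa, Xb, theta) {
  Xa <- as.matrix(Xa); Xb <- as.matrix(Xb)
  D <- length(theta$lengthscales)
  if (ncol(Xa) != D || ncol(Xb) != D)
    stop("input dimension mismatch: kernel has ", D, " lengthscale(s), inputs have ",
         ncol(Xa), " and ", ncol(Xb), " columns")
  As <- sweep(Xa, 2, theta$lengthscales, "/")
  Bs <- sweep(Xb, 2, theta$lengthscales, "/")
  d2 <- outer(rowSums(As^2), rowSums(Bs^2), "+") - 2 * tcrossprod(As, Bs)
  d2[d2 < 0] <- 0   # guard tiny negatives from cancellation
  theta$sigma_s2 * exp(-0.5 * d2)
}

# Cholesky of K + sigma_n2 I with escalating jitter (1e-8..1e-4 of sigma_s2).
.gprChol <- function(K, theta) {
  n <- nrow(K)
  Ky <- K + diag(theta$sigma_n2, n)
  jit <- 0
  for (j in c(0, 10^(-8:-4))) {
    L <- tryCatch(chol(Ky + diag(j * theta$sigma_s2, n)), error = function(e) NULL)
    if (!is.null(L)) { jit <- j; break }
  }
  if (is.null(L))
    stop("kernel system singular even after jitter up to 1e-4 * sigma_s2 ",
         "(n = ", n, ", sigma_n2 = ", format(theta$sigma_n2), ")")
  list(L = L, jitter = jit * theta$sigma_s2)
}

#' Build a GPR model with fixed hyperparameters
#'
#' Centers y on its training mean (the zero-mean GP assumption; the center is
#' added back at prediction) and caches the Cholesky factor of
#' \eqn{K + \sigma_n^2 I}.
#'
#' @param X N x D training inputs
#' @param y length-N training outputs
#' @param theta a \code{\link{gprHyperparams}}
#' @return list of class \code{GPRModel}
#' @export
gprModel <- function(X, y, theta) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("need at least one training sample")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  center <- mean(y)
  yc <- y - center
  K <- seKernel(X, X, theta)
  f <- .gprChol(K, theta)
  alpha <- backsolve(f$L, forwardsolve(t(f$L), yc))
  structure(list(X = X, y = yc, center = center, theta = theta,
                 L = f$L, alpha = alpha, jitter = f$jitter),
            class = "GPRModel")
}

#' @export
print.GPRModel <- function(x, ...) {
  cat(sprintf("GPRModel: N = %d, D = %d\n", nrow(x$X), ncol(x$X)))
  cat(sprintf("  sigma_s2 = %.4g, sigma_n2 = %.4g\n",
              x$theta$sigma_s2, x$theta$sigma_n2))
  cat("  lengthscales:", paste(signif(x$theta$lengthscales, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Predictive distribution of a GPR model
#'
#' Mean \eqn{k_*^T (K+\sigma_n^2 I)^{-1} y} (plus the retained center) and
#' variance \eqn{c_* - k_*^T (K+\sigma_n^2 I)^{-1} k_*} with
#' \eqn{c_* = k(x_*,x_*) + \sigma_n^2}, evaluated row-wise over \code{Xstar}.
#'
#' @param model a \code{\link{gprModel}}
#' @param Xstar Q x D query inputs
#' @return list with numeric vectors \code{mean} and \code{variance}
#' @export
gprPredict <- function(model, Xstar) {
  Xstar <- as.matrix(Xstar)
  Ks <- seKernel(model$X, Xstar, model$theta)     # N x Q
  mu <- drop(crossprod(Ks, model$alpha)) + model$center
  v <- forwardsolve(t(model$L), Ks)               # N x Q
  cstar <- model$theta$sigma_s2 + model$theta$sigma_n2
  var <- cstar - colSums(v^2)
  var <- pmax(var, 1e-12 * model$theta$sigma_s2)
  list(mean = mu, variance = var)
}

#' Log marginal likelihood of a GPR model
#'
#' \eqn{-\tfrac12 y^T (K+\sigma_n^2 I)^{-1} y - \tfrac12 \log|K+\sigma_n^2 I|
#' - \tfrac{N}{2}\log 2\pi} on the centered outputs. Its maximization over the
#' hyperparameters is what "training the GPR" means here.
#'
#' @param model a \code{\link{gprModel}}
#' @param parts if TRUE also return the data-fit, complexity and constant terms
#' @return scalar, or a list when \code{parts = TRUE}
#' @export
gprLogMarginalLikelihood <- function(model, parts = FALSE) {
  n <- length(model$y)
  fit <- -0.5 * sum(model$y * model$alpha)
  complexity <- -sum(log(diag(model$L)))
  const <- -n / 2 * log(2 * pi)
  val <- fit + complexity + const
  if (!is.finite(val)) stop("non-finite log marginal likelihood")
  if (parts) list(value = val, fit = fit, complexity = complexity, const = const)
  else val
}

# Log marginal likelihood and its gradient in log-hyperparameter space.
# p = c(log sigma_s2, log lengthscales, log sigma_n2).
.gprObjective <- function(p, X, yc) {
  D <- ncol(X)
  theta <- gprHyperparams(exp(p[1]), exp(p[2:(D + 1)]), exp(p[D + 2]))
  n <- nrow(X)
  K <- seKernel(X, X, theta)
  f <- tryCatch(.gprChol(K, theta), error = function(e) NULL)
  if (is.null(f)) return(list(value = -Inf, gradient = rep(0, length(p))))
  L <- f$L
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  val <- -0.5 * sum(yc * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  Kinv <- chol2inv(L)
  W <- tcrossprod(alpha) - Kinv           # d lml / dK = W / 2
  g <- numeric(length(p))
  g[1] <- 0.5 * sum(W * K)                # dK/dlog sigma_s2 = K
  for (b in seq_len(D)) {
    Db <- outer(X[, b], X[, b], "-")^2 / theta$lengthscales[b]^2
    g[1 + b] <- 0.5 * sum(W * (K * Db))   # dK/dlog sigma_b = K * d2_b
  }
  g[D + 2] <- 0.5 * theta$sigma_n2 * sum(diag(W))
  list(value = val, gradient = g)
}

#' Gradient of the log marginal likelihood
#'
#' Analytic gradient with respect to the log-hyperparameters
#' (log sigma_s2, log lengthscales, log sigma_n2); exposed so it can be
#' validated against finite differences.
#'
#' @param model a \code{\link{gprModel}}
#' @return numeric gradient vector of length D + 2
#' @export
gprGradient <- function(model) {
  p <- log(c(model$theta$sigma_s2, model$theta$lengthscales, model$theta$sigma_n2))
  .gprObjective(p, model$X, model$y)$gradient
}

#' Fit a GPR model by marginal-likelihood maximization
#'
#' Optimizes the hyperparameters in log space with L-BFGS-B and analytic
#' gradients, from a data-driven initialization (lengthscales = per-dimension
#' input SD, sigma_s2 = var(y), sigma_n2 = 0.1 var(y)) plus \code{nRestarts}
#' log-uniform perturbations. Lengthscales are bounded to [1e-3, 1e3] times
#' their initial value. Deterministic under \code{seed}.
#'
#' @param X N x D training inputs (N >= 2)
#' @param y length-N outputs
#' @param init optional \code{\link{gprHyperparams}} starting point
#' @param nRestarts extra randomized restarts (default 3)
#' @param seed integer seed for the restart perturbations
#' @return the best \code{GPRModel} over all restarts
#' @export
fitGPR <- function(X, y, init = NULL, nRestarts = 3, seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples to optimize hyperparameters")
  D <- ncol(X)
  if (is.null(init)) {
    ls0 <- apply(X, 2, stats::sd)
    ls0[!is.finite(ls0) | ls0 <= 0] <- 1
    vy <- stats::var(y)
    if (!is.finite(vy) || vy <= 0) vy <- 1
    init <- gprHyperparams(vy, ls0, 0.1 * vy)
  }
  p0 <- log(c(init$sigma_s2, init$lengthscales, max(init$sigma_n2, 1e-8)))
  lower <- c(p0[1] - log(1e4), p0[2:(D + 1)] - log(1e3), log(1e-10))
  upper <- c(p0[1] + log(1e4), p0[2:(D + 1)] + log(1e3), p0[1] + log(10))
  starts <- list(p0)
  if (nRestarts > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    for (r in seq_len(nRestarts))
      starts[[r + 1]] <- pmin(pmax(p0 + stats::runif(D + 2, -1, 1) * log(10), lower), upper)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
      rm(".Random.seed", envir = .GlobalEnv)
  }
  best <- NULL; bestVal <- -Inf; failures <- character(0)
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, fn = function(p) -.gprObjective(p, X, y - mean(y))$value,
                   gr = function(p) -.gprObjective(p, X, y - mean(y))$gradient,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) e)
    if (inherits(res, "error")) { failures <- c(failures, conditionMessage(res)); next }
    if (-res$value > bestVal) { bestVal <- -res$value; best <- res$par }
  }
  if (is.null(best))
    stop("all optimizer restarts failed: ", paste(unique(failures), collapse = "; "))
  theta <- gprHyperparams(exp(best[1]), exp(best[2:(D + 1)]), exp(best[D + 2]))
  gprModel(X, y, theta)
}

#' Save / load a GPR model as JSON
#'
#' The hyperparameters, training set, center and optional metadata are written
#' as a portable JSON document.
#'
#' @param model a \code{GPRModel}
#' @param path file path
#' @param metadata optional named list (e.g. band dialect)
#' @return \code{writeGPRModel} returns \code{path} invisibly;
#'   \code{readGPRModel} returns the restored \code{GPRModel}.
#' @export
writeGPRModel <- function(model, path, metadata = list()) {
  doc <- list(
    sigma_s2 = model$theta$sigma_s2,
    lengthscales = model$theta$lengthscales,
    sigma_n2 = model$theta$sigma_n2,
    center = model$center,
    X = model$X,
    y_centered = model$y,
    metadata = metadata)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGPRModel
#' @export
readGPRModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- gprHyperparams(doc$sigma_s2, doc$lengthscales, doc$sigma_n2)
  m <- gprModel(as.matrix(doc$X), doc$y_centered + doc$center, theta)
  attr(m, "metadata") <- doc$metadata
  m
}
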