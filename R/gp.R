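## Gaussian-process regression with an isotropic RBF kernel, written in
## closed form (Cholesky). Inputs are expected in the unit box and the
## response standardized by the caller. The kernel is
##   k(x, x') = exp(-||x - x'||^2 / (2 l^2)) + nugget * 1{x == x'}
## with unit signal variance. The lengthscale starts from the median
## heuristic and (lengthscale, nugget) are picked by maximizing the log
## marginal likelihood over a small deterministic grid.

rbf_kernel <- function(X1, X2, ell) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * ell^2))
}

gp_logml <- function(K, y) {
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  -0.5 * sum(y * alpha) - sum(log(diag(ch))) - length(y) / 2 * log(2 * pi)
}

gp_fit <- function(X, y, ell_grid = c(0.5, 1, 2, 4),
                   nugget_grid = c(1e-6, 1e-4, 1e-2, 1e-1)) {
  X <- rbind(X)
  n <- nrow(X)
  if (n > 1) {
    d2 <- as.vector(stats::dist(X))^2
    ell0 <- sqrt(stats::median(d2[d2 > 0]) / 2)
    if (!is.finite(ell0) || ell0 <= 0) ell0 <- 1
  } else ell0 <- 1
  best <- list(ml = -Inf)
  for (em in ell_grid) for (ng in nugget_grid) {
    ell <- ell0 * em
    K <- rbf_kernel(X, X, ell) + diag(ng, n)
    ml <- gp_logml(K, y)
    if (ml > best$ml) best <- list(ml = ml, ell = ell, nugget = ng)
  }
  K <- rbf_kernel(X, X, best$ell) + diag(best$nugget, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  structure(list(X = X, y = y, ell = best$ell, nugget = best$nugget,
                 chol = ch, alpha = alpha, logml = best$ml),
            class = "gp_model")
}

#' @export
predict.gp_model <- function(object, newdata, ...) {
  Xq <- rbind(newdata)
  Ks <- rbf_kernel(Xq, object$X, object$ell)
  mu <- as.vector(Ks %*% object$alpha)
  v <- forwardsolve(t(object$chol), t(Ks))
  var <- pmax(0, 1 + object$nugget - colSums(v^2))
  list(mean = mu, var = var)
}
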