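#' Differential evolution over the unit box
#'
#' Plain rand/1/bin differential evolution maximizing a vectorised objective
#' over `[0, 1]^d`. The objective receives a population matrix (rows are
#' candidates) and returns one value per row, so surrogate predictions are
#' batched per generation.
#'
#' @param fn Objective: `function(U)` with `U` an n x d matrix, returning a
#'   numeric vector (maximized).
#' @param d Dimension.
#' @param pop Population size (default `15 * d`, minimum 8).
#' @param maxiter Maximum generations.
#' @param F Differential weight.
#' @param CR Crossover probability.
#' @param tol Convergence tolerance: stop when the population fitness spread
#'   `max - min` falls below `tol * (abs(best) + tol)`.
#' @param seed RNG seed.
#' @return List: `par` (best point), `value`, `iter`, `converged`.
#' @export
differential_evolution <- function(fn, d, pop = NULL, maxiter = 500,
                                   F = 0.8, CR = 0.9, tol = 1e-6,
                                   seed = NULL) {
  if (is.null(pop)) pop <- max(8L, 15L * d)
  pop <- max(8L, as.integer(pop))
  with_seed(seed, {
    U <- matrix(stats::runif(pop * d), pop, d)
    fit <- fn(U)
    converged <- FALSE
    iter <- 0L
    for (g in seq_len(maxiter)) {
      iter <- g
      r1 <- sample(pop); r2 <- sample(pop); r3 <- sample(pop)
      V <- U[r1, , drop = FALSE] +
        F * (U[r2, , drop = FALSE] - U[r3, , drop = FALSE])
      V[V < 0] <- 0; V[V > 1] <- 1
      mask <- matrix(stats::runif(pop * d) < CR, pop, d)
      ## guarantee at least one mutated coordinate per candidate
      forced <- cbind(seq_len(pop), sample.int(d, pop, replace = TRUE))
      mask[forced] <- TRUE
      Trial <- U
      Trial[mask] <- V[mask]
      fit_t <- fn(Trial)
      better <- fit_t >= fit
      U[better, ] <- Trial[better, , drop = FALSE]
      fit[better] <- fit_t[better]
      spread <- max(fit) - min(fit)
      if (is.finite(spread) && spread < tol * (abs(max(fit)) + tol)) {
        converged <- TRUE
        break
      }
    }
    best <- which.max(fit)
    list(par = U[best, ], value = fit[best], iter = iter,
         converged = converged)
  })
}
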