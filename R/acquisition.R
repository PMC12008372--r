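#' Exploration/exploitation acquisition
#'
#' The scalar objective maximized to pick the next media designs,
#' `G(x) = (1 - alpha) E(y) + alpha Var(y)`: at `alpha = 1` it reduces to the
#' predictive variance (pure exploration), at `alpha = 0` to the predictive
#' mean (pure exploitation).
#'
#' @param E Predictive mean (vectorized).
#' @param Var Predictive variance (non-negative, same length).
#' @param alpha Trade-off in `[0, 1]`.
#' @return `G` values.
#' @export
acquisition_G <- function(E, Var, alpha) {
  if (length(alpha) != 1 || !is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
  if (any(Var < 0)) stop("Var must be non-negative")
  (1 - alpha) * E + alpha * Var
}

#' Exploration/exploitation schedule over DBTL cycles
#'
#' The default schedule starts at pure exploration (`alpha = 1`, cycle 1
#' maximizes Var(y)) and ends at pure exploitation (`alpha = 0`, final cycle
#' maximizes E(y)), linear in between:
#' `alpha = (total - N) / (total - 1)`. The literal increasing variant
#' `alpha = 0.1 N` (clipped to 1) is selectable.
#'
#' @param cycle Cycle number N, `1 <= N <= total_cycles`.
#' @param total_cycles Planned number of cycles.
#' @param variant `"endpoint"` (default, decreasing) or `"literal"`
#'   (`0.1 * N`).
#' @return `alpha` in `[0, 1]`.
#' @export
alpha_schedule <- function(cycle, total_cycles,
                           variant = c("endpoint", "literal")) {
  variant <- match.arg(variant)
  if (total_cycles < 2) return(0)
  if (cycle < 1 || cycle > total_cycles) {
    stop("cycle must be within 1..total_cycles")
  }
  if (variant == "literal") return(min(1, 0.1 * cycle))
  (total_cycles - cycle) / (total_cycles - 1)
}

## Acquisition over the unit box for a model predicting (mean, var) in
## concentration units; `exclude` is a matrix of unit-scaled points whose
## eps-balls are penalized to enforce batch diversity.
acq_objective <- function(model, space = NULL, alpha, lower = NULL,
                          upper = NULL, exclude = NULL, eps = 0) {
  function(U) {
    X <- if (!is.null(space)) unit_unscale(space, U)
         else sweep(sweep(U, 2, upper - lower, "*"), 2, lower, "+")
    p <- predict(model, X)
    g <- acquisition_G(p$mean, p$var, alpha)
    if (!is.null(exclude) && nrow(exclude) > 0 && eps > 0) {
      scale_pen <- max(abs(g), 1)
      for (i in seq_len(nrow(exclude))) {
        dist <- sqrt(rowSums(sweep(U, 2, exclude[i, ])^2))
        close <- dist < eps
        if (any(close)) {
          g[close] <- g[close] - 1e3 * scale_pen * (eps - dist[close]) / eps -
            1e3 * scale_pen
        }
      }
    }
    g
  }
}

#' Maximize the acquisition with differential evolution
#'
#' Global maximization of `G(x)` over the phase-space box: differential
#' evolution (rand/1/bin) runs in the unit-scaled space and the best point is
#' mapped back to concentration units.
#'
#' @param model A fitted surrogate with a `predict` method returning
#'   `mean`/`var` (e.g. [fit_ensemble()]).
#' @param space A [phase_space()] (or give `lower`/`upper` box bounds).
#' @param alpha Trade-off passed to [acquisition_G()].
#' @param seed RNG seed.
#' @param lower,upper Box bounds when no `space` is given.
#' @param de_params List overriding DE settings `pop` (default `15 * d`),
#'   `maxiter` (500), `tol` (1e-6), `F` (0.8), `CR` (0.9).
#' @param exclude Matrix of unit-scaled points to keep away from.
#' @param eps Exclusion radius in unit space.
#' @return List: `x` (concentration units), `u` (unit scale), `value` (G at
#'   the maximizer), `converged`.
#' @export
optimize_acquisition <- function(model, space = NULL, alpha = 0, seed = NULL,
                                 lower = NULL, upper = NULL,
                                 de_params = list(), exclude = NULL,
                                 eps = 0) {
  d <- if (!is.null(space)) space$d else length(lower)
  dp <- utils::modifyList(list(pop = 15L * d, maxiter = 500L, tol = 1e-6,
                               F = 0.8, CR = 0.9), de_params)
  obj <- acq_objective(model, space, alpha, lower, upper, exclude, eps)
  res <- differential_evolution(obj, d, pop = dp$pop, maxiter = dp$maxiter,
                                F = dp$F, CR = dp$CR, tol = dp$tol,
                                seed = seed)
  x <- if (!is.null(space)) unit_unscale(space, rbind(res$par))[1, ]
       else lower + res$par * (upper - lower)
  list(x = x, u = res$par, value = res$value, converged = res$converged)
}

#' Recommend the next batch of media designs
#'
#' Sequentially maximizes the acquisition K times: the first
#' `round(K * explore_fraction)` designs run in pure-explore mode
#' (`alpha = 1`, maximizing Var(y)), the remainder at the configured
#' `alpha`. Each accepted design excludes an `eps`-ball around itself (in
#' unit-scaled space) from subsequent runs, so the batch is diverse. Fixed
#' components are set to base concentration.
#'
#' @param model Fitted surrogate ([fit_ensemble()]).
#' @param space A [phase_space()].
#' @param K Batch size.
#' @param alpha Trade-off for the exploitative designs.
#' @param explore_fraction Fraction of the batch run in pure-explore mode.
#' @param eps Minimum pairwise distance in unit-scaled space.
#' @param seed RNG seed.
#' @param de_params DE overrides (see [optimize_acquisition()]).
#' @param cycle Cycle label for the returned batch.
#' @param id_prefix Prefix for design identifiers.
#' @return A [design_batch()] with per-design `label`
#'   (`"explorative"`/`"exploitative"`) and attribute `acquisition_values`;
#'   attribute `short` is TRUE if fewer than K separated designs were placed.
#' @export
recommend_batch <- function(model, space, K, alpha = 0,
                            explore_fraction = 0, eps = 0.05, seed = 1L,
                            de_params = list(), cycle = NA_integer_,
                            id_prefix = "rec") {
  stopifnot(K >= 0, explore_fraction >= 0, explore_fraction <= 1, eps >= 0)
  if (K == 0) {
    return(design_batch(space, matrix(numeric(0), 0, nrow(space$components)),
                        design_id = character(0), cycle = cycle, seed = seed))
  }
  n_explore <- round(K * explore_fraction)
  accepted_u <- matrix(numeric(0), 0, space$d)
  rows <- list()
  labels <- character(0)
  values <- numeric(0)
  short <- FALSE
  for (i in seq_len(K)) {
    a_i <- if (i <= n_explore) 1 else alpha
    placed <- FALSE
    for (try in 1:3) {
      res <- optimize_acquisition(model, space, alpha = a_i,
                                  seed = seed + 1000L * i + try,
                                  de_params = de_params,
                                  exclude = accepted_u, eps = eps)
      if (nrow(accepted_u) == 0 ||
          min(sqrt(rowSums(sweep(accepted_u, 2, res$u)^2))) >= eps) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      short <- TRUE
      warning("could only place ", length(rows), " of ", K,
              " eps-separated designs")
      break
    }
    accepted_u <- rbind(accepted_u, res$u)
    rows[[length(rows) + 1L]] <- res$x
    labels <- c(labels, if (i <= n_explore) "explorative" else "exploitative")
    values <- c(values, res$value)
  }
  tab <- space$components
  conc <- matrix(rep(tab$base, each = length(rows)), length(rows), nrow(tab))
  for (i in seq_along(rows)) conc[i, space$variable] <- rows[[i]]
  out <- design_batch(space, conc,
                      design_id = paste0(id_prefix, "_c", cycle, "_",
                                         seq_along(rows)),
                      label = labels, cycle = cycle, seed = seed)
  attr(out, "acquisition_values") <- values
  attr(out, "short") <- short
  out
}
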