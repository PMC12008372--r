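## Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Latin hypercube initial designs
#'
#' Space-filling initial designs for the first DBTL cycles: for each variable
#' component the n sampled values occupy n distinct equal-probability strata
#' of the bound interval (in log or linear scale), one value per stratum,
#' uniformly placed within it. Fixed components stay at base concentration.
#'
#' @param space A [phase_space()].
#' @param n Number of designs.
#' @param seed RNG seed (same seed, same batch).
#' @param scale `"log"` (default, bounds span orders of magnitude) or
#'   `"linear"`; components with a zero lower bound fall back to linear strata
#'   regardless.
#' @param cycle Cycle label stored on the batch.
#' @return A [design_batch()].
#' @export
lhs_design <- function(space, n, seed = 1L, scale = c("log", "linear"),
                       cycle = NA_integer_) {
  stopifnot(n >= 1)
  scale <- match.arg(scale)
  d <- space$d
  u <- with_seed(seed, lhs::randomLHS(n, d))
  sc <- space_scales(space)
  if (scale == "linear") sc[] <- "linear"
  tab <- space$components
  v <- space$variable
  conc <- matrix(rep(tab$base, each = n), n, nrow(tab))
  for (j in seq_along(v)) {
    lo <- tab$lower[v[j]]; hi <- tab$upper[v[j]]
    conc[, v[j]] <- if (sc[j] == "log") {
      exp(log(lo) + u[, j] * (log(hi) - log(lo)))
    } else {
      lo + u[, j] * (hi - lo)
    }
  }
  design_batch(space, conc, cycle = cycle, seed = seed)
}

#' Split a design batch into consecutive DBTL cycles
#'
#' Order-preserving partition of an initial batch (e.g. 30 LHS designs into
#' two cycles of 15).
#' @param batch A [design_batch()].
#' @param sizes Integer vector of cycle sizes; must sum to the batch size.
#' @param first_cycle Label of the first cycle.
#' @return List of `design_batch` objects with cycle labels assigned.
#' @export
split_cycles <- function(batch, sizes, first_cycle = 1L) {
  n <- nrow(batch$conc)
  if (sum(sizes) != n) stop("sizes sum to ", sum(sizes), ", batch has ", n)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_along(sizes), function(i) {
    idx <- starts[i]:ends[i]
    design_batch(batch$space, batch$conc[idx, , drop = FALSE],
                 design_id = batch$design_id[idx],
                 role = batch$role[idx], label = batch$label[idx],
                 cycle = first_cycle + i - 1L, seed = batch$seed)
  })
}

#' Jittered control designs
#'
#' Each DBTL cycle carries replicates of the base medium with up to +/-10%
#' uniformly distributed multiplicative noise on every variable component, to
#' probe repeatability between cycles and model robustness. Fixed components
#' are untouched; jittered values are clipped at solubility only (controls
#' represent the base medium, not the search box).
#'
#' @param space A [phase_space()].
#' @param seed RNG seed.
#' @param n_replicates Number of control wells.
#' @param magnitude Jitter half-width as a fraction of base (default 0.10).
#' @param cycle Cycle label.
#' @return A [design_batch()] of `n_replicates` control designs.
#' @export
jitter_control <- function(space, seed = 1L, n_replicates = 3,
                           magnitude = 0.10, cycle = NA_integer_) {
  stopifnot(magnitude >= 0, magnitude < 1)
  tab <- space$components
  v <- space$variable
  conc <- with_seed(seed, {
    m <- matrix(rep(tab$base, each = n_replicates), n_replicates, nrow(tab))
    for (j in v) {
      u <- stats::runif(n_replicates, -magnitude, magnitude)
      m[, j] <- pmin(tab$base[j] * (1 + u), tab$solubility[j])
    }
    m
  })
  design_batch(space, conc,
               design_id = paste0("control_c", cycle, "_r",
                                  seq_len(n_replicates)),
               role = "control", cycle = cycle, seed = seed)
}
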