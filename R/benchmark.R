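## Coerce a vector or matrix of evaluation points to an unnamed matrix.
as_points <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  dimnames(X) <- NULL
  X
}

#' Synthetic benchmark functions
#'
#' Three black-box objectives of increasing learning difficulty used to
#' compare recommendation algorithms on simulated active-learning campaigns:
#' \describe{
#'   \item{easy}{`(1/d) sum_i (x_i - 5)^2 + exp(-sum_i x_i^2) + 25` — a
#'     quadratic bowl plus a sharp exponential bump at the origin.}
#'   \item{medium}{`(1/d) sum_i (x_i^4 - 16 x_i^2 + 5 x_i)` — a separable
#'     quartic, negative over most of the interior of the box.}
#'   \item{difficult}{`sum_i sqrt(x_i) sin(x_i)` — oscillatory; requires
#'     `x >= 0`.}
#' }
#' All are maximized over `[0, 10]^d` (default `d = 15`).
#'
#' @param X A vector (one point) or matrix (rows are points).
#' @return Objective value(s).
#' @export
f_easy <- function(X) {
  X <- as_points(X)
  rowMeans((X - 5)^2) + exp(-rowSums(X^2)) + 25
}

#' @rdname f_easy
#' @export
f_medium <- function(X) {
  X <- as_points(X)
  rowMeans(X^4 - 16 * X^2 + 5 * X)
}

#' @rdname f_easy
#' @export
f_diff <- function(X) {
  X <- as_points(X)
  if (any(X < 0)) stop("f_diff requires non-negative coordinates")
  rowSums(sqrt(X) * sin(X))
}

#' Construct a benchmark function object
#'
#' Default domains: `[-4, 4]` for the easy and medium functions and
#' `[0, 10]` for the difficult one (which requires non-negative
#' coordinates). On the symmetric box the least-squares quadratic
#' approximation of the quartic has curvature `6 L^2 / 7 - 16`, negative for
#' `L = 4`, so a second-order response surface is genuinely deceived on the
#' medium function — the interior it is drawn to is negative-valued — while
#' the easy function's optimum sits on a corner a quadratic fit identifies
#' exactly.
#'
#' @param name `"easy"`, `"medium"` or `"difficult"`.
#' @param d Dimension (default 15).
#' @param lower,upper Per-coordinate domain overriding the per-function
#'   defaults.
#' @return List of class `benchmark_function`: `name, fn, d, lower, upper,
#'   separable`.
#' @export
benchmark_function <- function(name = c("easy", "medium", "difficult"),
                               d = 15L, lower = NULL, upper = NULL) {
  name <- match.arg(name)
  fn <- switch(name, easy = f_easy, medium = f_medium, difficult = f_diff)
  if (is.null(lower)) lower <- if (name == "difficult") 0 else -4
  if (is.null(upper)) upper <- if (name == "difficult") 10 else 4
  structure(list(name = name, fn = fn, d = as.integer(d),
                 lower = rep(lower, d), upper = rep(upper, d),
                 separable = name != "easy"),
            class = "benchmark_function")
}

#' True optimum of a benchmark function
#'
#' Separable functions are maximized by per-dimension 1-D grid search plus
#' local refinement, composed across dimensions. The easy function (made
#' non-separable by its exponential term) is handled by evaluating the
#' separable-part optimum candidates plus the origin and refining locally.
#'
#' @param bf A [benchmark_function()].
#' @param n_grid Grid points per dimension.
#' @return List: `x_star`, `f_star`.
#' @export
true_optimum <- function(bf, n_grid = 1e6) {
  lo <- bf$lower[1]; hi <- bf$upper[1]; d <- bf$d
  grid <- seq(lo, hi, length.out = n_grid)
  per_dim <- switch(bf$name,
    medium = function(x) x^4 - 16 * x^2 + 5 * x,
    difficult = function(x) sqrt(x) * sin(x),
    easy = function(x) (x - 5)^2)
  vals <- per_dim(grid)
  x0 <- grid[which.max(vals)]
  ## local refinement around the best grid point
  lo_b <- max(lo, x0 - (hi - lo) / n_grid)
  hi_b <- min(hi, x0 + (hi - lo) / n_grid)
  ref <- stats::optimize(per_dim, lower = lo_b, upper = hi_b, maximum = TRUE,
                         tol = 1e-12)
  x1 <- ref$maximum
  if (per_dim(x0) > per_dim(x1)) x1 <- x0
  if (bf$separable) {
    x_star <- rep(x1, d)
    return(list(x_star = x_star, f_star = bf$fn(x_star)[1]))
  }
  ## easy: candidates are the separable-part optimum corner(s) and the origin
  cands <- rbind(rep(x1, d), rep(lo, d), rep(hi, d))
  fv <- bf$fn(cands)
  best <- cands[which.max(fv), ]
  opt <- stats::optim(best, function(x) -bf$fn(rbind(x))[1],
                      method = "L-BFGS-B", lower = bf$lower,
                      upper = bf$upper)
  if (-opt$value >= max(fv)) list(x_star = opt$par, f_star = -opt$value)
  else list(x_star = best, f_star = max(fv))
}

## ---- optimizers ------------------------------------------------------------
## An optimizer is a list(name, fit(X, y, seed) -> model, supports_variance);
## the fitted model must have a predict method returning mean/var, so the
## shared acquisition machinery drives every optimizer identically.

#' Ensemble + differential evolution optimizer
#'
#' The package's own recommender: the probabilistic ensemble surrogate with
#' recommendations from differential evolution on the exploration/
#' exploitation acquisition.
#'
#' @param members Ensemble roster (see [fit_ensemble()]).
#' @param control Member hyperparameters.
#' @return An optimizer object for [run_simulated_campaign()].
#' @export
optimizer_ensemble <- function(members = c("gp", "rf", "gbt", "ridge"),
                               control = list()) {
  list(name = "ensemble_de", supports_variance = TRUE,
       fit = function(X, y, lower, upper, seed) {
         obs <- observation_set(X, y, mode = "yield_proxy")
         fit_ensemble(obs, seed = seed, members = members,
                      lower = lower, upper = upper, control = control)
       })
}

## Quadratic response-surface model (full second-order polynomial fit).
rsm_features <- function(X) {
  d <- ncol(X)
  sq <- X^2
  colnames(sq) <- paste0("sq", seq_len(d))
  inter <- NULL
  if (d > 1) {
    pairs <- utils::combn(d, 2)
    inter <- matrix(0, nrow(X), ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      inter[, k] <- X[, pairs[1, k]] * X[, pairs[2, k]]
    }
  }
  cbind(1, X, sq, inter)
}

#' Quadratic response-surface baseline
#'
#' A Response Surface Methodology stand-in: least-squares fit of a full
#' second-order polynomial (ridge-regularized while the design matrix is
#' rank-deficient), maximized over the box by the shared differential-
#' evolution machinery. It reports no predictive variance, so its
#' recommendations are always pure exploitation.
#'
#' @return An optimizer object for [run_simulated_campaign()].
#' @export
optimizer_rsm <- function() {
  list(name = "rsm", supports_variance = FALSE,
       fit = function(X, y, lower, upper, seed) {
         rng <- pmax(upper - lower, .Machine$double.eps)
         U <- sweep(sweep(X, 2, lower), 2, rng, "/")
         Phi <- rsm_features(U)
         ridged <- nrow(Phi) < ncol(Phi) + 1 || qr(Phi)$rank < ncol(Phi)
         lambda <- if (ridged) 1e-3 else 0
         A <- crossprod(Phi) + diag(lambda, ncol(Phi))
         beta <- tryCatch(solve(A, crossprod(Phi, y)), error = function(e) {
           solve(crossprod(Phi) + diag(1e-3, ncol(Phi)), crossprod(Phi, y))
         })
         structure(list(beta = as.vector(beta), lower = lower, range = rng,
                        ridged = ridged),
                   class = "rsm_model")
       })
}

#' @export
predict.rsm_model <- function(object, newdata, ...) {
  U <- sweep(sweep(rbind(newdata), 2, object$lower), 2, object$range, "/")
  mu <- as.vector(rsm_features(U) %*% object$beta)
  list(mean = mu, var = rep(0, length(mu)))
}

#' Single-Gaussian-process baseline
#'
#' A plain GP(RBF) surrogate (the package's internal GP regressor) driven by
#' the same acquisition machinery as the ensemble — a stand-in for
#' GP-autonomous-experimentation tools.
#'
#' @return An optimizer object for [run_simulated_campaign()].
#' @export
optimizer_gp <- function() {
  list(name = "gp", supports_variance = TRUE,
       fit = function(X, y, lower, upper, seed) {
         rng <- pmax(upper - lower, .Machine$double.eps)
         U <- sweep(sweep(X, 2, lower), 2, rng, "/")
         mu <- mean(y); sd <- stats::sd(y)
         if (!is.finite(sd) || sd == 0) sd <- 1
         g <- gp_fit(U, (y - mu) / sd)
         structure(list(gp = g, lower = lower, range = rng,
                        y_mu = mu, y_sd = sd),
                   class = "gp_box_model")
       })
}

#' @export
predict.gp_box_model <- function(object, newdata, ...) {
  U <- sweep(sweep(rbind(newdata), 2, object$lower), 2, object$range, "/")
  p <- predict(object$gp, U)
  list(mean = object$y_mu + object$y_sd * p$mean,
       var = object$y_sd^2 * p$var)
}

#' Simulate an active-learning campaign on a benchmark function
#'
#' Mirrors the simulated-campaign protocol: `n0` Latin-hypercube starting
#' observations with known function values, then `cycles` rounds of fit /
#' recommend-K / evaluate / append, repeated `repeats` times. Starting data
#' depend only on the repeat seed, so different optimizers run from
#' bit-identical initial observations. Exploration decays over cycles via
#' [alpha_schedule()] (optimizers without predictive variance always
#' exploit). `Y*` is the best response found up to each cycle, normalized by
#' the function's true optimum.
#'
#' @param optimizer An optimizer object ([optimizer_ensemble()],
#'   [optimizer_rsm()], [optimizer_gp()]), or `"oracle"` for the exhaustive
#'   upper bound that recommends the known argmax.
#' @param bf A [benchmark_function()].
#' @param n0 Starting observations.
#' @param K Recommendations per cycle.
#' @param cycles Learning cycles.
#' @param repeats Independent repeats.
#' @param seed Base seed; repeat r uses `seed + r - 1`.
#' @param de_params DE overrides for the per-recommendation maximization.
#' @param eps Batch-diversity radius in unit space.
#' @return An object of class `campaign_trace`: matrices `best` and `ystar`
#'   (repeats x cycles), `mean`/`sd` of `Y*` per cycle, `f_star`, `failed`.
#' @export
run_simulated_campaign <- function(optimizer, bf, n0 = 16, K = 16,
                                   cycles = 10, repeats = 10, seed = 1L,
                                   de_params = list(pop = 20, maxiter = 60),
                                   eps = 0.05) {
  opt_struct <- true_optimum(bf, n_grid = 1e5)
  f_star <- opt_struct$f_star
  d <- bf$d
  best_mat <- matrix(NA_real_, repeats, cycles)
  failed <- logical(repeats)
  for (r in seq_len(repeats)) {
    seed_r <- seed + r - 1L
    U0 <- with_seed(seed_r, lhs::randomLHS(n0, d))
    X <- sweep(sweep(U0, 2, bf$upper - bf$lower, "*"), 2, bf$lower, "+")
    y <- bf$fn(X)
    ok <- TRUE
    for (N in seq_len(cycles)) {
      res <- tryCatch({
        if (identical(optimizer, "oracle")) {
          Xn <- matrix(rep(opt_struct$x_star, K), K, d, byrow = TRUE)
        } else {
          model <- optimizer$fit(X, y, bf$lower, bf$upper,
                                 seed = seed_r + 101L * N)
          alpha <- if (isTRUE(optimizer$supports_variance)) {
            alpha_schedule(N, cycles)
          } else 0
          Xn <- recommend_box(model, bf$lower, bf$upper, K, alpha,
                              seed = seed_r + 101L * N, de_params, eps)
        }
        Xn
      }, error = function(e) NULL)
      if (is.null(res)) { ok <- FALSE; break }
      X <- rbind(X, res)
      y <- c(y, bf$fn(res))
      best_mat[r, N] <- max(y)
    }
    failed[r] <- !ok
  }
  ystar <- best_mat / f_star
  structure(list(best = best_mat, ystar = ystar,
                 mean = colMeans(ystar, na.rm = TRUE),
                 sd = apply(ystar, 2, stats::sd, na.rm = TRUE),
                 f_star = f_star, x_star = opt_struct$x_star,
                 failed = failed,
                 optimizer = if (is.character(optimizer)) optimizer
                             else optimizer$name,
                 fn = bf$name),
            class = "campaign_trace")
}

## Sequential eps-separated batch over a plain box (benchmark version of
## recommend_batch, without a phase space).
recommend_box <- function(model, lower, upper, K, alpha, seed, de_params,
                          eps) {
  d <- length(lower)
  acc_u <- matrix(numeric(0), 0, d)
  out <- matrix(NA_real_, K, d)
  for (i in seq_len(K)) {
    res <- optimize_acquisition(model, alpha = alpha,
                                seed = seed + 997L * i,
                                lower = lower, upper = upper,
                                de_params = de_params,
                                exclude = acc_u, eps = eps)
    acc_u <- rbind(acc_u, res$u)
    out[i, ] <- res$x
  }
  out
}

#' @export
print.campaign_trace <- function(x, ...) {
  cat("Simulated campaign: ", x$optimizer, " on ", x$fn, ", ",
      nrow(x$ystar), " repeats x ", ncol(x$ystar), " cycles\n", sep = "")
  cat("Y* per cycle (mean):", paste(sprintf("%.3f", x$mean), collapse = " "),
      "\n")
  invisible(x)
}

#' Tidy trace of a set of benchmark campaigns
#'
#' @param traces A list of `campaign_trace` objects.
#' @param path Optional CSV path.
#' @return Data.frame `optimizer, fn, repeat, cycle, best, ystar`.
#' @export
trace_table <- function(traces, path = NULL) {
  rows <- lapply(traces, function(tr) {
    data.frame(
      optimizer = tr$optimizer, fn = tr$fn,
      repeat_ = rep(seq_len(nrow(tr$best)), times = ncol(tr$best)),
      cycle = rep(seq_len(ncol(tr$best)), each = nrow(tr$best)),
      best = as.vector(tr$best), ystar = as.vector(tr$ystar),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  names(out)[3] <- "repeat"
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
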