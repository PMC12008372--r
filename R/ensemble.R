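#' Bundle observations for surrogate training
#'
#' Pairs media designs (variable-component concentrations) with measured
#' responses, keeping cycle labels and replicate groups so that replicates of
#' one design never straddle cross-validation folds.
#'
#' @param X Numeric matrix, n observations x d variable components.
#' @param y Numeric response vector (titer proxy or process-yield proxy).
#' @param cycle Optional integer cycle labels.
#' @param replicate_group Optional grouping labels (replicates of one design
#'   share a group); defaults to one group per row.
#' @param mode `"titer_proxy"` (responses must be non-negative) or
#'   `"yield_proxy"`.
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(X, y, cycle = NULL, replicate_group = NULL,
                            mode = c("titer_proxy", "yield_proxy")) {
  mode <- match.arg(mode)
  X <- rbind(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < 1) stop("need at least one observation")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("observations must be finite")
  }
  if (mode == "titer_proxy" && any(y < 0)) {
    stop("titer-proxy responses must be non-negative")
  }
  if (is.null(replicate_group)) replicate_group <- as.character(seq_along(y))
  structure(list(X = X, y = y,
                 cycle = if (is.null(cycle)) rep(NA_integer_, length(y))
                         else as.integer(cycle),
                 replicate_group = as.character(replicate_group),
                 mode = mode),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("Observation set: ", length(x$y), " observations, ", ncol(x$X),
      " components, mode ", x$mode, "\n", sep = "")
  invisible(x)
}

## ---- ensemble members ------------------------------------------------------
## Each member fits on unit-scaled inputs U and standardized response z, and
## predicts list(mu, var); members without a native predictive variance get
## their out-of-fold residual variance attached by fit_ensemble.

fit_member <- function(kind, U, z, seed, control) {
  switch(kind,
    gp = gp_fit(U, z),
    rf = with_seed(seed, {
      ## small CV folds trip randomForest's few-unique-values advisory
      m <- suppressWarnings(
        randomForest::randomForest(U, z, ntree = control$rf_trees))
      structure(list(fit = m), class = "member_rf")
    }),
    gbt = {
      dm <- xgboost::xgb.DMatrix(U, label = z, nthread = 1)
      m <- xgboost::xgb.train(
        params = list(eta = 0.1, max_depth = 3, subsample = 1,
                      objective = "reg:squarederror", nthread = 1,
                      seed = as.integer(seed)),
        data = dm, nrounds = control$gbt_rounds, verbose = 0
      )
      structure(list(fit = m), class = "member_gbt")
    },
    ridge = {
      Xd <- cbind(1, U)
      lambda <- control$ridge_lambda
      P <- diag(c(0, rep(lambda, ncol(U))))
      beta <- solve(crossprod(Xd) + P, crossprod(Xd, z))
      structure(list(beta = as.vector(beta)), class = "member_ridge")
    },
    stop("unknown member kind: ", kind)
  )
}

predict_member <- function(member, U) {
  if (inherits(member, "gp_model")) {
    predict(member, U)
  } else if (inherits(member, "member_rf")) {
    list(mean = as.vector(stats::predict(member$fit, U)), var = NULL)
  } else if (inherits(member, "member_gbt")) {
    list(mean = as.vector(stats::predict(member$fit, U)), var = NULL)
  } else if (inherits(member, "member_ridge")) {
    list(mean = as.vector(cbind(1, U) %*% member$beta), var = NULL)
  } else stop("unknown member class")
}

## Grouped k-fold assignment: groups (replicate sets) stay within one fold.
grouped_folds <- function(groups, k, seed) {
  ug <- unique(groups)
  if (length(ug) < k) k <- max(2L, length(ug))
  fold_of_group <- with_seed(seed, {
    stats::setNames(rep(seq_len(k), length.out = length(ug))[sample(length(ug))],
                    ug)
  })
  list(fold = unname(fold_of_group[groups]), k = k)
}

#' Fit the probabilistic ensemble surrogate
#'
#' Combines a Gaussian-process regressor, a random forest, gradient-boosted
#' trees and a ridge regression into a weighted mixture predicting both the
#' response mean E(y) and variance Var(y) from media-component concentrations.
#' Inputs are scaled to the unit box per the phase-space bounds (log scale
#' where bounds span orders of magnitude) and the response is standardized.
#' Member weights are `softmax(-CV-RMSE / tau)` from grouped k-fold
#' cross-validation with temperature `tau` the median CV-RMSE; members without
#' a native predictive variance contribute their out-of-fold residual
#' variance to the mixture.
#'
#' @param obs An [observation_set()].
#' @param space Optional [phase_space()] giving bounds and scales; otherwise
#'   supply `lower` and `upper`.
#' @param seed RNG seed; the fit is reproducible (same data, config and seed
#'   give identical predictions).
#' @param members Character subset of `c("gp", "rf", "gbt", "ridge")`. With
#'   fewer than 4 observations the roster falls back to the GP alone.
#' @param k Cross-validation folds (grouped by `replicate_group`).
#' @param lower,upper Explicit per-column bounds when no `space` is given
#'   (linear scaling).
#' @param control List of member hyperparameters: `rf_trees` (default 200),
#'   `gbt_rounds` (60), `ridge_lambda` (1e-2).
#' @return An object of class `media_ensemble` with `predict`, `print` and
#'   `summary` methods.
#' @seealso [predict.media_ensemble()], [cross_validated_r2()]
#' @export
fit_ensemble <- function(obs, space = NULL, seed = 1L,
                         members = c("gp", "rf", "gbt", "ridge"), k = 5,
                         lower = NULL, upper = NULL, control = list()) {
  stopifnot(inherits(obs, "observation_set"))
  control <- utils::modifyList(
    list(rf_trees = 200L, gbt_rounds = 60L, ridge_lambda = 1e-2), control)
  n <- length(obs$y)
  if (n < 4 && !identical(members, "gp")) members <- "gp"

  if (!is.null(space)) {
    U <- unit_scale(space, obs$X)
    scaler <- list(type = "space", space = space)
  } else {
    if (is.null(lower) || is.null(upper)) {
      lower <- apply(obs$X, 2, min)
      upper <- apply(obs$X, 2, max)
    }
    rng <- pmax(upper - lower, .Machine$double.eps)
    U <- sweep(sweep(obs$X, 2, lower), 2, rng, "/")
    scaler <- list(type = "box", lower = lower, range = rng)
  }
  colnames(U) <- paste0("x", seq_len(ncol(U)))  # canonical member features

  y_mu <- mean(obs$y)
  y_sd <- stats::sd(obs$y)
  degenerate <- !is.finite(y_sd) || y_sd == 0
  if (degenerate) {
    warning("degenerate response (zero variance): constant-model fallback")
    return(structure(list(members = list(), weights = numeric(0),
                          scaler = scaler, y_mu = y_mu, y_sd = 1,
                          degenerate = TRUE, seed = seed,
                          members_kind = character(0), n = n),
                     class = "media_ensemble"))
  }
  z <- (obs$y - y_mu) / y_sd

  ## grouped CV for member weights and fallback variances
  cv_rmse <- stats::setNames(rep(NA_real_, length(members)), members)
  oof_var <- stats::setNames(rep(NA_real_, length(members)), members)
  fl <- grouped_folds(obs$replicate_group, k, seed)
  oof <- matrix(NA_real_, n, length(members))
  for (f in seq_len(fl$k)) {
    tr <- fl$fold != f
    if (sum(tr) < 2 || sum(!tr) < 1) next
    for (m in seq_along(members)) {
      fit_f <- tryCatch(
        fit_member(members[m], U[tr, , drop = FALSE], z[tr],
                   seed + f, control),
        error = function(e) NULL)
      if (!is.null(fit_f)) {
        oof[!tr, m] <- predict_member(fit_f, U[!tr, , drop = FALSE])$mean
      }
    }
  }
  for (m in seq_along(members)) {
    r <- z - oof[, m]
    r <- r[is.finite(r)]
    cv_rmse[m] <- if (length(r)) sqrt(mean(r^2)) else 1
    oof_var[m] <- if (length(r)) mean(r^2) else 1
  }
  tau <- stats::median(cv_rmse)
  w <- if (tau <= 0 || !is.finite(tau)) rep(1, length(members))
       else exp(-cv_rmse / tau)
  w <- w / sum(w)

  fits <- lapply(seq_along(members),
                 function(m) fit_member(members[m], U, z, seed, control))
  structure(list(members = fits, members_kind = members,
                 weights = as.vector(w), cv_rmse = cv_rmse,
                 oof_var = oof_var, scaler = scaler,
                 y_mu = y_mu, y_sd = y_sd, degenerate = FALSE,
                 seed = seed, control = control, n = n),
            class = "media_ensemble")
}

scale_query <- function(scaler, X) {
  X <- rbind(X)
  U <- if (scaler$type == "space") unit_scale(scaler$space, X)
       else sweep(sweep(X, 2, scaler$lower), 2, scaler$range, "/")
  colnames(U) <- paste0("x", seq_len(ncol(U)))
  U
}

#' Posterior mean and variance of the ensemble
#'
#' Mixture prediction over the weighted members: `E = sum(w_i mu_i)` and
#' `Var = sum(w_i (sigma_i^2 + mu_i^2)) - E^2` (law of total variance over
#' the member mixture). Members without a native predictive variance use
#' their out-of-fold residual variance. Queries outside the unit box are
#' allowed but flagged as extrapolation.
#'
#' @param object A fitted [fit_ensemble()] model.
#' @param newdata Query matrix in concentration units (n x d).
#' @param ... Unused.
#' @return A list of class `posterior_prediction`: `mean`, `var` (response
#'   units), `extrapolated` (logical per query).
#' @export
predict.media_ensemble <- function(object, newdata, ...) {
  U <- scale_query(object$scaler, newdata)
  nq <- nrow(U)
  if (object$degenerate) {
    return(structure(list(mean = rep(object$y_mu, nq), var = rep(0, nq),
                          extrapolated = rep(FALSE, nq)),
                     class = "posterior_prediction"))
  }
  M <- length(object$members)
  mu <- var <- matrix(0, nq, M)
  for (m in seq_len(M)) {
    p <- predict_member(object$members[[m]], U)
    mu[, m] <- p$mean
    var[, m] <- if (is.null(p$var)) object$oof_var[[m]] else p$var
  }
  w <- object$weights
  E <- as.vector(mu %*% w)
  V <- as.vector((var + mu^2) %*% w) - E^2
  V <- pmax(V, 0)
  structure(list(mean = object$y_mu + object$y_sd * E,
                 var = object$y_sd^2 * V,
                 extrapolated = apply(U < -1e-8 | U > 1 + 1e-8, 1, any)),
            class = "posterior_prediction")
}

#' @export
print.media_ensemble <- function(x, ...) {
  cat("Probabilistic ensemble surrogate (", x$n, " observations)\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate response: constant model\n")
  } else {
    for (m in seq_along(x$members_kind)) {
      cat(sprintf("  %-6s weight %.3f  CV-RMSE %.3f\n", x$members_kind[m],
                  x$weights[m], x$cv_rmse[m]))
    }
  }
  invisible(x)
}

#' @export
summary.media_ensemble <- function(object, ...) {
  out <- list(n = object$n, members = object$members_kind,
              weights = object$weights, cv_rmse = object$cv_rmse,
              degenerate = object$degenerate)
  class(out) <- "summary.media_ensemble"
  out
}

#' @export
print.summary.media_ensemble <- function(x, ...) {
  cat("Ensemble of", length(x$members), "members on", x$n, "observations\n")
  print(data.frame(member = x$members, weight = round(x$weights, 4),
                   cv_rmse = round(unname(x$cv_rmse), 4)), row.names = FALSE)
  invisible(x)
}

#' Cross-validated coefficient of determination
#'
#' Grouped k-fold R-squared of the ensemble: replicates of one design never
#' straddle folds, out-of-fold predictions are pooled and
#' `R2 = 1 - SS_res / SS_tot` (may be negative).
#'
#' @inheritParams fit_ensemble
#' @param ... Passed to [fit_ensemble()] for each training fold.
#' @return Scalar R-squared.
#' @export
cross_validated_r2 <- function(obs, space = NULL, k = 5, seed = 1L, ...) {
  stopifnot(inherits(obs, "observation_set"))
  n <- length(obs$y)
  if (k > n) k <- n
  if (k < 2) stop("need k >= 2")
  fl <- grouped_folds(obs$replicate_group, k, seed)
  if (fl$k < k) warning("fewer replicate groups than folds; using k = ", fl$k)
  pred <- rep(NA_real_, n)
  for (f in seq_len(fl$k)) {
    tr <- fl$fold != f
    if (sum(tr) < 2 || sum(!tr) < 1) next
    sub <- observation_set(obs$X[tr, , drop = FALSE], obs$y[tr],
                           obs$cycle[tr], obs$replicate_group[tr], obs$mode)
    fit <- fit_ensemble(sub, space = space, seed = seed + f, ...)
    pred[!tr] <- predict(fit, obs$X[!tr, , drop = FALSE])$mean
  }
  keep <- is.finite(pred)
  r_squared(obs$y[keep], pred[keep])
}

## Pooled coefficient of determination, 1 - SS_res / SS_tot.
r_squared <- function(y, pred) {
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}
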