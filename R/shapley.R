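#' Shapley-value feature attribution of a surrogate
#'
#' Per-feature additive attribution of the model's mean prediction relative
#' to a single-reference baseline: absent features are set to the column
#' means of the background observations, and each feature's Shapley value
#' phi_j averages its marginal contribution over coalitions. Values are in
#' units of the response, and for every explained point
#' `sum_j phi_j = f(x) - baseline_value` (efficiency; exact under full
#' enumeration, Monte-Carlo accurate for the sampled estimator).
#'
#' @param model A fitted model whose `predict` returns a `mean` element
#'   (e.g. [fit_ensemble()]); ignored when `predict_fun` is given.
#' @param X_background Background matrix (training observations); its column
#'   means form the reference point.
#' @param X_explain Points to explain (n x d matrix).
#' @param method `"exact"` (full 2^d coalition enumeration, requires
#'   `d <= 15`) or `"sampled"` (uniform random feature permutations).
#' @param n_permutations Permutations per point for the sampled method;
#'   fewer than 10 sets a warning flag on the result.
#' @param seed RNG seed for the sampled method.
#' @param predict_fun Optional `function(X) -> numeric` replacing the model's
#'   mean prediction.
#' @return An object of class `attribution_result`: `phi` (n x d),
#'   `baseline_value`, `feature_order` (ranking by mean |phi|), `method`,
#'   `low_permutations` flag.
#' @export
shapley_values <- function(model = NULL, X_background, X_explain,
                           method = c("exact", "sampled"),
                           n_permutations = 200, seed = NULL,
                           predict_fun = NULL) {
  method <- match.arg(method)
  X_background <- rbind(X_background)
  X_explain <- rbind(X_explain)
  if (nrow(X_background) < 1) stop("background must be non-empty")
  d <- ncol(X_explain)
  if (ncol(X_background) != d) stop("background/explain dimension mismatch")
  f <- if (!is.null(predict_fun)) {
    function(X) as.numeric(predict_fun(X))
  } else {
    function(X) as.numeric(predict(model, X)$mean)
  }
  ref <- colMeans(X_background)
  baseline <- f(rbind(ref))[1]
  low_perm <- FALSE

  if (method == "exact") {
    if (d > 15) stop("exact enumeration limited to d <= 15 (2^d coalitions)")
    phi <- shapley_exact(f, ref, X_explain)
  } else {
    if (n_permutations < 10) low_perm <- TRUE
    phi <- shapley_sampled(f, ref, X_explain, n_permutations, seed)
  }
  colnames(phi) <- colnames(X_explain)
  res <- structure(list(phi = phi, baseline_value = baseline,
                        method = method, low_permutations = low_perm,
                        X_explain = X_explain),
                   class = "attribution_result")
  res$feature_order <- rank_features(res)$feature
  res
}

## Exact Shapley values by full coalition enumeration with a single
## reference point. One batched model call of 2^d rows per explained point.
shapley_exact <- function(f, ref, X_explain) {
  d <- length(ref)
  n_sub <- 2^d
  ## subset membership: row s (0-based mask s-1), column j
  member <- matrix(FALSE, n_sub, d)
  for (j in seq_len(d)) {
    member[, j] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  sizes <- rowSums(member)
  ## Shapley weight for adding feature j to a coalition of size s (j absent):
  ## s! (d - s - 1)! / d!
  wt <- exp(lfactorial(0:(d - 1)) + lfactorial(d - 1 - (0:(d - 1))) -
              lfactorial(d))
  phi <- matrix(0, nrow(X_explain), d)
  for (i in seq_len(nrow(X_explain))) {
    x <- X_explain[i, ]
    Xi <- matrix(rep(ref, each = n_sub), n_sub, d)
    Xi[member] <- matrix(rep(x, each = n_sub), n_sub, d)[member]
    v <- f(Xi)
    for (j in seq_len(d)) {
      without <- which(!member[, j])
      with_j <- without + bitwShiftL(1L, j - 1L)
      phi[i, j] <- sum(wt[sizes[without] + 1L] * (v[with_j] - v[without]))
    }
  }
  phi
}

## Permutation-sampling Shapley estimator: walk each random feature order,
## switching features from the reference to the explained value, and average
## the marginal contributions. Batched: (d + 1) rows per permutation.
shapley_sampled <- function(f, ref, X_explain, n_permutations, seed) {
  d <- length(ref)
  n <- nrow(X_explain)
  phi <- matrix(0, n, d)
  with_seed(seed, {
    for (i in seq_len(n)) {
      x <- X_explain[i, ]
      acc <- numeric(d)
      for (p in seq_len(n_permutations)) {
        ord <- sample.int(d)
        steps <- matrix(rep(ref, each = d + 1L), d + 1L, d)
        cur <- ref
        for (s in seq_len(d)) {
          cur[ord[s]] <- x[ord[s]]
          steps[s + 1L, ] <- cur
        }
        v <- f(steps)
        acc[ord] <- acc[ord] + diff(v)
      }
      phi[i, ] <- acc / n_permutations
    }
  })
  phi
}

#' Rank features by mean absolute Shapley value
#'
#' @param result An [shapley_values()] result.
#' @return A data.frame `feature, mean_abs_phi, rank`, in descending order
#'   of importance (ties broken by original feature order).
#' @export
rank_features <- function(result) {
  stopifnot(inherits(result, "attribution_result"))
  phi <- result$phi
  if (nrow(phi) < 1) stop("empty attribution result")
  score <- colMeans(abs(phi))
  nm <- colnames(phi)
  if (is.null(nm)) nm <- paste0("x", seq_along(score))
  ord <- order(-score, seq_along(score))
  data.frame(feature = nm[ord], mean_abs_phi = unname(score[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("Shapley attribution (", x$method, "): ", nrow(x$phi), " points, ",
      ncol(x$phi), " features; baseline ", signif(x$baseline_value, 5),
      "\n", sep = "")
  print(utils::head(rank_features(x), 10), row.names = FALSE)
  invisible(x)
}

#' Export attributions as a tidy table
#'
#' One row per (explained point, feature): `point_id, feature, phi,
#' feature_value` — the shape expected by beeswarm-style importance plots.
#' @param result An [shapley_values()] result.
#' @param path Optional CSV path to write.
#' @return The tidy data.frame (invisibly when writing).
#' @export
attribution_table <- function(result, path = NULL) {
  phi <- result$phi
  nm <- colnames(phi)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(phi)))
  out <- data.frame(
    point_id = rep(seq_len(nrow(phi)), times = ncol(phi)),
    feature = rep(nm, each = nrow(phi)),
    phi = as.vector(phi),
    feature_value = as.vector(result$X_explain),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
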