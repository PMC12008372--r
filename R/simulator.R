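#' Default synthetic flaviolin response surface
#'
#' A hidden, separable response surface over the MOPS-like phase space that
#' stands in for the wet-lab Test step. Five components drive production —
#' NaCl dominant (log-Gaussian peak at 450 mM, nine times the 50 mM base),
#' K2HPO4 and K2SO4 (peaked), NH4Cl and FeSO4 (saturating Hill curves) — and
#' all other variable components are inert. The maximum titer is calibrated
#' so the base MOPS design produces 95 mg/L. Replicate noise is
#' multiplicative lognormal with a 10% coefficient of variation, and the
#' optical proxy is linear in true titer with a nonzero intercept
#' (`Abs340 = a titer + b`). When glucose is variable, titer increases and
#' process yield decreases with initial glucose (`titer ~ glucose^gamma`,
#' `gamma < 1`).
#'
#' @param space A [phase_space()] containing the named MOPS-like components.
#' @param seed Seed recorded on the simulator (generation is deterministic).
#' @param noise_cv Replicate coefficient of variation.
#' @return An object of class `flaviolin_simulator`.
#' @export
make_default_simulator <- function(space, seed = 1L, noise_cv = 0.10) {
  need <- c("NaCl", "K2HPO4", "K2SO4", "FeSO4", "NH4Cl", "glucose")
  miss <- setdiff(need, component_names(space))
  if (length(miss)) stop("phase space missing components: ",
                         paste(miss, collapse = ", "))
  base <- stats::setNames(space$components$base, space$components$name)
  active <- data.frame(
    component = c("NaCl", "K2HPO4", "K2SO4", "FeSO4", "NH4Cl"),
    curve = c("peaked", "peaked", "peaked", "saturating", "saturating"),
    ## peaked: optimum concentration and log10 width;
    ## saturating: half-max concentration (width unused)
    optimum = c(450, base[["K2HPO4"]] * 5, base[["K2SO4"]] * 3,
                base[["FeSO4"]] / 4, base[["NH4Cl"]] / 4),
    width = c(1.0, 1.2, 1.5, NA, NA),
    weight = c(1.5, 1.0, 0.8, 0.8, 1.0),
    stringsAsFactors = FALSE
  )
  sim <- structure(list(space = space, active = active,
                        inert = setdiff(variable_names(space),
                                        active$component),
                        max_titer = 1, noise_cv = noise_cv,
                        proxy_slope = 0.004, proxy_intercept = 0.05,
                        glucose_exponent = 0.4,
                        glucose_base = base[["glucose"]],
                        noise_model = "lognormal", seed = seed),
                   class = "flaviolin_simulator")
  ## calibrate max_titer so the base design yields 95 mg/L
  base_design <- matrix(space$components$base, 1,
                        dimnames = list(NULL, component_names(space)))
  sim$max_titer <- 95 / true_titer(sim, base_design)[1]
  sim
}

## One response factor in (0, 1] per active component; acts in
## log-concentration because bounds span orders of magnitude.
response_factor <- function(curve, conc, optimum, width) {
  if (curve == "peaked") {
    exp(-(log10(conc) - log10(optimum))^2 / (2 * width^2))
  } else {
    conc^2 / (optimum^2 + conc^2)  # Hill, coefficient 2, half-max = optimum
  }
}

#' True (noiseless) flaviolin titer of designs
#'
#' Deterministic product of per-active-component response factors (raised to
#' their effect weights), scaled by the calibrated maximum titer and the
#' glucose coupling; inert components have no effect.
#'
#' @param sim A [make_default_simulator()] object.
#' @param designs A [design_batch()] or a concentration matrix with named
#'   columns covering all components.
#' @return Titer in mg/L, one value per design.
#' @export
true_titer <- function(sim, designs) {
  conc <- if (inherits(designs, "design_batch")) designs$conc else rbind(designs)
  fac <- rep(sim$max_titer, nrow(conc))
  for (i in seq_len(nrow(sim$active))) {
    a <- sim$active[i, ]
    fac <- fac * response_factor(a$curve, conc[, a$component],
                                 a$optimum, a$width)^a$weight
  }
  unname(fac * (conc[, "glucose"] / sim$glucose_base)^sim$glucose_exponent)
}

#' Known optimum of the synthetic surface
#'
#' The surface is separable, so its optimum over the phase-space box is
#' composed from per-component 1-D maximization (peaked factors at their
#' optimum concentration, saturating factors at the upper bound, glucose at
#' its upper bound when variable).
#'
#' @param sim A simulator.
#' @return List: `design` (concentration vector at the optimum), `titer`.
#' @export
simulator_optimum <- function(sim) {
  tab <- sim$space$components
  x <- stats::setNames(tab$base, tab$name)
  for (i in seq_len(nrow(sim$active))) {
    a <- sim$active[i, ]
    k <- match(a$component, tab$name)
    if (tab$fixed[k]) next
    opt <- stats::optimize(
      function(c) response_factor(a$curve, c, a$optimum, a$width),
      lower = tab$lower[k], upper = tab$upper[k], maximum = TRUE,
      tol = 1e-10)
    x[a$component] <- opt$maximum
  }
  k <- match("glucose", tab$name)
  if (!tab$fixed[k]) x["glucose"] <- tab$upper[k]
  titer <- true_titer(sim, matrix(x, 1, dimnames = list(NULL, names(x))))[1]
  list(design = x, titer = titer)
}

#' Simulate replicate measurements of designs
#'
#' The Test-step stand-in: per replicate the optical proxy
#' `Abs340 = a titer + b` is multiplied by lognormal noise with coefficient
#' of variation `noise_cv` (additive Gaussian available for robustness
#' checks). Yield mode divides the proxy by the design's initial glucose
#' concentration. A cell-density proxy (OD600 around 1.0 with the same noise
#' law) is returned alongside.
#'
#' @param sim A simulator.
#' @param designs A [design_batch()] or concentration matrix.
#' @param n_replicates Replicates per design.
#' @param mode `"titer_proxy"` or `"yield_proxy"`.
#' @param seed RNG seed.
#' @param noise `"lognormal"` (default) or `"gaussian"`.
#' @return A data.frame: `design_id, replicate, abs340, od600, response`
#'   (`response` is `abs340` in titer mode, `abs340 / glucose` in yield
#'   mode).
#' @export
observe <- function(sim, designs, n_replicates = 3,
                    mode = c("titer_proxy", "yield_proxy"), seed = 1L,
                    noise = c("lognormal", "gaussian")) {
  mode <- match.arg(mode)
  noise <- match.arg(noise)
  stopifnot(n_replicates >= 1)
  conc <- if (inherits(designs, "design_batch")) designs$conc else rbind(designs)
  ids <- if (inherits(designs, "design_batch")) designs$design_id
         else paste0("d", seq_len(nrow(conc)))
  titer <- true_titer(sim, conc)
  abs_clean <- sim$proxy_slope * titer + sim$proxy_intercept
  n <- length(titer)
  cv <- sim$noise_cv
  noise_mult <- function(m) {
    if (cv == 0) return(matrix(1, m, n_replicates))
    if (noise == "lognormal") {
      s2 <- log(1 + cv^2)
      matrix(exp(stats::rnorm(m * n_replicates, -s2 / 2, sqrt(s2))),
             m, n_replicates)
    } else {
      matrix(1 + stats::rnorm(m * n_replicates, 0, cv), m, n_replicates)
    }
  }
  out <- with_seed(seed, {
    abs_mat <- abs_clean * noise_mult(n)
    od_mat <- 1.0 * noise_mult(n)
    list(abs = abs_mat, od = od_mat)
  })
  resp <- out$abs
  if (mode == "yield_proxy") resp <- resp / conc[, "glucose"]
  data.frame(
    design_id = rep(ids, times = n_replicates),
    replicate = rep(seq_len(n_replicates), each = n),
    abs340 = as.vector(out$abs),
    od600 = as.vector(out$od),
    response = as.vector(resp),
    stringsAsFactors = FALSE
  )
}
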