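#' Define a media component
#'
#' A media component is one chemical species of a defined medium, carrying its
#' base (starting-medium) concentration, the lower and upper bounds between
#' which the optimizer may vary it, the solubility limit that caps any stock
#' solution, and a flag marking components held fixed during a campaign.
#'
#' Concentrations are in mM by default; glucose is conventionally specified in
#' g/L and the unit is carried per component, never converted implicitly.
#'
#' @param name Component name (unique within a phase space).
#' @param base Base concentration (the starting medium).
#' @param lower,upper Bounds of the search interval. For fixed components both
#'   must equal `base`.
#' @param solubility Maximum feasible stock concentration.
#' @param fixed Logical; fixed components are never varied by the optimizer.
#' @param unit Concentration unit, `"mM"` or `"g/L"`.
#' @return An object of class `media_component`.
#' @examples
#' media_component("NaCl", base = 50, lower = 5, upper = 500, solubility = 5000)
#' @export
media_component <- function(name, base, lower, upper, solubility,
                            fixed = FALSE, unit = "mM") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  vals <- c(lower = lower, base = base, upper = upper, solubility = solubility)
  if (any(!is.finite(vals))) stop("non-finite concentration for ", name)
  if (!(0 <= lower && lower <= base && base <= upper && upper <= solubility)) {
    stop("component ", name,
         ": need 0 <= lower <= base <= upper <= solubility, got ",
         paste(signif(vals, 6), collapse = ", "))
  }
  if (fixed && !(lower == base && upper == base)) {
    stop("fixed component ", name, " must have lower = upper = base")
  }
  unit <- match.arg(unit, c("mM", "g/L"))
  structure(list(name = name, base = base, lower = lower, upper = upper,
                 solubility = solubility, fixed = fixed, unit = unit),
            class = "media_component")
}

#' Construct a media phase space
#'
#' The phase space is the d-dimensional box of feasible concentrations spanned
#' by the variable components of the medium; fixed components are carried along
#' at their base concentration.
#'
#' @param components A list of [media_component()] objects, or a data.frame
#'   with columns `name, base, lower, upper, solubility, fixed, unit`.
#' @return An object of class `phase_space` with a `components` data.frame and
#'   derived fields (`d`, indices of variable components, per-component
#'   sampling scale).
#' @export
phase_space <- function(components) {
  if (is.data.frame(components)) {
    df <- components
    req <- c("name", "base", "lower", "upper", "solubility", "fixed")
    miss <- setdiff(req, names(df))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    if (is.null(df$unit)) df$unit <- "mM"
    comps <- lapply(seq_len(nrow(df)), function(i) {
      media_component(as.character(df$name[i]), df$base[i], df$lower[i],
                      df$upper[i], df$solubility[i],
                      as.logical(df$fixed[i]), as.character(df$unit[i]))
    })
  } else {
    comps <- components
    ok <- vapply(comps, inherits, logical(1), "media_component")
    if (!all(ok)) stop("components must be media_component objects")
  }
  nm <- vapply(comps, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate component names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  tab <- data.frame(
    name = nm,
    base = vapply(comps, `[[`, numeric(1), "base"),
    lower = vapply(comps, `[[`, numeric(1), "lower"),
    upper = vapply(comps, `[[`, numeric(1), "upper"),
    solubility = vapply(comps, `[[`, numeric(1), "solubility"),
    fixed = vapply(comps, `[[`, logical(1), "fixed"),
    unit = vapply(comps, `[[`, character(1), "unit"),
    stringsAsFactors = FALSE
  )
  variable <- which(!tab$fixed)
  if (length(variable) < 1L) stop("phase space needs at least one variable component")
  structure(list(components = tab, d = length(variable), variable = variable),
            class = "phase_space")
}

#' @export
print.phase_space <- function(x, ...) {
  cat("Media phase space: ", nrow(x$components), " components (",
      x$d, " variable, ", sum(x$components$fixed), " fixed)\n", sep = "")
  print(x$components, row.names = FALSE)
  invisible(x)
}

component_names <- function(space) space$components$name

variable_names <- function(space) space$components$name[space$variable]

#' Per-component sampling scale
#'
#' Components whose lower bound is strictly positive are sampled and scaled
#' logarithmically (bounds typically span 1-2 orders of magnitude); a zero
#' lower bound falls back to a linear scale.
#' @param space A `phase_space`.
#' @return Character vector (`"log"`/`"linear"`), one entry per variable
#'   component.
#' @export
space_scales <- function(space) {
  lo <- space$components$lower[space$variable]
  ifelse(lo > 0, "log", "linear")
}

## Map variable-component concentrations (n x d matrix) into the unit box,
## honoring the per-component scale.
unit_scale <- function(space, conc) {
  conc <- rbind(conc)
  v <- space$variable
  lo <- space$components$lower[v]
  hi <- space$components$upper[v]
  sc <- space_scales(space)
  u <- conc
  for (j in seq_along(v)) {
    if (sc[j] == "log") {
      u[, j] <- (log(conc[, j]) - log(lo[j])) / (log(hi[j]) - log(lo[j]))
    } else {
      u[, j] <- (conc[, j] - lo[j]) / (hi[j] - lo[j])
    }
  }
  u
}

unit_unscale <- function(space, u) {
  u <- rbind(u)
  v <- space$variable
  lo <- space$components$lower[v]
  hi <- space$components$upper[v]
  sc <- space_scales(space)
  conc <- u
  for (j in seq_along(v)) {
    if (sc[j] == "log") {
      conc[, j] <- exp(log(lo[j]) + u[, j] * (log(hi[j]) - log(lo[j])))
    } else {
      conc[, j] <- lo[j] + u[, j] * (hi[j] - lo[j])
    }
  }
  colnames(conc) <- variable_names(space)
  conc
}

#' Read / write a media specification table
#'
#' The media specification is a plain CSV with one row per component and
#' columns `name, base, lower, upper, solubility, fixed, unit`.
#'
#' @param path File path.
#' @return `read_media_spec()` returns a `phase_space`.
#' @export
read_media_spec <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  phase_space(df)
}

#' @rdname read_media_spec
#' @param space A `phase_space` to write.
#' @export
write_media_spec <- function(space, path) {
  utils::write.csv(space$components, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default MOPS-like phase space
#'
#' A 15-component defined medium modeled on MOPS minimal medium: glucose, MOPS
#' buffer and Tricine held fixed, and 12 variable components (salts, phosphate,
#' sulfate, nitrogen and trace metals) with bounds spanning one to two orders
#' of magnitude around the base recipe. Base values are plausible MOPS-medium
#' concentrations recorded here as simulator/search defaults (synthetic, not a
#' published recipe). With `glucose_variable = TRUE` the glucose concentration
#' joins the search space (13 variable components), as used when optimizing
#' process yield rather than titer.
#'
#' @param glucose_variable Logical; make glucose a 13th variable component.
#' @return A `phase_space`.
#' @export
mops_phase_space <- function(glucose_variable = FALSE) {
  tab <- data.frame(
    name = c("glucose", "MOPS", "Tricine", "K2HPO4", "NaCl", "NH4Cl",
             "K2SO4", "FeSO4", "MgCl2", "Mo7O24", "H3BO3", "CoCl2",
             "CuSO4", "MnSO4", "ZnSO4"),
    base = c(10, 40, 4, 1.32, 50, 9.52, 0.276, 0.01, 0.523,
             3e-06, 4e-04, 3e-05, 1e-05, 8e-05, 1e-05),
    lower = c(10, 40, 4, 0.33, 5, 0.952, 0.0276, 0.001, 0.0523,
              3e-07, 4e-05, 3e-06, 1e-06, 8e-06, 1e-06),
    upper = c(10, 40, 4, 13.2, 500, 95.2, 2.76, 0.1, 5.23,
              3e-05, 4e-03, 3e-04, 1e-04, 8e-04, 1e-04),
    solubility = c(500, 1000, 500, 3000, 5000, 5000, 500, 100, 5000,
                   1, 100, 100, 100, 100, 100),
    fixed = c(TRUE, TRUE, TRUE, rep(FALSE, 12)),
    unit = c("g/L", rep("mM", 14)),
    stringsAsFactors = FALSE
  )
  if (glucose_variable) {
    tab$fixed[1] <- FALSE
    tab$lower[1] <- 2
    tab$upper[1] <- 40
  }
  phase_space(tab)
}
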