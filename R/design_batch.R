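#' Construct a batch of media designs
#'
#' A media design is one concentration vector over all components of the phase
#' space; a batch bundles several designs with identifiers, roles
#' (experimental vs control) and an optional DBTL cycle label.
#'
#' @param space A [phase_space()].
#' @param conc Numeric matrix, one row per design, columns aligned to (and
#'   named by) the phase-space component order.
#' @param design_id Character vector of unique identifiers (default `d1..dn`).
#' @param role `"experimental"` or `"control"` per design. Experimental
#'   designs must lie within bounds and hold fixed components at base; control
#'   designs may exceed the box by the control-jitter margin but never
#'   solubility.
#' @param label Optional per-design label (e.g. `"explorative"`).
#' @param cycle Optional integer cycle label.
#' @param seed Seed recorded for provenance.
#' @return An object of class `design_batch`.
#' @export
design_batch <- function(space, conc, design_id = NULL, role = "experimental",
                         label = NA_character_, cycle = NA_integer_,
                         seed = NA_integer_) {
  conc <- rbind(conc)
  p <- nrow(space$components)
  if (ncol(conc) != p) {
    stop("conc must have ", p, " columns (one per component), got ", ncol(conc))
  }
  colnames(conc) <- component_names(space)
  n <- nrow(conc)
  if (is.null(design_id)) design_id <- paste0("d", seq_len(n))
  if (anyDuplicated(design_id)) stop("design_id values must be unique")
  role <- rep_len(role, n)
  label <- rep_len(label, n)
  out <- structure(list(space = space, conc = conc,
                        design_id = as.character(design_id),
                        role = role, label = label,
                        cycle = rep_len(as.integer(cycle), n),
                        seed = seed),
                   class = "design_batch")
  validate_design_batch(out)
  out
}

validate_design_batch <- function(batch, jitter_margin = 0.10) {
  sp <- batch$space
  tab <- sp$components
  conc <- batch$conc
  for (i in seq_len(nrow(conc))) {
    ctrl <- batch$role[i] == "control"
    for (k in seq_len(nrow(tab))) {
      x <- conc[i, k]
      if (x > tab$solubility[k]) {
        stop("design ", batch$design_id[i], ": ", tab$name[k],
             " exceeds solubility")
      }
      if (tab$fixed[k]) {
        lim <- if (ctrl) tab$base[k] * (1 + jitter_margin) else tab$base[k]
        if (!ctrl && abs(x - tab$base[k]) > 1e-9 * max(1, tab$base[k])) {
          stop("design ", batch$design_id[i], ": fixed component ",
               tab$name[k], " must equal base")
        }
      } else if (ctrl) {
        if (x > tab$base[k] * (1 + jitter_margin) + 1e-12 ||
            x < tab$base[k] * (1 - jitter_margin) - 1e-12) {
          stop("control design ", batch$design_id[i], ": ", tab$name[k],
               " outside the +/-", jitter_margin * 100, "% control margin")
        }
      } else {
        if (x < tab$lower[k] - 1e-12 || x > tab$upper[k] + 1e-12) {
          stop("design ", batch$design_id[i], ": ", tab$name[k],
               " outside [", tab$lower[k], ", ", tab$upper[k], "]")
        }
      }
    }
  }
  invisible(batch)
}

#' @export
print.design_batch <- function(x, ...) {
  cat("Design batch: ", nrow(x$conc), " designs (",
      sum(x$role == "control"), " control)\n", sep = "")
  utils::str(x$conc, give.attr = FALSE)
  invisible(x)
}

#' @export
as.data.frame.design_batch <- function(x, ...) {
  data.frame(design_id = x$design_id, role = x$role, label = x$label,
             cycle = x$cycle, x$conc, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read / write a design CSV
#'
#' Designs are exchanged as a flat CSV: `design_id, role, label, cycle`, then
#' one column per component in phase-space order.
#' @param batch A `design_batch`.
#' @param path File path.
#' @export
write_designs <- function(batch, path) {
  utils::write.csv(as.data.frame(batch), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_designs
#' @param space The `phase_space` the file refers to.
#' @export
read_designs <- function(path, space) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- component_names(space)
  miss <- setdiff(nm, names(df))
  if (length(miss)) stop("design file missing component columns: ",
                         paste(miss, collapse = ", "))
  design_batch(space, as.matrix(df[, nm, drop = FALSE]),
               design_id = df$design_id, role = df$role,
               label = if (is.null(df$label)) NA_character_ else df$label,
               cycle = if (is.null(df$cycle)) NA_integer_ else df$cycle)
}

## Combine row-wise; spaces must be identical.
rbind_batches <- function(...) {
  bs <- list(...)
  bs <- bs[!vapply(bs, is.null, logical(1))]
  if (length(bs) == 1L) return(bs[[1]])
  ids <- unlist(lapply(bs, `[[`, "design_id"))
  if (anyDuplicated(ids)) stop("duplicate design_id across batches")
  structure(list(space = bs[[1]]$space,
                 conc = do.call(rbind, lapply(bs, `[[`, "conc")),
                 design_id = ids,
                 role = unlist(lapply(bs, `[[`, "role")),
                 label = unlist(lapply(bs, `[[`, "label")),
                 cycle = unlist(lapply(bs, `[[`, "cycle")),
                 seed = bs[[1]]$seed),
            class = "design_batch")
}
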