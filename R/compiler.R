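#' Derive the high/low stock pair for one component
#'
#' The media compiler keeps two stock solutions per component. The high stock
#' is chosen so the upper concentration bound is delivered at a reference
#' transfer volume (capped at the solubility limit); the low stock is the high
#' stock diluted by `r`, diluted further if the lower bound would otherwise
#' require a transfer below the instrument minimum.
#'
#' @param component A [media_component()].
#' @param v_min Minimum instrument transfer volume (uL).
#' @param v_ref Reference transfer volume at which the upper bound should be
#'   delivered (uL).
#' @param final_volume Final well volume (uL).
#' @param r Dilution ratio between high and low stock.
#' @return A list of class `stock_pair`: `component`, `high_stock`,
#'   `low_stock` (same unit as the component).
#' @export
compute_stock_pair <- function(component, v_min = 5, v_ref = 150,
                               final_volume = 1500, r = 20) {
  stopifnot(inherits(component, "media_component"))
  if (!(v_min < v_ref && v_ref < final_volume)) {
    stop("need v_min < v_ref < final_volume")
  }
  if (component$upper <= 0) stop("upper bound must be positive for ",
                                 component$name)
  high <- min(component$solubility, component$upper * final_volume / v_ref)
  ## feasibility: even the solubility-capped stock must deliver the upper
  ## bound within the final volume
  if (component$upper * final_volume / high > final_volume + 1e-9) {
    stop("infeasible stock for ", component$name,
         ": solubility limit ", component$solubility,
         " cannot deliver upper bound ", component$upper,
         " within the final volume")
  }
  low <- high / r
  if (component$lower > 0 && component$lower * final_volume / low < v_min) {
    ## dilute further so the lower bound needs at least v_min
    low <- component$lower * final_volume / v_min
  }
  if (low >= high) low <- high / r
  structure(list(component = component$name, unit = component$unit,
                 high_stock = high, low_stock = low),
            class = "stock_pair")
}

#' Stock table for a whole phase space
#'
#' @param space A [phase_space()].
#' @inheritParams compute_stock_pair
#' @return A data.frame with one row per component: `component, unit,
#'   high_stock, low_stock, source_high, source_well_high, source_low,
#'   source_well_low` (source labels/wells for the worklist).
#' @export
stock_table <- function(space, v_min = 5, v_ref = 150, final_volume = 1500,
                        r = 20) {
  tab <- space$components
  pairs <- lapply(seq_len(nrow(tab)), function(i) {
    comp <- media_component(tab$name[i], tab$base[i], tab$lower[i],
                            tab$upper[i], tab$solubility[i], tab$fixed[i],
                            tab$unit[i])
    compute_stock_pair(comp, v_min, v_ref, final_volume, r)
  })
  n <- length(pairs)
  src_wells <- well_names(2L * n)
  data.frame(
    component = vapply(pairs, `[[`, character(1), "component"),
    unit = vapply(pairs, `[[`, character(1), "unit"),
    high_stock = vapply(pairs, `[[`, numeric(1), "high_stock"),
    low_stock = vapply(pairs, `[[`, numeric(1), "low_stock"),
    source_high = paste0(tab$name, "_high"),
    source_well_high = src_wells[seq_len(n) * 2L - 1L],
    source_low = paste0(tab$name, "_low"),
    source_well_low = src_wells[seq_len(n) * 2L],
    stringsAsFactors = FALSE
  )
}

#' Transfer volume delivering a target concentration
#'
#' Dilution identity `c1 v1 = c2 v2`.
#' @param target Target concentration in the final well.
#' @param stock Stock concentration.
#' @param final_volume Final well volume (uL).
#' @return Volume of stock (uL).
#' @export
volume_for_target <- function(target, stock, final_volume = 1500) {
  stopifnot(stock > 0, target >= 0)
  if (any(target > stock)) stop("infeasible dilution: target ", max(target),
                                " exceeds stock ", stock)
  target * final_volume / stock
}

## Well names for an n-well plate laid out in 8-column rows: A1..A8, B1..B8, ...
well_names <- function(n, ncol = 8L) {
  nrow <- ceiling(n / ncol)
  rows <- if (nrow <= 26) LETTERS[seq_len(nrow)] else
    paste0(LETTERS[(seq_len(nrow) - 1L) %/% 26 + 1L],
           LETTERS[(seq_len(nrow) - 1L) %% 26 + 1L])
  paste0(rep(rows, each = ncol), rep(seq_len(ncol), nrow))[seq_len(n)]
}

#' Assign designs and replicates to plate wells
#'
#' Deterministic row-major layout on a 48-well cultivation plate: each design
#' occupies `replicates` consecutive wells; when a control is included it
#' occupies the final replicate block (wells F5-F8 on a full 48/4 plate).
#'
#' @param n_designs Number of experimental designs.
#' @param replicates Replicates per design.
#' @param capacity Plate capacity in wells.
#' @param control Include a control design in the last block?
#' @param design_id Optional identifiers (length `n_designs`); default
#'   `d1..dn` with control id `"control"`.
#' @return A data.frame of class `plate_layout`: `well, design_id, replicate`.
#' @export
layout_plate <- function(n_designs, replicates = 3, capacity = 48,
                         control = TRUE, design_id = NULL) {
  stopifnot(n_designs >= 0, replicates >= 1)
  total <- (n_designs + as.integer(control)) * replicates
  if (total > capacity) {
    stop("plate capacity exceeded: need ", total, " wells, have ", capacity,
         " (", total - capacity, " over)")
  }
  if (is.null(design_id)) design_id <- paste0("d", seq_len(n_designs))
  stopifnot(length(design_id) == n_designs)
  ids <- c(rep(design_id, each = replicates),
           if (control) rep("control", replicates))
  ## control goes in the last replicate block of the plate
  wells <- well_names(capacity)
  n_exp <- n_designs * replicates
  assigned <- c(wells[seq_len(n_exp)],
                if (control) wells[(capacity - replicates + 1L):capacity])
  out <- data.frame(well = assigned, design_id = ids,
                    replicate = rep(seq_len(replicates),
                                    times = n_designs + as.integer(control)),
                    stringsAsFactors = FALSE)
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Compile media designs into a liquid-handler transfer plan
#'
#' For every well of the layout, one transfer per nonzero component (using the
#' high stock when its volume reaches the instrument minimum, otherwise the
#' low stock), one inoculum transfer, and a water top-up to the final volume.
#' Volumes are kept at full precision in the plan so the realized
#' concentrations reproduce the design targets exactly; rounding to 0.01 uL
#' happens only when writing the worklist.
#'
#' @param designs A [design_batch()] covering every `design_id` in the layout.
#' @param layout A [layout_plate()] result.
#' @param stocks A [stock_table()] for the same phase space.
#' @param final_volume Final well volume (uL).
#' @param inoculum_fraction Fraction of the final volume taken by inoculum.
#' @param v_min Minimum transfer volume (uL); the water top-up is exempt.
#' @return An object of class `transfer_plan`: a list with `transfers`
#'   (data.frame `source_label, source_well, dest_well, volume`),
#'   `final_volume`, `inoculum_fraction`, `layout`, `designs`.
#' @export
compile_plate <- function(designs, layout, stocks, final_volume = 1500,
                          inoculum_fraction = 0.02, v_min = 5) {
  stopifnot(inherits(designs, "design_batch"))
  ids <- unique(layout$design_id)
  miss <- setdiff(ids, designs$design_id)
  if (length(miss)) stop("layout references unknown designs: ",
                         paste(miss, collapse = ", "))
  comp_names <- component_names(designs$space)
  miss <- setdiff(comp_names, stocks$component)
  if (length(miss)) stop("stock table missing components: ",
                         paste(miss, collapse = ", "))
  stocks <- stocks[match(comp_names, stocks$component), ]
  v_inoc <- inoculum_fraction * final_volume

  rows <- vector("list", nrow(layout))
  for (w in seq_len(nrow(layout))) {
    di <- match(layout$design_id[w], designs$design_id)
    target <- designs$conc[di, ]
    lab <- vol <- swell <- character(0)
    vols <- numeric(0)
    for (k in seq_along(target)) {
      if (target[k] <= 0) next
      vh <- volume_for_target(target[k], stocks$high_stock[k], final_volume)
      if (vh >= v_min) {
        vols <- c(vols, vh)
        lab <- c(lab, stocks$source_high[k])
        swell <- c(swell, stocks$source_well_high[k])
      } else {
        vl <- volume_for_target(target[k], stocks$low_stock[k], final_volume)
        if (vl < v_min) {
          stop("well ", layout$well[w], ": target ", signif(target[k], 6),
               " ", stocks$unit[k], " of ", comp_names[k],
               " is deliverable from neither stock (volumes ",
               signif(vh, 4), " / ", signif(vl, 4), " uL < v_min)")
        }
        vols <- c(vols, vl)
        lab <- c(lab, stocks$source_low[k])
        swell <- c(swell, stocks$source_well_low[k])
      }
    }
    used <- sum(vols) + v_inoc
    if (used > final_volume + 1e-9) {
      stop("well ", layout$well[w], ": component volumes (",
           round(used, 2), " uL) exceed the final volume")
    }
    rows[[w]] <- data.frame(
      source_label = c(lab, "inoculum", "water"),
      source_well = c(swell, "INOC", "WATER"),
      dest_well = layout$well[w],
      volume = c(vols, v_inoc, final_volume - used),
      stringsAsFactors = FALSE
    )
  }
  structure(list(transfers = do.call(rbind, rows),
                 final_volume = final_volume,
                 inoculum_fraction = inoculum_fraction,
                 layout = layout, designs = designs),
            class = "transfer_plan")
}

#' @export
print.transfer_plan <- function(x, ...) {
  cat("Transfer plan: ", nrow(x$transfers), " transfers into ",
      length(unique(x$transfers$dest_well)), " wells (final volume ",
      x$final_volume, " uL)\n", sep = "")
  invisible(x)
}

#' Re-simulate mixing from a transfer plan
#'
#' Independent check of a compiled plan: recompute the realized concentration
#' of every component in every well from the emitted volumes and the stock
#' concentrations.
#'
#' @param plan A [compile_plate()] result.
#' @param stocks The [stock_table()] used to compile it.
#' @return Matrix of realized concentrations, wells x components.
#' @export
realized_concentrations <- function(plan, stocks) {
  wells <- unique(plan$transfers$dest_well)
  comp <- stocks$component
  out <- matrix(0, length(wells), length(comp),
                dimnames = list(wells, comp))
  conc_of <- c(stats::setNames(stocks$high_stock, stocks$source_high),
               stats::setNames(stocks$low_stock, stocks$source_low))
  tr <- plan$transfers
  for (i in seq_len(nrow(tr))) {
    src <- tr$source_label[i]
    if (src %in% c("inoculum", "water")) next
    cname <- sub("_(high|low)$", "", src)
    out[tr$dest_well[i], cname] <- out[tr$dest_well[i], cname] +
      tr$volume[i] * conc_of[[src]] / plan$final_volume
  }
  out
}

#' Write / read a liquid-handler worklist CSV
#'
#' Header `SourceLabel,SourceWell,DestWell,VolumeUL`; volumes printed with two
#' decimals; rows ordered destination-major then component order (the order
#' the plan was compiled in).
#' @param plan A `transfer_plan`.
#' @param path Output path.
#' @export
write_worklist <- function(plan, path) {
  tr <- plan$transfers
  df <- data.frame(SourceLabel = tr$source_label,
                   SourceWell = tr$source_well,
                   DestWell = tr$dest_well,
                   VolumeUL = sprintf("%.2f", tr$volume),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_worklist
#' @return `read_worklist()` returns the worklist as a data.frame with
#'   numeric `VolumeUL`.
#' @export
read_worklist <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("SourceLabel", "SourceWell", "DestWell", "VolumeUL")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("worklist missing columns: ",
                         paste(miss, collapse = ", "))
  df$VolumeUL <- as.numeric(df$VolumeUL)
  df
}
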