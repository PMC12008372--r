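#' Read / write observation tables
#'
#' Observations travel in a flat CSV dialect: one column per media component
#' (phase-space order), then `Abs340, OD600, cycle, replicate, design_id`.
#' Unknown extra columns are preserved as passthrough metadata; missing
#' required columns raise a schema error listing them.
#'
#' @param path File path.
#' @param space A [phase_space()] used to validate component columns.
#' @return `read_observations()` returns the records data.frame.
#' @export
read_observations <- function(path, space) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c(component_names(space), "Abs340", "OD600", "cycle", "replicate",
           "design_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("observation file missing columns: ",
                         paste(miss, collapse = ", "))
  for (nm in component_names(space)) {
    k <- match(nm, space$components$name)
    if (any(df[[nm]] > space$components$solubility[k] + 1e-9)) {
      stop("column ", nm, " exceeds its solubility limit")
    }
  }
  if (any(df$Abs340 < 0) || any(df$OD600 < 0)) {
    stop("readings must be non-negative")
  }
  df
}

#' @rdname read_observations
#' @param records Observation records data.frame.
#' @export
write_observations <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Assemble observation records from a design batch plus measured replicates.
make_records <- function(batch, measured, cycle) {
  idx <- match(measured$design_id, batch$design_id)
  conc <- batch$conc[idx, , drop = FALSE]
  data.frame(conc, Abs340 = measured$abs340, OD600 = measured$od600,
             cycle = cycle, replicate = measured$replicate,
             design_id = measured$design_id, role = batch$role[idx],
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Convert observation records to a surrogate training set
#'
#' Builds the n x d matrix of variable-component concentrations and the
#' response vector: `Abs340` in titer mode, `Abs340 / glucose` (process
#' yield) in yield mode. Replicates of one design share a replicate group.
#'
#' @param records Observation records (see [read_observations()]).
#' @param space A [phase_space()].
#' @param mode `"titer_proxy"` or `"yield_proxy"`.
#' @return An [observation_set()].
#' @export
as_observation_set <- function(records, space,
                               mode = c("titer_proxy", "yield_proxy")) {
  mode <- match.arg(mode)
  X <- as.matrix(records[, variable_names(space), drop = FALSE])
  y <- records$Abs340
  if (mode == "yield_proxy") y <- y / records$glucose
  observation_set(X, y, cycle = records$cycle,
                  replicate_group = paste(records$design_id, records$cycle),
                  mode = mode)
}

#' Replicate-based outlier filtering
#'
#' Removes whole designs whose replicate sets betray liquid-handling errors:
#' rule 1 drops a design when any replicate's Abs340 or OD600 falls below
#' `theta_low` times the design's replicate median (a well that produced no
#' biomass or product); rule 2 drops it when any replicate's Abs340 exceeds
#' `theta_high` times the median (carried-over cells inflating the reading).
#'
#' @param records Observation records.
#' @param theta_low,theta_high Multiplicative thresholds (defaults 0.2, 2.0).
#' @return List: `kept` (records), `removed` (records), `report` (data.frame
#'   `design_id, cycle, rule, replicate`).
#' @export
filter_outliers <- function(records, theta_low = 0.2, theta_high = 2.0) {
  key <- paste(records$design_id, records$cycle)
  report <- NULL
  drop_key <- character(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    med_abs <- stats::median(records$Abs340[idx])
    med_od <- stats::median(records$OD600[idx])
    r1 <- records$Abs340[idx] < theta_low * med_abs |
          records$OD600[idx] < theta_low * med_od
    r2 <- records$Abs340[idx] > theta_high * med_abs
    if (any(r1) || any(r2)) {
      drop_key <- c(drop_key, k)
      off <- which(r1 | r2)[1]
      report <- rbind(report, data.frame(
        design_id = records$design_id[idx[1]],
        cycle = records$cycle[idx[1]],
        rule = if (any(r1)) 1L else 2L,
        replicate = records$replicate[idx][off],
        stringsAsFactors = FALSE))
    }
  }
  keep <- !(key %in% drop_key)
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE],
       report = if (is.null(report))
         data.frame(design_id = character(0), cycle = integer(0),
                    rule = integer(0), replicate = integer(0)) else report)
}

#' Campaign configuration
#'
#' @param space A [phase_space()].
#' @param objective `"titer_proxy"` or `"yield_proxy"`.
#' @param cycles Total DBTL cycles (first `initial_cycles` are LHS).
#' @param designs_per_cycle Experimental designs per plate (plus 1 control).
#' @param replicates Replicates per design (3 or 4).
#' @param initial_cycles Number of LHS cycles before active learning.
#' @param capacity Plate capacity.
#' @param seed Campaign seed.
#' @param explore_fractions Optional vector of explore fractions for the
#'   active-learning cycles; default declines linearly from 2/3 to 1/3.
#' @param de_params DE overrides for recommendation runs.
#' @param eps Batch-diversity radius.
#' @param theta_low,theta_high Outlier thresholds.
#' @param members Ensemble roster.
#' @param control Ensemble member hyperparameters.
#' @return List of class `campaign_config`.
#' @export
campaign_config <- function(space, objective = c("titer_proxy", "yield_proxy"),
                            cycles = 5, designs_per_cycle = 15,
                            replicates = 3, initial_cycles = 2,
                            capacity = 48, seed = 1L,
                            explore_fractions = NULL,
                            de_params = list(pop = 20, maxiter = 60),
                            eps = 0.05, theta_low = 0.2, theta_high = 2.0,
                            members = c("gp", "rf", "gbt", "ridge"),
                            control = list()) {
  objective <- match.arg(objective)
  if (!replicates %in% c(3, 4)) stop("replicates must be 3 or 4")
  if ((designs_per_cycle + 1) * replicates > capacity) {
    stop("plate arithmetic: (designs_per_cycle + 1) x replicates exceeds ",
         capacity, " wells")
  }
  n_al <- cycles - initial_cycles
  if (is.null(explore_fractions)) {
    explore_fractions <- if (n_al <= 1) rep(1 / 3, max(n_al, 0))
      else 2 / 3 - (1 / 3) * (seq_len(n_al) - 1) / (n_al - 1)
  }
  structure(list(space = space, objective = objective, cycles = cycles,
                 designs_per_cycle = designs_per_cycle,
                 replicates = replicates, initial_cycles = initial_cycles,
                 capacity = capacity, seed = as.integer(seed),
                 explore_fractions = explore_fractions,
                 de_params = de_params, eps = eps,
                 theta_low = theta_low, theta_high = theta_high,
                 members = members, control = control),
            class = "campaign_config")
}

#' Run a simulated DBTL campaign
#'
#' Full Design-Build-Test-Learn loop against the synthetic response surface:
#' the initial cycles use Latin-hypercube designs (one LHS batch split across
#' them), each subsequent cycle filters outliers from all accumulated
#' observations, fits the ensemble on them, records the cross-validated R2,
#' and recommends the next batch (declining explore fraction, scheduled
#' alpha). Jittered control designs ride along on every plate.
#' Recommendations for cycle N are produced strictly from the observations
#' of cycles 1..N-1. With fixed seeds the whole campaign is bit-stable.
#'
#' @param config A [campaign_config()].
#' @param sim A [make_default_simulator()] (the Test-step stand-in).
#' @param out_dir Optional directory: per-cycle designs, observations and a
#'   final attribution table are written beneath it.
#' @param attribution Compute exact Shapley attribution of the final model?
#' @param attribution_points Cap on the number of explained observations
#'   (a deterministic subsample keeps the attribution cost bounded on long
#'   campaigns); `Inf` explains every training point.
#' @param compute_r2 Record the cross-validated R2 each learning cycle?
#'   (Adds a k-fold refit per cycle.)
#' @return An object of class `campaign_result`: `records` (all
#'   observations), `cycle_info` (per-cycle data.frame with R2 and best
#'   response), `model` (final ensemble), `attribution`, `best` (best
#'   experimental design row), `config`.
#' @export
run_campaign <- function(config, sim, out_dir = NULL, attribution = TRUE,
                         attribution_points = 100, compute_r2 = TRUE) {
  stopifnot(inherits(config, "campaign_config"))
  space <- config$space
  seed <- config$seed
  n_init <- config$designs_per_cycle * config$initial_cycles
  init <- lhs_design(space, n_init, seed = seed)
  init_batches <- split_cycles(init, rep(config$designs_per_cycle,
                                         config$initial_cycles))
  records <- NULL
  cycle_info <- NULL
  next_batch <- NULL
  model <- NULL
  for (N in seq_len(config$cycles)) {
    batch <- if (N <= config$initial_cycles) init_batches[[N]] else next_batch
    batch$design_id <- paste0("c", N, "_", batch$design_id)
    control <- jitter_control(space, seed = seed + 7919L * N,
                              n_replicates = config$replicates, cycle = N)
    ## Test: simulate replicate measurements for designs and control wells
    meas <- observe(sim, batch, n_replicates = config$replicates,
                    mode = config$objective, seed = seed + 104729L * N)
    ctrl_meas <- observe(sim, control, n_replicates = 1,
                         mode = config$objective, seed = seed + 130003L * N)
    records <- rbind(records,
                     make_records(batch, meas, N),
                     make_records(control, ctrl_meas, N))
    if (!is.null(out_dir)) {
      cyc_dir <- file.path(out_dir, paste0("cycle", N))
      dir.create(cyc_dir, recursive = TRUE, showWarnings = FALSE)
      write_designs(batch, file.path(cyc_dir, "designs.csv"))
      write_observations(records, file.path(cyc_dir, "observations.csv"))
      plate <- rbind_batches(batch, control)
      lay <- layout_plate(nrow(batch$conc), config$replicates,
                          capacity = config$capacity, control = TRUE,
                          design_id = batch$design_id)
      ## jittered control replicates are distinct designs: remap the control
      ## block wells to them one-to-one
      ctrl_wells <- lay$design_id == "control"
      lay$design_id[ctrl_wells] <- control$design_id
      lay$replicate[ctrl_wells] <- 1L
      plan <- compile_plate(plate, lay, stock_table(space))
      write_worklist(plan, file.path(cyc_dir, "worklist.csv"))
    }
    ## Learn + Design for the next cycle (never reads cycle N+1 data: only
    ## `records`, which holds cycles 1..N)
    flt <- filter_outliers(records, config$theta_low, config$theta_high)
    obs <- as_observation_set(flt$kept, space, config$objective)
    r2 <- NA_real_
    if (N >= config$initial_cycles && N < config$cycles) {
      model <- fit_ensemble(obs, space = space, seed = seed + 15485863L * N,
                            members = config$members,
                            control = config$control)
      r2 <- if (!compute_r2) NA_real_ else tryCatch(
        cross_validated_r2(obs, space = space, seed = seed + N,
                           members = config$members,
                           control = config$control),
        error = function(e) NA_real_)
      ef <- config$explore_fractions[N - config$initial_cycles + 1L]
      alpha <- alpha_schedule(N + 1L, config$cycles)
      next_batch <- recommend_batch(model, space,
                                    K = config$designs_per_cycle,
                                    alpha = alpha, explore_fraction = ef,
                                    eps = config$eps,
                                    seed = seed + 32452843L * N,
                                    de_params = config$de_params, cycle = N + 1L)
    }
    exp_rows <- records$role != "control"
    cycle_info <- rbind(cycle_info, data.frame(
      cycle = N, n_obs = length(obs$y), n_removed = nrow(flt$removed),
      cv_r2 = r2,
      best_response = max(stats::aggregate(
        if (config$objective == "yield_proxy")
          records$Abs340[exp_rows] / records$glucose[exp_rows]
        else records$Abs340[exp_rows],
        list(records$design_id[exp_rows]), mean)$x)))
  }
  ## final model on everything, for attribution
  flt <- filter_outliers(records, config$theta_low, config$theta_high)
  obs <- as_observation_set(flt$kept, space, config$objective)
  model <- fit_ensemble(obs, space = space, seed = seed,
                        members = config$members, control = config$control)
  attr_res <- NULL
  if (attribution) {
    n_exp <- min(attribution_points, nrow(obs$X))
    idx <- if (n_exp < nrow(obs$X)) {
      with_seed(seed, sort(sample(nrow(obs$X), n_exp)))
    } else seq_len(nrow(obs$X))
    attr_res <- shapley_values(model, X_background = obs$X,
                               X_explain = obs$X[idx, , drop = FALSE],
                               method = "exact")
    if (!is.null(out_dir)) {
      attribution_table(attr_res, file.path(out_dir, "attribution.csv"))
    }
  }
  ## best experimental design by mean measured response
  exp_rec <- records[records$role != "control", , drop = FALSE]
  resp <- if (config$objective == "yield_proxy")
    exp_rec$Abs340 / exp_rec$glucose else exp_rec$Abs340
  agg <- stats::aggregate(resp, list(design_id = exp_rec$design_id), mean)
  best_id <- agg$design_id[which.max(agg$x)]
  best_row <- exp_rec[match(best_id, exp_rec$design_id), , drop = FALSE]
  structure(list(records = records, cycle_info = cycle_info, model = model,
                 attribution = attr_res, best = best_row,
                 best_mean_response = max(agg$x), config = config),
            class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  cat("DBTL campaign: ", x$config$cycles, " cycles, objective ",
      x$config$objective, "\n", sep = "")
  print(x$cycle_info, row.names = FALSE)
  cat("Best design:", x$best$design_id, "mean response",
      signif(x$best_mean_response, 4), "\n")
  invisible(x)
}

#' Between-cycle control repeatability
#'
#' Coefficient of variation of the per-cycle mean control response — the
#' repeatability statistic tracked on every campaign plate.
#' @param records Observation records including control rows (`role ==
#'   "control"` or design ids starting with `control`).
#' @return CV (sd/mean) across cycles.
#' @export
control_cv <- function(records) {
  is_ctrl <- if (!is.null(records$role)) records$role == "control"
             else grepl("^control", records$design_id)
  ctrl <- records[is_ctrl, , drop = FALSE]
  if (nrow(ctrl) < 2) stop("need control records from at least two cycles")
  m <- stats::aggregate(ctrl$Abs340, list(cycle = ctrl$cycle), mean)
  stats::sd(m$x) / mean(m$x)
}

#' PCA of explored media designs
#'
#' Principal component analysis of the unit-scaled design concentrations
#' across a campaign; reports the variance explained by the leading
#' components (how concentrated the explored trajectory is).
#'
#' @param records Observation records.
#' @param space A [phase_space()].
#' @param k Number of leading components to report.
#' @return List: `explained` (fraction of total variance in the first `k`
#'   PCs), `pca` (the `prcomp` object), `scores` (design scores).
#' @export
design_pca <- function(records, space, k = 2) {
  X <- as.matrix(records[, variable_names(space), drop = FALSE])
  U <- unit_scale(space, X)
  p <- stats::prcomp(U, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  list(explained = sum(v[seq_len(min(k, length(v)))]) / sum(v),
       pca = p, scores = p$x)
}
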