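make_toy_records <- function(n = 4, cycle = 1L, abs = NULL, od = NULL) {
  conc <- matrix(rep(mops$components$base, each = n), n,
                 dimnames = list(NULL, mops$components$name))
  data.frame(conc,
             Abs340 = if (is.null(abs)) rep(1, n) else abs,
             OD600 = if (is.null(od)) rep(1, n) else od,
             cycle = cycle, replicate = seq_len(n),
             design_id = "dX", check.names = FALSE,
             stringsAsFactors = FALSE)
}

test_that("observation CSVs round-trip losslessly with passthrough columns", {
  sim <- make_default_simulator(mops)
  batch <- lhs_design(mops, 5, seed = 2)
  meas <- observe(sim, batch, 2, seed = 4)
  rec <- medialearn:::make_records(batch, meas, cycle = 1L)
  rec$note <- paste0("meta", seq_len(nrow(rec)))  # unknown column
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(rec, path)
  back <- read_observations(path, mops)
  expect_equal(back$Abs340, rec$Abs340, tolerance = 1e-12)
  expect_equal(back$note, rec$note)
  expect_equal(as.matrix(back[, mops$components$name]),
               as.matrix(rec[, mops$components$name]), tolerance = 1e-12)

  # schema errors list the missing columns
  broken <- rec[, setdiff(names(rec), c("NaCl", "OD600"))]
  write_observations(broken, path)
  expect_error(read_observations(path, mops), "NaCl.*OD600|OD600.*NaCl")
})

test_that("outlier rules drop failed and contaminated replicate sets", {
  ok <- make_toy_records(3, abs = c(1, 1.02, 0.98))
  f <- filter_outliers(ok)
  expect_equal(nrow(f$kept), 3)
  expect_equal(nrow(f$report), 0)

  # rule 1: a replicate with no product or biomass
  dead <- make_toy_records(3, abs = c(1, 1, 0))
  f1 <- filter_outliers(dead)
  expect_equal(nrow(f1$kept), 0)
  expect_equal(f1$report$rule, 1L)

  dead_od <- make_toy_records(3, od = c(1, 1, 0.05))
  expect_equal(filter_outliers(dead_od)$report$rule, 1L)

  # rule 2: one replicate far above its siblings
  hot <- make_toy_records(3, abs = c(1, 1, 3))
  f2 <- filter_outliers(hot)
  expect_equal(nrow(f2$kept), 0)
  expect_equal(f2$report$rule, 2L)

  # threshold boundary: 2x the median is kept at theta_high = 2
  edge <- make_toy_records(3, abs = c(1, 1, 2))
  expect_equal(nrow(filter_outliers(edge)$kept), 3)

  # kept + removed partition the input exactly
  both <- rbind(make_toy_records(3, cycle = 1L),
                transform(make_toy_records(3, cycle = 2L,
                                           abs = c(1, 1, 0)),
                          design_id = "dY"))
  fb <- filter_outliers(both)
  expect_equal(nrow(fb$kept) + nrow(fb$removed), nrow(both))
  expect_equal(sort(c(rownames(fb$kept), rownames(fb$removed))),
               sort(rownames(both)))
})

test_that("yield objective divides the proxy by initial glucose", {
  spy <- mops_phase_space(glucose_variable = TRUE)
  rec <- make_toy_records(2)
  rec$glucose <- c(10, 20)
  obs <- as_observation_set(rec, spy, mode = "yield_proxy")
  expect_equal(obs$y, rec$Abs340 / c(10, 20))
  expect_equal(ncol(obs$X), 13)
})

test_that("control CV and design PCA summarize a campaign's records", {
  sim <- make_default_simulator(mops)
  recs <- NULL
  for (cyc in 1:3) {
    ctrl <- jitter_control(mops, seed = cyc, n_replicates = 3, cycle = cyc)
    meas <- observe(sim, ctrl, 1, seed = 100 + cyc)
    recs <- rbind(recs, medialearn:::make_records(ctrl, meas, cyc))
  }
  cv <- control_cv(recs)
  expect_gt(cv, 0)
  expect_lt(cv, 0.15)  # controls jittered by 10%, noise CV 10%

  batch <- lhs_design(mops, 30, seed = 9)
  m <- observe(sim, batch, 1, seed = 9)
  rec2 <- medialearn:::make_records(batch, m, 1L)
  p <- design_pca(rec2, mops, k = 2)
  expect_gt(p$explained, 0)
  expect_lte(p$explained, 1)
  expect_equal(nrow(p$scores), 30)
})

test_that("a short simulated campaign is bit-stable and leak-free", {
  cfg <- campaign_config(mops, cycles = 3, designs_per_cycle = 5,
                         replicates = 3, seed = 31,
                         de_params = list(pop = 10, maxiter = 12))
  sim <- make_default_simulator(mops)
  r1 <- run_campaign(cfg, sim, attribution = FALSE, compute_r2 = FALSE)
  r2 <- run_campaign(cfg, sim, attribution = FALSE, compute_r2 = FALSE)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$cycle_info, r2$cycle_info)

  # cycle-3 training data are exactly the kept records of cycles 1-2
  rec12 <- r1$records[r1$records$cycle <= 2, ]
  expect_equal(sum(r1$records$cycle == 3),
               (5 + 1) * 3)  # 5 designs + control, 3 replicates
  # recommended designs carry the cycle-3 label and stay in bounds
  c3 <- r1$records[r1$records$cycle == 3 & r1$records$role != "control", ]
  tab <- mops$components
  for (j in mops$variable) {
    expect_true(all(c3[[tab$name[j]]] >= tab$lower[j] - 1e-9))
    expect_true(all(c3[[tab$name[j]]] <= tab$upper[j] + 1e-9))
  }
  # control designs present in every cycle
  expect_equal(sort(unique(r1$records$cycle[r1$records$role == "control"])),
               1:3)
})

test_that("campaign artifacts are written under the output directory", {
  cfg <- campaign_config(mops, cycles = 2, designs_per_cycle = 4,
                         replicates = 3, seed = 5)
  sim <- make_default_simulator(mops)
  out <- withr::local_tempdir()
  res <- run_campaign(cfg, sim, out_dir = out, attribution = TRUE,
                      attribution_points = 10, compute_r2 = FALSE)
  expect_true(file.exists(file.path(out, "cycle1", "designs.csv")))
  expect_true(file.exists(file.path(out, "cycle1", "worklist.csv")))
  expect_true(file.exists(file.path(out, "cycle2", "observations.csv")))
  expect_true(file.exists(file.path(out, "attribution.csv")))
  wl <- read_worklist(file.path(out, "cycle1", "worklist.csv"))
  # 4 designs x 3 + 3 control wells, 15 components each + inoculum + water
  expect_equal(length(unique(wl$DestWell)), 15)
})

test_that("the CLI drives design, compile and attribution end to end", {
  tmp <- withr::local_tempdir()
  media <- file.path(tmp, "media.csv")
  write_media_spec(mops, media)

  designs <- file.path(tmp, "designs.csv")
  s1 <- medialearn_cli(c("init-design", "--media", media, "--n", "6",
                         "--seed", "3", "--out", designs))
  expect_equal(s1, 0L)
  d1 <- read_designs(designs, mops)
  expect_equal(nrow(d1$conc), 6)
  # same seed twice gives identical output
  designs2 <- file.path(tmp, "designs2.csv")
  medialearn_cli(c("init-design", "--media", media, "--n", "6",
                   "--seed", "3", "--out", designs2))
  expect_identical(readLines(designs), readLines(designs2))

  wl <- file.path(tmp, "worklist.csv")
  s2 <- medialearn_cli(c("compile", "--media", media, "--designs", designs,
                         "--replicates", "3", "--out", wl))
  expect_equal(s2, 0L)
  expect_equal(length(unique(read_worklist(wl)$DestWell)), 18)

  expect_equal(suppressMessages(medialearn_cli(c("no-such-command"))), 2L)
  expect_equal(suppressWarnings(suppressMessages(
    medialearn_cli(c("compile", "--media", "/nonexistent")))), 1L)
})
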