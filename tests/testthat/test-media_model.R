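test_that("component and phase-space invariants are enforced", {
  expect_error(media_component("X", base = 5, lower = 6, upper = 10,
                               solubility = 20), "lower <= base")
  expect_error(media_component("X", base = 5, lower = 1, upper = 10,
                               solubility = 8), "solubility")
  expect_error(media_component("X", base = 5, lower = 1, upper = 10,
                               solubility = 20, fixed = TRUE), "fixed")
  expect_error(phase_space(data.frame(
    name = c("A", "A"), base = 1, lower = 1, upper = 1, solubility = 1,
    fixed = TRUE, unit = "mM")), "duplicate|variable")
  expect_equal(mops$d, 12)
  expect_equal(mops_yield$d, 13)
})

test_that("stock pairs follow the solubility-capped reference-volume rule", {
  nacl <- media_component("NaCl", 50, 5, 500, 5000)
  sp <- compute_stock_pair(nacl, v_min = 5, v_ref = 150, final_volume = 1500)
  # 500 * 1500 / 150 = 5000, exactly the solubility cap
  expect_equal(sp$high_stock, 5000)
  expect_equal(sp$low_stock, 250)

  fixed <- media_component("MOPS", 40, 40, 40, 1000, fixed = TRUE)
  spf <- compute_stock_pair(fixed)
  # degenerate bounds: the high stock delivers base at exactly v_ref
  expect_equal(volume_for_target(40, spf$high_stock, 1500), 150)

  # a bound table violating upper <= solubility cannot pass the constructor;
  # the compiler still reports the limiting constraint defensively
  sol_bound <- structure(list(name = "X", base = 10, lower = 1, upper = 100,
                              solubility = 50, fixed = FALSE, unit = "mM"),
                         class = "media_component")
  expect_error(compute_stock_pair(sol_bound), "solubility limit")
})

test_that("every MOPS bound endpoint is deliverable from its stock pair", {
  # brute-force feasibility: for each component, both bound endpoints must be
  # deliverable from at least one stock within [v_min, final_volume]
  st <- stock_table(mops)
  tab <- mops$components
  v_min <- 5; final <- 1500
  for (i in seq_len(nrow(tab))) {
    for (target in c(tab$lower[i], tab$upper[i])) {
      if (target == 0) next
      vols <- target * final / c(st$high_stock[i], st$low_stock[i])
      ok <- any(vols >= v_min & vols <= final)
      expect_true(ok, info = paste(tab$name[i], "at", target))
    }
  }
  expect_true(all(st$low_stock < st$high_stock))
  expect_true(all(st$high_stock <= tab$solubility))
})

test_that("volume_for_target is the dilution identity", {
  expect_equal(volume_for_target(460, 4600, 1500), 150)
  expect_equal(volume_for_target(0, 4600, 1500), 0)
  expect_equal(volume_for_target(50, 5000, 1500), 15)
  expect_error(volume_for_target(10, 5, 1500), "infeasible dilution")
})

test_that("plate layout reproduces the 48-well plate arithmetic", {
  l3 <- layout_plate(15, 3, 48, control = TRUE)
  expect_equal(nrow(l3), 48)
  expect_equal(sum(l3$design_id == "control"), 3)
  # control occupies the final replicate block
  expect_equal(l3$well[l3$design_id == "control"], c("F6", "F7", "F8"))
  expect_false(anyDuplicated(l3$well) > 0)

  l4 <- layout_plate(11, 4, 48, control = TRUE)
  expect_equal(nrow(l4), 48)
  expect_equal(l4$well[l4$design_id == "control"], c("F5", "F6", "F7", "F8"))

  expect_error(layout_plate(16, 3, 48, control = TRUE), "capacity")
  # every design occupies exactly `replicates` wells
  expect_true(all(table(l3$design_id) == 3))
})

test_that("compiled plans conserve volume and reproduce targets exactly", {
  set.seed(42)
  batch <- lhs_design(mops, 10, seed = 42)
  lay <- layout_plate(10, 3, 48, control = FALSE,
                      design_id = batch$design_id)
  st <- stock_table(mops)
  plan <- compile_plate(batch, lay, st)

  # volume conservation, exact
  per_well <- tapply(plan$transfers$volume, plan$transfers$dest_well, sum)
  expect_true(all(abs(per_well - 1500) < 1e-9))

  # concentration fidelity from independent re-simulation of mixing
  rc <- realized_concentrations(plan, st)
  targets <- batch$conc[match(lay$design_id, batch$design_id), ]
  rel <- abs(rc[lay$well, ] - targets) / pmax(targets, 1e-300)
  expect_lt(max(rel), 1e-9)

  # one inoculum and one water transfer per well
  expect_equal(sum(plan$transfers$source_label == "inoculum"), nrow(lay))
  expect_equal(sum(plan$transfers$source_label == "water"), nrow(lay))
})

test_that("a zero-concentration design needs only fixed components plus carriers", {
  space0 <- phase_space(data.frame(
    name = c("A", "F"), base = c(5, 2), lower = c(0, 2), upper = c(50, 2),
    solubility = c(500, 100), fixed = c(FALSE, TRUE), unit = "mM"))
  b <- design_batch(space0, matrix(c(0, 2), 1))
  lay <- layout_plate(1, 1, 48, control = FALSE, design_id = b$design_id)
  plan <- compile_plate(b, lay, stock_table(space0))
  expect_setequal(unique(plan$transfers$source_label),
                  c("F_high", "inoculum", "water"))
  expect_equal(sum(plan$transfers$volume), 1500)
})

test_that("transfer volume is monotone in the target at fixed stock choice", {
  st <- stock_table(mops)
  i <- match("NaCl", st$component)
  targets <- seq(5, 500, length.out = 50)
  vols <- volume_for_target(targets, st$high_stock[i], 1500)
  expect_true(all(diff(vols) > 0))
})

test_that("worklists round-trip at the printed precision", {
  batch <- lhs_design(mops, 2, seed = 7)
  lay <- layout_plate(2, 1, 48, control = FALSE, design_id = batch$design_id)
  plan <- compile_plate(batch, lay, stock_table(mops))
  path <- withr::local_tempfile(fileext = ".csv")
  write_worklist(plan, path)
  wl <- read_worklist(path)
  expect_equal(nrow(wl), nrow(plan$transfers))
  expect_equal(wl$DestWell, plan$transfers$dest_well)
  expect_equal(wl$VolumeUL, round(plan$transfers$volume, 2))

  # empty plan: header-only file
  empty <- plan
  empty$transfers <- plan$transfers[0, ]
  write_worklist(empty, path)
  expect_equal(nrow(read_worklist(path)), 0)
  expect_equal(length(readLines(path)), 1L)
})

test_that("a full-scale triplicate plate needs on the order of 800 transfers", {
  batch <- lhs_design(mops, 15, seed = 1)
  ctrl <- jitter_control(mops, seed = 2, n_replicates = 3, cycle = 1L)
  lay <- layout_plate(15, 3, 48, control = TRUE, design_id = batch$design_id)
  lay$design_id[lay$design_id == "control"] <- ctrl$design_id
  plate <- medialearn:::rbind_batches(batch, ctrl)
  plan <- compile_plate(plate, lay, stock_table(mops))
  n_tr <- nrow(plan$transfers)
  expect_gte(n_tr, 720)
  expect_lte(n_tr, 864)
})

test_that("design CSV round-trips through read_designs", {
  batch <- lhs_design(mops, 5, seed = 3, cycle = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_designs(batch, path)
  back <- read_designs(path, mops)
  expect_equal(back$conc, batch$conc, tolerance = 1e-12)
  expect_equal(back$design_id, batch$design_id)
  expect_error(read_designs(path, tiny_space), "missing component")
})
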