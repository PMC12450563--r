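test_that("degenerate schedules behave as forced", {
  # no fertility: founders only
  cfg <- simulation_config(seed = 1, years = 10, n0_female = 20,
                           n0_male = 20, fertility = rep(0, 22))
  sim <- simulate_studbook(cfg)
  expect_equal(nrow(sim$studbook$records), 40L)
  expect_true(all(is.na(sim$studbook$records$dam_id)))

  # immortality without births: population constant
  cfg2 <- simulation_config(seed = 2, years = 15, n0_female = 25,
                            n0_male = 25, fertility = rep(0, 22),
                            survival = rep(1, 22))
  sim2 <- simulate_studbook(cfg2)
  expect_equal(nrow(sim2$studbook$records), 50L)
  expect_true(all(sim2$studbook$records$status == "alive"))
})

test_that("identical seeds give identical studbooks", {
  cfg <- simulation_config(seed = 33, years = 25, n0_female = 60,
                           n0_male = 60)
  a <- simulate_studbook(cfg)
  b <- simulate_studbook(cfg)
  expect_identical(a$studbook$records, b$studbook$records)
  c <- simulate_studbook(simulation_config(seed = 34, years = 25,
                                           n0_female = 60, n0_male = 60))
  expect_false(identical(a$studbook$records, c$studbook$records))
})

test_that("the realised growth rate matches the calibrated stationarity", {
  finals <- vapply(1:8, function(s) {
    cfg <- simulation_config(seed = s, years = 40, n0_female = 150,
                             n0_male = 150)
    sim <- simulate_studbook(cfg)
    rec <- sim$studbook$records
    ref <- popshape:::year_end(1999)
    sum(rec$birth_date <= ref & (is.na(rec$death_date) | rec$death_date > ref))
  }, numeric(1))
  # 40 years at lambda = 1: mean final size stays near the founding 300
  expect_gt(mean(finals), 300 * 0.7)
  expect_lt(mean(finals), 300 * 1.4)
})

test_that("simulated studbooks are clean under curation and recover truth", {
  sim <- simulate_studbook(simulation_config(seed = 8, years = 45,
                                             n0_female = 150, n0_male = 150))
  res <- run_curation(sim$studbook, seed = 9)
  expect_equal(nrow(res$report), 0L)
  expect_equal(unname(res$afr["female"]), sim$truth$afr)
  st <- estimate_life_stages(res$studbook)
  expect_lte(abs(st$female$senescence_onset - sim$truth$senescence_onset), 1)
})

test_that("error injection is exact bookkeeping and zero when disabled", {
  sim <- simulate_studbook(simulation_config(seed = 14, years = 35,
                                             n0_female = 100, n0_male = 100))
  none <- inject_errors(sim$studbook, counts = c(self_parent = 0), seed = 1)
  expect_identical(none$studbook$records, sim$studbook$records)
  expect_length(none$truth, 0L)

  five <- inject_errors(sim$studbook, counts = c(self_parent = 5), seed = 1)
  expect_length(five$truth$self_parent, 5L)
  rec <- five$studbook$records
  expect_equal(sum(rec$dam_id == rec$individual_id, na.rm = TRUE), 5L)

  expect_error(inject_errors(sim$studbook, counts = c(alien_abduction = 1),
                             seed = 1), "unknown error type")
})

test_that("curation after injection repairs exactly the injected truth list", {
  sim <- simulate_studbook(simulation_config(seed = 15, years = 35,
                                             n0_female = 120, n0_male = 120))
  inj <- inject_errors(sim$studbook,
                       counts = c(same_sex_parents = 8, self_parent = 8,
                                  swapped_dam_sire = 8), seed = 16)
  res <- run_curation(inj$studbook, seed = 17)
  rep <- res$report
  expect_setequal(rep$individual_id[rep$rule == "same_sex_parents"],
                  inj$truth$same_sex_parents)
  expect_setequal(rep$individual_id[rep$rule == "self_parentage"],
                  inj$truth$self_parent)
  expect_setequal(rep$individual_id[rep$rule == "dam_sire_swapped"],
                  inj$truth$swapped_dam_sire)
  expect_setequal(unique(rep$rule),
                  c("same_sex_parents", "self_parentage", "dam_sire_swapped"))
})

test_that("the scenario library ships the documented presets", {
  lib <- scenario_library(seed = 2)
  expect_true(all(c("steady_state", "reproduction_halt", "halt_then_resume",
                    "low_mortality_reduced_reproduction", "high_resilience",
                    "low_resilience") %in% names(lib)))
  expect_s3_class(lib$steady_state, "simulation_config")
  halt <- lib$reproduction_halt$events
  expect_equal(halt[[1]]$type, "halt_reproduction")
})

test_that("a steady-state population classifies mostly as pyramid", {
  sim <- simulate_studbook(scenario_library(seed = 4, n0 = 300)$steady_state)
  sb <- run_curation(sim$studbook, seed = 5)$studbook
  st <- estimate_life_stages(sb)
  ser <- build_series(sb, st, years = 1965:2019)
  e <- ser$entries[ser$entries$shape != "not_ascribed", ]
  expect_gt(mean(e$shape == "pyramid"), 0.5)
})

test_that("halting and resuming reproduction produces an hourglass phase", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_studbook(scenario_library(seed = s)$halt_then_resume)
    sb <- run_curation(sim$studbook, seed = s + 50)$studbook
    st <- estimate_life_stages(sb)
    ser <- build_series(sb, st, years = 2008:2024)
    any(ser$entries$shape[ser$entries$sex == "female"] == "hourglass")
  }, logical(1))
  expect_gte(sum(hits), 3L)
})
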