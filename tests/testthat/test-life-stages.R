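days <- function(y) round(y * 365.25)

test_that("AFR is the floored minimum parent age, with override precedence", {
  t0 <- as.Date("1980-01-01")
  rows <- list()
  for (i in seq_along(c(3.2, 4.1, 5.0))) {
    age <- c(3.2, 4.1, 5.0)[i]
    rows <- c(rows, list(
      rec_row(sprintf("F%d", i), "female", as.character(t0)),
      rec_row(sprintf("K%d", i), birth = as.character(t0 + days(age)),
              dam = sprintf("F%d", i))
    ))
  }
  sb <- make_studbook(rows)
  expect_equal(estimate_afr(sb, "female"), 3)
  expect_error(estimate_afr(sb, "male"), "afr_override")

  cfg <- test_config(afr_override = list(female = 4))
  sb$species <- cfg
  expect_equal(estimate_afr(sb, "female"), 4)
})

test_that("reproduction probabilities condition on breeders alive at that age", {
  t0 <- as.Date("1980-01-01")
  breeder <- function(id, repro_ages, death_age = NA) {
    c(list(rec_row(id, "female", as.character(t0),
                   death = if (is.na(death_age)) NA else
                     as.character(t0 + days(death_age)))),
      lapply(seq_along(repro_ages), function(j)
        rec_row(paste0(id, "k", j),
                birth = as.character(t0 + days(repro_ages[j] + 0.4)),
                dam = id)))
  }
  # 10 proven breeders, 4 reproducing at age 5, all alive then
  rows <- c(lapply(1:4, function(i) breeder(paste0("A", i), 5)),
            lapply(1:6, function(i) breeder(paste0("B", i), 7)))
  sb <- make_studbook(do.call(c, rows))
  prof <- reproduction_profile(sb, "female")
  expect_equal(prof$n_breeders, 10L)
  expect_equal(prof$probabilities[prof$ages == 5], 0.4)

  # a breeder dead before age 8 leaves the denominator at age 8
  rows2 <- do.call(c, list(breeder("A", 8), breeder("B", 8),
                           breeder("C", 4, death_age = 6),
                           breeder("D", 4), breeder("E", 4)))
  sb2 <- make_studbook(rows2)
  prof2 <- reproduction_profile(sb2, "female")
  expect_equal(prof2$probabilities[prof2$ages == 8], 2 / 4)

  # a single breeder reproducing at 3 and 4
  sb3 <- make_studbook(do.call(c, list(breeder("A", c(3, 4)))))
  prof3 <- reproduction_profile(sb3, "female")
  expect_equal(prof3$probabilities[prof3$ages %in% c(3, 4)], c(1, 1))

  expect_error(reproduction_profile(make_studbook(list(rec_row("X"))),
                                    "female"), "breeders")
})

test_that("the gamma fit recovers generating parameters", {
  ages <- 0:30
  p <- 0.8 * stats::dgamma(ages + 0.5, shape = 4, scale = 2)
  fit <- fit_gamma(list(ages = ages, probabilities = p))
  expect_lt(abs(fit$k - 4) / 4, 0.01)
  expect_lt(abs(fit$theta - 2) / 2, 0.01)
  expect_lt(abs(fit$amplitude - 0.8) / 0.8, 0.01)
  expect_equal(fit$mode, (fit$k - 1) * fit$theta)
  expect_equal(unname(coef(fit)["k"]), fit$k)
  expect_equal(predict(fit), fit$fitted)

  withr::with_seed(42, {
    noisy <- pmax(0, p + stats::rnorm(length(p), 0, 0.02))
    fit2 <- fit_gamma(list(ages = ages, probabilities = noisy))
    expect_lt(abs(fit2$mode - 6), 0.5)
  })

  expect_error(fit_gamma(list(ages = ages, probabilities = ages * 0)),
               "zero")
  expect_error(fit_gamma(list(ages = 0:5,
                              probabilities = c(0, 1, 0, 0, 0, 0))),
               "manual")
})

gamma_fit_obj <- function(k, theta) {
  structure(list(k = k, theta = theta, amplitude = 1,
                 mode = if (k > 1) (k - 1) * theta else 0,
                 rss = 0, ages = 0:30, observed = NULL, fitted = NULL),
            class = "repro_gamma")
}

test_that("senescence onset follows the right-tail rule", {
  cfg <- test_config()
  # exponential case, closed form: theta * log(1/0.75) = 1.1507 -> class 2
  expect_equal(senescence_onset(gamma_fit_obj(1, 4), cfg), 2L)

  # k = 2, theta = 3 against an independent dense-grid oracle
  oracle <- local({
    mode <- 3; peak <- stats::dgamma(mode, 2, scale = 3)
    x <- seq(mode, 60, by = 0.001)
    ceiling(x[stats::dgamma(x, 2, scale = 3) <= 0.75 * peak][1])
  })
  expect_equal(senescence_onset(gamma_fit_obj(2, 3), cfg), as.integer(oracle))

  # tail fraction 1 collapses to the mode
  cfg1 <- test_config(gamma_tail_fraction = 1)
  expect_equal(senescence_onset(gamma_fit_obj(4, 2), cfg1), 6L)

  # smaller fraction, later onset
  onsets <- vapply(c(0.9, 0.75, 0.5, 0.25), function(f) {
    senescence_onset(gamma_fit_obj(4, 2), test_config(gamma_tail_fraction = f))
  }, integer(1))
  expect_true(all(diff(onsets) >= 0))

  # configured override wins
  cfg_ov <- test_config(senescence_override = list(female = 9))
  expect_equal(senescence_onset(gamma_fit_obj(4, 2), cfg_ov, "female"), 9)
})

test_that("bucket boundaries partition the age classes", {
  th <- bucket_boundaries(4, 13, 20)
  expect_equal(th$buckets$from, c(0L, 4L, 7L, 10L, 13L))
  expect_equal(th$buckets$to, c(4L, 7L, 10L, 13L, 21L))

  th2 <- bucket_boundaries(2, 6, 10)
  expect_equal(th2$buckets$from, c(0L, 2L, 4L, 5L, 6L))
  expect_equal(th2$buckets$to, c(2L, 4L, 5L, 6L, 11L))

  expect_error(bucket_boundaries(5, 7, 20), "three years")

  withr::with_seed(1, {
    for (i in 1:50) {
      afr <- sample(1:6, 1)
      onset <- afr + sample(3:9, 1)
      maxl <- onset + sample(0:12, 1)
      b <- bucket_boundaries(afr, onset, maxl)$buckets
      expect_equal(b$from[1], 0L)
      expect_equal(b$to[5], maxl + 1L)
      expect_equal(b$from[-1], b$to[-5])             # no gaps, no overlap
      expect_equal(sum(b$to - b$from), maxl + 1L)    # all classes covered
      expect_true(all(b$to > b$from))
    }
  })
})

test_that("life stages are estimated per sex and round-trip as YAML", {
  sim <- simulate_studbook(simulation_config(seed = 3, years = 45,
                                             n0_female = 150, n0_male = 150))
  sb <- run_curation(sim$studbook, seed = 4)$studbook
  st <- estimate_life_stages(sb)
  expect_s3_class(st$female, "life_stage_thresholds")
  expect_equal(st$female$afr, sim$truth$afr)
  expect_lte(abs(st$female$senescence_onset - sim$truth$senescence_onset), 1)

  path <- withr::local_tempfile(fileext = ".yaml")
  write_life_stages(st, path)
  back <- read_life_stages(path)
  expect_equal(back$female$buckets, st$female$buckets)
  expect_equal(back$male$buckets, st$male$buckets)
})
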