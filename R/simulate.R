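# Seeded individual-based studbook simulator.
#
# Discrete yearly time steps: each female of reproductive age produces a
# litter with her age-specific fertility, litter size is drawn from the
# configured distribution, the sire is drawn uniformly among living
# reproductive-age males, and every individual survives each year with its
# age-specific probability. All events become dated studbook rows with
# fully known parentage, so the simulator provides ground truth for the
# curation, life-stage, and classification modules.

#' Age-specific fertility schedule of gamma form
#'
#' Annual probability that a female produces a litter:
#' `peak * dgamma(a + 0.5, k, scale = theta) / max(...)`, zeroed below the
#' age of first reproduction. This mirrors the hump-shaped reproduction
#' profiles the life-stage estimator assumes.
#'
#' @param k,theta Gamma shape and scale (years).
#' @param peak Annual litter probability at the schedule's maximum.
#' @param afr First reproductive age (whole years).
#' @param max_age Highest age class in the schedule.
#' @return Numeric vector over age classes `0..max_age`.
#' @export
fertility_gamma <- function(k, theta, peak, afr, max_age) {
  ages <- 0:max_age
  g <- stats::dgamma(ages + 0.5, shape = k, scale = theta)
  f <- peak * g / max(g)
  f[ages < afr] <- 0
  f
}

#' Analytic senescence onset of a gamma fertility schedule
#'
#' Independent dense-grid oracle for the right-tail rule: the smallest
#' whole age class at or past the mode where the gamma density has fallen
#' to `frac` of its maximum, located by scanning a 0.001-year grid.
#'
#' @inheritParams fertility_gamma
#' @param frac Tail fraction (default 0.75).
#' @return Onset age in whole years.
#' @export
gamma_onset_oracle <- function(k, theta, frac = 0.75) {
  stopifnot(k > 1)
  mode <- (k - 1) * theta
  peak <- stats::dgamma(mode, shape = k, scale = theta)
  x <- seq(mode, mode + 50 * theta, by = 0.001)
  cross <- x[stats::dgamma(x, shape = k, scale = theta) <= frac * peak][1]
  as.integer(ceiling(round(cross, 9)))
}

# Fertility peak giving a stationary population (net reproductive rate 1)
# under the survival schedule, sex ratio and mean litter size.
calibrate_peak <- function(k, theta, afr, survival, sex_ratio, litter_probs) {
  max_age <- length(survival) - 1L
  l <- cumprod(c(1, survival[-length(survival)]))
  g <- fertility_gamma(k, theta, 1, afr, max_age)
  mean_litter <- sum(seq_along(litter_probs) * litter_probs)
  1 / (sex_ratio * mean_litter * sum(l * g))
}

#' Configure a studbook simulation
#'
#' Defaults describe a zebra-like study species: gestation 360 days,
#' litters of 1 (90%) or 2, fertility following a gamma(k = 5,
#' theta = 2 y) schedule from age 3 (peak reproduction around age 8,
#' senescence onset at 12 under the 75% right-tail rule) with its peak
#' rate calibrated so the population is stationary, and annual survival
#' of 0.78 in the first year followed by a senescent decline
#' 0.96 - 0.006 * age, reaching zero past age 20.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param years Number of simulated years.
#' @param n0_female,n0_male Founding population per sex.
#' @param fertility Either a numeric schedule over age classes or a list
#'   with `k`, `theta`, `afr` and optionally `peak` (`NULL` = calibrate to
#'   stationarity).
#' @param survival Numeric annual survival over age classes; its length
#'   fixes the maximum attainable age.
#' @param sex_ratio Probability that a newborn is female.
#' @param litter_probs Probabilities of litter sizes `1..max`.
#' @param start_year First simulated calendar year.
#' @param species A [species_config()] describing the simulated species.
#' @param events List of scenario events, each
#'   `list(year = <offset from start>, type = <type>, value = <x>)` with
#'   type one of `"halt_reproduction"`, `"resume_reproduction"`,
#'   `"mortality_multiplier"`, `"fertility_multiplier"`.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(seed,
                              years = 60L,
                              n0_female = 200L, n0_male = 200L,
                              fertility = list(k = 5, theta = 2, afr = 3,
                                               peak = NULL),
                              survival = c(0.78,
                                           pmax(0, 0.96 - 0.006 * (1:20)),
                                           0),
                              sex_ratio = 0.5,
                              litter_probs = c(0.9, 0.1),
                              start_year = 1960L,
                              species = NULL,
                              events = list()) {
  abort_if(missing(seed), "simulation_config() requires a seed")
  abort_if(any(survival < 0 | survival > 1), "survival must lie in [0, 1]")
  abort_if(abs(sum(litter_probs) - 1) > 1e-8,
           "litter_probs must sum to 1")
  if (is.null(species))
    species <- species_config("Simulated equid", gestation_days = 360,
                              max_litter_size = length(litter_probs))
  max_age <- length(survival) - 1L
  gamma_pars <- NULL
  if (is.list(fertility)) {
    gamma_pars <- fertility
    if (is.null(gamma_pars$peak))
      gamma_pars$peak <- calibrate_peak(gamma_pars$k, gamma_pars$theta,
                                        gamma_pars$afr, survival,
                                        sex_ratio, litter_probs)
    fertility <- fertility_gamma(gamma_pars$k, gamma_pars$theta,
                                 gamma_pars$peak, gamma_pars$afr, max_age)
  }
  abort_if(length(fertility) != length(survival),
           "fertility and survival schedules must have equal length")
  abort_if(any(fertility < 0), "fertility must be non-negative")
  structure(list(seed = as.integer(seed), years = as.integer(years),
                 n0_female = as.integer(n0_female),
                 n0_male = as.integer(n0_male),
                 fertility = fertility, gamma_pars = gamma_pars,
                 survival = survival, sex_ratio = sex_ratio,
                 litter_probs = litter_probs,
                 start_year = as.integer(start_year),
                 species = species, events = events, max_age = max_age),
            class = "simulation_config")
}

#' Simulate a studbook
#'
#' Runs the individual-based simulation defined by a
#' [simulation_config()]. Founders are wild-born with estimated birth
#' dates and ages drawn from the survivorship-implied stable age
#' distribution; all simulated births carry 100% parentage. Litters are
#' dated July 1 plus a seeded jitter of at most the litter window, with a
#' single date per litter. Identical seeds give identical studbooks.
#' Extinction before the final year truncates the simulation (noted in the
#' `truncated` element) and is a valid outcome.
#'
#' @param config A `simulation_config`.
#' @return A list with `studbook`, `truth` (generating schedules and true
#'   life-stage quantities), and `truncated`.
#' @export
simulate_studbook <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  f_sched <- config$fertility
  s_sched <- config$survival
  max_age <- config$max_age
  repro_ages <- which(f_sched > 0) - 1L
  afr_true <- if (length(repro_ages)) min(repro_ages) else Inf

  id <- character(); sex <- character(); birth <- as.Date(character())
  death <- as.Date(character()); dam <- character(); sire <- character()
  wild <- logical()
  n_id <- 0L
  new_ids <- function(n) sprintf("S%05d", seq_len(n) + n_id)

  truncated <- FALSE
  with_seed(config$seed, {
    # founders: stable age structure from survivorship
    l <- cumprod(c(1, s_sched[-length(s_sched)]))
    n0 <- config$n0_female + config$n0_male
    ages0 <- sample(0:max_age, n0, replace = TRUE, prob = l)
    sex0 <- rep(c("female", "male"), c(config$n0_female, config$n0_male))
    birth0 <- as.Date(sprintf("%d-07-01", config$start_year - ages0)) +
      sample(-90:90, n0, replace = TRUE)
    id <- new_ids(n0); n_id <- n_id + n0
    sex <- sex0; birth <- birth0
    death <- as.Date(rep(NA, n0))
    dam <- rep(NA_character_, n0); sire <- rep(NA_character_, n0)
    wild <- rep(TRUE, n0)

    fert_mult <- 1; mort_mult <- 1
    last_year <- config$start_year + config$years - 1L
    for (y in config$start_year:last_year) {
      for (ev in config$events) {
        if (config$start_year + ev$year == y) {
          if (ev$type == "halt_reproduction") fert_mult <- 0
          else if (ev$type == "resume_reproduction") fert_mult <- 1
          else if (ev$type == "fertility_multiplier") fert_mult <- ev$value
          else if (ev$type == "mortality_multiplier") mort_mult <- ev$value
          else stop("unknown scenario event type: ", ev$type)
        }
      }
      midyear <- as.Date(sprintf("%d-07-01", y))
      alive_mid <- is.na(death) | death > midyear
      alive_mid <- alive_mid & birth <= midyear
      age_mid <- age_class_at(birth[alive_mid], midyear)
      sires_pool <- id[alive_mid][sex[alive_mid] == "male" &
                                    age_mid >= afr_true]
      dams_idx <- which(alive_mid)[sex[alive_mid] == "female"]
      if (length(sires_pool) > 0 && length(dams_idx) > 0 && fert_mult > 0) {
        dam_age <- pmin(age_class_at(birth[dams_idx], midyear), max_age)
        p_litter <- pmin(1, f_sched[dam_age + 1L] * fert_mult)
        breeds <- stats::runif(length(dams_idx)) < p_litter
        for (i in dams_idx[breeds]) {
          size <- sample.int(length(config$litter_probs), 1,
                             prob = config$litter_probs)
          d <- midyear + sample.int(config$species$litter_window_days + 1L,
                                    1) - 1L
          kid_sex <- ifelse(stats::runif(size) < config$sex_ratio,
                            "female", "male")
          kid_id <- new_ids(size); n_id <- n_id + size
          id <- c(id, kid_id); sex <- c(sex, kid_sex)
          birth <- c(birth, rep(d, size))
          death <- c(death, as.Date(rep(NA, size)))
          dam <- c(dam, rep(id[i], size))
          sire <- c(sire, rep(sample(sires_pool, 1), size))
          wild <- c(wild, rep(FALSE, size))
        }
      }
      # survival from Dec 31 of y through year y + 1
      if (y < last_year) {
        ref <- year_end(y)
        alive <- which((is.na(death) | death > ref) & birth <= ref)
        if (length(alive) == 0) { truncated <- TRUE; break }
        a <- pmin(age_class_at(birth[alive], ref), max_age)
        q <- pmin(1, (1 - s_sched[a + 1L]) * mort_mult)
        dies <- stats::runif(length(alive)) < q
        d_idx <- alive[dies]
        if (length(d_idx) > 0) {
          day <- sample.int(365, length(d_idx), replace = TRUE)
          d_date <- as.Date(sprintf("%d-01-01", y + 1L)) + (day - 1L)
          death[d_idx] <- pmax(d_date, birth[d_idx] + 1L)
        }
      }
    }
  })

  records <- data.frame(
    individual_id = id, sex = sex, birth_date = birth,
    birth_estimated = wild, death_date = death,
    status = ifelse(is.na(death), "alive", "dead"),
    dam_id = dam, sire_id = sire,
    dam_probability = ifelse(is.na(dam), NA_real_, 100),
    sire_probability = ifelse(is.na(sire), NA_real_, 100),
    wild_born = wild, region = "Europe", stringsAsFactors = FALSE)
  truth <- list(
    fertility = f_sched, survival = s_sched,
    afr = if (is.finite(afr_true)) afr_true else NA_integer_,
    senescence_onset = if (!is.null(config$gamma_pars))
      gamma_onset_oracle(config$gamma_pars$k, config$gamma_pars$theta,
                         config$species$gamma_tail_fraction)
    else NA_integer_,
    max_age = max_age)
  list(studbook = new_studbook(records, config$species),
       truth = truth, truncated = truncated)
}

#' Inject known record errors into a studbook
#'
#' Corrupts a clean studbook with seeded, mutually disjoint errors and
#' returns the exact truth list per error type, so that curation recall
#' and precision can be checked. Supported types: `same_sex_parents`
#' (dam replaced by a male), `self_parent` (dam or sire set to the
#' individual itself), `swapped_dam_sire` (dam and sire exchanged),
#' `short_interbirth` (an extra offspring within 90% of gestation after a
#' dam's last litter), `oversized_litter` (members added beyond the
#' species maximum), `immortal_record` (death date cleared),
#' `underage_parent` (dam replaced by a female below the age of first
#' reproduction).
#'
#' @param studbook A `studbook` object.
#' @param counts Named integer vector of injections per type.
#' @param seed Integer seed.
#' @return A list with `studbook` (corrupted) and `truth`, a named list
#'   per type: affected individual ids, or for `oversized_litter` a data
#'   frame of (dam, date, n_added).
#' @export
inject_errors <- function(studbook, counts, seed) {
  stopifnot(inherits(studbook, "studbook"))
  abort_if(missing(seed), "inject_errors() requires a seed")
  rec <- studbook$records
  types <- c("same_sex_parents", "self_parent", "swapped_dam_sire",
             "short_interbirth", "oversized_litter", "immortal_record",
             "underage_parent")
  bad <- setdiff(names(counts), types)
  abort_if(length(bad) > 0, "unknown error type(s): %s",
           paste(bad, collapse = ", "))
  truth <- stats::setNames(vector("list", length(types)), types)
  used <- character()      # offspring already corrupted
  used_dams <- character() # dams already targeted by date-based errors
  n_id <- nrow(rec)
  cfg <- studbook$species
  counts <- unlist(counts)
  take <- function(type) {
    n <- unname(counts[type])
    if (is.na(n)) 0L else as.integer(n)
  }
  resolvable <- function(ids) !is.na(ids) & ids %in% rec$individual_id

  with_seed(seed, {
    pick <- function(pool, n) {
      abort_if(length(pool) < n, "not enough eligible records to inject %d errors",
               n)
      sample(pool, n)
    }

    n <- take("swapped_dam_sire")
    if (n > 0) {
      pool <- rec$individual_id[resolvable(rec$dam_id) &
                                  resolvable(rec$sire_id) &
                                  !rec$individual_id %in% used]
      ids <- pick(pool, n)
      i <- match(ids, rec$individual_id)
      tmp <- rec$dam_id[i]; rec$dam_id[i] <- rec$sire_id[i]
      rec$sire_id[i] <- tmp
      truth$swapped_dam_sire <- ids
      used <- c(used, ids)
    }

    n <- take("same_sex_parents")
    if (n > 0) {
      pool <- rec$individual_id[resolvable(rec$dam_id) &
                                  resolvable(rec$sire_id) &
                                  !rec$individual_id %in% used]
      ids <- pick(pool, n)
      i <- match(ids, rec$individual_id)
      males <- rec$individual_id[rec$sex == "male"]
      for (k in seq_along(i)) {
        rec$dam_id[i[k]] <- sample(setdiff(males, c(ids[k], rec$sire_id[i[k]])), 1)
      }
      truth$same_sex_parents <- ids
      used <- c(used, ids)
    }

    n <- take("self_parent")
    if (n > 0) {
      pool <- rec$individual_id[resolvable(rec$dam_id) &
                                  !rec$individual_id %in% used]
      ids <- pick(pool, n)
      i <- match(ids, rec$individual_id)
      rec$dam_id[i] <- rec$individual_id[i]
      rec$dam_probability[i] <- 100
      truth$self_parent <- ids
      used <- c(used, ids)
    }

    n <- take("underage_parent")
    if (n > 0) {
      pool <- rec$individual_id[resolvable(rec$dam_id) &
                                  !rec$individual_id %in% used]
      pool <- sample(pool)
      ids <- character()
      used_young <- character()
      # fake dams are childless young females, so the bogus link can only
      # trip the underage rule, never the litter or interbirth rules
      childless <- !rec$individual_id %in% rec$dam_id
      for (cand in pool) {
        if (length(ids) == n) break
        i <- match(cand, rec$individual_id)
        b <- rec$birth_date[i]
        young <- rec$individual_id[rec$sex == "female" & childless &
                                     rec$birth_date < b - 183 &
                                     rec$birth_date > b - 2 * 365 &
                                     rec$individual_id != cand &
                                     !rec$individual_id %in% used_young]
        if (length(young) == 0) next
        fake <- young[sample.int(length(young), 1)]
        rec$dam_id[i] <- fake
        rec$dam_probability[i] <- 100
        used_young <- c(used_young, fake)
        ids <- c(ids, cand)
      }
      abort_if(length(ids) < n,
               "not enough eligible records to inject %d underage parents", n)
      truth$underage_parent <- ids
      used <- c(used, ids)
    }

    n <- take("short_interbirth")
    if (n > 0) {
      gap <- max(cfg$litter_window_days + 1,
                 floor(0.5 * cfg$interbirth_fraction *
                         effective_gestation(cfg)))
      # dams whose offspring were corrupted above are excluded: removing
      # those links during curation would shift the dam's last litter date
      dams_touched <- unique(rec$dam_id[!is.na(rec$dam_id) &
                                          rec$individual_id %in% used])
      dams <- setdiff(unique(rec$dam_id[resolvable(rec$dam_id)]),
                      c(used_dams, dams_touched))
      dams <- pick(dams, n)
      ids <- character()
      for (dm in dams) {
        last <- max(rec$birth_date[!is.na(rec$dam_id) & rec$dam_id == dm])
        n_id <- n_id + 1L
        kid <- sprintf("E%05d", n_id)
        rec <- rbind(rec, data.frame(
          individual_id = kid, sex = "female", birth_date = last + gap,
          birth_estimated = FALSE, death_date = as.Date(NA),
          status = "alive", dam_id = dm, sire_id = NA_character_,
          dam_probability = 100, sire_probability = NA_real_,
          wild_born = FALSE, region = rec$region[1],
          stringsAsFactors = FALSE))
        ids <- c(ids, kid)
      }
      truth$short_interbirth <- ids
      used <- c(used, ids)
      used_dams <- c(used_dams, dams)
    }

    n <- take("oversized_litter")
    if (n > 0) {
      # exclude litters touched by earlier injections: their membership can
      # change during curation, which would alter the litter size
      touched <- unique(paste(rec$dam_id, rec$birth_date)[
        !is.na(rec$dam_id) & rec$individual_id %in% used])
      litters <- unique(rec[resolvable(rec$dam_id) &
                              !rec$dam_id %in% used_dams,
                            c("dam_id", "birth_date")])
      litters <- litters[!paste(litters$dam_id, litters$birth_date) %in%
                           touched, , drop = FALSE]
      abort_if(nrow(litters) < n,
               "not enough eligible litters to inject %d errors", n)
      sel <- litters[sample.int(nrow(litters), n), , drop = FALSE]
      added <- list()
      for (k in seq_len(nrow(sel))) {
        dm <- sel$dam_id[k]; d <- sel$birth_date[k]
        size <- sum(!is.na(rec$dam_id) & rec$dam_id == dm &
                      rec$birth_date == d)
        n_add <- cfg$max_litter_size + 1L - size
        if (n_add < 1) n_add <- 1L
        for (j in seq_len(n_add)) {
          n_id <- n_id + 1L
          rec <- rbind(rec, data.frame(
            individual_id = sprintf("E%05d", n_id), sex = "male",
            birth_date = d, birth_estimated = FALSE,
            death_date = as.Date(NA), status = "alive", dam_id = dm,
            sire_id = NA_character_, dam_probability = 100,
            sire_probability = NA_real_, wild_born = FALSE,
            region = rec$region[1], stringsAsFactors = FALSE))
        }
        added[[k]] <- data.frame(dam = dm, date = d, n_added = n_add,
                                 stringsAsFactors = FALSE)
      }
      truth$oversized_litter <- do.call(rbind, added)
      used_dams <- c(used_dams, sel$dam_id)
    }

    n <- take("immortal_record")
    if (n > 0) {
      pool <- rec$individual_id[rec$status == "dead" &
                                  !rec$individual_id %in% used]
      ids <- pick(pool, n)
      i <- match(ids, rec$individual_id)
      rec$death_date[i] <- as.Date(NA)
      rec$status[i] <- "alive"
      truth$immortal_record <- ids
      used <- c(used, ids)
    }
  })
  rownames(rec) <- NULL
  list(studbook = new_studbook(rec, studbook$species, studbook$region_filter,
                               studbook$eligible),
       truth = truth[!vapply(truth, is.null, TRUE)])
}

#' Named scenario presets
#'
#' Ready-made simulation configurations for the demographic regimes the
#' shape classifier is meant to detect: `steady_state` (stationary
#' population, pyramid regime), `reproduction_halt` (breeding stops in
#' year 40 of 60, producing the lower -> middle -> upper diamond
#' progression), `halt_then_resume` (halt in year 40, resumption in year
#' 48, producing hourglasses), `low_mortality_reduced_reproduction`
#' (bell/column regime), and the `high_resilience` / `low_resilience`
#' pair contrasting a broad-based with a narrow-based population.
#'
#' Presets start from 500 founders per sex: the regimes are defined by the
#' deterministic expectation of the age structure, and at this size the
#' sampling noise of the bucket comparisons is small against the
#' structural differences the scenarios are meant to display.
#'
#' @param seed Integer seed applied to every preset.
#' @param years Override of the default duration per preset.
#' @param n0 Founding population per sex.
#' @return Named list of `simulation_config` objects.
#' @export
scenario_library <- function(seed, years = NULL, n0 = 500L) {
  cfg <- function(yrs, events = list(), ...) {
    simulation_config(seed = seed, years = years %||% yrs,
                      n0_female = n0, n0_male = n0,
                      events = events, ...)
  }
  list(
    steady_state = cfg(60),
    reproduction_halt = cfg(
      60, events = list(list(year = 40, type = "halt_reproduction"))),
    halt_then_resume = cfg(
      65, events = list(list(year = 40, type = "halt_reproduction"),
                        list(year = 48, type = "resume_reproduction"))),
    low_mortality_reduced_reproduction = cfg(
      60, events = list(list(year = 1, type = "fertility_multiplier",
                             value = 0.45),
                        list(year = 1, type = "mortality_multiplier",
                             value = 0.35))),
    high_resilience = cfg(60),
    low_resilience = cfg(
      60, events = list(list(year = 1, type = "fertility_multiplier",
                             value = 0.55),
                        list(year = 1, type = "mortality_multiplier",
                             value = 0.5)))
  )
}
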