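#' Species parameters and algorithm thresholds
#'
#' Bundles the per-species biology (gestation length, marsupial pouch
#' eviction, maximum litter size) with the thresholds used throughout the
#' pipeline. All thresholds default to the values used in the original
#' method: 90% of gestation as the minimum plausible interbirth interval,
#' a 3-day litter window, mean +/- 0.5 SEM bucket equality, shapes ascribed
#' only above 10 individuals, populations eligible from 150 individuals ever
#' recorded, and reproductive senescence at the age class where the fitted
#' gamma curve falls to 75% of its maximum on the right tail.
#'
#' @param species_name Species label.
#' @param gestation_days Average gestation length in days.
#' @param is_marsupial Logical; marsupials use gestation + pouch eviction as
#'   the effective gestation for the interbirth rule.
#' @param pouch_eviction_min_days Minimum age of first pouch eviction in
#'   days; required when `is_marsupial` is `TRUE`.
#' @param max_litter_size Largest biologically plausible litter.
#' @param afr_override Optional named list/vector (`female`, `male`) of ages
#'   of first reproduction in whole years, overriding estimation.
#' @param senescence_override Optional named list/vector (`female`, `male`)
#'   of senescence-onset ages in whole years, overriding estimation.
#' @param max_longevity_override Optional maximum longevity (whole years)
#'   asserted manually (e.g. from a longevity database) instead of the
#'   oldest zoo-born dead individual.
#' @param min_population_for_shape Shapes are ascribed only when the
#'   sex-specific yearly population strictly exceeds this count.
#' @param min_individuals_ever Minimum individuals ever recorded for a
#'   regional population to be eligible.
#' @param litter_window_days Same-dam births within this many days form one
#'   litter.
#' @param interbirth_fraction Fraction of the effective gestation below
#'   which an interbirth interval is implausible.
#' @param sem_factor Factor f in the mean +/- f*SEM bucket-overlap equality
#'   test.
#' @param gamma_tail_fraction Fraction of the gamma-curve maximum defining
#'   the senescence onset on the right tail.
#' @return An object of class `species_config`.
#' @examples
#' cfg <- species_config("Equus quagga", gestation_days = 360,
#'                       max_litter_size = 2)
#' cfg$interbirth_fraction
#' @export
species_config <- function(species_name,
                           gestation_days,
                           is_marsupial = FALSE,
                           pouch_eviction_min_days = NULL,
                           max_litter_size = 1L,
                           afr_override = NULL,
                           senescence_override = NULL,
                           max_longevity_override = NULL,
                           min_population_for_shape = 10L,
                           min_individuals_ever = 150L,
                           litter_window_days = 3L,
                           interbirth_fraction = 0.90,
                           sem_factor = 0.5,
                           gamma_tail_fraction = 0.75) {
  abort_if(!is.character(species_name) || length(species_name) != 1L,
           "species_name must be a single string")
  abort_if(!is.numeric(gestation_days) || gestation_days <= 0,
           "gestation_days must be a positive number")
  abort_if(isTRUE(is_marsupial) && is.null(pouch_eviction_min_days),
           "marsupial species require pouch_eviction_min_days")
  abort_if(!is.null(pouch_eviction_min_days) && pouch_eviction_min_days < 0,
           "pouch_eviction_min_days must be non-negative")
  abort_if(max_litter_size < 1, "max_litter_size must be a positive integer")
  for (nm in c("min_population_for_shape", "min_individuals_ever",
               "litter_window_days")) {
    v <- get(nm)
    abort_if(!is.numeric(v) || v <= 0, "%s must be strictly positive", nm)
  }
  for (nm in c("interbirth_fraction", "sem_factor", "gamma_tail_fraction")) {
    v <- get(nm)
    abort_if(!is.numeric(v) || v <= 0 || v > 1, "%s must lie in (0, 1]", nm)
  }
  check_override <- function(x, nm) {
    if (is.null(x)) return(NULL)
    x <- as.list(x)
    abort_if(!all(names(x) %in% c("female", "male")),
             "%s must be named with 'female'/'male'", nm)
    lapply(x, as.numeric)
  }
  structure(list(
    species_name = species_name,
    gestation_days = as.numeric(gestation_days),
    is_marsupial = isTRUE(is_marsupial),
    pouch_eviction_min_days =
      if (is.null(pouch_eviction_min_days)) NULL else as.numeric(pouch_eviction_min_days),
    max_litter_size = as.integer(max_litter_size),
    afr_override = check_override(afr_override, "afr_override"),
    senescence_override = check_override(senescence_override, "senescence_override"),
    max_longevity_override =
      if (is.null(max_longevity_override)) NULL else as.numeric(max_longevity_override),
    min_population_for_shape = as.integer(min_population_for_shape),
    min_individuals_ever = as.integer(min_individuals_ever),
    litter_window_days = as.integer(litter_window_days),
    interbirth_fraction = as.numeric(interbirth_fraction),
    sem_factor = as.numeric(sem_factor),
    gamma_tail_fraction = as.numeric(gamma_tail_fraction)
  ), class = "species_config")
}

# Effective gestation used by the interbirth rule.
effective_gestation <- function(config) {
  abort_if(config$is_marsupial && is.null(config$pouch_eviction_min_days),
           "marsupial species require pouch_eviction_min_days")
  config$gestation_days +
    if (config$is_marsupial) config$pouch_eviction_min_days else 0
}

#' @export
print.species_config <- function(x, ...) {
  cat("Species configuration:", x$species_name, "\n")
  cat(sprintf("  gestation: %g d%s, max litter %d\n", x$gestation_days,
              if (x$is_marsupial)
                sprintf(" (+%g d pouch eviction)", x$pouch_eviction_min_days)
              else "",
              x$max_litter_size))
  cat(sprintf("  thresholds: interbirth < %.0f%% gestation, litter window %d d,\n",
              100 * x$interbirth_fraction, x$litter_window_days))
  cat(sprintf("    shape if > %d individuals, eligible from %d ever recorded,\n",
              x$min_population_for_shape, x$min_individuals_ever))
  cat(sprintf("    equality mean +/- %.2f SEM, senescence at %.0f%% of gamma peak\n",
              x$sem_factor, 100 * x$gamma_tail_fraction))
  invisible(x)
}

#' Read or write a species configuration as YAML
#'
#' @param path File path.
#' @return `read_species_config()` returns a [species_config()] object;
#'   `write_species_config()` returns `path` invisibly.
#' @export
read_species_config <- function(path) {
  abort_if(!file.exists(path), "species config not found: %s", path)
  raw <- yaml::read_yaml(path)
  abort_if(is.null(raw$species_name) || is.null(raw$gestation_days),
           "species config must name species_name and gestation_days")
  do.call(species_config, raw)
}

#' @param config A [species_config()] object.
#' @rdname read_species_config
#' @export
write_species_config <- function(config, path) {
  stopifnot(inherits(config, "species_config"))
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null, TRUE)],
                   path)
  invisible(path)
}
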