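# In-code fixtures shared across test files.

test_config <- function(...) {
  species_config("Test species", gestation_days = 100, max_litter_size = 4,
                 ...)
}

# One studbook row with overridable fields.
rec_row <- function(id, sex = "female", birth = "2000-07-01",
                    death = NA, status = if (is.na(death)) "alive" else "dead",
                    dam = NA, sire = NA, dam_p = if (is.na(dam)) NA else 100,
                    sire_p = if (is.na(sire)) NA else 100,
                    wild = FALSE, region = "Europe", estimated = FALSE) {
  data.frame(individual_id = id, sex = sex,
             birth_date = as.Date(birth), birth_estimated = estimated,
             death_date = as.Date(death), status = status,
             dam_id = as.character(dam), sire_id = as.character(sire),
             dam_probability = as.numeric(dam_p),
             sire_probability = as.numeric(sire_p),
             wild_born = wild, region = region, stringsAsFactors = FALSE)
}

make_studbook <- function(rows, config = test_config()) {
  popshape:::new_studbook(do.call(rbind, rows), config)
}

# A minimal clean two-generation studbook.
family_studbook <- function(config = test_config()) {
  make_studbook(list(
    rec_row("F1", "female", "1990-01-01", "2010-06-01"),
    rec_row("M1", "male", "1990-01-01", "2012-06-01"),
    rec_row("K1", "female", "1995-05-01", dam = "F1", sire = "M1"),
    rec_row("K2", "male", "1997-05-01", dam = "F1", sire = "M1")
  ), config)
}

# Random bucket vector for classifier property tests.
random_bucket_vector <- function(sems_zero = FALSE) {
  means <- stats::runif(5, 0, 30)
  sems <- if (sems_zero) rep(0, 5) else abs(stats::rnorm(5, 0, 2))
  bucket_vector(means, sems, n_classes = sample(1:5, 5, replace = TRUE),
                total = 100)
}

# Bucket means realising a given step pattern exactly (SEMs zero).
means_for_pattern <- function(s) {
  m <- numeric(5)
  m[1] <- stats::runif(1, 21, 30)
  for (i in 1:4) {
    step <- stats::runif(1, 0.5, 5)
    m[i + 1] <- m[i] + s[i] * step
  }
  m
}
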