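# Life-stage estimation: age of first reproduction (AFR), onset of
# reproductive senescence via a gamma fit to age-specific reproduction
# probabilities, and the five bucket boundaries of the reduced pyramid.

#' Age of first reproduction
#'
#' The youngest (floored) age at which any individual of the given sex is
#' recorded as a parent, over all resolvable curated links. A configured
#' override wins over the data.
#'
#' @param studbook A `studbook` object (curated).
#' @param sex `"female"` (dam links) or `"male"` (sire links).
#' @param config A [species_config()]; consulted for `afr_override`.
#' @return Age of first reproduction in whole years.
#' @export
estimate_afr <- function(studbook, sex, config = studbook$species) {
  stopifnot(inherits(studbook, "studbook"), sex %in% c("female", "male"))
  override <- config$afr_override[[sex]]
  if (!is.null(override) && !is.na(override)) return(as.numeric(override))
  rec <- studbook$records
  id_col <- if (sex == "female") "dam_id" else "sire_id"
  parent_birth <- rec$birth_date[match(rec[[id_col]], rec$individual_id)]
  ages <- age_years_at(parent_birth, rec$birth_date)
  ages <- ages[!is.na(ages)]
  abort_if(length(ages) == 0,
           "no resolvable %s links and no afr_override for sex '%s'",
           id_col, sex)
  floor(min(ages))
}

#' Age-specific reproduction probabilities of proven breeders
#'
#' For each age class, the proportion of proven breeders (individuals of
#' the given sex with at least one offspring) that reproduced in that age
#' class, among the proven breeders alive during that age class. Living
#' breeders are taken as alive up to the most recent date in the studbook.
#'
#' @inheritParams estimate_afr
#' @return A `repro_profile` object: list with `sex`, `ages` (integer age
#'   classes), `probabilities`, `n_events`, `n_alive`, `n_breeders`.
#' @export
reproduction_profile <- function(studbook, sex) {
  stopifnot(inherits(studbook, "studbook"), sex %in% c("female", "male"))
  rec <- studbook$records
  id_col <- if (sex == "female") "dam_id" else "sire_id"
  link <- !is.na(rec[[id_col]]) & rec[[id_col]] %in% rec$individual_id
  breeders <- unique(rec[[id_col]][link])
  abort_if(length(breeders) == 0, "no proven breeders of sex '%s'", sex)
  bidx <- match(breeders, rec$individual_id)
  ref_date <- max(c(rec$birth_date, rec$death_date), na.rm = TRUE)
  last_date <- rec$death_date[bidx]
  last_date[is.na(last_date)] <- ref_date
  last_age <- age_class_at(rec$birth_date[bidx], last_date)

  parent_birth <- rec$birth_date[match(rec[[id_col]], rec$individual_id)]
  event_age <- age_class_at(parent_birth, rec$birth_date)[link]
  event_parent <- rec[[id_col]][link]

  ages <- 0:max(last_age)
  n_alive <- vapply(ages, function(a) sum(last_age >= a), integer(1))
  events <- unique(data.frame(parent = event_parent, age = event_age))
  n_events <- vapply(ages, function(a) sum(events$age == a), integer(1))
  structure(list(sex = sex, ages = ages,
                 probabilities = ifelse(n_alive > 0, n_events / n_alive, 0),
                 n_events = n_events, n_alive = n_alive,
                 n_breeders = length(breeders)),
            class = "repro_profile")
}

#' @export
print.repro_profile <- function(x, ...) {
  cat(sprintf("Reproduction profile (%s): %d proven breeders, ages 0-%d\n",
              x$sex, x$n_breeders, max(x$ages)))
  cat(sprintf("  peak probability %.3f at age %d\n",
              max(x$probabilities), x$ages[which.max(x$probabilities)]))
  invisible(x)
}

# Closed-form optimal amplitude and resulting residual sum of squares for a
# gamma density with fixed shape/scale, evaluated at class midpoints.
gamma_rss <- function(k, theta, ages, p) {
  g <- stats::dgamma(ages + 0.5, shape = k, scale = theta)
  denom <- sum(g * g)
  if (!is.finite(denom) || denom <= 0) return(list(A = NA_real_, rss = Inf))
  A <- sum(p * g) / denom
  if (!is.finite(A) || A <= 0) return(list(A = NA_real_, rss = Inf))
  list(A = A, rss = sum((p - A * g)^2))
}

#' Fit a gamma curve to a reproduction profile
#'
#' Least-squares fit of `A * dgamma(a + 0.5, shape = k, scale = theta)` to
#' the age-class reproduction probabilities, with a free amplitude `A`.
#' The fit is deterministic: a coarse grid multistart over
#' `k in {0.5, 1, ..., 16}` and `theta in {0.25, 0.5, ..., 8}` (amplitude
#' profiled out in closed form) followed by local refinement in
#' `(log k, log theta)`.
#'
#' @param profile A `repro_profile` from [reproduction_profile()], or any
#'   list with `ages` and `probabilities`.
#' @return An object of class `repro_gamma` with elements `k`, `theta`,
#'   `amplitude`, `mode` ((k-1)*theta for k > 1, else 0), `rss`, `ages`,
#'   `observed`, `fitted`.
#' @export
fit_gamma <- function(profile) {
  ages <- as.numeric(profile$ages)
  p <- as.numeric(profile$probabilities)
  stopifnot(length(ages) == length(p))
  abort_if(all(p == 0), "all reproduction probabilities are zero")
  abort_if(sum(p > 0) < 4, paste0(
    "fewer than 4 age classes with positive reproduction probability; ",
    "the gamma fit is underdetermined - set life-stage thresholds manually"))

  grid <- expand.grid(k = seq(0.5, 16, by = 0.5),
                      theta = seq(0.25, 8, by = 0.25))
  rss <- mapply(function(k, th) gamma_rss(k, th, ages, p)$rss,
                grid$k, grid$theta)
  abort_if(!any(is.finite(rss)), "gamma fit failed on the coarse grid")
  start <- grid[which.min(rss), ]

  obj <- function(par) {
    gamma_rss(exp(par[1]), exp(par[2]), ages, p)$rss
  }
  opt <- stats::optim(log(c(start$k, start$theta)), obj, method = "L-BFGS-B",
                      lower = log(c(1e-3, 1e-3)), upper = log(c(100, 100)))
  k <- exp(opt$par[1]); theta <- exp(opt$par[2])
  best <- gamma_rss(k, theta, ages, p)
  structure(list(k = k, theta = theta, amplitude = best$A,
                 mode = if (k > 1) (k - 1) * theta else 0,
                 rss = best$rss, ages = ages, observed = p,
                 fitted = best$A *
                   stats::dgamma(ages + 0.5, shape = k, scale = theta)),
            class = "repro_gamma")
}

#' @export
print.repro_gamma <- function(x, ...) {
  cat(sprintf(
    "Gamma reproduction curve: k = %.3f, theta = %.3f y, A = %.3f\n",
    x$k, x$theta, x$amplitude))
  cat(sprintf("  mode %.2f y, residual SS %.5f over %d age classes\n",
              x$mode, x$rss, length(x$ages)))
  invisible(x)
}

#' @export
coef.repro_gamma <- function(object, ...) {
  c(k = object$k, theta = object$theta, amplitude = object$amplitude)
}

#' @export
predict.repro_gamma <- function(object, ages = object$ages, ...) {
  object$amplitude *
    stats::dgamma(ages + 0.5, shape = object$k, scale = object$theta)
}

#' @export
plot.repro_gamma <- function(x, ...) {
  graphics::plot(x$ages, x$observed, pch = 16,
                 xlab = "age class (years)",
                 ylab = "proportion of proven breeders reproducing", ...)
  xx <- seq(min(x$ages), max(x$ages), length.out = 200)
  graphics::lines(xx, x$amplitude *
                    stats::dgamma(xx + 0.5, shape = x$k, scale = x$theta))
  invisible(x)
}

#' Onset of reproductive senescence from a fitted gamma curve
#'
#' The smallest whole age class at or past the curve's mode where the
#' fitted density has fallen to `gamma_tail_fraction` (75%) of its maximum,
#' located by root finding on the right tail and then rounded up (an
#' individual is senior only once past the threshold). A configured
#' override wins.
#'
#' @param fit A `repro_gamma` object from [fit_gamma()].
#' @param config A [species_config()].
#' @param sex Optional sex for looking up `senescence_override`.
#' @return Onset age in whole years.
#' @export
senescence_onset <- function(fit, config, sex = NULL) {
  stopifnot(inherits(fit, "repro_gamma"))
  if (!is.null(sex)) {
    override <- config$senescence_override[[sex]]
    if (!is.null(override) && !is.na(override)) return(as.numeric(override))
  }
  frac <- config$gamma_tail_fraction
  abort_if(fit$k < 1, paste0(
    "gamma shape < 1 (monotonically decreasing curve): the right-tail rule ",
    "is undefined - set life-stage thresholds manually"))
  mode <- fit$mode
  peak <- stats::dgamma(mode, shape = fit$k, scale = fit$theta)
  if (frac >= 1) return(as.integer(ceiling(mode)))
  target <- frac * peak
  f <- function(x) stats::dgamma(x, shape = fit$k, scale = fit$theta) - target
  upper <- mode + fit$theta
  while (f(upper) > 0) upper <- upper + fit$theta
  root <- stats::uniroot(f, c(mode, upper), tol = 1e-9)$root
  as.integer(ceiling(round(root, 9)))
}

#' Five bucket boundaries from the life-stage thresholds
#'
#' Partitions the age classes 0..max_longevity into the juvenile block
#' `[0, afr)`, three contiguous adult blocks covering `[afr, onset)` with
#' sizes as equal as possible (any remainder goes to the lower blocks), and
#' the senior block `[onset, max_longevity]`. The adult range must span at
#' least three years.
#'
#' @param afr Age of first reproduction (whole years, >= 1).
#' @param onset Onset of reproductive senescence (whole years).
#' @param max_longevity Maximum longevity (whole years).
#' @return A `life_stage_thresholds` object with a `buckets` data frame of
#'   half-open age-class ranges `[from, to)` (senior runs to
#'   `max_longevity + 1` so the top class is included).
#' @export
bucket_boundaries <- function(afr, onset, max_longevity) {
  abort_if(afr < 1, "age of first reproduction must be >= 1 year (got %g)",
           afr)
  span <- onset - afr
  abort_if(span < 3, paste0(
    "the adult range must consist of at least three years ",
    "(got %g: afr %g, senescence onset %g)"), span, afr, onset)
  abort_if(max_longevity < onset,
           "max_longevity (%g) must be >= senescence onset (%g)",
           max_longevity, onset)
  base <- span %/% 3L
  w <- base + c(span %% 3L >= 1L, span %% 3L >= 2L, 0L)
  from <- c(0L, afr, afr + w[1], afr + w[1] + w[2], onset)
  to <- c(afr, afr + w[1], afr + w[1] + w[2], onset, max_longevity + 1L)
  structure(list(
    afr = as.integer(afr), senescence_onset = as.integer(onset),
    max_longevity = as.integer(max_longevity),
    buckets = data.frame(
      bucket = c("juvenile", "adult_low", "adult_mid", "adult_high",
                 "senior"),
      from = as.integer(from), to = as.integer(to),
      stringsAsFactors = FALSE)),
    class = "life_stage_thresholds")
}

#' @export
print.life_stage_thresholds <- function(x, ...) {
  cat(sprintf(
    "Life stages: juvenile < %d y, adult %d-%d y, senior %d-%d y\n",
    x$afr, x$afr, x$senescence_onset - 1L, x$senescence_onset,
    x$max_longevity))
  b <- x$buckets
  cat(sprintf("  buckets: %s\n",
              paste(sprintf("%s [%d,%d)", b$bucket, b$from, b$to),
                    collapse = ", ")))
  invisible(x)
}

#' Estimate life stages for both sexes of a studbook
#'
#' Runs, per sex: AFR estimation, the reproduction profile, the gamma fit,
#' and the senescence onset; combines them with the studbook's maximum
#' longevity into bucket boundaries. Configured overrides (AFR, senescence
#' onset, maximum longevity) win over estimation.
#'
#' @param studbook A curated `studbook` object.
#' @param config A [species_config()].
#' @param max_longevity Optional precomputed maximum longevity (whole
#'   years); by default [compute_max_longevity()] is used.
#' @return A `life_stages` object: list with per-sex
#'   `life_stage_thresholds` (`$female`, `$male`) and the per-sex gamma
#'   fits (`$fits`).
#' @export
estimate_life_stages <- function(studbook, config = studbook$species,
                                 max_longevity = NULL) {
  longevity <- max_longevity %||% compute_max_longevity(studbook)
  out <- list(fits = list())
  for (sex in c("female", "male")) {
    afr <- estimate_afr(studbook, sex, config)
    override <- config$senescence_override[[sex]]
    if (!is.null(override) && !is.na(override)) {
      onset <- as.numeric(override)
      out$fits[[sex]] <- NULL
    } else {
      fit <- fit_gamma(reproduction_profile(studbook, sex))
      onset <- senescence_onset(fit, config, sex)
      out$fits[[sex]] <- fit
    }
    out[[sex]] <- bucket_boundaries(afr, onset, longevity)
  }
  structure(out, class = "life_stages")
}

#' @export
print.life_stages <- function(x, ...) {
  for (sex in c("female", "male")) {
    cat(sprintf("%s ", sex)); print(x[[sex]])
  }
  invisible(x)
}

#' Read or write life-stage thresholds as YAML
#'
#' Allows literature values to replace estimated thresholds.
#'
#' @param x A `life_stages` object (per-sex thresholds).
#' @param path File path.
#' @return `read_life_stages()` returns a `life_stages` object.
#' @export
write_life_stages <- function(x, path) {
  stopifnot(inherits(x, "life_stages"))
  yaml::write_yaml(list(
    female = x$female[c("afr", "senescence_onset", "max_longevity")],
    male = x$male[c("afr", "senescence_onset", "max_longevity")]), path)
  invisible(path)
}

#' @rdname write_life_stages
#' @export
read_life_stages <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list(fits = list())
  for (sex in c("female", "male")) {
    s <- raw[[sex]]
    abort_if(is.null(s), "life-stage YAML lacks entry for '%s'", sex)
    out[[sex]] <- bucket_boundaries(s$afr, s$senescence_onset,
                                    s$max_longevity)
  }
  structure(out, class = "life_stages")
}
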