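# Yearly sex-specific age pyramids and their reduction to five age buckets.

#' Build a yearly sex-specific age pyramid
#'
#' Counts the individuals of one sex alive on December 31 of the given year
#' (born on or before that date, death date absent or strictly after it; a
#' death on December 31 counts as dead) by floored age class. Ages beyond
#' the species' maximum longevity are clamped into the top class and
#' recorded in the `n_clamped` attribute rather than dropped.
#'
#' @param studbook A `studbook` object.
#' @param year Calendar year.
#' @param sex `"female"` or `"male"`.
#' @param thresholds A `life_stage_thresholds` object for this sex.
#' @return An `age_pyramid`: list with `year`, `sex`, `counts` (named
#'   integer vector over age classes `0..max_longevity`), `total`.
#' @export
build_pyramid <- function(studbook, year, sex, thresholds) {
  stopifnot(inherits(studbook, "studbook"),
            inherits(thresholds, "life_stage_thresholds"))
  ref <- year_end(year)
  rec <- studbook$records
  alive <- rec$sex == sex & rec$birth_date <= ref &
    (is.na(rec$death_date) | rec$death_date > ref)
  ages <- age_class_at(rec$birth_date[alive], ref)
  n_clamped <- sum(ages > thresholds$max_longevity)
  ages <- pmin(ages, thresholds$max_longevity)
  counts <- tabulate(ages + 1L, nbins = thresholds$max_longevity + 1L)
  names(counts) <- 0:thresholds$max_longevity
  structure(list(year = as.integer(year), sex = sex,
                 counts = counts, total = sum(counts),
                 max_longevity = thresholds$max_longevity,
                 n_clamped = n_clamped),
            class = "age_pyramid")
}

#' @export
print.age_pyramid <- function(x, ...) {
  cat(sprintf("Age pyramid %d (%s): %d individuals in classes 0-%d\n",
              x$year, x$sex, x$total, x$max_longevity))
  invisible(x)
}

#' @export
plot.age_pyramid <- function(x, ...) {
  graphics::barplot(rev(x$counts), horiz = TRUE, names.arg = rev(names(x$counts)),
                    las = 1, xlab = "individuals", ylab = "age class",
                    main = sprintf("%s, %d", x$sex, x$year), ...)
  invisible(x)
}

new_bucket_vector <- function(df, total, ascribable, year = NA_integer_,
                              sex = NA_character_) {
  structure(list(buckets = df, total = total, ascribable = ascribable,
                 year = year, sex = sex),
            class = "bucket_vector")
}

#' Construct a bucket vector from raw bucket summaries
#'
#' Mostly useful for tests and simulation studies of the classifier; the
#' ordinary route is [reduce_to_buckets()].
#'
#' @param means,sems Numeric length-5 vectors, bottom (juvenile) to top
#'   (senior).
#' @param n_classes Integer length-5 vector of classes per bucket.
#' @param total Population total; defaults to `sum(means * n_classes)`.
#' @param ascribable Logical; defaults to `total > 10`, the standard
#'   ascription threshold.
#' @return A `bucket_vector`.
#' @export
bucket_vector <- function(means, sems = rep(0, 5),
                          n_classes = rep(1L, 5),
                          total = round(sum(means * n_classes)),
                          ascribable = total > 10) {
  stopifnot(length(means) == 5, length(sems) == 5, length(n_classes) == 5)
  df <- data.frame(
    bucket = c("juvenile", "adult_low", "adult_mid", "adult_high", "senior"),
    mean = as.numeric(means), sem = as.numeric(sems),
    n_classes = as.integer(n_classes),
    total = as.numeric(means) * as.integer(n_classes),
    stringsAsFactors = FALSE)
  new_bucket_vector(df, total, ascribable)
}

#' Reduce an age pyramid to the five-bucket representation
#'
#' Each bucket (juvenile, three equal adult blocks, senior) is summarised
#' by the mean number of individuals per age class in its range, the
#' standard error of that mean (sample standard deviation over the classes
#' divided by sqrt(n); 0 for single-class buckets), the number of classes,
#' and the bucket total. The shape-ascription flag requires the population
#' to strictly exceed `min_population_for_shape` (10).
#'
#' @param pyramid An `age_pyramid`.
#' @param thresholds A `life_stage_thresholds` object.
#' @param config A [species_config()].
#' @return A `bucket_vector`: list with `buckets` (data frame with one row
#'   per bucket), `total`, `ascribable`, `year`, `sex`.
#' @export
reduce_to_buckets <- function(pyramid, thresholds, config) {
  stopifnot(inherits(pyramid, "age_pyramid"),
            inherits(thresholds, "life_stage_thresholds"))
  b <- thresholds$buckets
  rows <- lapply(seq_len(nrow(b)), function(i) {
    cls <- pyramid$counts[(b$from[i] + 1L):b$to[i]]
    n <- length(cls)
    data.frame(bucket = b$bucket[i], mean = mean(cls),
               sem = if (n > 1) stats::sd(cls) / sqrt(n) else 0,
               n_classes = n, total = sum(cls), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  new_bucket_vector(df, pyramid$total,
                    pyramid$total > config$min_population_for_shape,
                    pyramid$year, pyramid$sex)
}

#' @export
print.bucket_vector <- function(x, ...) {
  cat(sprintf("Bucket vector%s: total %d%s\n",
              if (!is.na(x$year)) sprintf(" (%s, %d)", x$sex, x$year) else "",
              x$total, if (x$ascribable) "" else " [not ascribable]"))
  print(x$buckets, row.names = FALSE)
  invisible(x)
}

#' Compare two buckets under the SEM-overlap equality test
#'
#' Two buckets hold an equal number of individuals when the intervals
#' `mean +/- sem_factor * SEM` overlap; otherwise they are ordered by their
#' means.
#'
#' @param a,b Single rows of a bucket data frame (or any list with `mean`
#'   and `sem`).
#' @param sem_factor Interval half-width factor (default 0.5).
#' @return `-1L` (a below b), `0L` (equal), or `1L` (a above b).
#' @export
compare_buckets <- function(a, b, sem_factor = 0.5) {
  cmp_ms(a$mean, a$sem, b$mean, b$sem, sem_factor)
}

# Vector-free core comparison on (mean, sem) pairs.
cmp_ms <- function(mean_a, sem_a, mean_b, sem_b, sem_factor) {
  lo_a <- mean_a - sem_factor * sem_a; hi_a <- mean_a + sem_factor * sem_a
  lo_b <- mean_b - sem_factor * sem_b; hi_b <- mean_b + sem_factor * sem_b
  if (lo_a <= hi_b && lo_b <= hi_a) 0L else if (mean_a < mean_b) -1L else 1L
}

#' Step sequence of a bucket vector
#'
#' The four bottom-up transitions between consecutive buckets, each `+1`
#' (becoming larger), `0` (same size under the SEM-overlap test), or `-1`
#' (becoming smaller).
#'
#' @param v A `bucket_vector`.
#' @param sem_factor Interval half-width factor (default 0.5).
#' @return Integer vector of length 4 over `{-1, 0, 1}`.
#' @export
step_sequence <- function(v, sem_factor = 0.5) {
  stopifnot(inherits(v, "bucket_vector"))
  b <- v$buckets
  vapply(1:4, function(i) {
    cmp_ms(b$mean[i + 1], b$sem[i + 1], b$mean[i], b$sem[i], sem_factor)
  }, integer(1))
}
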