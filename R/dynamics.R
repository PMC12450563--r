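# Shape-sequence statistics: yearly series, transition frequencies,
# population-size changes, age-group proportions, peak-size analysis.

#' Build the yearly shape series of a population
#'
#' For every year and sex: the classified shape (or `"not_ascribed"`), the
#' sex-specific population total, and the juvenile/adult/senior counts.
#'
#' @param studbook A curated `studbook` object.
#' @param stages A `life_stages` object (per-sex thresholds).
#' @param config A [species_config()].
#' @param years Integer vector of calendar years.
#' @param population_id Label carried into the series.
#' @return A `shape_series` object wrapping a data frame with columns
#'   `population`, `sex`, `year`, `shape`, `total`, `juvenile`, `adult`,
#'   `senior`.
#' @export
build_series <- function(studbook, stages, config = studbook$species, years,
                         population_id = studbook$species$species_name) {
  stopifnot(inherits(stages, "life_stages"))
  rows <- list()
  for (sex in c("female", "male")) {
    th <- stages[[sex]]
    for (y in years) {
      pyr <- build_pyramid(studbook, y, sex, th)
      bv <- reduce_to_buckets(pyr, th, config)
      tot <- bv$buckets$total
      rows[[length(rows) + 1L]] <- data.frame(
        population = population_id, sex = sex, year = as.integer(y),
        shape = classify_shape(bv, config),
        total = pyr$total, juvenile = tot[1],
        adult = tot[2] + tot[3] + tot[4], senior = tot[5],
        stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, rows)
  rownames(entries) <- NULL
  structure(list(entries = entries), class = "shape_series")
}

#' @export
print.shape_series <- function(x, ...) {
  e <- x$entries
  cat(sprintf("Shape series '%s': %d year x sex entries (%d-%d)\n",
              e$population[1], nrow(e), min(e$year), max(e$year)))
  tab <- sort(table(e$shape), decreasing = TRUE)
  cat(sprintf("  shapes: %s\n",
              paste(sprintf("%s %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

series_entries <- function(series) {
  if (inherits(series, "shape_series")) series$entries else series
}

#' Year-to-year shape transitions of a series
#'
#' One transition per pair of consecutive years of the same population and
#' sex in which both shapes are ascribed; transitions across a
#' not-ascribed year are dropped, not bridged. The population change is
#' the percentage change of the sex-specific total.
#'
#' @param series A `shape_series` (or its entries data frame).
#' @return Data frame with columns `population`, `sex`, `year_from`,
#'   `from`, `to`, `change_pct`.
#' @export
transitions <- function(series) {
  e <- series_entries(series)
  out <- list()
  for (key in split(seq_len(nrow(e)), paste(e$population, e$sex))) {
    g <- e[key, , drop = FALSE]
    g <- g[order(g$year), , drop = FALSE]
    if (nrow(g) < 2) next
    i <- seq_len(nrow(g) - 1L)
    ok <- (g$year[i + 1L] == g$year[i] + 1L) &
      g$shape[i] != NOT_ASCRIBED & g$shape[i + 1L] != NOT_ASCRIBED
    if (!any(ok)) next
    i <- i[ok]
    out[[length(out) + 1L]] <- data.frame(
      population = g$population[i], sex = g$sex[i], year_from = g$year[i],
      from = g$shape[i], to = g$shape[i + 1L],
      change_pct = 100 * (g$total[i + 1L] - g$total[i]) / g$total[i],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(population = character(), sex = character(),
                      year_from = integer(), from = character(),
                      to = character(), change_pct = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate shape transitions into matrices
#'
#' Counts and percentages of occurrence per (from, to) shape pair, and the
#' mean (and, for cells with at least two transitions, the SD) of the
#' percentage population change. All cells are computed; any display
#' thresholding is a reporting concern.
#'
#' @param trans A transitions data frame from [transitions()].
#' @return A `transition_stats` object: list of 11x11 matrices `counts`,
#'   `percentages`, `mean_change`, `sd_change`, plus `n_total`.
#' @export
aggregate_transitions <- function(trans) {
  f <- factor(trans$from, levels = SHAPES)
  t <- factor(trans$to, levels = SHAPES)
  counts <- table(from = f, to = t)
  n <- sum(counts)
  mean_change <- matrix(NA_real_, 11, 11, dimnames = dimnames(counts))
  sd_change <- mean_change
  if (nrow(trans) > 0) {
    agg_m <- tapply(trans$change_pct, list(f, t), mean)
    agg_s <- tapply(trans$change_pct, list(f, t), stats::sd)
    mean_change[] <- agg_m
    sd_change[] <- agg_s
  }
  sd_change[!is.na(counts) & counts < 2] <- NA_real_
  structure(list(counts = unclass(counts),
                 percentages = if (n > 0) 100 * unclass(counts) / n
                               else unclass(counts) * 0,
                 mean_change = mean_change, sd_change = sd_change,
                 n_total = n),
            class = "transition_stats")
}

#' @export
print.transition_stats <- function(x, digits = 1, display_threshold = 0, ...) {
  cat(sprintf("Shape transitions: n = %d\n", x$n_total))
  pct <- round(x$percentages, digits)
  pct[x$percentages <= display_threshold] <- NA
  keep_r <- rowSums(!is.na(pct)) > 0
  keep_c <- colSums(!is.na(pct)) > 0
  if (any(keep_r)) {
    cat("Percentage of occurrence (from rows to columns):\n")
    print(pct[keep_r, keep_c, drop = FALSE], na.print = ".")
  }
  invisible(x)
}

#' Mean age-group proportions per shape
#'
#' For each shape, the mean over all ascribed entries (with a positive
#' total) of the juvenile, adult, and senior percentages; per entry the
#' three percentages sum to 100.
#'
#' @param series A `shape_series`, its entries data frame, or a list of
#'   `shape_series`.
#' @return Data frame with columns `shape`, `n`, `juvenile_pct`,
#'   `adult_pct`, `senior_pct`.
#' @export
age_group_proportions <- function(series) {
  e <- combine_entries(series)
  e <- e[e$shape != NOT_ASCRIBED & e$total > 0, , drop = FALSE]
  if (nrow(e) == 0)
    return(data.frame(shape = character(), n = integer(),
                      juvenile_pct = numeric(), adult_pct = numeric(),
                      senior_pct = numeric(), stringsAsFactors = FALSE))
  pj <- 100 * e$juvenile / e$total
  pa <- 100 * e$adult / e$total
  ps <- 100 * e$senior / e$total
  sh <- factor(e$shape, levels = SHAPES)
  out <- data.frame(
    shape = SHAPES, n = as.integer(table(sh)),
    juvenile_pct = as.numeric(tapply(pj, sh, mean)),
    adult_pct = as.numeric(tapply(pa, sh, mean)),
    senior_pct = as.numeric(tapply(ps, sh, mean)),
    stringsAsFactors = FALSE)
  out[out$n > 0, , drop = FALSE]
}

combine_entries <- function(series) {
  if (inherits(series, "shape_series")) return(series$entries)
  if (is.data.frame(series)) return(series)
  do.call(rbind, lapply(series, series_entries))
}

#' Peak-size analysis of shape series
#'
#' Per population-sex series: the maximum (ascribed) population size and
#' the shape in that year (earliest year on ties). Per shape, over all
#' ascribed occurrences: the count and the mean population size as a
#' percentage of the series maximum. Series with no ascribed entry are
#' excluded.
#'
#' @param series As in [age_group_proportions()].
#' @return A list with `per_shape` (data frame: `shape`, `n`,
#'   `mean_pct_of_max`, `n_at_max`) and `per_series` (data frame: one row
#'   per population-sex with `max_total`, `max_year`, `shape_at_max`).
#' @export
peak_analysis <- function(series) {
  e <- combine_entries(series)
  e <- e[e$shape != NOT_ASCRIBED, , drop = FALSE]
  per_series <- list()
  pct_rows <- list()
  for (key in split(seq_len(nrow(e)), paste(e$population, e$sex))) {
    g <- e[key, , drop = FALSE]
    g <- g[order(g$year), , drop = FALSE]
    imax <- which.max(g$total)      # earliest year on ties
    per_series[[length(per_series) + 1L]] <- data.frame(
      population = g$population[1], sex = g$sex[1],
      max_total = g$total[imax], max_year = g$year[imax],
      shape_at_max = g$shape[imax], stringsAsFactors = FALSE)
    pct_rows[[length(pct_rows) + 1L]] <- data.frame(
      shape = g$shape, pct_of_max = 100 * g$total / g$total[imax],
      stringsAsFactors = FALSE)
  }
  per_series <- do.call(rbind, per_series)
  pct <- do.call(rbind, pct_rows)
  sh <- factor(pct$shape, levels = SHAPES)
  at_max <- factor(per_series$shape_at_max, levels = SHAPES)
  per_shape <- data.frame(
    shape = SHAPES, n = as.integer(table(sh)),
    mean_pct_of_max = as.numeric(tapply(pct$pct_of_max, sh, mean)),
    n_at_max = as.integer(table(at_max)), stringsAsFactors = FALSE)
  list(per_shape = per_shape[per_shape$n > 0, , drop = FALSE],
       per_series = per_series)
}
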