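# Studbook records: reading, writing, regional filtering.
#
# A studbook is a plain table with one row per individual. Parent links are
# identifier references that may point outside a regional extract; such
# external links are kept but excluded from age-based curation rules.

STUDBOOK_COLUMNS <- c("individual_id", "sex", "birth_date", "birth_estimated",
                      "death_date", "status", "dam_id", "sire_id",
                      "dam_probability", "sire_probability", "wild_born",
                      "region")

SEX_LEVELS <- c("female", "male", "unknown")
STATUS_LEVELS <- c("dead", "alive", "lost")
REGION_LEVELS <- c("Europe", "NorthAmerica", "other")

new_studbook <- function(records, species, region_filter = NA_character_,
                         eligible = NA) {
  structure(list(records = records, species = species,
                 region_filter = region_filter, eligible = eligible),
            class = "studbook")
}

# Empty records table with the right column types.
empty_records <- function() {
  data.frame(individual_id = character(), sex = character(),
             birth_date = as.Date(character()), birth_estimated = logical(),
             death_date = as.Date(character()), status = character(),
             dam_id = character(), sire_id = character(),
             dam_probability = numeric(), sire_probability = numeric(),
             wild_born = logical(), region = character(),
             stringsAsFactors = FALSE)
}

validate_records <- function(records) {
  dup <- unique(records$individual_id[duplicated(records$individual_id)])
  abort_if(length(dup) > 0, "duplicate individual_id: %s",
           paste(dup, collapse = ", "))
  records$sex[is.na(records$sex) | records$sex == ""] <- "unknown"
  bad_sex <- setdiff(unique(records$sex), SEX_LEVELS)
  abort_if(length(bad_sex) > 0, "unknown sex code(s): %s",
           paste(bad_sex, collapse = ", "))
  bad_status <- setdiff(unique(records$status), STATUS_LEVELS)
  abort_if(length(bad_status) > 0, "unknown status code(s): %s",
           paste(bad_status, collapse = ", "))
  bad_dates <- !is.na(records$death_date) &
    records$death_date < records$birth_date
  abort_if(any(bad_dates), "death before birth for: %s",
           paste(records$individual_id[bad_dates], collapse = ", "))
  records
}

#' Read a studbook table
#'
#' Reads a comma-separated studbook (UTF-8, ISO-8601 dates) with one row per
#' individual. Rows with missing sex are retained with `sex = "unknown"`.
#' A missing mandatory column, an unparseable date, or a duplicated
#' `individual_id` is a hard error naming the offender.
#'
#' @param path CSV file path.
#' @param config A [species_config()] object attached to the studbook.
#' @return A `studbook` object: a list with elements `records`
#'   (data frame), `species`, `region_filter` and `eligible`.
#' @export
read_studbook <- function(path, config) {
  stopifnot(inherits(config, "species_config"))
  abort_if(!file.exists(path), "studbook file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("NA", ""))
  missing_cols <- setdiff(STUDBOOK_COLUMNS, names(raw))
  abort_if(length(missing_cols) > 0, "missing mandatory column(s): %s",
           paste(missing_cols, collapse = ", "))
  parse_date <- function(x, col) {
    out <- as.Date(rep(NA_character_, length(x)))
    ok <- !is.na(x)
    parsed <- as.Date(x[ok], format = "%Y-%m-%d")
    abort_if(anyNA(parsed), "unparseable %s for: %s", col,
             paste(raw$individual_id[ok][is.na(parsed)], collapse = ", "))
    out[ok] <- parsed
    out
  }
  records <- data.frame(
    individual_id = raw$individual_id,
    sex = raw$sex,
    birth_date = parse_date(raw$birth_date, "birth_date"),
    birth_estimated = as.logical(raw$birth_estimated),
    death_date = parse_date(raw$death_date, "death_date"),
    status = raw$status,
    dam_id = raw$dam_id,
    sire_id = raw$sire_id,
    dam_probability = as.numeric(raw$dam_probability),
    sire_probability = as.numeric(raw$sire_probability),
    wild_born = as.logical(raw$wild_born),
    region = raw$region,
    stringsAsFactors = FALSE
  )
  abort_if(anyNA(records$birth_date), "missing birth_date for: %s",
           paste(records$individual_id[is.na(records$birth_date)],
                 collapse = ", "))
  records <- validate_records(records)
  new_studbook(records, config)
}

#' Write a studbook table
#'
#' Inverse of [read_studbook()]: writes CSV with ISO-8601 dates and empty
#' cells for absent values, so that a read/write round trip reproduces the
#' records field for field.
#'
#' @param studbook A `studbook` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_studbook <- function(studbook, path) {
  stopifnot(inherits(studbook, "studbook"))
  rec <- studbook$records[, STUDBOOK_COLUMNS, drop = FALSE]
  out <- data.frame(lapply(rec, function(col) {
    if (inherits(col, "Date")) format(col, "%Y-%m-%d") else as.character(col)
  }), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Filter a studbook to one region and check eligibility
#'
#' Keeps the records of the named region and flags whether the population
#' is large enough for shape analysis (at least `min_ever` individuals ever
#' recorded there).
#'
#' @param studbook A `studbook` object.
#' @param region One of `"Europe"`, `"NorthAmerica"`, `"other"`.
#' @param min_ever Minimum number ever recorded; defaults to the species
#'   configuration (150).
#' @return A `studbook` with `region_filter` set and `eligible` TRUE/FALSE.
#' @export
filter_population <- function(studbook, region,
                              min_ever = studbook$species$min_individuals_ever) {
  stopifnot(inherits(studbook, "studbook"))
  abort_if(!region %in% REGION_LEVELS, "unknown region code: %s", region)
  abort_if(min_ever < 1, "min_ever must be >= 1")
  rec <- studbook$records[studbook$records$region == region, , drop = FALSE]
  rownames(rec) <- NULL
  new_studbook(rec, studbook$species, region_filter = region,
               eligible = nrow(rec) >= min_ever)
}

#' @export
print.studbook <- function(x, ...) {
  rec <- x$records
  cat(sprintf("Studbook of %s: %d individuals", x$species$species_name,
              nrow(rec)))
  if (!is.na(x$region_filter))
    cat(sprintf(" [%s%s]", x$region_filter,
                if (isFALSE(x$eligible)) ", ineligible" else ""))
  cat("\n")
  if (nrow(rec) > 0) {
    cat(sprintf("  sex: %s\n",
                paste(sprintf("%s %d", names(table(rec$sex)),
                              as.integer(table(rec$sex))), collapse = ", ")))
    cat(sprintf("  births %s..%s, %d dead, %d with a dam link\n",
                min(rec$birth_date), max(rec$birth_date),
                sum(rec$status == "dead"), sum(!is.na(rec$dam_id))))
  }
  invisible(x)
}

# Number of parent links present (dam + sire).
n_parent_links <- function(studbook) {
  sum(!is.na(studbook$records$dam_id)) + sum(!is.na(studbook$records$sire_id))
}
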