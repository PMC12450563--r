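# Studbook curation: parentage plausibility, litter grouping, interbirth
# intervals, and the maximum-longevity record.
#
# Every mutation of the studbook is logged in an audit report with one row
# per affected individual. Parent links may reference individuals outside
# the studbook (regional extracts); such links are kept but exempt from
# age-based rules, because the parent's birth date is unknown.

report_row <- function(rule, id, action, detail) {
  data.frame(rule = rule, individual_id = id, action = action,
             detail = detail, stringsAsFactors = FALSE)
}

empty_report <- function() {
  data.frame(rule = character(), individual_id = character(),
             action = character(), detail = character(),
             stringsAsFactors = FALSE)
}

#' Curate parentage links
#'
#' Applies the parentage plausibility rules, in order: (a) links with a
#' parentage probability below 100% are removed; (b) when dam and sire are
#' recorded with the same sex, the link of the parent with the incorrect
#' sex for its role is removed; (c) self-parentage links are removed;
#' (d) a male recorded as dam together with a female recorded as sire are
#' exchanged; (e), only when `afr_by_sex` is supplied, links whose parent
#' was younger than the age of first reproduction for its sex at the
#' offspring's birth are removed. Link removal never deletes individuals.
#'
#' @param studbook A `studbook` object.
#' @param afr_by_sex Optional named vector/list (`female`, `male`) of ages
#'   of first reproduction in years; enables rule (e).
#' @return A list with elements `studbook` (curated) and `report`
#'   (data frame: rule, individual_id, action, detail).
#' @export
curate_parentage <- function(studbook, afr_by_sex = NULL) {
  stopifnot(inherits(studbook, "studbook"))
  rec <- studbook$records
  rep <- list()

  drop_link <- function(which, idx, rule, detail) {
    id_col <- paste0(which, "_id")
    pr_col <- paste0(which, "_probability")
    for (i in idx) {
      rep[[length(rep) + 1L]] <<- report_row(
        rule, rec$individual_id[i], "parent_link_removed",
        sprintf("%s link to '%s' removed: %s", which, rec[[id_col]][i], detail))
    }
    rec[[id_col]][idx] <<- NA_character_
    rec[[pr_col]][idx] <<- NA_real_
  }

  # (a) parentage probability below 100%
  idx <- which(!is.na(rec$dam_id) & !is.na(rec$dam_probability) &
                 rec$dam_probability < 100)
  drop_link("dam", idx, "parentage_probability", "probability < 100%")
  idx <- which(!is.na(rec$sire_id) & !is.na(rec$sire_probability) &
                 rec$sire_probability < 100)
  drop_link("sire", idx, "parentage_probability", "probability < 100%")

  # (c) parent of itself
  idx <- which(!is.na(rec$dam_id) & rec$dam_id == rec$individual_id)
  drop_link("dam", idx, "self_parentage", "individual recorded as its own dam")
  idx <- which(!is.na(rec$sire_id) & rec$sire_id == rec$individual_id)
  drop_link("sire", idx, "self_parentage", "individual recorded as its own sire")

  # (b) two parents of the same recorded sex: the parent whose sex is wrong
  # for its role is removed; an unknown-sex pair cannot be adjudicated.
  dam_sex <- rec$sex[match(rec$dam_id, rec$individual_id)]
  sire_sex <- rec$sex[match(rec$sire_id, rec$individual_id)]
  both <- !is.na(rec$dam_id) & !is.na(rec$sire_id) &
    !is.na(dam_sex) & !is.na(sire_sex) & dam_sex == sire_sex
  drop_link("dam", which(both & dam_sex == "male"), "same_sex_parents",
            "dam and sire both male; male dam removed")
  drop_link("sire", which(both & dam_sex == "female"), "same_sex_parents",
            "dam and sire both female; female sire removed")

  # (d) male marked as dam with female marked as sire: exchange the two
  dam_sex <- rec$sex[match(rec$dam_id, rec$individual_id)]
  sire_sex <- rec$sex[match(rec$sire_id, rec$individual_id)]
  idx <- which(!is.na(rec$dam_id) & !is.na(rec$sire_id) &
                 !is.na(dam_sex) & !is.na(sire_sex) &
                 dam_sex == "male" & sire_sex == "female")
  if (length(idx) > 0) {
    for (i in idx) {
      rep[[length(rep) + 1L]] <- report_row(
        "dam_sire_swapped", rec$individual_id[i], "parents_swapped",
        sprintf("dam '%s' (male) and sire '%s' (female) exchanged",
                rec$dam_id[i], rec$sire_id[i]))
    }
    tmp_id <- rec$dam_id[idx]; tmp_pr <- rec$dam_probability[idx]
    rec$dam_id[idx] <- rec$sire_id[idx]
    rec$dam_probability[idx] <- rec$sire_probability[idx]
    rec$sire_id[idx] <- tmp_id
    rec$sire_probability[idx] <- tmp_pr
  }

  out <- new_studbook(rec, studbook$species, studbook$region_filter,
                      studbook$eligible)

  # (e) parents younger than the age of first reproduction
  if (!is.null(afr_by_sex)) {
    under <- apply_underage_rule(out, afr_by_sex)
    out <- under$studbook
    rep <- c(rep, list(under$report))
  }

  list(studbook = out,
       report = do.call(rbind, c(list(empty_report()), rep)))
}

# Rule (e): remove links whose parent, by its role sex, was younger than
# the age of first reproduction at the offspring's birth. Links to parents
# outside the studbook are exempt (unknown birth date).
apply_underage_rule <- function(studbook, afr_by_sex) {
  rec <- studbook$records
  afr_by_sex <- as.list(afr_by_sex)
  rep <- list()
  for (spec in list(c("dam", "female"), c("sire", "male"))) {
    which <- spec[1]; role_sex <- spec[2]
    afr <- afr_by_sex[[role_sex]]
    if (is.null(afr) || is.na(afr)) next
    id_col <- paste0(which, "_id"); pr_col <- paste0(which, "_probability")
    parent_birth <- rec$birth_date[match(rec[[id_col]], rec$individual_id)]
    age <- age_years_at(parent_birth, rec$birth_date)
    idx <- which(!is.na(rec[[id_col]]) & !is.na(parent_birth) & age < afr)
    for (i in idx) {
      rep[[length(rep) + 1L]] <- report_row(
        "underage_parent", rec$individual_id[i], "parent_link_removed",
        sprintf("%s link to '%s' removed: parent aged %.2f y < AFR %g y",
                which, rec[[id_col]][i], age[i], afr))
    }
    rec[[id_col]][idx] <- NA_character_
    rec[[pr_col]][idx] <- NA_real_
  }
  list(studbook = new_studbook(rec, studbook$species, studbook$region_filter,
                               studbook$eligible),
       report = do.call(rbind, c(list(empty_report()), rep)))
}

#' Maximum longevity record of a studbook
#'
#' The record holder is the oldest zoo-born, dead individual; wild-born
#' individuals (estimated birth dates) and living or lost individuals never
#' hold the record. The returned age is floored to whole years. A manual
#' override in the species configuration wins over the data.
#'
#' @param studbook A `studbook` object.
#' @return Maximum longevity in whole years.
#' @export
compute_max_longevity <- function(studbook) {
  stopifnot(inherits(studbook, "studbook"))
  override <- studbook$species$max_longevity_override
  if (!is.null(override)) return(as.integer(floor(override)))
  rec <- studbook$records
  ok <- !rec$wild_born & rec$status == "dead" & !is.na(rec$death_date)
  abort_if(!any(ok), paste0(
    "no zoo-born dead individual to define maximum longevity; ",
    "supply max_longevity_override in the species configuration"))
  max(age_class_at(rec$birth_date[ok], rec$death_date[ok]))
}

# Litters of one dam: single-linkage chaining of birth dates with gaps of
# at most `window` days. Returns a list of integer index vectors (into rec).
litters_of <- function(birth_dates, window) {
  ord <- order(birth_dates)
  d <- birth_dates[ord]
  gaps <- as.numeric(diff(d))
  grp <- cumsum(c(1, as.integer(gaps > window)))
  split(ord, grp)
}

# Median birth date of a litter: the earlier central date for even sizes.
litter_median_date <- function(dates) {
  sort(dates)[(length(dates) + 1L) %/% 2L]
}

#' Group litters and resolve oversized litters
#'
#' Same-dam births within the litter window (3 days by default) are one
#' litter; all members are re-dated to the litter's median birth date (the
#' earlier central date for even litter sizes). Litters larger than the
#' species' maximum litter size are treated as duplications and cut in
#' half: floor(size/2) members are removed uniformly at random under the
#' given seed.
#'
#' @param studbook A `studbook` object.
#' @param config A [species_config()]; defaults to the studbook's.
#' @param seed Integer seed controlling the random halving.
#' @return A list with `studbook` and `report`.
#' @export
curate_litters <- function(studbook, config = studbook$species, seed) {
  stopifnot(inherits(studbook, "studbook"))
  abort_if(missing(seed), "curate_litters() requires a seed")
  rec <- studbook$records
  rep <- list()
  removed <- character()
  with_seed(seed, {
    for (dam in unique(stats::na.omit(rec$dam_id))) {
      members <- which(!is.na(rec$dam_id) & rec$dam_id == dam)
      for (lit in litters_of(rec$birth_date[members],
                             config$litter_window_days)) {
        idx <- members[lit]
        med <- litter_median_date(rec$birth_date[idx])
        changed <- idx[rec$birth_date[idx] != med]
        for (i in changed) {
          rep[[length(rep) + 1L]] <- report_row(
            "litter_dates", rec$individual_id[i], "dates_merged",
            sprintf("birth date %s set to litter median %s (dam '%s')",
                    rec$birth_date[i], med, dam))
        }
        rec$birth_date[idx] <- med
        if (length(idx) > config$max_litter_size) {
          drop <- sample(idx, length(idx) %/% 2L)
          for (i in drop) {
            rep[[length(rep) + 1L]] <- report_row(
              "litter_oversize", rec$individual_id[i], "individuals_removed",
              sprintf("litter of %d (dam '%s', %s) exceeds maximum %d; removed",
                      length(idx), dam, med, config$max_litter_size))
          }
          removed <- c(removed, rec$individual_id[drop])
        }
      }
    }
  })
  if (length(removed) > 0) {
    rec <- rec[!rec$individual_id %in% removed, , drop = FALSE]
    rownames(rec) <- NULL
  }
  list(studbook = new_studbook(rec, studbook$species, studbook$region_filter,
                               studbook$eligible),
       report = do.call(rbind, c(list(empty_report()), rep)))
}

#' Remove implausibly short interbirth intervals
#'
#' For each dam, consecutive litter dates are compared. An interval shorter
#' than `interbirth_fraction` (90%) of the effective gestation (gestation
#' length, plus minimum pouch-eviction age for marsupials) marks the later
#' litter as invalid: the dam link of each of its members is removed.
#' Litter grouping ([curate_litters()]) must already have been applied.
#'
#' @inheritParams curate_litters
#' @return A list with `studbook` and `report`.
#' @export
curate_interbirth <- function(studbook, config = studbook$species) {
  stopifnot(inherits(studbook, "studbook"))
  min_days <- config$interbirth_fraction * effective_gestation(config)
  rec <- studbook$records
  rep <- list()
  for (dam in unique(stats::na.omit(rec$dam_id))) {
    members <- which(!is.na(rec$dam_id) & rec$dam_id == dam)
    dates <- sort(unique(rec$birth_date[members]))
    if (length(dates) < 2) next
    bad_dates <- dates[-1][as.numeric(diff(dates)) < min_days]
    for (bd in as.list(bad_dates)) {
      idx <- members[rec$birth_date[members] == bd]
      for (i in idx) {
        rep[[length(rep) + 1L]] <- report_row(
          "interbirth", rec$individual_id[i], "parent_link_removed",
          sprintf("dam link to '%s' removed: interbirth interval < %.0f d",
                  dam, min_days))
      }
      rec$dam_id[idx] <- NA_character_
      rec$dam_probability[idx] <- NA_real_
    }
  }
  list(studbook = new_studbook(rec, studbook$species, studbook$region_filter,
                               studbook$eligible),
       report = do.call(rbind, c(list(empty_report()), rep)))
}

#' Run the full curation pipeline
#'
#' Applies, in order: parentage rules (a)-(d), litter grouping, the
#' interbirth-interval rule, a provisional estimate of the age of first
#' reproduction per sex from the surviving links (overridden by any
#' configured value), the underage-parent rule (e) in a single pass, and
#' the maximum-longevity computation. Litters are grouped before interbirth
#' intervals are checked so that litter mates are never flagged as
#' implausible siblings.
#'
#' @inheritParams curate_litters
#' @return A list with `studbook` (curated), `report` (consolidated audit
#'   data frame), `afr` (named numeric, the AFR per sex used by rule (e)),
#'   and `max_longevity` (whole years).
#' @export
run_curation <- function(studbook, config = studbook$species, seed) {
  abort_if(missing(seed), "run_curation() requires a seed")
  p <- curate_parentage(studbook)
  l <- curate_litters(p$studbook, config, seed)
  ib <- curate_interbirth(l$studbook, config)
  afr <- c(
    female = tryCatch(estimate_afr(ib$studbook, "female", config),
                      error = function(e) NA_real_),
    male = tryCatch(estimate_afr(ib$studbook, "male", config),
                    error = function(e) NA_real_)
  )
  e <- apply_underage_rule(ib$studbook, afr)
  longevity <- tryCatch(compute_max_longevity(e$studbook),
                        error = function(err) NA_integer_)
  list(studbook = e$studbook,
       report = rbind(p$report, l$report, ib$report, e$report),
       afr = afr,
       max_longevity = longevity)
}
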