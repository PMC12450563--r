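test_that("parent links below 100% probability are removed", {
  sb <- make_studbook(list(
    rec_row("F1", "female", "1990-01-01"),
    rec_row("M1", "male", "1990-01-01"),
    rec_row("K1", birth = "1995-01-01", dam = "F1", sire = "M1", dam_p = 80)
  ))
  out <- curate_parentage(sb)
  expect_true(is.na(out$studbook$records$dam_id[3]))
  expect_equal(out$studbook$records$sire_id[3], "M1")
  expect_equal(out$report$rule, "parentage_probability")
})

test_that("self-parentage links are removed", {
  sb <- make_studbook(list(
    rec_row("F1", "female", "1990-01-01"),
    rec_row("K1", sex = "male", birth = "1995-01-01", dam = "F1",
            sire = "K1")
  ))
  out <- curate_parentage(sb)
  expect_true(is.na(out$studbook$records$sire_id[2]))
  expect_equal(out$report$rule, "self_parentage")
})

test_that("same-sex parent pairs lose the wrongly sexed link", {
  sb <- make_studbook(list(
    rec_row("M1", "male", "1990-01-01"),
    rec_row("M2", "male", "1990-01-01"),
    rec_row("F1", "female", "1990-01-01"),
    rec_row("F2", "female", "1990-01-01"),
    rec_row("K1", birth = "1995-01-01", dam = "M1", sire = "M2"),
    rec_row("K2", birth = "1995-01-01", dam = "F1", sire = "F2")
  ))
  out <- curate_parentage(sb)
  rec <- out$studbook$records
  expect_true(is.na(rec$dam_id[rec$individual_id == "K1"]))   # male dam
  expect_equal(rec$sire_id[rec$individual_id == "K1"], "M2")
  expect_true(is.na(rec$sire_id[rec$individual_id == "K2"]))  # female sire
  expect_equal(rec$dam_id[rec$individual_id == "K2"], "F1")
  expect_equal(nrow(out$studbook$records), 6L)  # no individual deleted
})

test_that("male-as-dam with female-as-sire is exchanged, both retained", {
  sb <- make_studbook(list(
    rec_row("F1", "female", "1990-01-01"),
    rec_row("M1", "male", "1990-01-01"),
    rec_row("K1", birth = "1995-01-01", dam = "M1", sire = "F1")
  ))
  out <- curate_parentage(sb)
  rec <- out$studbook$records
  expect_equal(rec$dam_id[3], "F1")
  expect_equal(rec$sire_id[3], "M1")
  expect_equal(out$report$action, "parents_swapped")
})

test_that("underage parents lose their link under a configured AFR", {
  sb <- make_studbook(list(
    rec_row("F1", "female", "1994-01-01"),   # aged 1.5 at K1's birth
    rec_row("M1", "male", "1990-01-01"),
    rec_row("K1", birth = "1995-07-01", dam = "F1", sire = "M1")
  ))
  out <- curate_parentage(sb, afr_by_sex = c(female = 3, male = 3))
  expect_true(is.na(out$studbook$records$dam_id[3]))
  expect_equal(out$studbook$records$sire_id[3], "M1")
  expect_equal(out$report$rule, "underage_parent")
})

test_that("the longevity record holder is the oldest zoo-born dead individual", {
  sb <- make_studbook(list(
    rec_row("A", birth = "1990-01-01", death = "2002-04-20"),  # 12.3 y
    rec_row("B", birth = "1980-01-01", death = "2000-09-15"),  # 20.7 y
    rec_row("C", birth = "1970-01-01", death = "1995-01-01", wild = TRUE),
    rec_row("D", birth = "1985-01-01")                          # alive
  ))
  expect_equal(compute_max_longevity(sb), 20L)

  living <- make_studbook(list(rec_row("D", birth = "1985-01-01")))
  expect_error(compute_max_longevity(living), "override")

  sb$species$max_longevity_override <- 22
  expect_equal(compute_max_longevity(sb), 22L)
})

test_that("implausibly short interbirth intervals drop the later litter's dam", {
  two_litters <- function(gap_days, config = test_config()) {
    make_studbook(list(
      rec_row("F1", "female", "1990-01-01"),
      rec_row("K1", birth = "1995-01-01", dam = "F1"),
      rec_row("K2", birth = as.character(as.Date("1995-01-01") + gap_days),
              dam = "F1")
    ), config)
  }
  # gestation 100 d: threshold 90 d
  out <- curate_interbirth(two_litters(60))
  expect_true(is.na(out$studbook$records$dam_id[3]))
  expect_equal(out$studbook$records$dam_id[2], "F1")

  out <- curate_interbirth(two_litters(95))
  expect_equal(nrow(out$report), 0L)

  # marsupial: effective gestation 30 + 60 = 90, threshold 81
  mars <- species_config("Wallaby", gestation_days = 30, is_marsupial = TRUE,
                         pouch_eviction_min_days = 60, max_litter_size = 4)
  out <- curate_interbirth(two_litters(70, mars))
  expect_true(is.na(out$studbook$records$dam_id[3]))
  out <- curate_interbirth(two_litters(85, mars))
  expect_equal(nrow(out$report), 0L)
})

test_that("litters are grouped to the median date and oversizes halved", {
  sb <- make_studbook(c(list(rec_row("F1", "female", "1990-01-01")),
                        lapply(0:2, function(d)
                          rec_row(paste0("K", d),
                                  birth = as.character(as.Date("1995-01-01") + d),
                                  dam = "F1"))))
  out <- curate_litters(sb, seed = 1)
  rec <- out$studbook$records
  expect_equal(unique(rec$birth_date[rec$dam_id %in% "F1"]),
               as.Date("1995-01-02"))
  expect_equal(sort(unique(out$report$action)), "dates_merged")

  # births five days apart are separate litters, dates untouched
  sb2 <- make_studbook(list(rec_row("F1", "female", "1990-01-01"),
                            rec_row("K1", birth = "1995-01-01", dam = "F1"),
                            rec_row("K2", birth = "1995-01-06", dam = "F1")))
  out2 <- curate_litters(sb2, seed = 1)
  expect_equal(nrow(out2$report), 0L)
  expect_equal(out2$studbook$records$birth_date,
               sb2$records$birth_date)

  # an 8-member litter with a maximum of 4 keeps 4 members
  sb3 <- make_studbook(c(list(rec_row("F1", "female", "1990-01-01")),
                         lapply(1:8, function(i)
                           rec_row(paste0("K", i), birth = "1995-01-01",
                                   dam = "F1"))))
  out3 <- curate_litters(sb3, seed = 7)
  expect_equal(sum(!is.na(out3$studbook$records$dam_id)), 4L)
  expect_equal(sum(out3$report$action == "individuals_removed"), 4L)
})

test_that("the full pipeline is audited, deterministic and idempotent", {
  clean <- family_studbook()
  res <- run_curation(clean, seed = 5)
  expect_equal(nrow(res$report), 0L)
  expect_equal(res$studbook$records, clean$records)

  # one same-sex pair plus one short interbirth pair: exactly two entries
  dirty <- make_studbook(list(
    rec_row("M1", "male", "1990-01-01"),
    rec_row("M2", "male", "1990-01-01"),
    rec_row("F1", "female", "1990-01-01"),
    rec_row("K1", birth = "1995-01-01", dam = "M1", sire = "M2"),
    rec_row("K2", birth = "1996-01-01", dam = "F1"),
    rec_row("K3", birth = "1996-03-01", dam = "F1")   # 60 d < 90 d
  ))
  res2 <- run_curation(dirty, seed = 5)
  expect_equal(nrow(res2$report), 2L)
  expect_setequal(res2$report$rule, c("same_sex_parents", "interbirth"))

  # curation never adds links or individuals, and removals are audited
  n_links <- function(s) popshape:::n_parent_links(s)
  expect_lte(n_links(res2$studbook), n_links(dirty))
  expect_equal(n_links(dirty) - n_links(res2$studbook),
               sum(res2$report$action == "parent_link_removed"))

  # determinism and idempotence
  res2b <- run_curation(dirty, seed = 5)
  expect_identical(res2$studbook$records, res2b$studbook$records)
  res3 <- run_curation(res2$studbook, seed = 5)
  expect_equal(nrow(res3$report), 0L)
})
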