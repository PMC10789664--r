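test_that("eligibility is strictly more than the threshold, per scope", {
  df <- rbind(records_with_counts(c(point = 30L), "a", "mother"),
              records_with_counts(c(point = 31L), "b", "mother"),
              records_with_counts(c(point = 31L), "c", "peer"))
  df$record_id <- sprintf("r%04d", seq_len(nrow(df)))
  prof <- profile_individuals(validate_records(df))
  expect_equal(select_eligible(prof, "mother"), "b")
  expect_equal(select_eligible(prof, "other"), "c")
  expect_equal(select_eligible(prof, "peer"), "c")
  expect_equal(select_eligible(prof, "older"), character(0))
})

test_that("eligibility equals a brute-force filter on randomised profiles", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(5:15, 1L)
    prof <- data.frame(
      individual_id = sprintf("i%02d", seq_len(n)),
      effort_mother = sample(0:60, n, replace = TRUE),
      effort_peer = sample(0:40, n, replace = TRUE),
      effort_older = sample(0:40, n, replace = TRUE))
    thr <- sample(10:40, 1L)
    for (sc in c("mother", "other", "peer", "older")) {
      eff <- switch(sc, mother = prof$effort_mother, peer = prof$effort_peer,
                    older = prof$effort_older,
                    other = prof$effort_peer + prof$effort_older)
      expect_equal(select_eligible(prof, sc, thr),
                   prof$individual_id[eff > thr])
    }
  }
})

test_that("customary-use threshold keeps only types used at least twice", {
  df <- records_with_counts(c(point = 5L, hit_other = 1L, touch = 26L),
                            partner_class = "peer")
  rep <- build_repertoire(validate_records(df), "ind1", "other")
  expect_equal(rep$signal_types, c("point", "touch"))
  expect_equal(rep$size, 2L)
  expect_equal(rep$effort, 32L)
})

test_that("an individual with one type and 31 records has size 1", {
  df <- records_with_counts(c(point = 31L))
  rep <- build_repertoire(validate_records(df), "ind1", "mother")
  expect_equal(rep$size, 1L)
  expect_equal(rep$effort, 31L)
})

test_that("building for an ineligible individual or unknown scope errors", {
  df <- records_with_counts(c(point = 30L))
  expect_error(build_repertoire(validate_records(df), "ind1", "mother"),
               "not eligible")
  prof <- profile_individuals(validate_records(df))
  expect_error(select_eligible(prof, "stranger"))
})

test_that("repertoires equal a brute-force recount on synthetic data", {
  ds <- generate_dataset(small_config(4L), seed = 7L)
  reps <- build_repertoires(ds$records, "other")
  expect_gt(length(reps), 0L)
  for (r in reps) {
    sub <- ds$records[ds$records$individual_id == r$individual_id &
                        ds$records$partner_class %in% c("peer", "older"), ]
    counts <- table(sub$signal_type)
    expect_equal(r$signal_types, sort(names(counts)[counts >= 2]))
    expect_equal(r$effort, nrow(sub))
    gcounts <- table(sub$social_goal)
    expect_equal(r$goal_set, sort(names(gcounts)[gcounts >= 2]))
    expect_lte(r$goal_count, 7L)
  }
})

test_that("mother- and other-scope repertoires use disjoint record subsets", {
  ds <- generate_dataset(small_config(4L), seed = 19L)
  prof <- profile_individuals(ds$records)
  both <- intersect(select_eligible(prof, "mother"),
                    select_eligible(prof, "other"))
  expect_gt(length(both), 0L)
  eff <- scope_effort(prof, "mother")[both] + scope_effort(prof, "other")[both]
  total <- table(ds$records$individual_id)[both]
  expect_equal(unname(eff), as.integer(total))
})

test_that("raising thresholds never increases sizes or inventory counts", {
  ds <- generate_dataset(small_config(5L), seed = 23L)
  base <- build_repertoires(ds$records, "other", min_uses = 2L,
                            min_interactions = 30L)
  for (min_uses in c(3L, 5L)) {
    tight <- build_repertoires(ds$records, "other", min_uses = min_uses,
                               min_interactions = 30L)
    for (id in names(tight)) {
      expect_lte(tight[[id]]$size, base[[id]]$size)
      expect_true(all(tight[[id]]$signal_types %in% base[[id]]$signal_types))
    }
    inv_base <- inventory_counts(base)
    inv_tight <- inventory_counts(tight)
    expect_true(all(inv_tight$n_types <= inv_base$n_types))
  }
  stricter <- build_repertoires(ds$records, "other", min_interactions = 60L)
  expect_true(all(names(stricter) %in% names(base)))
})

test_that("inventory cells are unions of individual repertoires", {
  reps <- list(fake_repertoire("a", c("x", "y")),
               fake_repertoire("b", c("y", "z")))
  inv <- inventory_counts(reps)
  expect_equal(inv$n_types[inv$setting == "wild" & inv$species == "bornean"],
               3L)
  expect_equal(inv$n_types[inv$setting == "all" & inv$species == "all"], 3L)

  single <- inventory_counts(list(fake_repertoire("a", c("x", "y", "z"))))
  expect_equal(single$n_types[single$setting == "all" &
                                single$species == "all"], 3L)
  expect_error(inventory_counts(list()), "no repertoires")
})

test_that("inventory equals a brute-force union over filtered records", {
  ds <- generate_dataset(small_config(4L), seed = 29L)
  reps <- build_repertoires(ds$records, "other")
  inv <- inventory_counts(reps)
  # brute force: re-filter raw records per individual, union per cell
  brute_union <- function(keep) {
    types <- character(0)
    for (r in reps[keep]) types <- union(types, r$signal_types)
    length(types)
  }
  settings <- vapply(reps, `[[`, "", "setting")
  species <- vapply(reps, `[[`, "", "species")
  for (i in seq_len(nrow(inv))) {
    keep <- (inv$setting[i] == "all" | settings == inv$setting[i]) &
      (inv$species[i] == "all" | species == inv$species[i])
    expect_equal(inv$n_types[i], brute_union(keep))
    expect_lte(inv$n_types[i],
               inv$n_types[inv$setting == "all" & inv$species == "all"])
  }
})

test_that("mother-scope inventory is a subset of the global inventory", {
  ds <- generate_dataset(synthetic_config(), seed = 5L)
  reps_m <- build_repertoires(ds$records, "mother")
  reps_o <- build_repertoires(ds$records, "other")
  types_m <- unique(unlist(lapply(reps_m, `[[`, "signal_types")))
  types_all <- union(types_m,
                     unique(unlist(lapply(reps_o, `[[`, "signal_types"))))
  expect_true(all(types_m %in% types_all))
  # generator truth: the tail of the inventory is never mother-directed
  expect_false(any(sprintf("sig%02d", 36:41) %in%
                     ds$records$signal_type[ds$records$partner_class ==
                                              "mother"]))
})

test_that("goal_min_uses = 1 counts every observed goal", {
  df <- records_with_counts(c(point = 40L))
  df$social_goal <- c("groom", rep("play_affiliate", 39L))
  rep2 <- build_repertoire(validate_records(df), "ind1", "mother")
  rep1 <- build_repertoire(validate_records(df), "ind1", "mother",
                           goal_min_uses = 1L)
  expect_equal(rep2$goal_set, "play_affiliate")
  expect_equal(sort(rep1$goal_set), c("groom", "play_affiliate"))
})
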