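test_that("generation is deterministic and respects empty designs", {
  cfg <- small_config(3L)
  a <- generate_dataset(cfg, seed = 77L)
  b <- generate_dataset(cfg, seed = 77L)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$latent, b$truth$latent)
  c2 <- generate_dataset(cfg, seed = 78L)
  expect_false(identical(a$records$signal_type, c2$records$signal_type))

  empty <- synthetic_config(design = data.frame(
    species = "bornean", setting = "wild", group_id = "site",
    n_individuals = 0L))
  pop <- generate_population(empty, seed = 1L)
  expect_equal(nrow(pop$population), 0L)
  expect_equal(nrow(generate_records(pop, empty, seed = 1L)), 0L)
})

test_that("per-individual sub-seeds keep draws stable under design growth", {
  cfg_small <- small_config(3L)
  bigger <- cfg_small$design
  bigger$n_individuals <- c(3L, 5L)
  cfg_big <- synthetic_config(design = bigger)
  pa <- generate_population(cfg_small, seed = 4L)
  pb <- generate_population(cfg_big, seed = 4L)
  shared <- pa$population$individual_id
  expect_identical(pa$truth$latent$other[shared],
                   pb$truth$latent$other[shared])
})

test_that("emitted records validate and conserve effort draws", {
  ds <- generate_dataset(small_config(4L), seed = 12L)
  expect_silent(validate_records(ds$records))
  draws <- attr(ds$records, "effort_draws")
  expect_equal(nrow(ds$records),
               sum(draws$effort_mother + draws$effort_other))
  # an individual with a single latent type emits only that type
  one_type <- ds$truth$latent$mother
  one_type[["x"]] <- "sig01"
  expect_true(all(vapply(names(ds$truth$latent$other), function(id) {
    obs <- unique(ds$records$signal_type[
      ds$records$individual_id == id & ds$records$partner_class != "mother"])
    all(obs %in% ds$truth$latent$other[[id]])
  }, logical(1))))
})

test_that("full setting-cores make within-setting repertoires identical", {
  cfg <- synthetic_config(core_fraction = 1, design = small_config(4L)$design)
  pop <- generate_population(cfg, seed = 9L)
  expect_equal(expected_dice(cfg, "bornean", "other", "wild", "wild"), 1)
  expect_lt(expected_dice(cfg, "bornean", "other", "wild", "captive"), 1)
  reps <- latent_repertoire_objects(pop, "other")
  dm <- build_dice_matrix(reps)
  p <- which(upper.tri(dm$values), arr.ind = TRUE)
  same <- dm$settings[p[, 1]] == dm$settings[p[, 2]]
  expect_true(all(dm$values[p][same] == 1))
  expect_true(all(dm$values[p][!same] < 1))
})

test_that("simulated within/between Dice means track the closed-form expectation", {
  cfg <- small_config(10L)
  means <- replicate(20, {
    pop <- generate_population(cfg, seed = sample.int(1e6, 1L))
    dm <- build_dice_matrix(latent_repertoire_objects(pop, "other"))
    tab <- mean_dice_table(dm)
    c(tab$mean_dice[tab$category == "within_settings"],
      tab$mean_dice[tab$category == "between_settings"])
  })
  exp_within <- mean(c(expected_dice(cfg, "bornean", "other", "wild", "wild"),
                       expected_dice(cfg, "bornean", "other", "captive",
                                     "captive")))
  exp_between <- expected_dice(cfg, "bornean", "other", "wild", "captive")
  expect_lt(abs(mean(means[1, ]) - exp_within), 0.05)
  expect_lt(abs(mean(means[2, ]) - exp_between), 0.05)
})

test_that("the expected within-between Dice gap is monotone in core fraction", {
  # size effects off, so the gap is driven by the core structure alone
  gaps <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(cf) {
    cfg <- synthetic_config(core_fraction = cf, beta_setting_captive = 0,
                            beta_species_sumatran = 0)
    tab <- signalrep:::expected_dice_table(cfg)
    tab$within_minus_between[tab$species == "bornean" & tab$scope == "other"]
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_lt(abs(gaps[1]), 1e-9)  # no core structure, no gap

  # with the default setting effect on, size heterogeneity alone already
  # separates within from between pairs; cores only widen the gap
  gaps_eff <- vapply(c(0, 0.5, 1), function(cf) {
    tab <- signalrep:::expected_dice_table(synthetic_config(core_fraction = cf))
    tab$within_minus_between[tab$species == "bornean" & tab$scope == "other"]
  }, numeric(1))
  expect_true(all(diff(gaps_eff) > 0))
  expect_gt(gaps_eff[1], 0)
})

test_that("the customary filter recovers the latent repertoire at high effort", {
  cfg <- synthetic_config(design = small_config(3L)$design,
                          effort_range = c(6000L, 6000L),
                          p_subthreshold = 0)
  ds <- generate_dataset(cfg, seed = 14L)
  reps <- build_repertoires(ds$records, "other")
  for (r in reps) {
    expect_equal(r$signal_types, ds$truth$latent$other[[r$individual_id]])
  }
})

test_that("null_scenario removes every systematic contrast", {
  cfg <- synthetic_config()
  ncfg <- null_scenario(cfg)
  expect_equal(ncfg$beta_setting_captive, 0)
  expect_equal(ncfg$beta_species_sumatran, 0)
  expect_equal(ncfg$core_fraction, 0)
  expect_equal(ncfg$sigma_group, 0)
  # expected sizes equal across cells under the null
  sizes <- outer(c("wild", "captive"), c("bornean", "sumatran"),
                 Vectorize(function(se, sp)
                   signalrep:::cell_expected_size(ncfg, sp, se, "other")))
  expect_true(all(sizes == sizes[1, 1]))
})

test_that("model-based count simulation matches its declared truth", {
  d <- simulate_size_counts(n = 300L, n_groups = 10L, seed = 2L)
  truth <- attr(d, "truth")
  expect_equal(truth$coefficients[["settingwild"]], -0.42)
  expect_equal(truth$coefficients[["speciessumatran"]], 0.52)
  expect_identical(d, simulate_size_counts(n = 300L, n_groups = 10L,
                                           seed = 2L))
  # group-level cells: every group carries one setting and one species
  expect_true(all(rowSums(table(d$group_id, d$setting) > 0) == 1))
  expect_true(all(rowSums(table(d$group_id, d$species) > 0) == 1))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_types = 0L))
  expect_error(synthetic_config(mother_pool_size = 99L))
  expect_error(synthetic_config(core_fraction = 1.5))
  expect_error(synthetic_config(goal_probs = c(play_affiliate = 1)))
})
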