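# Synthetic interaction-record generator.
#
# Emulates the statistical structure the analyses assume: a fixed global
# inventory of 41 signal types and 7 social goals; two species crossed
# with two research settings over multiple groups (one field site per
# species, several zoos); per-individual observation effort of 32-776
# signal instances per partner scope (with occasional sub-threshold
# individuals to exercise the eligibility filter); multiplicative setting
# and species effects on the expected other-directed (but not
# mother-directed) latent repertoire size; and a "setting-core" overlap
# structure so that repertoires are more similar within than between
# settings. Ground truth (latent repertoires, true effects) is returned
# alongside for calibration and recovery studies.

#' Configuration of the synthetic interaction-record generator
#'
#' Defaults reproduce the study conditions the analyses target: 27
#' immatures (8 wild / 5 captive Bornean across one field site and three
#' zoos; 7 wild / 7 captive Sumatran across one field site and two zoos),
#' ages uniform on 1-9 years, effort uniform on 32-776 instances per
#' partner scope with a 10% chance of a sub-threshold (5-30) draw,
#' a 41-type global inventory of which only the first 35 types can be
#' directed at mothers, captive and Sumatran multiplicative effects of
#' `exp(0.42)` and `exp(0.52)` on expected other-directed latent
#' repertoire size only, and a within-setting core covering 70% of the
#' expected repertoire with 45% core sharing between settings.
#'
#' @param n_types global signal-type inventory size.
#' @param mother_pool_size number of leading inventory types available for
#'   mother-directed signalling (the remainder are never mother-directed).
#' @param design data frame with columns `species`, `setting`, `group_id`,
#'   `n_individuals`.
#' @param age_range,effort_range,subthreshold_range uniform draw ranges.
#' @param p_subthreshold probability that an individual-by-scope effort
#'   draw falls below the eligibility threshold.
#' @param base_size named vector: expected latent repertoire size of a
#'   wild Bornean individual, per scope.
#' @param beta_setting_captive,beta_species_sumatran log-scale effects on
#'   expected other-directed latent size.
#' @param sigma_group SD of the log-scale group random effect on latent size.
#' @param core_fraction fraction of the expected repertoire made of the
#'   deterministic setting core (1 = identical repertoires within a cell).
#' @param core_overlap fraction of the smaller setting core shared between
#'   the wild and captive cores.
#' @param zipf_exponent usage-frequency skew within a repertoire
#'   (weights `1/rank^a`), so rare types can fail the customary-use filter.
#' @param peer_frac_range per-individual range of the probability that an
#'   other-directed act targets a peer rather than an older partner.
#' @param goal_probs named probability vector over the 7 social goals
#'   (population mean of the per-individual goal preferences).
#' @param goal_concentration Dirichlet concentration of per-individual goal
#'   preferences around `goal_probs`; smaller values give more
#'   between-individual variation in goal use, so the number of distinct
#'   goals an individual communicates for varies rather than saturating.
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    n_types = 41L,
    mother_pool_size = 35L,
    design = default_design(),
    age_range = c(1, 9),
    effort_range = c(32L, 776L),
    subthreshold_range = c(5L, 30L),
    p_subthreshold = 0.1,
    base_size = c(mother = 12, other = 9),
    beta_setting_captive = 0.42,
    beta_species_sumatran = 0.52,
    sigma_group = 0.2,
    core_fraction = 0.7,
    core_overlap = 0.45,
    zipf_exponent = 1,
    peer_frac_range = c(0.2, 0.8),
    goal_probs = c(co_locomote = 0.20, share_food_object = 0.15,
                   groom = 0.10, play_affiliate = 0.30, move_away = 0.10,
                   sexual_contact = 0.05, stop_action = 0.10),
    goal_concentration = 3) {
  stopifnot(n_types >= 1L, mother_pool_size >= 1L,
            mother_pool_size <= n_types,
            is.data.frame(design),
            all(c("species", "setting", "group_id", "n_individuals") %in%
                  names(design)),
            all(design$species %in% record_levels$species),
            all(design$setting %in% record_levels$setting),
            all(design$n_individuals >= 0L),
            p_subthreshold >= 0, p_subthreshold <= 1,
            all(base_size > 0), sigma_group >= 0,
            core_fraction >= 0, core_fraction <= 1,
            core_overlap >= 0, core_overlap <= 1,
            all(names(base_size) == c("mother", "other")),
            abs(sum(goal_probs) - 1) < 1e-8,
            setequal(names(goal_probs), record_levels$social_goal),
            goal_concentration > 0)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Default population design (groups and head counts)
#' @return data frame with one row per group.
#' @export
default_design <- function() {
  data.frame(
    species = c("bornean", "bornean", "bornean", "bornean",
                "sumatran", "sumatran", "sumatran"),
    setting = c("wild", "captive", "captive", "captive",
                "wild", "captive", "captive"),
    group_id = c("site_b1", "zoo_b1", "zoo_b2", "zoo_b3",
                 "site_s1", "zoo_s1", "zoo_s2"),
    n_individuals = c(8L, 2L, 2L, 1L, 7L, 4L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Exchangeable-null variant of a generator configuration
#'
#' Returns a copy of the configuration with every systematic contrast
#' switched off — setting and species effects zero, setting-core structure
#' off (`core_fraction = 0`), and group effects zero — so all individuals'
#' latent repertoires and sizes are independent and identically
#' distributed. Under this null, setting labels are exchangeable and the
#' permutation tests and full-vs-null likelihood-ratio tests should reject
#' at their nominal rates.
#'
#' @param config a [synthetic_config()].
#' @return A `"synthetic_config"`.
#' @export
null_scenario <- function(config) {
  config$beta_setting_captive <- 0
  config$beta_species_sumatran <- 0
  config$core_fraction <- 0
  config$sigma_group <- 0
  config
}

signal_labels <- function(n) sprintf("sig%02d", seq_len(n))

sub_seed <- function(seed, k) as.integer((as.numeric(seed) + 7919 * k) %%
                                           2147483647)

# expected latent size of a cell (no group/individual noise), per scope
cell_expected_size <- function(config, species, setting, scope) {
  s <- config$base_size[[scope]]
  if (scope == "other") {
    if (setting == "captive") s <- s * exp(config$beta_setting_captive)
    if (species == "sumatran") s <- s * exp(config$beta_species_sumatran)
  }
  s
}

# deterministic setting cores per (species, scope): wild and captive cores
# share round(core_overlap * min size) leading types, then occupy disjoint
# blocks of the scope's type pool
setting_cores <- function(config, species, scope) {
  pool_n <- if (scope == "mother") config$mother_pool_size else config$n_types
  labs <- signal_labels(config$n_types)[seq_len(pool_n)]
  m_w <- round(config$core_fraction *
                 cell_expected_size(config, species, "wild", scope))
  m_c <- round(config$core_fraction *
                 cell_expected_size(config, species, "captive", scope))
  n_shared <- round(config$core_overlap * min(m_w, m_c))
  total <- n_shared + (m_w - n_shared) + (m_c - n_shared)
  if (total > pool_n) stop("type pool too small for the requested cores")
  shared <- labs[seq_len(n_shared)]
  wild_only <- labs[seq_len(m_w - n_shared) + n_shared]
  captive_only <- labs[seq_len(m_c - n_shared) + n_shared + (m_w - n_shared)]
  list(wild = c(shared, wild_only), captive = c(shared, captive_only),
       pool = labs)
}

# one individual's latent repertoire: the cell core plus private types,
# each non-core pool type included with the probability that makes the
# expected size equal the individual's target
draw_latent_repertoire <- function(config, species, setting, scope,
                                   target_size) {
  cores <- setting_cores(config, species, scope)
  core <- cores[[setting]]
  pool <- cores$pool
  non_core <- setdiff(pool, core)
  p_priv <- if (length(non_core) == 0L) 0 else
    min(1, max(0, (1 - config$core_fraction) * target_size /
                 length(non_core)))
  private <- non_core[stats::runif(length(non_core)) < p_priv]
  rep_i <- c(core, private)
  if (length(rep_i) == 0L) rep_i <- sample(pool, 1L)
  sort(rep_i)
}

#' Generate a synthetic population with latent ground truth
#'
#' Draws individuals per the design (attributes, group effects, latent
#' mother- and other-directed repertoires) without yet emitting records.
#' Per-individual sub-seeds are derived deterministically from the master
#' seed, so an individual's draws are stable under design edits elsewhere.
#'
#' @param config a [synthetic_config()].
#' @param seed master integer seed.
#' @return List with `population` (data frame: `individual_id`, `species`,
#'   `setting`, `group_id`, `sex`, `age_years`, `peer_frac`, per-scope
#'   expected sizes) and `truth` (list: `latent` — per scope, named list
#'   of latent repertoires —, `beta`, `sigma2`, `group_effects`,
#'   `expected_dice`, `config`).
#' @export
generate_population <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(seed, 0L))
  groups <- config$design
  u_g <- stats::setNames(stats::rnorm(nrow(groups), 0, config$sigma_group),
                         groups$group_id)
  rows <- list()
  latent <- list(mother = list(), other = list())
  goal_pref <- list()
  k <- 0L
  for (g in seq_len(nrow(groups))) {
    for (i in seq_len(groups$n_individuals[g])) {
      k <- k + 1L
      set.seed(sub_seed(seed, k))
      id <- sprintf("%s_ind%02d", groups$group_id[g], i)
      sex <- sample(record_levels$sex, 1L)
      age <- stats::runif(1L, config$age_range[1L], config$age_range[2L])
      peer_frac <- stats::runif(1L, config$peer_frac_range[1L],
                                config$peer_frac_range[2L])
      # Dirichlet via gamma draws: individual goal preferences around the
      # population distribution
      gam <- stats::rgamma(length(config$goal_probs),
                           shape = config$goal_concentration * 7 *
                             config$goal_probs)
      goal_pref[[id]] <- stats::setNames(gam / sum(gam),
                                         names(config$goal_probs))
      exp_size <- vapply(c("mother", "other"), function(sc) {
        cell_expected_size(config, groups$species[g], groups$setting[g], sc) *
          exp(u_g[[groups$group_id[g]]])
      }, numeric(1))
      for (sc in c("mother", "other")) {
        latent[[sc]][[id]] <- draw_latent_repertoire(
          config, groups$species[g], groups$setting[g], sc, exp_size[[sc]])
      }
      rows[[k]] <- data.frame(
        individual_id = id, species = groups$species[g],
        setting = groups$setting[g], group_id = groups$group_id[g],
        sex = sex, age_years = round(age, 2L), peer_frac = peer_frac,
        expected_size_mother = exp_size[["mother"]],
        expected_size_other = exp_size[["other"]],
        stringsAsFactors = FALSE)
    }
  }
  population <- if (k == 0L) {
    data.frame(individual_id = character(0), species = character(0),
               setting = character(0), group_id = character(0),
               sex = character(0), age_years = numeric(0),
               peer_frac = numeric(0), expected_size_mother = numeric(0),
               expected_size_other = numeric(0))
  } else do.call(rbind, rows)
  rownames(population) <- NULL
  list(population = population,
       truth = list(latent = latent, goal_pref = goal_pref,
                    beta = c(setting_captive = config$beta_setting_captive,
                             species_sumatran = config$beta_species_sumatran),
                    sigma2 = config$sigma_group^2,
                    group_effects = u_g,
                    expected_dice = expected_dice_table(config),
                    config = config))
}

#' Approximate expected Dice similarity under the inclusion model
#'
#' First-order (ratio of expectations) approximation of the expected Dice
#' coefficient between the latent repertoires of two individuals from
#' given settings of one species and scope, using cell-level expected
#' sizes. Exact in the `core_fraction = 1` limit, where all individuals of
#' a cell carry exactly the cell core.
#'
#' @param config a [synthetic_config()].
#' @param species,scope the cell population.
#' @param setting_a,setting_b settings of the two individuals.
#' @return A number in `[0, 1]`.
#' @export
expected_dice <- function(config, species, scope, setting_a, setting_b) {
  cores <- setting_cores(config, species, scope)
  pool_n <- length(cores$pool)
  ca <- cores[[setting_a]]
  cb <- cores[[setting_b]]
  p_of <- function(setting, core_len) {
    s <- cell_expected_size(config, species, setting, scope)
    non_core <- pool_n - core_len
    if (non_core == 0L) 0 else
      min(1, max(0, (1 - config$core_fraction) * s / non_core))
  }
  pa <- p_of(setting_a, length(ca))
  pb <- p_of(setting_b, length(cb))
  shared <- length(intersect(ca, cb))
  only_a <- length(setdiff(ca, cb))
  only_b <- length(setdiff(cb, ca))
  outside <- pool_n - shared - only_a - only_b
  e_inter <- shared + only_a * pb + only_b * pa + outside * pa * pb
  e_a <- length(ca) + (pool_n - length(ca)) * pa
  e_b <- length(cb) + (pool_n - length(cb)) * pb
  2 * e_inter / (e_a + e_b)
}

expected_dice_table <- function(config) {
  grid <- expand.grid(species = record_levels$species,
                      scope = c("mother", "other"),
                      stringsAsFactors = FALSE)
  grid$within_wild <- NA_real_
  grid$within_captive <- NA_real_
  grid$between <- NA_real_
  for (r in seq_len(nrow(grid))) {
    grid$within_wild[r] <- expected_dice(config, grid$species[r],
                                         grid$scope[r], "wild", "wild")
    grid$within_captive[r] <- expected_dice(config, grid$species[r],
                                            grid$scope[r], "captive",
                                            "captive")
    grid$between[r] <- expected_dice(config, grid$species[r], grid$scope[r],
                                     "wild", "captive")
  }
  grid$within_minus_between <-
    (grid$within_wild + grid$within_captive) / 2 - grid$between
  grid
}

# Zipf usage weights over a latent repertoire (rank = inventory order)
zipf_weights <- function(n, exponent) {
  w <- 1 / seq_len(n)^exponent
  w / sum(w)
}

#' Generate interaction records for a synthetic population
#'
#' For each individual and partner scope, draws an observation effort
#' (uniform on the configured range, or a sub-threshold count with
#' probability `p_subthreshold`), then draws that many signal types from
#' the individual's latent repertoire under Zipf-skewed usage frequencies
#' (so rare types can occur once and fail the customary-use filter) and
#' social goals from the configured goal distribution, identical across
#' settings. Other-directed acts are split between peer and older partners
#' by the individual's `peer_frac`. Mother-directed generation carries no
#' setting or species effect.
#'
#' @param population output of [generate_population()].
#' @param config the same [synthetic_config()].
#' @param seed master integer seed (record draws use sub-seeds offset from
#'   the population's).
#' @return Validated records data frame; attribute `"effort_draws"` holds
#'   the generator's per-individual, per-scope effort bookkeeping.
#' @export
generate_records <- function(population, config, seed) {
  pop <- population$population
  latent <- population$truth$latent
  all_rows <- list()
  draws <- list()
  for (k in seq_len(nrow(pop))) {
    set.seed(sub_seed(seed, 100000L + k))
    ind <- pop[k, ]
    eff <- c(mother = NA_integer_, other = NA_integer_)
    for (sc in c("mother", "other")) {
      sub <- stats::runif(1L) < config$p_subthreshold
      rng <- if (sub) config$subthreshold_range else config$effort_range
      eff[[sc]] <- sample(seq.int(rng[1L], rng[2L]), 1L)
      rep_i <- latent[[sc]][[ind$individual_id]]
      types <- sample(rep_i, eff[[sc]], replace = TRUE,
                      prob = zipf_weights(length(rep_i),
                                          config$zipf_exponent))
      pref <- population$truth$goal_pref[[ind$individual_id]]
      goals <- sample(names(pref), eff[[sc]], replace = TRUE, prob = pref)
      partner <- if (sc == "mother") rep("mother", eff[[sc]]) else
        ifelse(stats::runif(eff[[sc]]) < ind$peer_frac, "peer", "older")
      all_rows[[length(all_rows) + 1L]] <- data.frame(
        individual_id = ind$individual_id, species = ind$species,
        setting = ind$setting, group_id = ind$group_id, sex = ind$sex,
        age_years = ind$age_years, partner_class = partner,
        signal_type = types, social_goal = goals, stringsAsFactors = FALSE)
    }
    draws[[k]] <- data.frame(individual_id = ind$individual_id,
                             effort_mother = eff[["mother"]],
                             effort_other = eff[["other"]],
                             stringsAsFactors = FALSE)
  }
  if (length(all_rows) == 0L) {
    records <- data.frame(record_id = character(0))
    for (col in setdiff(record_columns, "record_id")) records[[col]] <- character(0)
    records$age_years <- numeric(0)
    return(validate_records(records))
  }
  records <- do.call(rbind, all_rows)
  records$record_id <- sprintf("r%06d", seq_len(nrow(records)))
  records <- records[, record_columns]
  rownames(records) <- NULL
  records <- validate_records(records)
  attr(records, "effort_draws") <- do.call(rbind, draws)
  records
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [generate_population()] then [generate_records()].
#'
#' @inheritParams generate_population
#' @return List with `records`, `population`, `truth`.
#' @export
generate_dataset <- function(config = synthetic_config(), seed = 20180101L) {
  pop <- generate_population(config, seed)
  records <- generate_records(pop, config, seed)
  list(records = records, population = pop$population, truth = pop$truth)
}

#' Simulate per-individual counts directly from the Poisson mixed model
#'
#' Draws repertoire-size-like counts from the exact model the inference
#' module fits: log-link Poisson with uncentred age and age-squared,
#' group-level setting and species effects, sex, a log-z effort slope and
#' a Gaussian group random intercept. Groups are assigned to
#' setting-by-species cells in rotation; effects default to the
#' generator's other-scope values. Used for estimator calibration and
#' parameter-recovery studies where the data-generating model must equal
#' the fitted model.
#'
#' @param n number of individuals.
#' @param n_groups number of groups (evenly filled).
#' @param beta_intercept log expected count at the reference levels (wild
#'   Bornean female) and mean log effort.
#' @param beta_setting_captive,beta_species_sumatran,beta_age,beta_age2,beta_sex_male,beta_effort
#'   link-scale coefficients; the effort coefficient applies to log-z
#'   transformed effort.
#' @param sigma_group SD of the group random intercept.
#' @param assign `"group"` assigns setting and species at the group level
#'   (each group is one zoo or field site, as in the observational design);
#'   `"individual"` randomises them within groups (a confound-free design
#'   for estimator-calibration studies, where Wald intervals for the
#'   contrasts are not limited by the number of groups).
#' @param seed integer seed.
#' @return data frame with `size`, `age_years`, `setting`, `species`,
#'   `sex`, `effort`, `group_id`; attribute `"truth"` holds the named
#'   coefficient vector (fit parameterisation: `settingwild = -
#'   beta_setting_captive`) and `sigma2`.
#' @export
simulate_size_counts <- function(n = 200L, n_groups = 10L,
                                 beta_intercept = log(9),
                                 beta_setting_captive = 0.42,
                                 beta_species_sumatran = 0.52,
                                 beta_age = 0, beta_age2 = 0,
                                 beta_sex_male = 0, beta_effort = 0.349,
                                 sigma_group = 0.2,
                                 assign = c("group", "individual"),
                                 seed = 1L) {
  assign <- match.arg(assign)
  stopifnot(n_groups >= 2L, n >= n_groups)
  set.seed(seed)
  cells <- expand.grid(setting = record_levels$setting,
                       species = record_levels$species,
                       stringsAsFactors = FALSE)
  gcell <- cells[rep_len(seq_len(4L), n_groups), ]
  group_id <- sprintf("g%02d", seq_len(n_groups))
  u_g <- stats::rnorm(n_groups, 0, sigma_group)
  g_of <- rep_len(seq_len(n_groups), n)
  if (assign == "group") {
    setting <- gcell$setting[g_of]
    species <- gcell$species[g_of]
  } else {
    setting <- sample(record_levels$setting, n, replace = TRUE)
    species <- sample(record_levels$species, n, replace = TRUE)
  }
  age <- stats::runif(n, 1, 9)
  sex <- sample(record_levels$sex, n, replace = TRUE)
  effort <- sample(32:776, n, replace = TRUE)
  lz <- log_z_transform(effort)
  eta <- beta_intercept +
    beta_setting_captive * (setting == "captive") +
    beta_species_sumatran * (species == "sumatran") +
    beta_age * age + beta_age2 * age^2 + beta_sex_male * (sex == "male") +
    beta_effort * lz + u_g[g_of]
  size <- stats::rpois(n, exp(eta))
  out <- data.frame(size = size, age_years = age,
                    setting = setting,
                    species = species, sex = sex,
                    effort = effort, group_id = group_id[g_of],
                    stringsAsFactors = FALSE)
  # fit parameterisation: reference levels are captive and bornean
  attr(out, "truth") <- list(
    coefficients = c("(Intercept)" = beta_intercept + beta_setting_captive,
                     "age_years" = beta_age, "I(age_years^2)" = beta_age2,
                     "settingwild" = -beta_setting_captive,
                     "speciessumatran" = beta_species_sumatran,
                     "sexmale" = beta_sex_male,
                     "log_z_effort" = beta_effort),
    sigma2 = sigma_group^2)
  out
}

#' View latent ground-truth repertoires as repertoire objects
#'
#' Wraps the generator's latent (true) per-individual repertoires in the
#' same objects [build_repertoire()] produces from records, so similarity
#' analyses can run directly on the ground truth — e.g. for permutation
#' calibration studies that need no record-level noise.
#'
#' @param population output of [generate_population()].
#' @param scope `"mother"` or `"other"`.
#' @return Named list of `"repertoire"` objects (effort and goal fields
#'   unset).
#' @export
latent_repertoire_objects <- function(population, scope = "other") {
  scope <- match.arg(scope, c("mother", "other"))
  pop <- population$population
  latent <- population$truth$latent[[scope]]
  reps <- lapply(seq_len(nrow(pop)), function(k) {
    types <- latent[[pop$individual_id[k]]]
    structure(list(individual_id = pop$individual_id[k], scope = scope,
                   signal_types = types, size = length(types),
                   effort = NA_integer_, goal_set = character(0),
                   goal_count = NA_integer_, species = pop$species[k],
                   setting = pop$setting[k], group_id = pop$group_id[k],
                   sex = pop$sex[k], age_years = pop$age_years[k]),
              class = "repertoire")
  })
  stats::setNames(reps, pop$individual_id)
}
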