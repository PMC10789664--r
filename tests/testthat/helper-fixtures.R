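# In-code fixtures shared across the suite.

# minimal valid record rows; override any field per row via ...
make_records <- function(n = 3L, individual_id = "ind1", species = "bornean",
                         setting = "wild", group_id = "site1",
                         sex = "female", age_years = 4, partner_class = "mother",
                         signal_type = "point", social_goal = "groom") {
  data.frame(
    record_id = sprintf("r%04d", seq_len(n)),
    individual_id = rep_len(individual_id, n),
    species = rep_len(species, n),
    setting = rep_len(setting, n),
    group_id = rep_len(group_id, n),
    sex = rep_len(sex, n),
    age_years = rep_len(age_years, n),
    partner_class = rep_len(partner_class, n),
    signal_type = rep_len(signal_type, n),
    social_goal = rep_len(social_goal, n),
    stringsAsFactors = FALSE
  )
}

# records for one individual with given per-type counts in one scope
records_with_counts <- function(type_counts, individual_id = "ind1",
                                partner_class = "mother", ...) {
  types <- rep(names(type_counts), times = type_counts)
  make_records(n = length(types), individual_id = individual_id,
               partner_class = partner_class, ...)[
                 , , drop = FALSE] -> df
  df$signal_type <- types
  df
}

# a repertoire object without going through records (for Dice tests)
fake_repertoire <- function(id, types, setting = "wild",
                            species = "bornean", scope = "other",
                            group_id = "g1") {
  structure(list(individual_id = id, scope = scope,
                 signal_types = types, size = length(types),
                 effort = 100L, goal_set = character(0), goal_count = 0L,
                 species = species, setting = setting, group_id = group_id,
                 sex = "female", age_years = 4), class = "repertoire")
}

# a dice_matrix with hand-set pair values; labels per individual
fake_dice_matrix <- function(values, settings, species = "bornean",
                             scope = "other") {
  n <- length(settings)
  ids <- sprintf("i%02d", seq_len(n))
  dimnames(values) <- list(ids, ids)
  diag(values) <- NA_real_
  structure(list(values = values, individual_ids = ids, settings = settings,
                 species = species, scope = scope), class = "dice_matrix")
}

# small two-group, one-species generator config (fast calibration unit)
small_config <- function(n_per_cell = 6L) {
  synthetic_config(design = data.frame(
    species = "bornean", setting = c("wild", "captive"),
    group_id = c("site", "zoo"),
    n_individuals = c(n_per_cell, n_per_cell)))
}
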