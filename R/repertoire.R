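# Customary-repertoire construction: eligibility and customary-use filters.

#' Individuals eligible for repertoire analysis in a partner scope
#'
#' An individual enters the analysis for a partner scope only if it
#' contributed strictly more than `min_interactions` signal instances in
#' that scope (default 30; the strict reading of "more than 30
#' interactions"). Eligibility is scope-specific: an individual may
#' qualify for the mother scope but not the other scope, or vice versa.
#'
#' @param profiles output of [profile_individuals()].
#' @param scope partner scope: `"mother"`, `"other"`, `"peer"` or `"older"`.
#' @param min_interactions eligibility threshold; inclusion requires
#'   effort `> min_interactions`.
#' @return Character vector of eligible `individual_id`s (profile order).
#' @export
select_eligible <- function(profiles, scope, min_interactions = 30L) {
  eff <- scope_effort(profiles, scope)
  names(eff)[eff > min_interactions]
}

#' Build one individual's customary repertoire in a partner scope
#'
#' The customary repertoire is the set of signal types the individual used
#' at least `min_uses` times (default 2) towards partners of the given
#' scope. The set of presumed social goals is filtered with the same
#' occurrence rule (threshold `goal_min_uses`, defaulting to `min_uses`;
#' set to 1 to count every observed goal).
#'
#' @param records validated records data frame.
#' @param individual_id the subject.
#' @param scope partner scope (`"mother"`, `"other"`, `"peer"`, `"older"`).
#' @param min_uses customary-use threshold for signal types.
#' @param min_interactions eligibility threshold checked before building.
#' @param goal_min_uses occurrence threshold for social goals.
#' @return An object of class `"repertoire"`: a list with
#'   `individual_id`, `scope`, `signal_types` (sorted character vector),
#'   `size`, `effort`, `goal_set`, `goal_count`, and the individual's
#'   `species`, `setting`, `group_id`, `sex`, `age_years`.
#' @export
build_repertoire <- function(records, individual_id, scope,
                             min_uses = 2L, min_interactions = 30L,
                             goal_min_uses = min_uses) {
  sub <- scope_records(records[records$individual_id == individual_id, ,
                               drop = FALSE], scope)
  effort <- nrow(sub)
  if (effort <= min_interactions) {
    stop("individual '", individual_id, "' is not eligible in scope '",
         scope, "' (effort ", effort, " <= ", min_interactions, ")")
  }
  type_counts <- table(sub$signal_type)
  types <- sort(names(type_counts)[type_counts >= min_uses])
  goal_counts <- table(sub$social_goal)
  goals <- sort(names(goal_counts)[goal_counts >= goal_min_uses])
  structure(list(
    individual_id = individual_id,
    scope = scope,
    signal_types = types,
    size = length(types),
    effort = effort,
    goal_set = goals,
    goal_count = length(goals),
    species = sub$species[1L],
    setting = sub$setting[1L],
    group_id = sub$group_id[1L],
    sex = sub$sex[1L],
    age_years = sub$age_years[1L]
  ), class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> %s [%s-directed] %s/%s %s\n",
              x$individual_id, x$scope, x$species, x$setting, x$group_id))
  cat(sprintf("  %d customary signal types from %d instances; %d goals\n",
              x$size, x$effort, x$goal_count))
  invisible(x)
}

#' Build customary repertoires for all eligible individuals in a scope
#'
#' @inheritParams build_repertoire
#' @param records validated records data frame.
#' @param scope partner scope.
#' @return Named list of [build_repertoire()] objects, one per eligible
#'   individual.
#' @export
build_repertoires <- function(records, scope, min_uses = 2L,
                              min_interactions = 30L,
                              goal_min_uses = min_uses) {
  profiles <- profile_individuals(records)
  ids <- select_eligible(profiles, scope, min_interactions)
  reps <- lapply(ids, function(id) {
    build_repertoire(records, id, scope, min_uses = min_uses,
                     min_interactions = min_interactions,
                     goal_min_uses = goal_min_uses)
  })
  stats::setNames(reps, ids)
}

#' Flatten repertoires into a per-individual analysis table
#'
#' One row per repertoire with the response variables (`size`,
#' `goal_count`), the subject attributes, and the scope effort — the input
#' expected by [fit_poisson_glmm()].
#'
#' @param repertoires list returned by [build_repertoires()].
#' @return data frame with columns `individual_id`, `scope`, `size`,
#'   `goal_count`, `effort`, `species`, `setting`, `group_id`, `sex`,
#'   `age_years`.
#' @export
repertoire_table <- function(repertoires) {
  stopifnot(length(repertoires) > 0L)
  rows <- lapply(repertoires, function(r) {
    data.frame(individual_id = r$individual_id, scope = r$scope,
               size = r$size, goal_count = r$goal_count, effort = r$effort,
               species = r$species, setting = r$setting,
               group_id = r$group_id, sex = r$sex, age_years = r$age_years,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inventory of distinct customary signal types by setting and species
#'
#' Tabulates, for a collection of customary repertoires from one partner
#' scope, the number of distinct signal types (the union of individual
#' repertoires) within each setting-by-species cell, plus per-setting and
#' overall margins. To tabulate all observed (unfiltered) types instead,
#' build the repertoires with `min_uses = 1`.
#'
#' @param repertoires list returned by [build_repertoires()] (all one scope).
#' @return data frame with columns `scope`, `setting`, `species`,
#'   `n_types`; margin rows use `"all"`.
#' @export
inventory_counts <- function(repertoires) {
  if (length(repertoires) == 0L) stop("no repertoires supplied")
  scope <- unique(vapply(repertoires, `[[`, "", "scope"))
  stopifnot(length(scope) == 1L)
  union_size <- function(reps) length(unique(unlist(lapply(reps, `[[`,
                                                           "signal_types"))))
  settings <- vapply(repertoires, `[[`, "", "setting")
  species <- vapply(repertoires, `[[`, "", "species")
  cells <- expand.grid(setting = c(record_levels$setting, "all"),
                       species = c(record_levels$species, "all"),
                       stringsAsFactors = FALSE)
  cells$n_types <- vapply(seq_len(nrow(cells)), function(i) {
    keep <- (cells$setting[i] == "all" | settings == cells$setting[i]) &
            (cells$species[i] == "all" | species == cells$species[i])
    union_size(repertoires[keep])
  }, integer(1))
  data.frame(scope = scope, cells, stringsAsFactors = FALSE)
}
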