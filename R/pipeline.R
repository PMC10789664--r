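# End-to-end orchestration: records -> profiles -> repertoires ->
# inventories -> Dice matrices -> permutation tests -> mixed models,
# with all artifacts written as plain CSV/JSON plus a run manifest.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

glmm_fit_artifact <- function(full, null) {
  test <- lrt(full, null)
  drop1_tab <- drop1_lrt(full)
  stab <- tryCatch(stability_by_group_deletion(full),
                   error = function(e) list(ranges = NULL,
                                            failures = conditionMessage(e)))
  list(
    response = full$response,
    n_obs = full$n_obs,
    n_groups = full$n_groups,
    coefficients = data.frame(term = rownames(full$coefficients),
                              estimate = full$coefficients[, "estimate"],
                              se = full$coefficients[, "se"],
                              row.names = NULL),
    sigma2 = full$sigma2,
    logLik_full = full$logLik,
    logLik_null = null$logLik,
    converged = full$converged && null$converged,
    singular = full$singular,
    lrt_full_null = unclass(test),
    drop1 = drop1_tab,
    dispersion = overdispersion(full),
    vif = as.list(vif_main_effects(full)),
    stability = stab
  )
}

#' Run the full repertoire analysis pipeline
#'
#' Executes every analysis stage over a record table (supplied or freshly
#' simulated) and writes all artifacts into `out_dir`: validated records,
#' per-individual profiles, customary repertoires for the four partner
#' scopes, the signal-type inventory table, per-species Dice matrices and
#' category means, both permutation contrasts per species and scope,
#' Poisson mixed models (full and null, with LRTs, drop-one tables and
#' diagnostics) of repertoire size and social-goal count for the mother
#' and other scopes, and a JSON run manifest with seeds, counts and
#' per-stage timings. Any stage failure aborts with a stage-named error.
#'
#' @param records validated records data frame, or `NULL` to simulate.
#' @param sim_config [synthetic_config()] used when `records` is `NULL`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for simulation and permutation tests.
#' @param n_perm permutations per test.
#' @param min_interactions,min_uses,goal_min_uses filter thresholds.
#' @return `out_dir`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(records = NULL, sim_config = synthetic_config(),
                         out_dir, seed = 20180101L, n_perm = 1000L,
                         min_interactions = 30L, min_uses = 2L,
                         goal_min_uses = min_uses) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  clock <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    out <- run_stage(name, expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3L)
    out
  }

  simulated <- is.null(records)
  if (simulated) {
    records <- clock("simulate", generate_dataset(sim_config, seed)$records)
  } else {
    records <- clock("validate", validate_records(records))
  }
  write_records(records, file.path(out_dir, "records.csv"))

  profiles <- clock("profile", profile_individuals(records))
  write_profiles(profiles, file.path(out_dir, "profiles.json"))

  scopes <- c("mother", "other", "peer", "older")
  reps <- clock("repertoires", {
    r <- lapply(scopes, function(sc) {
      build_repertoires(records, sc, min_uses = min_uses,
                        min_interactions = min_interactions,
                        goal_min_uses = goal_min_uses)
    })
    names(r) <- scopes
    r
  })
  for (sc in scopes) {
    jsonlite::write_json(lapply(reps[[sc]], unclass),
                         file.path(out_dir, paste0("repertoires_", sc,
                                                   ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  inventory <- clock("inventory", {
    do.call(rbind, lapply(c("mother", "other"), function(sc) {
      if (length(reps[[sc]]) == 0L) return(NULL)
      inventory_counts(reps[[sc]])
    }))
  })
  utils::write.csv(inventory, file.path(out_dir, "inventory.csv"),
                   row.names = FALSE)

  # Dice matrices and permutation tests, per species x scope
  matrices <- list()
  perm_rows <- list()
  clock("similarity", {
    for (sp in record_levels$species) {
      for (sc in c("mother", "other")) {
        sel <- Filter(function(r) r$species == sp, reps[[sc]])
        key <- paste(sp, sc, sep = "_")
        if (length(sel) < 2L ||
            length(unique(vapply(sel, `[[`, "", "setting"))) < 2L) next
        dm <- build_dice_matrix(sel)
        matrices[[key]] <- dm
        write_dice_matrix(dm, file.path(out_dir, paste0("dice_", key,
                                                        ".csv")))
        for (cmp in c("within_vs_between",
                      "captive_within_vs_wild_within")) {
          ok <- tryCatch({overlap_statistic(dm, cmp); TRUE},
                         error = function(e) FALSE)
          if (!ok) next
          pr <- matrix_permutation_test(dm, cmp, n_perm = n_perm,
                                        seed = sub_seed(seed,
                                                        length(perm_rows) + 1L))
          write_perm_result(pr, file.path(out_dir,
                                          paste0("perm_", key, "_", cmp,
                                                 ".json")))
          perm_rows[[length(perm_rows) + 1L]] <- data.frame(
            species = sp, scope = sc, comparison = cmp,
            observed_stat = pr$observed_stat, p_value = pr$p_value,
            p_lower = pr$p_lower, decision = pr$decision,
            n_perm = pr$n_perm, seed = pr$seed, stringsAsFactors = FALSE)
        }
      }
    }
  })
  perm_summary <- if (length(perm_rows) > 0L) do.call(rbind, perm_rows) else
    data.frame()
  utils::write.csv(perm_summary, file.path(out_dir, "perm_results.csv"),
                   row.names = FALSE)
  dice_means <- if (length(matrices) > 0L) mean_dice_table(matrices) else
    data.frame()
  utils::write.csv(dice_means, file.path(out_dir, "dice_means.csv"),
                   row.names = FALSE)

  # mixed models: size and goal count, mother- and other-directed
  glmm_artifacts <- list()
  clock("glmm", {
    for (sc in c("mother", "other")) {
      if (length(reps[[sc]]) < 2L) next
      tbl <- repertoire_table(reps[[sc]])
      if (length(unique(tbl$group_id)) < 2L) next
      for (resp in c("size", "goal_count")) {
        key <- paste(resp, sc, sep = "_")
        art <- tryCatch({
          full <- fit_poisson_glmm(tbl, resp, "full")
          null <- fit_poisson_glmm(tbl, resp, "null")
          glmm_fit_artifact(full, null)
        }, error = function(e) list(error = conditionMessage(e)))
        glmm_artifacts[[key]] <- art
        jsonlite::write_json(art, file.path(out_dir, paste0("glmm_", key,
                                                            ".json")),
                             auto_unbox = TRUE, digits = NA, na = "null",
                             dataframe = "rows", pretty = TRUE)
      }
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("signalrep")),
    seed = seed, n_perm = n_perm,
    min_interactions = min_interactions, min_uses = min_uses,
    goal_min_uses = goal_min_uses,
    simulated = simulated,
    sim_config = if (simulated) unclass(sim_config) else NULL,
    counts = list(
      n_records = nrow(records),
      n_records_mother = sum(records$partner_class == "mother"),
      n_records_other = sum(records$partner_class != "mother"),
      n_individuals = nrow(profiles),
      n_eligible = lapply(stats::setNames(scopes, scopes),
                          function(sc) length(reps[[sc]]))
    ),
    timings_s = timings,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3L)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows", pretty = TRUE)
  render_summary(out_dir)
  invisible(out_dir)
}

fmt_or_dash <- function(x, digits) {
  ifelse(is.na(x), "—", formatC(x, format = "f", digits = digits))
}

#' Render the human-readable run report from pipeline artifacts
#'
#' A pure view over the artifacts of [run_pipeline()]: reads the
#' inventory, Dice-mean, permutation and mixed-model files from `out_dir`
#' and writes `report.txt` mirroring the study's table layouts (signal-type
#' counts by setting and species; mean Dice within / between / within-
#' captive / within-wild; coefficient tables). No value is recomputed, so
#' deleting and re-rendering the report reproduces it byte-identically.
#' Dice means are displayed to 2 decimals, coefficients to 3; empty
#' categories render as an em dash.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @return Path of the report, invisibly.
#' @export
render_summary <- function(out_dir) {
  need <- function(f) {
    p <- file.path(out_dir, f)
    if (!file.exists(p)) stop("missing upstream artifact: ", f)
    p
  }
  manifest <- jsonlite::read_json(need("manifest.json"))
  lines <- c("Non-vocal signal repertoire analysis - run report",
             sprintf("seed %s; %s records from %s individuals",
                     manifest$seed, manifest$counts$n_records,
                     manifest$counts$n_individuals),
             sprintf("eligible individuals: mother %s, other %s, peer %s, older %s",
                     manifest$counts$n_eligible$mother,
                     manifest$counts$n_eligible$other,
                     manifest$counts$n_eligible$peer,
                     manifest$counts$n_eligible$older),
             "")

  inv <- utils::read.csv(need("inventory.csv"), stringsAsFactors = FALSE)
  lines <- c(lines, "Distinct customary signal types (union over individuals)")
  if (nrow(inv) > 0L) {
    for (sc in unique(inv$scope)) {
      sub <- inv[inv$scope == sc, ]
      cell <- function(se, sp) {
        v <- sub$n_types[sub$setting == se & sub$species == sp]
        if (length(v) == 0L) "—" else as.character(v)
      }
      lines <- c(lines, sprintf(
        "  %-6s captive: bornean %s, sumatran %s | wild: bornean %s, sumatran %s | all %s",
        paste0(sc, "-directed:"), cell("captive", "bornean"),
        cell("captive", "sumatran"), cell("wild", "bornean"),
        cell("wild", "sumatran"), cell("all", "all")))
    }
  }
  lines <- c(lines, "")

  dm <- utils::read.csv(need("dice_means.csv"), stringsAsFactors = FALSE)
  lines <- c(lines, "Mean Dice coefficients by pair category")
  if (nrow(dm) > 0L) {
    for (i in seq_len(nrow(dm))) {
      lines <- c(lines, sprintf("  %-8s %-6s %-22s %s", dm$species[i],
                                dm$scope[i], dm$category[i],
                                fmt_or_dash(dm$mean_dice[i], 2L)))
    }
  }
  lines <- c(lines, "")

  pm <- utils::read.csv(need("perm_results.csv"), stringsAsFactors = FALSE)
  lines <- c(lines, "Matrix permutation tests (upper-tail P, add-one)")
  if (nrow(pm) > 0L) {
    for (i in seq_len(nrow(pm))) {
      lines <- c(lines, sprintf(
        "  %-8s %-6s %-30s stat %s  P %s  %s", pm$species[i], pm$scope[i],
        pm$comparison[i], fmt_or_dash(pm$observed_stat[i], 3L),
        fmt_or_dash(pm$p_value[i], 4L), pm$decision[i]))
    }
  }
  lines <- c(lines, "")

  glmm_files <- sort(list.files(out_dir, pattern = "^glmm_.*\\.json$"))
  for (f in glmm_files) {
    art <- jsonlite::read_json(file.path(out_dir, f), simplifyVector = TRUE)
    label <- sub("^glmm_(.*)\\.json$", "\\1", f)
    if (!is.null(art$error)) {
      lines <- c(lines, sprintf("Mixed model %s: failed (%s)", label,
                                art$error), "")
      next
    }
    lines <- c(lines, sprintf(
      "Mixed model of %s (n = %s, %s groups): full-vs-null chi-square(%s) = %s, P = %s",
      label, art$n_obs, art$n_groups, art$lrt_full_null$df,
      fmt_or_dash(art$lrt_full_null$chi_square, 3L),
      fmt_or_dash(art$lrt_full_null$p_value, 4L)))
    co <- art$coefficients
    d1 <- art$drop1
    for (i in seq_len(nrow(co))) {
      dp <- d1$p_value[match(co$term[i], d1$term)]
      lines <- c(lines, sprintf("  %-18s %s ± %s%s", co$term[i],
                                fmt_or_dash(co$estimate[i], 3L),
                                fmt_or_dash(co$se[i], 3L),
                                ifelse(is.na(dp), "",
                                       sprintf("  (drop-one P %s)",
                                               fmt_or_dash(dp, 4L)))))
    }
    lines <- c(lines, sprintf(
      "  random-intercept variance %s; dispersion %s; max VIF %s",
      fmt_or_dash(art$sigma2, 4L), fmt_or_dash(art$dispersion, 3L),
      fmt_or_dash(max(unlist(art$vif)), 2L)), "")
  }

  path <- file.path(out_dir, "report.txt")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
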