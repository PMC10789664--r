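#!/usr/bin/env Rscript
# Apply the inclusion filters and build customary repertoires: an
# individual enters a partner scope with more than 30 signal instances
# there, and its repertoire is the set of signal types it used at least
# twice in that scope. Produces the per-scope repertoire files and the
# signal-type inventory table (distinct types by setting and species).

library(signalrep)

out <- "results/tables"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
records <- read_records("results/data/records.csv")
profiles <- profile_individuals(records)

cat(sprintf("%d individuals observed\n", nrow(profiles)))
for (sc in c("mother", "other", "peer", "older")) {
  elig <- select_eligible(profiles, sc)
  cat(sprintf("  %-6s scope: %2d eligible (effort > 30)\n", sc,
              length(elig)))
}

inv_all <- NULL
for (sc in c("mother", "other", "peer", "older")) {
  reps <- build_repertoires(records, sc)
  jsonlite::write_json(lapply(reps, unclass),
                       file.path("results/data",
                                 sprintf("repertoires_%s.json", sc)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (sc %in% c("mother", "other") && length(reps) > 0L) {
    inv_all <- rbind(inv_all, inventory_counts(reps))
  }
  sizes <- vapply(reps, `[[`, 0L, "size")
  if (length(sizes) > 0L) {
    cat(sprintf("  %-6s repertoire sizes: median %.0f (range %d-%d)\n",
                sc, stats::median(sizes), min(sizes), max(sizes)))
  }
}
write.csv(inv_all, file.path(out, "inventory.csv"), row.names = FALSE)

pool <- function(scope) inv_all$n_types[inv_all$scope == scope &
                                          inv_all$setting == "all" &
                                          inv_all$species == "all"]
cat(sprintf("inventory: %d types other-directed, %d mother-directed\n",
            pool("other"), pool("mother")))
cat("tables written to", out, "\n")
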