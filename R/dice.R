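# Dyadic Dice similarity between customary repertoires.

#' Dice coefficient between two repertoires
#'
#' Set-overlap similarity `D = 2|A n B| / (|A| + |B|)` between two signal
#' repertoires, ranging from 0 (no shared types) to 1 (identical,
#' non-empty repertoires). Undefined when both sets are empty.
#'
#' @param rep_a,rep_b character vectors of signal-type labels (duplicates
#'   ignored).
#' @return A number in `[0, 1]`.
#' @examples
#' dice_coefficient(c("point", "touch"), c("point", "hit"))  # 0.5
#' @export
dice_coefficient <- function(rep_a, rep_b) {
  a <- unique(as.character(rep_a))
  b <- unique(as.character(rep_b))
  if (length(a) == 0L && length(b) == 0L) {
    stop("Dice coefficient undefined: both repertoires empty")
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Dyadic Dice matrix over one species and partner scope
#'
#' Fills the symmetric matrix of pairwise Dice coefficients between the
#' customary repertoires of all individuals of a single species within a
#' single partner scope. Cross-species pairs are never formed; the
#' similarity analyses run separately per species. The diagonal is set to
#' `NA` and excluded from all statistics. Zoos are pooled within species:
#' the per-individual labels carried by the matrix are the research
#' settings (wild / captive), not the groups.
#'
#' @param repertoires list of [build_repertoire()] objects, all of one
#'   species and scope, length at least 2.
#' @return Object of class `"dice_matrix"`: list with `values` (symmetric
#'   numeric matrix, `NA` diagonal), `individual_ids`, `settings`
#'   (per-individual), `species`, `scope`.
#' @export
build_dice_matrix <- function(repertoires) {
  if (length(repertoires) < 2L) stop("need at least 2 individuals")
  species <- unique(vapply(repertoires, `[[`, "", "species"))
  scope <- unique(vapply(repertoires, `[[`, "", "scope"))
  if (length(species) != 1L) {
    stop("repertoires span several species; build one matrix per species")
  }
  stopifnot(length(scope) == 1L)
  ids <- vapply(repertoires, `[[`, "", "individual_id")
  n <- length(ids)
  values <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- dice_coefficient(repertoires[[i]]$signal_types,
                            repertoires[[j]]$signal_types)
      values[i, j] <- d
      values[j, i] <- d
    }
  }
  structure(list(values = values, individual_ids = unname(ids),
                 settings = unname(vapply(repertoires, `[[`, "", "setting")),
                 species = species, scope = scope),
            class = "dice_matrix")
}

#' @export
print.dice_matrix <- function(x, ...) {
  n <- length(x$individual_ids)
  cat(sprintf("<dice_matrix> %s / %s-directed: %d individuals (%d wild, %d captive), %d pairs\n",
              x$species, x$scope, n, sum(x$settings == "wild"),
              sum(x$settings == "captive"), n * (n - 1L) / 2L))
  invisible(x)
}

# unordered-pair view: indices (i < j) and values, the unit of all statistics
dice_pairs <- function(dm) {
  n <- nrow(dm$values)
  idx <- which(upper.tri(dm$values), arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L], v = dm$values[idx])
}

# contrast statistic on pair values given per-individual setting labels
pair_statistic <- function(pairs, labels, comparison) {
  li <- labels[pairs$i]
  lj <- labels[pairs$j]
  if (comparison == "within_vs_between") {
    within <- li == lj
    if (!any(within) || all(within)) stop("a contrasted pair category is empty")
    mean(pairs$v[within]) - mean(pairs$v[!within])
  } else if (comparison == "captive_within_vs_wild_within") {
    cc <- li == "captive" & lj == "captive"
    ww <- li == "wild" & lj == "wild"
    if (!any(cc) || !any(ww)) stop("a contrasted pair category is empty")
    mean(pairs$v[cc]) - mean(pairs$v[ww])
  } else stop("unknown comparison '", comparison, "'")
}

#' Observed overlap contrast on a Dice matrix
#'
#' The scalar statistic fed to the permutation tests:
#' * `"within_vs_between"` — mean Dice of within-setting pairs (wild-wild
#'   and captive-captive pooled) minus mean Dice of between-setting pairs;
#' * `"captive_within_vs_wild_within"` — mean Dice of captive-captive
#'   pairs minus mean Dice of wild-wild pairs.
#'
#' @param dm a [build_dice_matrix()] object.
#' @param comparison which contrast to compute.
#' @return A single number.
#' @export
overlap_statistic <- function(dm,
                              comparison = c("within_vs_between",
                                             "captive_within_vs_wild_within")) {
  comparison <- match.arg(comparison)
  pair_statistic(dice_pairs(dm), dm$settings, comparison)
}

#' Mean Dice coefficients by pair category
#'
#' Summary of dyadic similarity in the layout of the repertoire-overlap
#' table: for each Dice matrix, the mean coefficient over within-setting
#' pairs (pooled), between-setting pairs, captive-captive pairs only, and
#' wild-wild pairs only. Categories with no pairs are reported `NA`.
#'
#' @param matrices list of [build_dice_matrix()] objects (e.g. one per
#'   species by scope combination).
#' @return data frame with columns `species`, `scope`, `category`,
#'   `mean_dice` (full precision) and `mean_dice_2dp` (displayed rounding).
#' @export
mean_dice_table <- function(matrices) {
  if (inherits(matrices, "dice_matrix")) matrices <- list(matrices)
  rows <- lapply(matrices, function(dm) {
    p <- dice_pairs(dm)
    li <- dm$settings[p$i]
    lj <- dm$settings[p$j]
    cat_mean <- function(keep) if (any(keep)) mean(p$v[keep]) else NA_real_
    m <- c(within_settings = cat_mean(li == lj),
           between_settings = cat_mean(li != lj),
           within_captive_only = cat_mean(li == "captive" & lj == "captive"),
           within_wild_only = cat_mean(li == "wild" & lj == "wild"))
    data.frame(species = dm$species, scope = dm$scope,
               category = names(m), mean_dice = unname(m),
               mean_dice_2dp = round(unname(m), 2L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a Dice matrix as square CSV
#'
#' Individual ids as header row and first column; a second file
#' (`<path>.labels.csv`) carries the per-individual setting labels.
#'
#' @param dm a [build_dice_matrix()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dice_matrix <- function(dm, path) {
  utils::write.csv(as.data.frame(dm$values), path, row.names = TRUE)
  labels <- data.frame(individual_id = dm$individual_ids,
                       setting = dm$settings, species = dm$species,
                       scope = dm$scope)
  utils::write.csv(labels, paste0(path, ".labels.csv"), row.names = FALSE)
  invisible(path)
}
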