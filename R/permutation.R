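# Label-permutation inference on dyadic Dice matrices.
#
# Individuals contribute to many pairs, so pair values are non-independent
# row- and column-wise. The null distribution is built by permuting the
# per-individual setting labels (rows and columns jointly) while holding
# the similarity matrix fixed, which preserves the dyadic dependence
# structure and the group sizes.

perm_decision <- function(p_upper, low = 0.025, high = 0.975) {
  if (p_upper <= low) "significant_high"        # observed in the upper tail
  else if (p_upper >= high) "significant_low"   # observed in the lower tail
  else "ns"
}

new_perm_result <- function(comparison, observed, null_stats, n_perm, seed,
                            method) {
  k_ge <- sum(null_stats >= observed)
  k_le <- sum(null_stats <= observed)
  if (method == "monte_carlo") {
    # add-one position: the observed labelling counts as one realisation,
    # so p is never 0 and p = 1/(n_perm+1) means no null value reached it
    p_upper <- (k_ge + 1) / (n_perm + 1)
    p_lower <- (k_le + 1) / (n_perm + 1)
  } else {
    # exact enumeration already contains the observed labelling
    p_upper <- k_ge / n_perm
    p_lower <- k_le / n_perm
  }
  structure(list(comparison = comparison, observed_stat = observed,
                 null_stats = null_stats, p_value = p_upper,
                 p_lower = p_lower, raw_proportion = k_ge / n_perm,
                 n_perm = n_perm, seed = seed, method = method,
                 decision = perm_decision(p_upper)),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %s (%s, %d permutations)\n", x$comparison,
              x$method, x$n_perm))
  cat(sprintf("  observed = %.4f; upper-tail P = %.4g (lower-tail %.4g); %s\n",
              x$observed_stat, x$p_value, x$p_lower, x$decision))
  invisible(x)
}

#' Matrix permutation test of a setting contrast
#'
#' Monte-Carlo test of an [overlap_statistic()] contrast: the setting
#' labels of the individuals are randomly permuted `n_perm` times (group
#' sizes preserved; matrix values fixed) and the statistic recomputed
#' under each permutation. The reported `p_value` is the upper-tail
#' position of the observed statistic with the add-one correction,
#' `(#\{null >= observed\} + 1) / (n_perm + 1)`; ties count as at least as
#' extreme. The lower-tail position and the raw proportion are also
#' returned. Because the contrast can be extreme in either direction, the
#' decision uses the asymmetric thresholds `P <= 0.025` (upper tail,
#' `"significant_high"`) and `P >= 0.975` (lower tail,
#' `"significant_low"`).
#'
#' @param dm a [build_dice_matrix()] object.
#' @param comparison contrast, as in [overlap_statistic()].
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed; results are bit-identical given the seed.
#' @return Object of class `"perm_result"`: `comparison`,
#'   `observed_stat`, `null_stats`, `p_value` (upper tail), `p_lower`,
#'   `raw_proportion`, `n_perm`, `seed`, `method`, `decision`.
#' @export
matrix_permutation_test <- function(dm,
                                    comparison = c("within_vs_between",
                                                   "captive_within_vs_wild_within"),
                                    n_perm = 1000L, seed = 20180101L) {
  comparison <- match.arg(comparison)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  labels <- dm$settings
  if (length(unique(labels)) < 2L) {
    stop("degenerate label vector: all individuals share one setting")
  }
  pairs <- dice_pairs(dm)
  observed <- pair_statistic(pairs, labels, comparison)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(k) {
    pair_statistic(pairs, sample(labels), comparison)
  }, numeric(1))
  new_perm_result(comparison, observed, null_stats, as.integer(n_perm),
                  as.integer(seed), "monte_carlo")
}

#' Exact permutation test by full label enumeration
#'
#' Enumerates every assignment of the setting labels to individuals that
#' preserves the group sizes (all `choose(n, n_captive)` of them) and
#' computes the exact upper-tail p as the fraction of assignments whose
#' statistic is at least the observed one (the observed assignment is part
#' of the enumeration, so p is never 0). Serves as the oracle for
#' [matrix_permutation_test()] on small matrices.
#'
#' @inheritParams matrix_permutation_test
#' @param max_assignments refuse to enumerate beyond this many assignments.
#' @return A `"perm_result"` with `method = "exact"`; `n_perm` is the
#'   number of enumerated assignments.
#' @export
exact_permutation_test <- function(dm,
                                   comparison = c("within_vs_between",
                                                  "captive_within_vs_wild_within"),
                                   max_assignments = 1e5) {
  comparison <- match.arg(comparison)
  labels <- dm$settings
  if (length(unique(labels)) < 2L) {
    stop("degenerate label vector: all individuals share one setting")
  }
  n <- length(labels)
  n_captive <- sum(labels == "captive")
  n_assign <- choose(n, n_captive)
  if (n_assign > max_assignments) {
    stop("enumeration too large: ", n_assign, " assignments exceed cap ",
         max_assignments)
  }
  pairs <- dice_pairs(dm)
  observed <- pair_statistic(pairs, labels, comparison)
  combos <- utils::combn(n, n_captive)
  null_stats <- apply(combos, 2L, function(captive_idx) {
    lab <- rep("wild", n)
    lab[captive_idx] <- "captive"
    pair_statistic(pairs, lab, comparison)
  })
  new_perm_result(comparison, observed, null_stats, as.integer(n_assign),
                  NA_integer_, "exact")
}

#' Write a permutation result (including the null vector) to JSON
#'
#' @param result a `"perm_result"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_perm_result <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
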