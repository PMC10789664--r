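# Poisson mixed models of repertoire size and social-goal diversity.
#
# Response: per-individual count (customary repertoire size or number of
# distinct social goals) within one partner scope. Fixed effects: age, age
# squared, research setting and species (test predictors), sex and log-z
# observation effort (controls). Random intercept: group (zoo or field
# site). Estimation is maximum likelihood (Laplace by default, adaptive
# Gauss-Hermite quadrature on request) so likelihood-ratio tests on fixed
# effects are valid.

glmm_rhs_full <- "age_years + I(age_years^2) + setting + species + sex + log_z_effort + (1 | group_id)"
glmm_rhs_null <- "sex + log_z_effort + (1 | group_id)"
glmm_test_terms <- c("age_years", "I(age_years^2)", "setting", "species")

# glmer with optimiser chatter (convergence warnings, singular-fit notes)
# silenced; convergence is reported through the fit's flags instead
quiet_glmer <- function(form, data, nAGQ) {
  withCallingHandlers(
    suppressMessages(
      lme4::glmer(form, data = data, family = stats::poisson(link = "log"),
                  nAGQ = nAGQ)),
    warning = function(w) invokeRestart("muffleWarning"))
}

#' Log then z transform of observation effort
#'
#' Natural log followed by centring and scaling to mean 0, sd 1 (sample sd,
#' n-1 denominator), computed on the analysis subset at hand. Used to
#' approximate a linear effect of observation effort on the log link.
#'
#' @param effort vector of positive counts.
#' @return Numeric vector with mean 0 and sd 1.
#' @export
log_z_transform <- function(effort) {
  if (any(effort <= 0)) stop("effort must be positive")
  if (length(effort) < 2L) stop("need at least 2 values")
  le <- log(effort)
  s <- stats::sd(le)
  if (s == 0) stop("zero variance: all effort values equal after log")
  (le - mean(le)) / s
}

#' Fit a random-intercept Poisson mixed model of a repertoire response
#'
#' Fits, by maximum likelihood via [lme4::glmer()], the log-link Poisson
#' model of a per-individual count response with a Gaussian random
#' intercept for group. The full model carries the test predictors (age,
#' age squared — the square of uncentred age —, setting, species) plus the
#' controls (sex, log-z effort); the null model carries the controls and
#' the random intercept only, so the full-vs-null likelihood-ratio test
#' has 4 degrees of freedom.
#'
#' @param data data frame with the response column plus `age_years`,
#'   `setting`, `species`, `sex`, `effort`, `group_id` (as from
#'   [repertoire_table()]). `log_z_effort` is computed here on this subset.
#' @param response column name of the count response (e.g. `"size"` or
#'   `"goal_count"`).
#' @param type `"full"` or `"null"`.
#' @param nAGQ number of adaptive Gauss-Hermite quadrature points; 1 is
#'   the Laplace approximation.
#' @param center_age if `TRUE`, age is mean-centred before squaring
#'   (reduces the age / age-squared collinearity; off by default).
#' @return Object of class `"glmm_fit"`: `model` (the merMod),
#'   `coefficients` (matrix with `estimate`, `se`), `sigma2`
#'   (random-intercept variance), `logLik`, `n_obs`, `n_groups`, `fitted`,
#'   `pearson_resid`, `converged`, `singular`, `response`, `type`, `data`.
#' @export
fit_poisson_glmm <- function(data, response, type = c("full", "null"),
                             nAGQ = 1L, center_age = FALSE) {
  type <- match.arg(type)
  needed <- c(response, "age_years", "setting", "species", "sex", "effort",
              "group_id")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(data[, needed])) stop("missing values in model columns")
  if (length(unique(data$group_id)) < 2L) {
    stop("need at least 2 groups for a random-intercept fit")
  }
  d <- data
  d$log_z_effort <- log_z_transform(d$effort)
  if (center_age) d$age_years <- d$age_years - mean(d$age_years)
  # reference levels: captive, bornean, female — so the wild and sumatran
  # contrasts are the reported ones
  d$setting <- factor(d$setting,
                      levels = intersect(c("captive", "wild"), d$setting))
  d$species <- factor(d$species)
  d$sex <- factor(d$sex)
  d$group_id <- factor(d$group_id)

  rhs <- if (type == "full") glmm_rhs_full else glmm_rhs_null
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- quiet_glmer(form, d, nAGQ)

  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", msgs %||% character(0)))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  structure(list(
    model = fit,
    formula = form,
    coefficients = cbind(estimate = beta, se = se),
    sigma2 = unname(lme4::VarCorr(fit)$group_id[1L]),
    logLik = as.numeric(stats::logLik(fit)),
    n_obs = nrow(d),
    n_groups = nlevels(d$group_id),
    fitted = stats::fitted(fit),
    pearson_resid = stats::residuals(fit, type = "pearson"),
    converged = converged,
    singular = lme4::isSingular(fit),
    response = response,
    type = type,
    nAGQ = nAGQ,
    center_age = center_age,
    data = d
  ), class = "glmm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> Poisson mixed model of %s (%s model, nAGQ=%d)\n",
              x$response, x$type, x$nAGQ))
  cat(sprintf("  n = %d individuals in %d groups; logLik = %.3f; sigma2 = %.4f%s\n",
              x$n_obs, x$n_groups, x$logLik, x$sigma2,
              if (x$singular) " (singular)" else ""))
  print(round(x$coefficients, 3L))
  invisible(x)
}

n_params <- function(fit) nrow(fit$coefficients) + 1L  # + variance component

#' Likelihood-ratio test between nested mixed-model fits
#'
#' `chi_square = 2 (logLik_full - logLik_null)` referred to the chi-square
#' upper tail with df equal to the difference in parameter count. Both
#' fits must be on the same data and response, with the null's fixed terms
#' a subset of the full's.
#'
#' @param full,null `"glmm_fit"` objects.
#' @return List of class `"lrt_result"`: `chi_square`, `df`, `p_value`.
#' @export
lrt <- function(full, null) {
  if (full$n_obs != null$n_obs || full$response != null$response) {
    stop("models must be fitted to the same data and response")
  }
  terms_full <- attr(stats::terms(lme4::nobars(full$formula)), "term.labels")
  terms_null <- attr(stats::terms(lme4::nobars(null$formula)), "term.labels")
  if (!all(terms_null %in% terms_full)) {
    stop("null model is not nested in the full model")
  }
  df <- n_params(full) - n_params(null)
  if (df < 0L) stop("full model has fewer parameters than the null")
  chi2 <- max(0, 2 * (full$logLik - null$logLik))
  # identical specifications: zero extra parameters, no evidence either way
  p <- if (df == 0L) 1 else stats::pchisq(chi2, df = df, lower.tail = FALSE)
  structure(list(chi_square = chi2, df = df, p_value = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi-square(%d) = %.3f, P = %.4g\n",
              x$df, x$chi_square, x$p_value))
  invisible(x)
}

#' Per-term likelihood-ratio tests by single-term deletion
#'
#' Refits the full model once per fixed-effect term with that term
#' removed, and reports the single-df likelihood-ratio test for each
#' (the classical drop-one table). Every term, including the linear age
#' term, is droppable on its own.
#'
#' @param full a converged full `"glmm_fit"`.
#' @return data frame with `term`, `chi_square`, `df`, `p_value`,
#'   `converged` (of the reduced refit).
#' @export
drop1_lrt <- function(full) {
  terms_full <- attr(stats::terms(lme4::nobars(full$formula)), "term.labels")
  rows <- lapply(terms_full, function(tm) {
    reduced_rhs <- paste(c(setdiff(terms_full, tm), "(1 | group_id)"),
                         collapse = " + ")
    form <- stats::as.formula(paste(full$response, "~", reduced_rhs))
    red <- quiet_glmer(form, full$data, full$nAGQ)
    chi2 <- max(0, 2 * (full$logLik - as.numeric(stats::logLik(red))))
    df <- nrow(full$coefficients) - length(lme4::fixef(red))
    data.frame(term = tm, chi_square = chi2, df = df,
               p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE),
               converged = red@optinfo$conv$opt == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overdispersion statistic of a Poisson mixed-model fit
#'
#' Sum of squared Pearson residuals divided by the residual degrees of
#' freedom, `n_obs - n_fixed - n_variance_components`. Values near 1
#' indicate a well-specified Poisson model; values well above 1 indicate
#' overdispersion.
#'
#' @param fit a `"glmm_fit"`.
#' @return A single number.
#' @export
overdispersion <- function(fit) {
  rdf <- fit$n_obs - n_params(fit)
  if (rdf <= 0) stop("non-positive residual degrees of freedom")
  sum(fit$pearson_resid^2) / rdf
}

#' Variance inflation factors of the main-effect design
#'
#' Collinearity diagnostic computed from a design of fixed main effects
#' only (age, setting, species, sex, log-z effort; no squared or
#' interaction terms): for each non-intercept column, `VIF_j = 1 / (1 -
#' R2_j)` where `R2_j` is from the least-squares regression of column j on
#' the other columns plus an intercept. A column perfectly explained by
#' the others gets `Inf`.
#'
#' @param data analysis table as for [fit_poisson_glmm()]; or a
#'   `"glmm_fit"`, whose data are then used.
#' @return Named numeric vector of VIFs, one per non-intercept column.
#' @export
vif_main_effects <- function(data) {
  if (inherits(data, "glmm_fit")) data <- data$data
  d <- data
  if (!"log_z_effort" %in% names(d)) d$log_z_effort <- log_z_transform(d$effort)
  X <- stats::model.matrix(
    ~ age_years + setting + species + sex + log_z_effort, data = d)
  vif_design(X)
}

#' @rdname vif_main_effects
#' @param X numeric design matrix including an intercept column.
#' @export
vif_design <- function(X) {
  keep <- colnames(X) != "(Intercept)"
  cols <- colnames(X)[keep]
  if (length(cols) < 2L) stop("need at least 2 non-intercept columns")
  vif <- vapply(cols, function(j) {
    y <- X[, j]
    Z <- X[, colnames(X) != j, drop = FALSE]
    res <- stats::lm.fit(Z, y)$residuals
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(res^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  vif
}

#' Model stability under case-wise deletion of random-effect levels
#'
#' Refits the model once per group with that group's individuals removed
#' and reports, for each fixed-effect coefficient, the minimum and maximum
#' estimate across the leave-one-group-out refits alongside the full-data
#' estimate, flagging sign flips. Failed refits are recorded, not fatal.
#'
#' @param fit a converged `"glmm_fit"` with at least 3 groups.
#' @return List with `ranges` (data frame: `term`, `estimate`, `min`,
#'   `max`, `sign_flip`) and `failures` (character vector of group ids
#'   whose refit failed).
#' @export
stability_by_group_deletion <- function(fit) {
  groups <- levels(fit$data$group_id)
  if (length(groups) < 3L) stop("need at least 3 groups")
  beta_full <- fit$coefficients[, "estimate"]
  ests <- list()
  failures <- character(0)
  for (g in groups) {
    d <- droplevels(fit$data[fit$data$group_id != g, , drop = FALSE])
    est <- tryCatch({
      refit <- quiet_glmer(fit$formula, d, fit$nAGQ)
      lme4::fixef(refit)
    }, error = function(e) NULL)
    if (is.null(est) || !all(names(beta_full) %in% names(est))) {
      failures <- c(failures, g)
    } else {
      ests[[g]] <- est[names(beta_full)]
    }
  }
  if (length(ests) == 0L) stop("all leave-one-group-out refits failed")
  mat <- do.call(rbind, ests)
  ranges <- data.frame(
    term = names(beta_full),
    estimate = unname(beta_full),
    min = apply(mat, 2L, min),
    max = apply(mat, 2L, max),
    stringsAsFactors = FALSE
  )
  ranges$sign_flip <- sign(ranges$min) != sign(ranges$max) &
    ranges$min != 0 & ranges$max != 0
  rownames(ranges) <- NULL
  list(ranges = ranges, failures = failures)
}

#' Cohen's kappa for agreement between two categorical coders
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with
#' observed agreement `p_o` the fraction of items coded identically and
#' expected agreement `p_e` the sum of products of the two coders'
#' marginal proportions.
#'
#' @param codes_a,codes_b equal-length vectors of category labels.
#' @return A single number (1 = perfect agreement, 0 = chance level).
#' @export
cohen_kappa <- function(codes_a, codes_b) {
  if (length(codes_a) != length(codes_b)) stop("length mismatch")
  n <- length(codes_a)
  if (n < 2L) stop("need at least 2 items")
  levs <- sort(unique(c(as.character(codes_a), as.character(codes_b))))
  a <- factor(codes_a, levels = levs)
  b <- factor(codes_b, levels = levs)
  tab <- table(a, b)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) stop("degenerate marginals: expected agreement is 1")
  (p_o - p_e) / (1 - p_e)
}
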