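test_that("log-z transform standardises and rejects degenerate input", {
  set.seed(1)
  x <- sample(32:776, 40L)
  z <- log_z_transform(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(stats::sd(z) - 1), 1e-12)
  expect_error(log_z_transform(c(0, 5)), "positive")
  expect_error(log_z_transform(c(5, 5)), "variance")
  # hand-computed 3-value case
  y <- c(32, 100, 776)
  ly <- log(y)
  expect_equal(log_z_transform(y), (ly - mean(ly)) / stats::sd(ly))
})

test_that("with zero group variance the mixed model matches plain IRLS", {
  d <- simulate_size_counts(n = 150L, n_groups = 6L, sigma_group = 0,
                            seed = 42L)
  fit <- fit_poisson_glmm(d, "size", "full")
  d2 <- fit$data
  glm_fit <- stats::glm(
    size ~ age_years + I(age_years^2) + setting + species + sex +
      log_z_effort, data = d2, family = stats::poisson())
  expect_true(fit$singular || fit$sigma2 < 1e-4)
  expect_lt(max(abs(fit$coefficients[, "estimate"] -
                      stats::coef(glm_fit))), 1e-3)
})

test_that("the full-vs-null likelihood-ratio test has 4 degrees of freedom", {
  d <- simulate_size_counts(n = 80L, n_groups = 6L, seed = 9L)
  full <- fit_poisson_glmm(d, "size", "full")
  null <- fit_poisson_glmm(d, "size", "null")
  out <- lrt(full, null)
  expect_equal(out$df, 4L)
  expect_gte(out$chi_square, 0)
  expect_gte(full$logLik, null$logLik)  # ML never worse with more terms
  # identical specifications: no evidence either way
  self <- lrt(full, fit_poisson_glmm(d, "size", "full"))
  expect_equal(self$chi_square, 0, tolerance = 1e-6)
  expect_equal(self$p_value, 1)
  expect_error(lrt(null, full), "not nested")
})

test_that("drop-one refits reproduce the reference single-term deletion table", {
  d <- simulate_size_counts(n = 100L, n_groups = 6L, seed = 12L)
  full <- fit_poisson_glmm(d, "size", "full")
  mine <- drop1_lrt(full)
  expect_setequal(mine$term,
                  c("age_years", "I(age_years^2)", "setting", "species",
                    "sex", "log_z_effort"))
  expect_true(all(mine$df == 1L))
  dd <- full$data
  ref_model <- suppressWarnings(suppressMessages(lme4::glmer(
    size ~ age_years + I(age_years^2) + setting + species + sex +
      log_z_effort + (1 | group_id), data = dd, family = stats::poisson())))
  ref <- suppressMessages(suppressWarnings(
    stats::drop1(ref_model, scope = mine$term, test = "Chisq")))
  ref <- ref[mine$term, ]
  expect_equal(mine$chi_square, ref$LRT, tolerance = 1e-5)
  expect_equal(mine$p_value, ref$`Pr(Chi)`, tolerance = 1e-5)
})

test_that("Laplace equals one-point quadrature and more points stabilise", {
  d <- simulate_size_counts(n = 60L, n_groups = 5L, sigma_group = 0.4,
                            seed = 3L)
  f1 <- fit_poisson_glmm(d, "size", "full", nAGQ = 1L)
  f9 <- fit_poisson_glmm(d, "size", "full", nAGQ = 9L)
  f25 <- fit_poisson_glmm(d, "size", "full", nAGQ = 25L)
  expect_equal(f1$nAGQ, 1L)
  expect_lt(abs(f25$logLik - f9$logLik), abs(f9$logLik - f1$logLik) + 1e-6)
  expect_lt(max(abs(f25$coefficients[, "estimate"] -
                      f1$coefficients[, "estimate"])), 0.05)
})

test_that("overdispersion statistic behaves across regimes", {
  zero_fit <- structure(list(pearson_resid = rep(0, 30L), n_obs = 30L,
                             coefficients = matrix(0, 7L, 2L)),
                        class = "glmm_fit")
  expect_equal(overdispersion(zero_fit), 0)
  tiny <- structure(list(pearson_resid = rep(0, 8L), n_obs = 8L,
                         coefficients = matrix(0, 7L, 2L)),
                    class = "glmm_fit")
  expect_error(overdispersion(tiny), "degrees of freedom")

  disp_po <- vapply(1:10, function(i) {
    d <- simulate_size_counts(n = 150L, n_groups = 6L, seed = 100L + i)
    overdispersion(fit_poisson_glmm(d, "size", "full"))
  }, numeric(1))
  expect_lt(abs(mean(disp_po) - 1), 0.2)

  disp_nb <- vapply(1:10, function(i) {
    d <- simulate_size_counts(n = 150L, n_groups = 6L, seed = 200L + i)
    set.seed(300L + i)  # inflate variance: negative-binomial thinning
    d$size <- stats::rnbinom(nrow(d), mu = d$size + 1, size = 2)
    overdispersion(fit_poisson_glmm(d, "size", "full"))
  }, numeric(1))
  expect_gt(mean(disp_nb), 1.5)
})

test_that("variance inflation factors match construction and the reference", {
  # mutually orthogonal columns
  X <- cbind(`(Intercept)` = 1, a = rep(c(-1, 1), 10L),
             b = rep(c(-1, -1, 1, 1), 5L), c = rnorm(20))
  X[, "c"] <- stats::resid(stats::lm(X[, "c"] ~ X[, c("a", "b")]))
  v <- vif_design(X)
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-10)

  # duplicated column is perfectly explained
  Xd <- cbind(`(Intercept)` = 1, a = rnorm(20), b = rnorm(20))
  Xd <- cbind(Xd, a2 = Xd[, "a"])
  expect_true(is.infinite(vif_design(Xd)[["a"]]))

  # constructed pair with sample R^2 exactly 0.75 -> VIF = 4:
  # x2 = (unit-SS x1 part) + (orthogonal part with 1/3 of its sum of squares)
  set.seed(77)
  x1 <- rnorm(400)
  b <- scale(x1)[, 1]; b <- b / sqrt(sum(b^2))
  e <- stats::resid(stats::lm(rnorm(400) ~ x1))
  a <- e / sqrt(sum(e^2))
  x2 <- b + a / sqrt(3)
  Xp <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
  expect_equal(unname(vif_design(Xp)), c(4, 4), tolerance = 1e-8)

  # reference implementation agreement on a realistic design
  skip_if_not_installed("car")
  d <- simulate_size_counts(n = 120L, n_groups = 8L, seed = 8L)
  d$log_z_effort <- log_z_transform(d$effort)
  lm_fit <- stats::lm(size ~ age_years + setting + species + sex +
                        log_z_effort, data = d)
  ref <- car::vif(lm_fit)
  mine <- vif_main_effects(d)
  expect_equal(unname(mine[c("age_years", "log_z_effort")]),
               unname(ref[c("age_years", "log_z_effort")]),
               tolerance = 1e-8)
})

test_that("group-deletion stability brackets estimates and exposes outliers", {
  d <- simulate_size_counts(n = 120L, n_groups = 8L, seed = 15L)
  fit <- fit_poisson_glmm(d, "size", "full")
  stab <- stability_by_group_deletion(fit)
  expect_equal(length(stab$failures), 0L)
  # under exchangeable groups the ranges bracket the full-data estimate
  expect_true(all(stab$ranges$min <= stab$ranges$estimate + 1e-8))
  expect_true(all(stab$ranges$max >= stab$ranges$estimate - 1e-8))

  # plant an outlier group: deleting it gives the extreme range endpoint
  d2 <- d
  boost <- d2$group_id == "g01"
  d2$size[boost] <- d2$size[boost] + stats::rpois(sum(boost), 25)
  fit2 <- fit_poisson_glmm(d2, "size", "full")
  groups <- levels(fit2$data$group_id)
  ints <- vapply(groups, function(g) {
    dd <- droplevels(fit2$data[fit2$data$group_id != g, ])
    f <- suppressWarnings(suppressMessages(
      lme4::glmer(fit2$formula, data = dd, family = stats::poisson())))
    lme4::fixef(f)[["(Intercept)"]]
  }, numeric(1))
  expect_equal(names(which.min(ints)), "g01")
  stab2 <- stability_by_group_deletion(fit2)
  expect_equal(stab2$ranges$min[stab2$ranges$term == "(Intercept)"],
               min(ints), tolerance = 1e-6)
})

test_that("Cohen's kappa matches contingency arithmetic", {
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # 2x2 table (20,5 / 10,15): p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  a <- c(rep("x", 25L), rep("y", 25L))
  b <- c(rep("x", 20L), rep("y", 5L), rep("x", 10L), rep("y", 15L))
  expect_equal(cohen_kappa(a, b), 0.4)
  set.seed(6)
  ia <- sample(letters[1:4], 4000L, replace = TRUE)
  ib <- sample(letters[1:4], 4000L, replace = TRUE)
  expect_lt(abs(cohen_kappa(ia, ib)), 0.05)
  expect_error(cohen_kappa(c("a", "b"), "a"), "length")
  expect_error(cohen_kappa(rep("a", 5L), rep("a", 5L)), "marginals")
})
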