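test_that("beta regression recovers the logit of a constant response", {
  dat <- tibble::tibble(p = rep(0.5, 60))
  fit <- fit_beta_glm(dat, p ~ 1)
  expect_true(fit$converged)
  expect_equal(tidy(fit)$estimate[1], 0, tolerance = 1e-6)
  # boundary values are handled by smoothing, not errors
  datb <- tibble::tibble(p = c(rep(0, 10), rep(1, 10), runif(40)))
  expect_no_error(fit_beta_glm(datb, p ~ 1))
  expect_error(fit_beta_glm(tibble::tibble(p = c(-0.1, 0.5, 0.5, 0.5)), p ~ 1),
               "proportions")
})

test_that("beta regression matches the glmmTMB beta family on simulated data", {
  set.seed(90)
  n <- 150
  x <- rnorm(n)
  mu <- plogis(0.4 + 0.8 * x)
  y <- rbeta(n, mu * 25, (1 - mu) * 25)
  dat <- tibble::tibble(y = y, x = x)
  mine <- fit_beta_glm(dat, y ~ x)
  # oracle fit on the same smoothed response
  dat$ys <- smooth_proportion(dat$y)
  orc <- glmmTMB::glmmTMB(ys ~ x, data = dat, family = glmmTMB::beta_family())
  expect_equal(tidy(mine)$estimate, unname(glmmTMB::fixef(orc)$cond),
               tolerance = 1e-4)
  expect_equal(tidy(mine)$std.error,
               unname(sqrt(diag(vcov(orc)$cond))), tolerance = 1e-3)
  expect_equal(mine$phi, stats::sigma(orc), tolerance = 1e-3)
})

test_that("beta regression recovers generator coefficients from the fast path", {
  cfg <- sim_config(n_datasets = 400, seed = 91,
                    congruence_coefs = c(intercept = 0, log_reads = 0.3,
                                         year = 0.15, richness = -0.02),
                    beta_coverage = 0, beta_precision = 30)
  tab <- sim_congruence_table(cfg)
  tab$year_c <- tab$year - min(tab$year)
  fit <- fit_beta_glm(tab, p_sp ~ log(median_fish_reads) + year_c + richness)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_lt(abs(est[["year_c"]] - 0.15), 0.05)
  expect_lt(abs(est[["log(median_fish_reads)"]] - 0.3), 0.1)
  expect_lt(abs(fit$phi - 30), 6)
})

test_that("NB GLMM matches a fixed-effects NB fit in the zero-variance limit", {
  skip_if_not_installed("MASS")
  set.seed(92)
  n_d <- 30; n_s <- 15
  dat <- tibble::tibble(
    dataset_id = factor(rep(seq_len(n_d), each = n_s)),
    original_richness = rpois(n_d * n_s, 12)
  )
  mu <- exp(0.8 + 0.08 * dat$original_richness)  # no dataset effect
  dat$reanalyzed_richness <- rnbinom(nrow(dat), mu = mu, size = 8)
  fit <- fit_nb_glmm_richness(dat)
  orc <- MASS::glm.nb(reanalyzed_richness ~ original_richness, data = dat)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_equal(unname(est["original_richness"]),
               unname(coef(orc)["original_richness"]), tolerance = 1e-3)
  expect_lt(fit$sigma2_u, 0.01)
  expect_gte(fit$r2_conditional, fit$r2_marginal)
})

test_that("NB GLMM intercept-only recovers log of the mean", {
  set.seed(93)
  dat <- tibble::tibble(
    dataset_id = factor(rep(1:10, each = 10)),
    reanalyzed_richness = rpois(100, 9)
  )
  fit <- fit_nb_glmm_richness(dat, reanalyzed_richness ~ 1 + (1 | dataset_id))
  expect_equal(tidy(fit)$estimate[1], log(mean(dat$reanalyzed_richness)),
               tolerance = 1e-4)
})

test_that("NB GLMM separates dataset variance from the slope", {
  set.seed(94)
  n_d <- 40; n_s <- 15
  u <- rnorm(n_d, 0, sqrt(0.4))
  dat <- tibble::tibble(
    dataset_id = factor(rep(seq_len(n_d), each = n_s)),
    original_richness = rpois(n_d * n_s, 10)
  )
  mu <- exp(1 + 0.05 * dat$original_richness + u[as.integer(dat$dataset_id)])
  dat$reanalyzed_richness <- rnbinom(nrow(dat), mu = mu, size = 10)
  fit <- fit_nb_glmm_richness(dat)
  expect_true(fit$converged)
  expect_equal(fit$sigma2_u, 0.4, tolerance = 0.25)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_lt(abs(est[["original_richness"]] - 0.05), 0.02)
  expect_gte(fit$r2_conditional, fit$r2_marginal)
})

test_that("abundance mixed model detects the unique-species penalty", {
  cfg <- sim_config(n_datasets = 40, seed = 95, synonym_noise_rate = 0,
                    unique_abundance_shift = -1)
  ab <- abundance_table(sim_collection(cfg))
  fit <- fit_abundance_mixed(ab, index = "a")
  est <- dplyr::filter(tidy(fit), term == "shared_flagTRUE")
  expect_gt(est$estimate, 0)      # shared species sit higher
  expect_lt(est$p.value, 0.05)
  fitb <- fit_abundance_mixed(ab, index = "b")
  expect_gt(dplyr::filter(tidy(fitb), term == "shared_flagTRUE")$estimate, 0)
  expect_gte(fit$r2_conditional, fit$r2_marginal)
})

test_that("abundance mixed model matches a fixed-effects oracle when sigma2 is 0", {
  set.seed(96)
  n <- 2000
  dat <- tibble::tibble(
    dataset_id = factor(rep(1:50, each = 40)),
    shared_flag = rep(c(TRUE, FALSE), n / 2),
    refdb_type = sample(c("global", "custom"), n, TRUE),
    year = sample(2015:2022, n, TRUE)
  )
  mu <- plogis(-2 + 0.8 * dat$shared_flag)      # no dataset effect
  dat$a <- rbeta(n, mu * 20, (1 - mu) * 20)
  mixed <- fit_abundance_mixed(dat, index = "a")
  dat$year_c <- dat$year - min(dat$year)
  fixed <- fit_beta_glm(dat, a ~ shared_flag + refdb_type + year_c)
  est_m <- setNames(tidy(mixed)$estimate, tidy(mixed)$term)
  est_f <- setNames(tidy(fixed)$estimate, tidy(fixed)$term)
  expect_equal(unname(est_m["shared_flagTRUE"]),
               unname(est_f["shared_flagTRUE"]), tolerance = 1e-3)
})

test_that("sensitivity filter removes low-depth datasets and reports them", {
  col <- small_collection(seed = 97, n_datasets = 10)
  expect_identical(sensitivity_filter(col, 0)$collection$datasets,
                   col$datasets)
  med <- sort(col$datasets$median_fish_reads)
  thr <- med[3] + 1
  out <- sensitivity_filter(col, thr)
  expect_equal(nrow(out$report), 3)
  expect_equal(nrow(out$collection$datasets), 7)
  expect_true(all(out$collection$datasets$median_fish_reads >= thr))
  expect_error(sensitivity_filter(col, max(med) + 1), "every dataset")
})
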