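# Balanced two-arm data with symmetric camera deviations: group means are
# exact, residual variance positive, no true random-effect variance.
balanced_rates <- function(mean_non = 0.2, mean_fsc = 0.3, dev = 0.02,
                           n_pairs = 4, cams = 6) {
  d <- tidyr::expand_grid(
    pair_id = sprintf("p%d", seq_len(n_pairs)),
    certified = c(TRUE, FALSE),
    cam = seq_len(cams)
  )
  d$concession_id <- paste0(d$pair_id, ifelse(d$certified, "F", "N"))
  d$camera_id <- paste0(d$concession_id, "_", d$cam)
  d$status <- factor(ifelse(d$certified, "FSC", "non-FSC"),
                     levels = c("non-FSC", "FSC"))
  base <- ifelse(d$certified, mean_fsc, mean_non)
  d$encounter_rate <- base + dev * ifelse(d$cam %% 2 == 0, 1, -1)
  d
}

test_that("with no true random-effect variance the fit collapses to OLS", {
  set.seed(3)
  d <- balanced_rates()
  d$encounter_rate <- d$encounter_rate + rnorm(nrow(d), 0, 0.01)
  fit <- quiet(fit_lmm(d, lmm_spec()))
  ols <- lm(encounter_rate ~ status, data = d)
  expect_true(fit$singular)
  expect_lt(max(abs(lme4::fixef(fit$reml) - coef(ols))), 1e-8)
})

test_that("pair-only model on concession means reproduces the paired t-test", {
  set.seed(11)
  d <- tibble::tibble(
    pair_id = rep(sprintf("p%d", 1:7), each = 2),
    certified = rep(c(TRUE, FALSE), 7)
  )
  d$concession_id <- paste0(d$pair_id, ifelse(d$certified, "F", "N"))
  d$status <- factor(ifelse(d$certified, "FSC", "non-FSC"),
                     levels = c("non-FSC", "FSC"))
  d$encounter_rate <- rlnorm(14, -1, 0.4) * ifelse(d$certified, 1.4, 1)
  fit <- quiet(fit_lmm(d, lmm_spec()))
  td <- tidy(fit)
  tt <- t.test(d$encounter_rate[d$certified], d$encounter_rate[!d$certified],
               paired = TRUE)
  i <- which(td$term == "statusFSC")
  expect_equal(td$statistic[i], unname(tt$statistic), tolerance = 1e-6)
  expect_equal(td$p.value[i], tt$p.value, tolerance = 1e-6)
  expect_equal(td$df[i], 6)
})

test_that("marginal means and ratios follow the group means exactly", {
  d <- balanced_rates(mean_non = 0.2, mean_fsc = 0.3)
  fit <- quiet(fit_lmm(d, lmm_spec()))
  cr <- quiet(certification_ratios(fit, n_mc = 1e4))
  expect_equal(cr$mean_nonfsc, 0.2, tolerance = 1e-8)
  expect_equal(cr$mean_fsc, 0.3, tolerance = 1e-8)
  expect_equal(cr$ratio, 1.5, tolerance = 1e-8)
  d_eq <- balanced_rates(mean_non = 0.25, mean_fsc = 0.25)
  cr_eq <- quiet(certification_ratios(quiet(fit_lmm(d_eq, lmm_spec()))))
  expect_equal(cr_eq$ratio, 1, tolerance = 1e-8)
})

test_that("variance components are non-negative and BIC follows its definition", {
  set.seed(21)
  sim <- simulate_dataset(mini_community(), mini_design(seed = 21), emit = "events")
  rt <- quiet(encounter_rate(sim$events, sim_effort(sim), sim$traits,
                             "all", unit = "camera"))
  fit <- quiet(fit_lmm(rt, lmm_spec()))
  expect_true(all(fit$varcomp$variance >= 0))
  ll <- logLik(fit$ml)
  expect_equal(fit$bic, -2 * as.numeric(ll) + attr(ll, "df") * log(fit$n_obs))
  g <- glance(fit)
  expect_equal(g$n_obs, fit$n_obs)
})

test_that("REML solution is a local optimum over variance components", {
  set.seed(31)
  sim <- simulate_dataset(mini_community(), mini_design(seed = 31), emit = "events")
  rt <- quiet(encounter_rate(sim$events, sim_effort(sim), sim$traits,
                             "all", unit = "camera"))
  fit <- quiet(fit_lmm(rt, lmm_spec()))
  dev0 <- update(fit$reml, devFunOnly = TRUE)
  th <- fit$reml@theta
  base <- dev0(th)
  for (eps in c(-0.05, 0.05)) {
    for (j in seq_along(th)) {
      th2 <- th
      th2[j] <- max(th[j] + eps, 0)
      expect_gte(dev0(th2), base - 1e-6)
    }
  }
})

test_that("rank-deficient fixed effects raise a named error", {
  d <- balanced_rates()
  d$dup <- as.numeric(d$certified) # aliased with status
  expect_error(
    quiet(fit_lmm(d, lmm_spec(covariates = "dup"))),
    "rank deficient"
  )
})

test_that("multivariate-t adjustment: identity at m = 1, closed form under
           independence in the normal limit, degenerate under perfect correlation", {
  p1 <- mvt_adjust(2.0, matrix(1, 1, 1), df = 30)
  expect_equal(as.numeric(p1), 2 * pt(-2, 30))

  praw <- 2 * pt(-2, 500)
  p2 <- mvt_adjust(c(2, 2), diag(2), df = 500, n_mc = 2e5)
  expect_equal(as.numeric(p2), rep(1 - (1 - praw)^2, 2), tolerance = 2e-3)

  p3 <- mvt_adjust(c(1.5, 2.5), matrix(1, 2, 2), df = 40)
  expect_equal(as.numeric(p3), 2 * pt(-c(1.5, 2.5), 40), tolerance = 1e-3)
})

test_that("adjusted p-values dominate raw and are dominated by Bonferroni", {
  set.seed(5)
  for (i in 1:25) {
    m <- sample(2:6, 1)
    A <- matrix(rnorm(m * m), m)
    corr <- stats::cov2cor(A %*% t(A) + diag(m))
    t_stats <- rnorm(m, 0, 2)
    df <- sample(3:40, 1)
    p_adj <- mvt_adjust(t_stats, corr, df, n_mc = 2e4)
    p_raw <- 2 * pt(-abs(t_stats), df)
    expect_true(all(p_adj >= p_raw - 1e-12))
    expect_true(all(p_adj <= pmin(1, m * p_raw) + 1e-12))
    # monotone: sorting by |t| must sort p the other way
    ord <- order(abs(t_stats))
    expect_true(all(diff(p_adj[ord]) <= 1e-12))
  }
})

test_that("mvt_adjust rejects invalid inputs", {
  expect_error(mvt_adjust(numeric(0), diag(0), 5), "no contrasts")
  expect_error(mvt_adjust(c(1, 2), matrix(c(1, 2, 2, 1), 2), 5), "semi-definite")
  expect_error(mvt_adjust(1, matrix(1, 1, 1), 0), "positive")
})

test_that("model selection returns the base model when there are no candidates", {
  d <- balanced_rates()
  sel <- quiet(select_model(d, character(), lmm_spec()))
  expect_equal(nrow(sel$bic_table), 1)
  expect_equal(sel$bic_table$covariates, "(base)")
  expect_equal(sel$best_spec$covariates, character(0))
})

test_that("a strong covariate effect is selected; a null effect is not", {
  reps <- 40
  hit <- 0; null_base <- 0
  set.seed(55)
  for (r in 1:reps) {
    s <- sample.int(1e6, 2)
    make_rates <- function(beta, seed) {
      sim <- simulate_dataset(
        species_spec("sp", 20, "LC", "ungulates", 0.4),
        sim_design(
          n_pairs = 4, cameras_per_concession = c(8, 8), deployment_days = 40,
          downtime_prob = 0, sd_camera = 0.15, sd_concession = 0.1, sd_pair = 0.1,
          covariate_effects = if (beta != 0) c(elevation = beta),
          seed = seed
        ),
        emit = "events"
      )
      rt <- quiet(encounter_rate(sim$events, sim_effort(sim), level = "all",
                                 unit = "camera"))
      dplyr::left_join(
        rt, dplyr::select(sim$deployments, "camera_id", "elevation", "dist_rivers"),
        by = "camera_id"
      )
    }
    sel <- quiet(select_model(make_rates(0.8, s[1]),
                              c("elevation", "dist_rivers"), lmm_spec()))
    if ("elevation" %in% sel$best_spec$covariates) hit <- hit + 1
    sel0 <- quiet(select_model(make_rates(0, s[2]),
                               c("elevation", "dist_rivers"), lmm_spec()))
    if (length(sel0$best_spec$covariates) == 0) null_base <- null_base + 1
  }
  expect_gte(hit / reps, 0.9)
  expect_gt(null_base / reps, 0.5)
})
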