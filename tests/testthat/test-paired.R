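test_that("the worked all-positive example gives W = 28 and p = 2/128", {
  res <- wilcoxon_signed_rank(1:7)
  expect_equal(res$statistic, 28)
  expect_equal(res$p.value, 0.015625)
})

test_that("symmetric and degenerate inputs behave as documented", {
  expect_equal(wilcoxon_signed_rank(c(1, -1))$p.value, 1)
  res <- suppressWarnings(wilcoxon_signed_rank(c(0, 0, 5)))
  expect_equal(res$n, 1L)
  expect_equal(res$zeros_dropped, 2L)
  expect_equal(res$p.value, 1)
  expect_warning(wilcoxon_signed_rank(c(0, 0, 0)), "all paired differences")
})

test_that("exact p matches the enumeration oracle for n up to 12, ties included", {
  set.seed(12)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    d <- sample(c(-6:-1, 1:6), n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    got <- wilcoxon_signed_rank(d)
    want <- brute_wilcoxon(d)
    expect_equal(got$statistic, want$w)
    expect_equal(got$p.value, want$p)
  }
})

test_that("exact p agrees with stats::wilcox.test when there are no ties", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    d <- sample(seq_len(50), n) * sample(c(-1, 1), n, replace = TRUE)
    got <- wilcoxon_signed_rank(d)
    want <- wilcox.test(d, exact = TRUE)
    expect_equal(got$p.value, want$p.value)
  }
})

test_that("the p-value is invariant under monotone transforms of the differences", {
  d <- c(-3, 1, 4, -7, 2, 9)
  f <- function(x) sign(x) * (abs(x)^1.7 + 2 * abs(x))
  expect_equal(
    wilcoxon_signed_rank(d)$p.value,
    wilcoxon_signed_rank(f(d))$p.value
  )
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(14)
  d <- rnorm(40) + 0.5
  got <- wilcoxon_signed_rank(d)
  expect_match(got$method, "normal approximation")
  want <- wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
})

test_that("paired interfaces agree", {
  x <- c(3, 5, 2, 8); y <- c(1, 6, 2, 4)
  a <- wilcoxon_signed_rank(x, y)
  b <- wilcoxon_signed_rank(x - y)
  df <- tibble::tibble(pair_id = 1:4, value_fsc = x, value_nonfsc = y)
  c_ <- wilcoxon_signed_rank(df)
  expect_equal(a, b)
  expect_equal(a, c_)
})

test_that("hunting-sign prevalence is compared per pair", {
  dep <- tidyr::expand_grid(
    pair_id = sprintf("p%d", 1:5), certified = c(TRUE, FALSE),
    cam = 1:10
  )
  dep$hunting_signs <- ifelse(dep$certified, 0L, ifelse(dep$cam <= 6, 2L, 0L))
  res <- hunting_sign_test(dep)
  pairs <- attr(res, "pairs")
  expect_equal(pairs$value_nonfsc, rep(0.6, 5))
  expect_equal(pairs$value_fsc, rep(0, 5))
  expect_equal(res$n, 5L)
})

test_that("constant equal counts give a zero habituation interaction", {
  counts <- tidyr::expand_grid(
    concession_id = c("A", "B", "C", "D"), day = 1:70
  )
  counts$certified <- counts$concession_id %in% c("A", "B")
  counts$status <- factor(ifelse(counts$certified, "FSC", "non-FSC"),
                          levels = c("non-FSC", "FSC"))
  counts$n_obs <- 5L
  res <- suppressWarnings(habituation_test(counts)) # zero-residual fit
  expect_equal(res$estimate, 0, tolerance = 1e-12)
  expect_equal(res$window_days, 68)
})

test_that("the habituation window truncates to the shortest deployment", {
  counts <- tidyr::expand_grid(concession_id = c("A", "B", "C", "D"), day = 1:50)
  counts$certified <- counts$concession_id %in% c("A", "B")
  counts$status <- factor(ifelse(counts$certified, "FSC", "non-FSC"),
                          levels = c("non-FSC", "FSC"))
  counts$n_obs <- rpois(nrow(counts), 3)
  expect_warning(res <- habituation_test(counts, 68), "truncated")
  expect_equal(res$window_days, 50)
})

test_that("habituation null rejection rate is near nominal", {
  set.seed(15)
  reps <- 300
  rej <- 0
  grid <- tidyr::expand_grid(concession_id = sprintf("c%d", 1:14), day = 1:68)
  grid$certified <- grid$concession_id %in% sprintf("c%d", 1:7)
  grid$status <- factor(ifelse(grid$certified, "FSC", "non-FSC"),
                        levels = c("non-FSC", "FSC"))
  for (r in 1:reps) {
    grid$n_obs <- rpois(nrow(grid), 4)
    if (habituation_test(grid)$p.value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / reps, 0.02)
  expect_lte(rej / reps, 0.08)
})

test_that("a detection trend confined to one arm is flagged as an interaction", {
  hits <- 0
  for (s in 1:25) {
    sim <- simulate_dataset(
      mini_community(multiplier = 1),
      sim_design(
        n_pairs = 3, cameras_per_concession = c(10, 10), deployment_days = 70,
        downtime_prob = 0, detection_trend = c("non-FSC" = 1, "FSC" = 3),
        seed = 300 + s
      ),
      emit = "events"
    )
    counts <- daily_counts(sim$events, sim$deployments)
    res <- habituation_test(counts)
    if (res$p.value < 0.05 && res$estimate > 0) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.9)
})
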