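#' Exact two-sided Wilcoxon signed-rank test for paired concessions
#'
#' Computes the signed-rank statistic `W` (sum of the ranks of positive
#' differences, ties mid-ranked) after dropping zero differences
#' (Wilcoxon's convention), and a two-sided p-value. For `n <=
#' exact_threshold` non-zero pairs the p-value is exact, from the full
#' distribution of `W` over all `2^n` equiprobable sign assignments of the
#' observed absolute ranks (evaluated by dynamic programming, so ties are
#' handled exactly); beyond the threshold a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x Either a numeric vector (the certified-arm values, or the
#'   paired differences if `y` is `NULL`) or a data frame with columns
#'   `value_fsc` and `value_nonfsc` (one row per pair).
#' @param y Optional numeric vector of non-certified-arm values.
#' @param exact_threshold Largest `n` for which the exact distribution is
#'   enumerated.
#' @param correct Continuity correction in the normal approximation.
#' @return A one-row tibble: `statistic` (W), `p.value`, `n` (non-zero
#'   pairs), `zeros_dropped`, `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6, 7)) # p = 2/128
wilcoxon_signed_rank <- function(x, y = NULL, exact_threshold = 25, correct = TRUE) {
  if (is.data.frame(x)) {
    assert_columns(x, c("value_fsc", "value_nonfsc"), "paired table")
    d <- x$value_fsc - x$value_nonfsc
  } else if (!is.null(y)) {
    if (length(x) != length(y)) abort("`x` and `y` must have equal length")
    d <- x - y
  } else {
    d <- x
  }
  if (any(!is.finite(d))) abort("paired differences must be finite")

  zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; p = 1")
    return(tibble::tibble(
      statistic = 0, p.value = 1, n = 0L, zeros_dropped = zeros,
      method = "degenerate (all differences zero)"
    ))
  }

  r <- rank(abs(d)) # midranks
  w <- sum(r[d > 0])

  if (n <= exact_threshold) {
    # distribution of 2W over sign assignments (2r is integer even with ties)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)
    f[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(total + 1 - ri)])
      f <- f + shifted
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(f[seq_len(w2 + 1)])
    p_ge <- sum(f[seq(w2 + 1, total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration of sign assignments"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    dev <- w - mu
    if (correct) dev <- dev - sign(dev) * 0.5
    z <- dev / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }

  tibble::tibble(
    statistic = w, p.value = p, n = as.integer(n),
    zeros_dropped = as.integer(zeros), method = method
  )
}

#' Per-pair summaries of a concession-level value
#'
#' Reshapes a concession-level summary into the one-row-per-pair layout
#' used by [wilcoxon_signed_rank()].
#'
#' @param df Data frame with `pair_id`, `certified` and the value column.
#' @param value Name of the value column.
#' @return A tibble: `pair_id`, `value_fsc`, `value_nonfsc`.
#' @export
pair_values <- function(df, value) {
  assert_columns(df, c("pair_id", "certified", value), "concession summary")
  df |>
    dplyr::select("pair_id", "certified", value = dplyr::all_of(value)) |>
    dplyr::mutate(arm = ifelse(.data$certified, "value_fsc", "value_nonfsc")) |>
    dplyr::select(!"certified") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "value") |>
    dplyr::arrange(.data$pair_id)
}

#' Paired test of hunting-sign prevalence
#'
#' Summarises each concession by the proportion of camera locations with at
#' least one hunting sign (cartridges, snares or camps recorded on the
#' approach) and compares certified with non-certified concessions by the
#' exact Wilcoxon signed-rank test across pairs.
#'
#' @param deployments Validated deployment table with `hunting_signs`.
#' @return A one-row test tibble (see [wilcoxon_signed_rank()]) with the
#'   per-pair proportions attached as attribute `pairs`.
#' @export
hunting_sign_test <- function(deployments) {
  assert_columns(deployments, c("pair_id", "certified", "hunting_signs"),
                 "deployment table")
  props <- deployments |>
    dplyr::summarise(
      prop_with_signs = mean(.data$hunting_signs >= 1),
      .by = c("pair_id", "certified")
    )
  pairs <- pair_values(props, "prop_with_signs")
  out <- wilcoxon_signed_rank(pairs)
  attr(out, "pairs") <- pairs
  out
}

#' Daily observation counts per concession
#'
#' Tabulates independent detections per concession and deployment day
#' (day 1 is the first day after installation), filling days without
#' detections with zero up to each concession's deployment length.
#'
#' @param events Event table from [build_events()].
#' @param deployments Validated deployment table.
#' @return A tibble: `concession_id`, `certified`, `status`, `day`, `n_obs`.
#' @export
daily_counts <- function(events, deployments) {
  dep <- deployments |>
    dplyr::summarise(
      start = min(.data$start),
      n_days = max(ceiling(days_between(min(.data$start), max(.data$end)))),
      .by = c("concession_id", "certified")
    )
  cam2conc <- dplyr::select(deployments, "camera_id", "concession_id")
  counts <- events |>
    dplyr::left_join(cam2conc, by = "camera_id") |>
    dplyr::left_join(dep, by = "concession_id") |>
    dplyr::mutate(day = pmax(1, ceiling(days_between(.data$start, .data$start_time)))) |>
    dplyr::count(.data$concession_id, .data$day, name = "n_obs")
  dep |>
    dplyr::reframe(day = seq_len(.data$n_days), .by = c("concession_id", "certified")) |>
    dplyr::left_join(counts, by = c("concession_id", "day")) |>
    dplyr::mutate(
      n_obs = dplyr::coalesce(.data$n_obs, 0L),
      status = status_factor(.data$certified)
    )
}

#' Habituation check: detections over time by certification status
#'
#' Fits a linear model of log-transformed daily detection counts (with a +1
#' offset, since days without detections occur) on deployment day,
#' certification status, their interaction, and concession intercepts, over
#' the first `window_days` days of every deployment. A positive day-status
#' interaction would indicate camera shyness fading faster in one arm —
#' the confound the check is designed to detect. The window is truncated to
#' the shortest concession deployment when necessary.
#'
#' @param counts Daily counts from [daily_counts()].
#' @param window_days Analysis window in days (default 68).
#' @return A one-row tibble for the `day x status` interaction: `term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`, `window_days`,
#'   `n_obs`; the full `lm` fit is attached as attribute `fit`.
#' @export
habituation_test <- function(counts, window_days = 68) {
  assert_columns(counts, c("concession_id", "status", "day", "n_obs"), "daily counts")
  if (dplyr::n_distinct(counts$concession_id[counts$status == "FSC"]) < 2 ||
      dplyr::n_distinct(counts$concession_id[counts$status == "non-FSC"]) < 2) {
    abort("need at least two concessions per certification status")
  }
  shortest <- counts |>
    dplyr::summarise(len = max(.data$day), .by = "concession_id") |>
    dplyr::pull(.data$len) |>
    min()
  if (window_days > shortest) {
    warn(sprintf(
      "window of %d days exceeds the shortest deployment (%d days); truncated",
      window_days, shortest
    ))
    window_days <- shortest
  }
  d <- dplyr::filter(counts, .data$day <= window_days)
  fit <- lm(log(n_obs + 1) ~ day * status + concession_id, data = d)
  sm <- summary(fit)$coefficients
  row <- sm["day:statusFSC", ]
  out <- tibble::tibble(
    term = "day:statusFSC",
    estimate = row[["Estimate"]],
    std.error = row[["Std. Error"]],
    statistic = row[["t value"]],
    p.value = row[["Pr(>|t|)"]],
    window_days = window_days,
    n_obs = nrow(d)
  )
  attr(out, "fit") <- fit
  out
}
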