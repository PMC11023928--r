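#' Multivariate-t adjustment of a family of contrasts
#'
#' Adjusts each contrast's p-value for multiplicity using the joint
#' t-distribution of the contrast vector: the adjusted p-value of contrast
#' `i` is `P(max_j |T_j| >= |t_i|)` where `T` follows an m-dimensional t
#' distribution with the contrasts' correlation matrix and the given
#' degrees of freedom. The rectangle probabilities are evaluated by the
#' seeded Genz-Bretz quasi-Monte-Carlo algorithm; the Monte-Carlo standard
#' error is attached as attribute `mc_error`. Results are clamped to the
#' exact bounds `p_raw <= p_adj <= min(1, m * p_raw)` (single-step
#' adjustment never below the raw p, never above Bonferroni) and forced
#' monotone in `|t|`, so Monte-Carlo noise cannot violate either property.
#'
#' @param t_stats Observed t statistics (length m >= 1).
#' @param corr m x m correlation matrix of the contrasts (positive
#'   semi-definite).
#' @param df Degrees of freedom (positive; rounded to an integer).
#' @param n_mc Maximum number of quasi-Monte-Carlo function evaluations.
#' @param seed Seed for the quasi-Monte-Carlo lattice.
#' @return Numeric vector of adjusted p-values with attribute `mc_error`.
#' @export
#' @examples
#' mvt_adjust(c(2.0, -1.0), diag(2), df = 10)
mvt_adjust <- function(t_stats, corr, df, n_mc = 1e5, seed = 1L) {
  m <- length(t_stats)
  if (m == 0) abort("no contrasts to adjust")
  if (!is.matrix(corr) || !all(dim(corr) == m)) abort("`corr` must be an m x m matrix")
  if (any(abs(corr - t(corr)) > 1e-8) || min(eigen(corr, symmetric = TRUE,
                                                   only.values = TRUE)$values) < -1e-8) {
    abort("`corr` must be a symmetric positive semi-definite correlation matrix")
  }
  if (df <= 0) abort("`df` must be positive")
  df <- as.integer(round(df))

  p_raw <- 2 * pt(-abs(t_stats), df)
  if (m == 1) {
    out <- p_raw
    attr(out, "mc_error") <- 0
    return(out)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  p_adj <- numeric(m)
  err <- numeric(m)
  for (i in seq_len(m)) {
    q <- abs(t_stats[i])
    set.seed(seed)
    pr <- mvtnorm::pmvt(
      lower = rep(-q, m), upper = rep(q, m), df = df, corr = corr,
      algorithm = mvtnorm::GenzBretz(maxpts = n_mc, abseps = 1e-6)
    )
    p_adj[i] <- 1 - as.numeric(pr)
    err[i] <- attr(pr, "error") %||% NA_real_
  }

  # exact single-step bounds, then monotonicity in |t| (p non-increasing as
  # |t| grows; only ever raised, in running-max fashion, so MC noise cannot
  # make a larger statistic look less significant)
  p_adj <- pmin(pmax(p_adj, p_raw), pmin(1, m * p_raw))
  ord <- order(abs(t_stats))
  p_adj[ord] <- rev(cummax(rev(p_adj[ord])))
  attr(p_adj, "mc_error") <- max(err)
  p_adj
}

#' Certification contrasts and encounter-rate ratios
#'
#' For each level of the grouping factor (or once, for a pooled model),
#' estimates the marginal mean encounter rate in certified and
#' non-certified concessions, their difference with containment degrees of
#' freedom (`n_pairs - 1`), the multivariate-t adjusted p-value across
#' groups, and the FSC:non-FSC ratio of the estimated means on the response
#' scale with a delta-method standard error. For a `log1p` response the
#' means are back-transformed before the ratio is taken. A ratio is
#' reported as `NA` when the non-certified marginal mean is not positive.
#'
#' @param fit A [fit_lmm()] object.
#' @param n_mc,seed Passed to [mvt_adjust()].
#' @return A tibble of class `ctp_contrasts`: `group`, `mean_nonfsc`,
#'   `mean_fsc`, `estimate` (difference on the model scale), `std.error`,
#'   `df`, `statistic`, `p.value`, `p.adjusted`, `ratio`, `ratio_se`. The
#'   contrast correlation matrix and Monte-Carlo metadata are attached as
#'   attributes.
#' @export
certification_ratios <- function(fit, n_mc = 1e5, seed = 1L) {
  stopifnot(inherits(fit, "ctp_lmm"))
  groups <- if (fit$has_group) fit$group_levels else "all"
  grid <- tidyr::expand_grid(group = groups, status = c("non-FSC", "FSC"))
  if (!fit$has_group) grid$group <- NULL
  X <- fixed_model_matrix(fit, grid)

  beta <- lme4::fixef(fit$reml)
  V <- as.matrix(vcov(fit$reml))
  mu <- unname(drop(X %*% beta))    # marginal means, model scale
  i_non <- seq(1, nrow(X), by = 2)
  i_fsc <- seq(2, nrow(X), by = 2)

  L <- X[i_fsc, , drop = FALSE] - X[i_non, , drop = FALSE]
  est <- unname(drop(L %*% beta))
  Vc <- L %*% V %*% t(L)
  se <- sqrt(pmax(diag(Vc), 0))
  tstat <- est / se
  df <- fit$df_contrast
  p_raw <- 2 * pt(-abs(tstat), df)
  corr <- stats::cov2cor(Vc)
  p_adj <- mvt_adjust(tstat, corr, df, n_mc = n_mc, seed = seed)

  m_non <- mu[i_non]
  m_fsc <- mu[i_fsc]
  # per-group covariance of (mean_fsc, mean_non) for the delta method
  ratio <- ratio_se <- rep(NA_real_, length(groups))
  for (g in seq_along(groups)) {
    Xi <- X[c(i_fsc[g], i_non[g]), , drop = FALSE]
    Vi <- Xi %*% V %*% t(Xi)
    a <- m_fsc[g]; b <- m_non[g]
    if (fit$spec$transform == "log1p") {
      fa <- expm1(a); fb <- expm1(b)
      if (fb > 0) {
        ratio[g] <- fa / fb
        grad <- c(exp(a) / fb, -fa * exp(b) / fb^2)
        ratio_se[g] <- sqrt(drop(t(grad) %*% Vi %*% grad))
      }
    } else if (b > 0) {
      ratio[g] <- a / b
      grad <- c(1 / b, -a / b^2)
      ratio_se[g] <- sqrt(drop(t(grad) %*% Vi %*% grad))
    }
  }
  if (anyNA(ratio)) {
    inform("ratio undefined for group(s) with non-positive non-FSC marginal mean")
  }

  out <- tibble::tibble(
    group = groups,
    mean_nonfsc = if (fit$spec$transform == "log1p") expm1(m_non) else m_non,
    mean_fsc = if (fit$spec$transform == "log1p") expm1(m_fsc) else m_fsc,
    estimate = est, std.error = se, df = df,
    statistic = tstat, p.value = p_raw,
    p.adjusted = as.numeric(p_adj),
    ratio = ratio, ratio_se = ratio_se
  )
  attr(out, "corr") <- corr
  attr(out, "mc_error") <- attr(p_adj, "mc_error")
  attr(out, "mc_seed") <- seed
  attr(out, "n_mc") <- n_mc
  attr(out, "transform") <- fit$spec$transform
  class(out) <- c("ctp_contrasts", class(out))
  out
}
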