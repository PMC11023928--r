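#' Specify the encounter-rate mixed model
#'
#' The model regresses camera-level encounter rates on certification status,
#' optionally a grouping factor (body-mass class, IUCN category or taxon)
#' with a status-by-group interaction, and optional standardized geographic
#' covariates, with nested random intercepts for concession pair,
#' concession within pair and camera within concession.
#'
#' @param transform Response transformation: `"identity"` (default; the
#'   model describes rates directly) or `"log1p"`.
#' @param use_group Include the grouping factor and its interaction with
#'   status when the data carry more than one group (default `TRUE`).
#' @param covariates Character vector of covariate columns entering linearly
#'   (z-scored before fitting).
#' @param quadratic Subset of `covariates` that also enter as squared terms.
#' @return An object of class `ctp_lmm_spec`.
#' @export
lmm_spec <- function(transform = c("identity", "log1p"),
                     use_group = TRUE,
                     covariates = character(),
                     quadratic = character()) {
  transform <- match.arg(transform)
  if (!all(quadratic %in% covariates)) {
    abort("`quadratic` must be a subset of `covariates`")
  }
  structure(
    list(
      transform = transform, use_group = use_group,
      covariates = covariates, quadratic = quadratic
    ),
    class = "ctp_lmm_spec"
  )
}

spec_label <- function(spec) {
  if (length(spec$covariates) == 0) return("(base)")
  paste(vapply(spec$covariates, function(cv) {
    if (cv %in% spec$quadratic) paste0(cv, "+", cv, "^2") else cv
  }, character(1)), collapse = " + ")
}

#' Fit the nested linear mixed-effects model for encounter rates
#'
#' Fits `transform(encounter_rate) ~ status (* group) (+ covariates)` with
#' random intercepts for `pair_id`, `concession_id` (within pair) and
#' `camera_id` (within concession) via restricted maximum likelihood, and
#' refits by maximum likelihood for information-criterion comparisons
#' (`BIC = -2 logL_ML + k log n` with `n` the number of observations).
#' Random-effect terms that cannot be identified from the data — fewer than
#' two levels, or as many levels as observations (then confounded with the
#' residual) — are dropped with a message. Singular fits (a variance
#' component estimated at zero) are flagged, not fatal. Covariates are
#' z-scored internally; certification contrasts use containment degrees of
#' freedom, `n_pairs - 1`, since certification varies at the
#' concession-within-pair level.
#'
#' @param data Camera-level (or concession-level) rate table from
#'   [encounter_rate()], with any covariate columns joined on.
#' @param spec A [lmm_spec()].
#' @return An object of class `ctp_lmm`; see [tidy()] and [glance()]
#'   methods, [certification_ratios()] and [select_model()].
#' @export
fit_lmm <- function(data, spec = lmm_spec()) {
  stopifnot(inherits(spec, "ctp_lmm_spec"))
  assert_columns(data, c("encounter_rate", "status", "pair_id", "concession_id"),
                 "rate table")
  data <- tibble::as_tibble(data)
  if (dplyr::n_distinct(data$pair_id) < 2) abort("need at least 2 concession pairs")
  if (!all(is.finite(data$encounter_rate))) abort("non-finite encounter rates")

  d <- data
  d$.y <- switch(spec$transform,
    identity = d$encounter_rate,
    log1p = log1p(d$encounter_rate)
  )

  has_group <- spec$use_group && "group" %in% names(d) &&
    dplyr::n_distinct(d$group) > 1
  if (has_group) d$group <- droplevels(factor(d$group))

  for (cv in spec$covariates) {
    if (!cv %in% names(d)) abort(paste0("covariate column not found: ", cv))
    if (!all(is.finite(d[[cv]]))) abort(paste0("non-finite covariate: ", cv))
    s <- sd(d[[cv]])
    d[[cv]] <- if (s > 0) (d[[cv]] - mean(d[[cv]])) / s else d[[cv]] - mean(d[[cv]])
  }

  fixed_terms <- c(
    "status",
    if (has_group) c("group", "status:group"),
    spec$covariates,
    if (length(spec$quadratic)) paste0("I(", spec$quadratic, "^2)")
  )
  fixed_rhs <- paste(fixed_terms, collapse = " + ")

  n <- nrow(d)
  re_candidates <- c("pair_id", "concession_id", if ("camera_id" %in% names(d)) "camera_id")
  re_terms <- character(0)
  for (g in re_candidates) {
    nl <- dplyr::n_distinct(d[[g]])
    if (nl < 2) {
      warn(paste0("random effect '", g, "' has <2 levels and is dropped"))
    } else if (nl >= n) {
      inform(paste0(
        "random effect '", g, "' has one observation per level; ",
        "it is absorbed by the residual and dropped"
      ))
    } else {
      re_terms <- c(re_terms, paste0("(1 | ", g, ")"))
    }
  }
  if (length(re_terms) == 0) abort("no identifiable random-effect term; use lm() instead")

  # reject aliased fixed effects before lme4 can silently drop them
  X0 <- model.matrix(as.formula(paste("~", fixed_rhs)), d)
  qr0 <- qr(X0)
  if (qr0$rank < ncol(X0)) {
    aliased <- colnames(X0)[qr0$pivot[-seq_len(qr0$rank)]]
    abort(paste0(
      "fixed-effect design is rank deficient; aliased column(s): ",
      paste(aliased, collapse = ", ")
    ))
  }

  f <- as.formula(paste(".y ~", fixed_rhs, "+", paste(re_terms, collapse = " + ")))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = TRUE)
  reml <- lme4::lmer(f, data = d, REML = TRUE, control = ctrl)
  ml <- lme4::refitML(reml)

  vc <- as.data.frame(lme4::VarCorr(reml))
  varcomp <- tibble::tibble(
    component = ifelse(vc$grp == "Residual", "residual", vc$grp),
    variance = vc$vcov, sd = vc$sdcor
  )

  msgs <- reml@optinfo$conv$lme4$messages
  structure(
    list(
      reml = reml, ml = ml, spec = spec, data = d,
      fixed_rhs = fixed_rhs, has_group = has_group,
      group_levels = if (has_group) levels(d$group),
      n_obs = n,
      n_pairs = dplyr::n_distinct(d$pair_id),
      df_contrast = dplyr::n_distinct(d$pair_id) - 1,
      varcomp = varcomp,
      bic = stats::BIC(ml),
      logLik_reml = as.numeric(logLik(reml)),
      logLik_ml = as.numeric(logLik(ml)),
      singular = lme4::isSingular(reml),
      converged = is.null(msgs) || length(msgs) == 0
    ),
    class = "ctp_lmm"
  )
}

#' @export
print.ctp_lmm <- function(x, ...) {
  cat("Encounter-rate mixed model (", x$spec$transform, " response)\n", sep = "")
  cat("  fixed:  ~", x$fixed_rhs, "\n")
  cat("  n =", x$n_obs, "obs,", x$n_pairs, "pairs; BIC(ML) =", round(x$bic, 2), "\n")
  if (x$singular) cat("  note: singular fit (a variance component is zero)\n")
  print(x$varcomp)
  invisible(x)
}

#' Tidy the fixed effects or variance components of a rate model
#'
#' @param x A `ctp_lmm` object.
#' @param effects `"fixed"` (default) or `"ran_pars"`.
#' @param ... Unused.
#' @return A tibble in broom layout; fixed-effect p-values use the
#'   containment degrees of freedom (`n_pairs - 1`).
#' @method tidy ctp_lmm
#' @export
tidy.ctp_lmm <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "ran_pars") {
    return(dplyr::transmute(x$varcomp,
      term = paste0("sd__", .data$component), estimate = .data$sd
    ))
  }
  est <- lme4::fixef(x$reml)
  se <- sqrt(diag(as.matrix(vcov(x$reml))))
  stat <- unname(est / se)
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = stat,
    df = x$df_contrast,
    p.value = 2 * pt(-abs(stat), x$df_contrast)
  )
}

#' @rdname tidy.ctp_lmm
#' @method glance ctp_lmm
#' @export
glance.ctp_lmm <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    sigma = x$varcomp$sd[x$varcomp$component == "residual"],
    logLik_REML = x$logLik_reml,
    logLik_ML = x$logLik_ml,
    BIC = x$bic,
    singular = x$singular,
    converged = x$converged
  )
}

# Model matrix rows for a prediction grid on the fixed effects, with
# covariates held at their (z-scored) mean of zero.
fixed_model_matrix <- function(fit, grid) {
  for (cv in fit$spec$covariates) grid[[cv]] <- 0
  ff <- as.formula(paste("~", fit$fixed_rhs))
  xlev <- list()
  if (fit$has_group) xlev$group <- fit$group_levels
  xlev$status <- levels(fit$data$status)
  grid$status <- factor(grid$status, levels = xlev$status)
  if (fit$has_group) grid$group <- factor(grid$group, levels = xlev$group)
  model.matrix(ff, grid)
}
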