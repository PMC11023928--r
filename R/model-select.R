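
# Candidate states per covariate: absent, linear, or linear + quadratic.
select_states <- function(n_active_max, candidates, allow_quadratic) {
  states <- list(integer(0))
  grids <- expand.grid(rep(list(0:(1 + allow_quadratic)), length(candidates)))
  keep <- rowSums(grids > 0) <= n_active_max
  lapply(seq_len(nrow(grids))[keep], function(i) unlist(grids[i, ], use.names = FALSE))
}

state_to_spec <- function(state, candidates, base_spec) {
  lmm_spec(
    transform = base_spec$transform,
    use_group = base_spec$use_group,
    covariates = candidates[state > 0],
    quadratic = candidates[state == 2]
  )
}

#' Select covariates by BIC
#'
#' Searches over subsets of candidate geographic covariates (each entering
#' linearly or with an added quadratic term) and returns the specification
#' minimizing the Bayesian information criterion computed from maximum
#' likelihood fits, `BIC = -2 logL_ML + k log(n_obs)`. The search is
#' exhaustive over subsets of up to `max_exhaustive` covariates and then
#' extends the best subset forward one term at a time while BIC improves.
#' Ties are broken toward fewer parameters. Candidates are z-scored inside
#' [fit_lmm()].
#'
#' @param data Camera-level rate table with candidate covariate columns.
#' @param candidates Character vector of covariate column names.
#' @param base_spec The specification to which covariates are added
#'   (a [lmm_spec()]).
#' @param max_exhaustive Exhaustive-search bound on active covariates.
#' @param allow_quadratic Consider squared terms too?
#' @return A list of class `ctp_selection`: `best_spec`, `best_fit`, and
#'   `bic_table` (one row per model visited: covariate label, number of
#'   parameters, BIC and delta-BIC, sorted best first).
#' @export
select_model <- function(data, candidates = character(), base_spec = lmm_spec(),
                         max_exhaustive = 2, allow_quadratic = TRUE) {
  stopifnot(inherits(base_spec, "ctp_lmm_spec"))
  for (cv in candidates) {
    if (!cv %in% names(data)) abort(paste0("candidate column not found: ", cv))
    if (!all(is.finite(data[[cv]]))) abort(paste0("non-finite candidate covariate: ", cv))
  }

  fit_state <- function(state) {
    spec <- state_to_spec(state, candidates, base_spec)
    fit <- fit_lmm(data, spec)
    k <- attr(logLik(fit$ml), "df")
    tibble::tibble(
      covariates = spec_label(spec), k = k, BIC = fit$bic,
      state = list(state), fit = list(fit)
    )
  }

  if (length(candidates) == 0) {
    row <- fit_state(integer(0))
    out <- list(
      best_spec = base_spec, best_fit = row$fit[[1]],
      bic_table = dplyr::mutate(
        dplyr::select(row, "covariates", "k", "BIC"), delta_BIC = 0
      )
    )
    class(out) <- "ctp_selection"
    return(out)
  }

  states <- select_states(max_exhaustive, candidates, allow_quadratic)
  rows <- purrr::map_dfr(states, fit_state)

  pick_best <- function(tb) tb[order(tb$BIC, tb$k), ][1, ]
  best <- pick_best(rows)

  # forward extension beyond the exhaustive bound
  repeat {
    state <- best$state[[1]]
    moves <- list()
    for (j in seq_along(candidates)) {
      if (state[j] < 1) { s <- state; s[j] <- 1L; moves <- c(moves, list(s)) }
      if (allow_quadratic && state[j] == 1) { s <- state; s[j] <- 2L; moves <- c(moves, list(s)) }
    }
    moves <- Filter(function(s) sum(s > 0) > max_exhaustive, moves)
    if (length(moves) == 0) break
    seen <- vapply(rows$state, paste, character(1), collapse = "")
    moves <- Filter(function(s) !paste(s, collapse = "") %in% seen, moves)
    if (length(moves) == 0) break
    new_rows <- purrr::map_dfr(moves, fit_state)
    rows <- dplyr::bind_rows(rows, new_rows)
    cand <- pick_best(new_rows)
    if (cand$BIC < best$BIC - 1e-9) best <- cand else break
  }

  tab <- rows |>
    dplyr::mutate(delta_BIC = .data$BIC - min(.data$BIC)) |>
    dplyr::arrange(.data$BIC, .data$k) |>
    dplyr::select("covariates", "k", "BIC", "delta_BIC")

  out <- list(
    best_spec = state_to_spec(best$state[[1]], candidates, base_spec),
    best_fit = best$fit[[1]],
    bic_table = tab
  )
  class(out) <- "ctp_selection"
  out
}

#' @export
print.ctp_selection <- function(x, ...) {
  cat("BIC model selection (", nrow(x$bic_table), " models)\n", sep = "")
  cat("best:", spec_label(x$best_spec), "\n")
  print(x$bic_table, n = 10)
  invisible(x)
}
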