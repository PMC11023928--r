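
# Grouping levels at which rates are reported. At the taxon level the
# "other" group (hyraxes, aardvarks) is excluded for low sample sizes;
# shrews enter the rodent group through their taxon assignment in the
# trait table.
rate_levels <- c("all", "species", "body_mass_class", "iucn", "taxon")

#' Group-size-weighted encounter rates
#'
#' The encounter rate is the sum of event group sizes divided by sampling
#' effort, reported as observations per camera-trap day. Rates are computed
#' at a grouping level (`all` species pooled, per `species`, per
#' `body_mass_class`, per `iucn` category or per `taxon`) and a sampling
#' unit (`concession`, using the concession's total camera-days, or
#' `camera`, the unit used for mixed-model input). Units and groups with no
#' events get explicit zero rates; units with zero effort are dropped with a
#' message.
#'
#' @param events Event table from [build_events()].
#' @param effort Per-camera effort from [compute_effort()].
#' @param traits Trait table (see [load_traits()]); not needed for
#'   `level = "all"`.
#' @param level Grouping level.
#' @param unit `"concession"` or `"camera"`.
#' @return A tibble with `concession_id`, `pair_id`, `status` (and
#'   `camera_id` for camera-level rates), `group` (factor), `effort_days`,
#'   `n_observations` (group-size-weighted) and `encounter_rate`.
#' @export
#' @examples
#' # three events with group sizes 2, 3 and 1 over 100 camera-days: rate 0.06
encounter_rate <- function(events, effort, traits = NULL,
                           level = c("all", "species", "body_mass_class", "iucn", "taxon"),
                           unit = c("concession", "camera")) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  assert_columns(effort, c("camera_id", "concession_id", "pair_id", "certified", "active_days"),
                 "effort table")

  ev <- tibble::as_tibble(events)
  if (level != "all") {
    if (is.null(traits)) abort("`traits` is required for grouped rates")
    col <- switch(level,
      species = "species_label",
      body_mass_class = "body_mass_class",
      iucn = "iucn",
      taxon = "taxon"
    )
    missing_tr <- setdiff(unique(ev$species_label), traits$species_label)
    if (length(missing_tr) > 0) {
      abort(paste0(
        "species without trait rows at level '", level, "': ",
        paste(missing_tr, collapse = ", ")
      ))
    }
    tr <- tibble::tibble(
      species_label = traits$species_label,
      group = as.character(traits[[col]])
    )
    ev <- dplyr::inner_join(ev, tr, by = "species_label")
    groups <- if (is.factor(traits[[col]])) {
      levels(traits[[col]])
    } else {
      sort(unique(as.character(traits[[col]])))
    }
    if (level == "taxon") {
      groups <- setdiff(groups, "other")
      ev <- dplyr::filter(ev, .data$group != "other")
    }
  } else {
    ev$group <- "all"
    groups <- "all"
  }

  zero_effort <- effort$active_days <= 0
  if (any(zero_effort)) {
    inform(sprintf("dropping %d zero-effort camera(s)", sum(zero_effort)))
    effort <- effort[!zero_effort, , drop = FALSE]
  }
  ev <- dplyr::semi_join(ev, effort, by = "camera_id")

  obs <- ev |>
    dplyr::summarise(
      n_observations = sum(.data$group_size),
      .by = c("camera_id", "group")
    )

  unit_effort <- if (unit == "camera") {
    dplyr::transmute(effort,
      camera_id = .data$camera_id, concession_id = .data$concession_id,
      pair_id = .data$pair_id, certified = .data$certified,
      effort_days = .data$active_days
    )
  } else {
    effort |>
      dplyr::summarise(
        effort_days = sum(.data$active_days),
        .by = c("concession_id", "pair_id", "certified")
      )
  }

  if (unit == "camera") {
    grid <- tidyr::expand_grid(unit_effort, group = groups)
    rates <- grid |>
      dplyr::left_join(obs, by = c("camera_id", "group"))
  } else {
    cam_map <- dplyr::select(effort, "camera_id", "concession_id")
    obs_conc <- obs |>
      dplyr::left_join(cam_map, by = "camera_id") |>
      dplyr::summarise(
        n_observations = sum(.data$n_observations),
        .by = c("concession_id", "group")
      )
    grid <- tidyr::expand_grid(unit_effort, group = groups)
    rates <- grid |>
      dplyr::left_join(obs_conc, by = c("concession_id", "group"))
  }

  rates |>
    dplyr::mutate(
      n_observations = dplyr::coalesce(.data$n_observations, 0L),
      encounter_rate = .data$n_observations / .data$effort_days,
      status = status_factor(.data$certified),
      group = factor(.data$group, levels = groups),
      grouping_level = level
    ) |>
    dplyr::relocate("status", .after = "certified") |>
    dplyr::arrange(.data$pair_id, .data$concession_id, .data$group)
}

#' Relative faunal biomass index
#'
#' Sums encounter rate times mean body mass over species, per concession:
#' an index in kg per camera-trap day that tracks how total biomass differs
#' between units. It is a relative proxy derived from encounter rates and
#' cannot be interpreted as true (absolute) biomass. `literal = TRUE`
#' additionally divides each species' term by the concession's effort once
#' more (an alternative reading of the index's verbal definition); the
#' default keeps the index in rate units.
#'
#' @param species_rates Species-level, concession-unit rate table from
#'   [encounter_rate()].
#' @param traits Trait table with `mean_body_mass`.
#' @param literal Divide by effort a second time (see Details).
#' @return A tibble: `concession_id`, `pair_id`, `status`,
#'   `biomass_index` (kg per camera-day).
#' @export
biomass_proxy <- function(species_rates, traits, literal = FALSE) {
  assert_columns(species_rates, c("concession_id", "pair_id", "certified", "group",
                                  "effort_days", "encounter_rate"), "rate table")
  if (!identical(unique(species_rates$grouping_level), "species")) {
    abort("`species_rates` must be a species-level rate table")
  }
  joined <- species_rates |>
    dplyr::left_join(
      dplyr::select(traits, group = "species_label", "mean_body_mass"),
      by = "group"
    )
  if (anyNA(joined$mean_body_mass)) {
    abort(paste0(
      "missing body mass for: ",
      paste(unique(joined$group[is.na(joined$mean_body_mass)]), collapse = ", ")
    ))
  }
  joined |>
    dplyr::mutate(
      term = .data$encounter_rate * .data$mean_body_mass /
        (if (literal) .data$effort_days else 1)
    ) |>
    dplyr::summarise(
      biomass_index = sum(.data$term),
      .by = c("concession_id", "pair_id", "certified", "status")
    ) |>
    dplyr::arrange(.data$pair_id, .data$concession_id)
}
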