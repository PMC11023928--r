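#' Collapse photo streams into independent detection events
#'
#' Photos of one species at one camera are chained into a single event while
#' consecutive photos are less than `threshold_minutes` apart; a gap of at
#' least the threshold starts a new event (photos exactly at the threshold
#' are separate detections). The event's group size is the maximum per-photo
#' individual count among its members. With `anchor = "event_start"` the gap
#' is instead measured from the first photo of the current event, so no
#' event can span more than one threshold window.
#'
#' Status photos never seed events; duplicated rows (same camera, species,
#' timestamp and count) are collapsed with a warning. The result does not
#' depend on the input row order.
#'
#' @param photos Validated photo table (see [load_photos()]).
#' @param threshold_minutes Independence threshold in minutes (> 0);
#'   10 by default.
#' @param anchor `"last_photo"` (default, the camera-trap community norm) or
#'   `"event_start"`.
#' @return A tibble with one row per event: `camera_id`, `species_label`,
#'   `start_time`, `end_time`, `group_size`, `n_photos`.
#' @export
#' @examples
#' ph <- tibble::tibble(
#'   camera_id = "c1", species_label = "blue duiker",
#'   timestamp = as.POSIXct("2020-06-01", tz = "UTC") + c(0, 5, 9, 25) * 60,
#'   n_individuals = c(2L, 5L, 3L, 1L), is_status_photo = FALSE
#' )
#' build_events(ph) # two events; the first has group size 5
build_events <- function(photos, threshold_minutes = 10,
                         anchor = c("last_photo", "event_start")) {
  anchor <- match.arg(anchor)
  if (!is.numeric(threshold_minutes) || threshold_minutes <= 0) {
    abort("`threshold_minutes` must be positive")
  }
  assert_columns(photos, c(
    "camera_id", "timestamp", "species_label", "n_individuals", "is_status_photo"
  ), "photo table")

  ph <- photos |>
    dplyr::filter(!.data$is_status_photo) |>
    dplyr::select("camera_id", "species_label", "timestamp", "n_individuals")
  if (nrow(ph) == 0L) {
    return(tibble::tibble(
      camera_id = character(0), species_label = character(0),
      start_time = as.POSIXct(character(0), tz = "UTC"),
      end_time = as.POSIXct(character(0), tz = "UTC"),
      group_size = integer(0), n_photos = integer(0)
    ))
  }

  n0 <- nrow(ph)
  ph <- dplyr::distinct(ph)
  if (nrow(ph) < n0) {
    warn(sprintf("collapsed %d duplicate photo row(s)", n0 - nrow(ph)))
  }
  ph <- dplyr::arrange(ph, .data$camera_id, .data$species_label, .data$timestamp)

  key <- paste(ph$camera_id, ph$species_label, sep = "\r")
  new_group <- key != dplyr::lag(key, default = "\r\r")
  t <- as.numeric(ph$timestamp)
  thr <- threshold_minutes * 60

  if (anchor == "last_photo") {
    gap <- t - dplyr::lag(t, default = -Inf)
    ph$event <- cumsum(new_group | gap >= thr)
  } else {
    # gap measured from the first photo of the current event: sequential scan
    ev <- integer(nrow(ph))
    eid <- 0L
    anchor_t <- -Inf
    for (i in seq_len(nrow(ph))) {
      if (new_group[i] || (t[i] - anchor_t) >= thr) {
        eid <- eid + 1L
        anchor_t <- t[i]
      }
      ev[i] <- eid
    }
    ph$event <- ev
  }

  # events are contiguous runs of the sorted stream: aggregate by run
  # boundaries (vectorized; grouped summaries are too slow at photo scale)
  i_start <- which(!duplicated(ph$event))
  i_end <- c(i_start[-1] - 1L, nrow(ph))
  gs <- ph$n_individuals[i_start]
  off <- 1L
  repeat {
    idx <- i_start + off
    ok <- idx <= i_end
    if (!any(ok)) break
    gs[ok] <- pmax(gs[ok], ph$n_individuals[idx[ok]])
    off <- off + 1L
  }
  tibble::tibble(
    camera_id = ph$camera_id[i_start],
    species_label = ph$species_label[i_start],
    start_time = ph$timestamp[i_start],
    end_time = ph$timestamp[i_end],
    group_size = as.integer(gs),
    n_photos = i_end - i_start + 1L
  )
}

#' Sensitivity of event counts to the independence threshold
#'
#' Recomputes events under several independence thresholds and tabulates
#' counts (and within-threshold proportions) per body-mass class, the
#' standard check that the choice of threshold does not redistribute
#' detections across classes.
#'
#' @param photos Validated photo table.
#' @param traits Trait table with `body_mass_class` (see [load_traits()]).
#' @param thresholds Minutes; defaults to 10, 30, 60 and 1440.
#' @inheritParams build_events
#' @return A tibble: `threshold_minutes`, `body_mass_class`, `n_events`,
#'   `proportion` (of that threshold's total).
#' @export
sensitivity_table <- function(photos, traits, thresholds = c(10, 30, 60, 1440),
                              anchor = c("last_photo", "event_start")) {
  anchor <- match.arg(anchor)
  if (length(thresholds) == 0L) abort("`thresholds` must be non-empty")
  purrr::map_dfr(sort(thresholds), function(th) {
    build_events(photos, threshold_minutes = th, anchor = anchor) |>
      dplyr::inner_join(
        dplyr::select(traits, "species_label", "body_mass_class"),
        by = "species_label"
      ) |>
      dplyr::count(.data$body_mass_class, name = "n_events", .drop = FALSE) |>
      dplyr::mutate(
        threshold_minutes = th,
        proportion = .data$n_events / sum(.data$n_events)
      )
  }) |>
    dplyr::select("threshold_minutes", "body_mass_class", "n_events", "proportion")
}

#' Compute sampling effort (active camera-days)
#'
#' Effort is camera-days minus downtime. A camera's active window runs from
#' its deployment start to the earlier of the scheduled end and its last
#' photo (status or animal) plus one status interval — the rule that lets
#' scheduled status photos bound the failure time of a camera that died
#' early. Reported vegetation-obstruction downtime (`downtime_days`) is then
#' subtracted. Effort is reported in fractional days and never negative.
#'
#' @param deployments Validated deployment table (see [load_deployments()]).
#' @param photos Validated photo table (status photos included).
#' @param status_interval_h Scheduled status-photo interval, hours.
#' @return A tibble with one row per camera: `camera_id`, `concession_id`,
#'   `pair_id`, `certified`, `active_days`; concession totals are attached
#'   as attribute `concession_effort`.
#' @export
compute_effort <- function(deployments, photos, status_interval_h = 12) {
  assert_columns(deployments, c(
    "camera_id", "concession_id", "pair_id", "certified", "start", "end", "downtime_days"
  ), "deployment table")
  orphan <- setdiff(unique(photos$camera_id), deployments$camera_id)
  if (length(orphan) > 0) {
    abort(paste0(
      "photo(s) from camera(s) with no deployment record: ",
      paste(orphan, collapse = ", ")
    ))
  }

  last_photo <- photos |>
    dplyr::summarise(last_time = max(.data$timestamp), .by = "camera_id")

  eff <- deployments |>
    dplyr::left_join(last_photo, by = "camera_id") |>
    dplyr::mutate(
      window_end = pmin(.data$end, .data$last_time + status_interval_h * 3600, na.rm = FALSE),
      window_end = dplyr::if_else(is.na(.data$last_time), .data$start, .data$window_end),
      active_days = pmax(
        days_between(.data$start, .data$window_end) - .data$downtime_days, 0
      )
    )
  silent <- eff$camera_id[is.na(eff$last_time)]
  if (length(silent) > 0) {
    warn(paste0(
      "camera(s) with a deployment record but no photos get zero effort: ",
      paste(silent, collapse = ", ")
    ))
  }
  zero <- eff$camera_id[eff$active_days <= 0]
  if (length(zero) > 0 && length(zero) > length(silent)) {
    warn(sprintf("%d camera(s) have zero active days", length(zero)))
  }

  out <- dplyr::select(
    eff, "camera_id", "concession_id", "pair_id", "certified", "active_days"
  )
  attr(out, "concession_effort") <- out |>
    dplyr::summarise(
      total_days = sum(.data$active_days),
      .by = c("concession_id", "pair_id", "certified")
    )
  out
}
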