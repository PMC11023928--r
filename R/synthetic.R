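#' Describe one species for the synthetic community
#'
#' A species is characterised by its trait values (mean adult body mass, IUCN
#' Red List category, taxonomic group), its expected independent-detection
#' rate in a non-certified concession, a typical group size, and the
#' multiplicative effect of forest-management certification on its rate.
#' Group sizes are drawn from a shifted Poisson, `1 + Poisson(mean - 1)`,
#' which keeps them on the positive integers with the requested mean.
#'
#' @param name Species label (used as `species_label` downstream).
#' @param mean_body_mass Mean adult body mass across sexes, kg (> 0).
#' @param iucn IUCN category, one of CR, EN, VU, NT, LC, DD.
#' @param taxon Taxonomic group used in the analysis: one of
#'   `"elephants"`, `"primates"`, `"ungulates"`, `"carnivores"`,
#'   `"pangolins"`, `"rodents"`, `"other"`.
#' @param base_rate Expected independent detections per camera-day in a
#'   non-certified concession (>= 0).
#' @param group_size_mean Mean group size (>= 1).
#' @param certification_multiplier Ratio applied to `base_rate` in certified
#'   concessions (>= 0, finite).
#'
#' @return A one-row tibble; rows from several calls can be bound into a
#'   community table for [simulate_dataset()].
#' @export
#' @examples
#' species_spec("blue duiker", 4.5, "LC", "ungulates", base_rate = 0.25)
species_spec <- function(name, mean_body_mass, iucn, taxon,
                         base_rate, group_size_mean = 1,
                         certification_multiplier = 1) {
  iucn <- match.arg(iucn, c("CR", "EN", "VU", "NT", "LC", "DD"))
  taxon <- match.arg(taxon, c(
    "elephants", "primates", "ungulates", "carnivores",
    "pangolins", "rodents", "other"
  ))
  stopifnot(
    is.character(name), length(name) == 1L,
    is.finite(mean_body_mass), mean_body_mass > 0,
    is.finite(base_rate), base_rate >= 0,
    is.finite(group_size_mean), group_size_mean >= 1,
    is.finite(certification_multiplier), certification_multiplier >= 0
  )
  tibble::tibble(
    name = name, mean_body_mass = mean_body_mass, iucn = iucn, taxon = taxon,
    base_rate = base_rate, group_size_mean = group_size_mean,
    certification_multiplier = certification_multiplier
  )
}

#' Default synthetic mammal community
#'
#' A deterministic community of 28 western-equatorial-African-forest-like
#' mammal "species" spanning all five body-mass classes, all taxonomic
#' groups and five IUCN categories, with heavy-tailed detection rates
#' (a few common duikers and rodents, many rare species). Certification
#' multipliers follow the pattern the analysis is designed to detect:
#' no effect below 10 kg, and multipliers of 3.5, 2.5 and 2.7 for the
#' 10-30 kg, 30-100 kg and >100 kg classes respectively.
#'
#' @return A tibble of species specifications (see [species_spec()]).
#' @export
#' @examples
#' comm <- default_community()
#' table(assign_body_mass_class(comm$mean_body_mass))
default_community <- function() {
  s <- function(...) species_spec(...)
  dplyr::bind_rows(
    # > 100 kg (certification multiplier 2.7)
    s("forest elephant",        2800, "CR", "elephants",  0.040, 1.8, 2.7),
    s("forest buffalo",          400, "NT", "ungulates",  0.012, 2.5, 2.7),
    s("western gorilla",         120, "CR", "primates",   0.020, 2.2, 2.7),
    # 30-100 kg (multiplier 2.5)
    s("chimpanzee",               45, "EN", "primates",   0.025, 2.0, 2.5),
    s("leopard",                  52, "VU", "carnivores", 0.008, 1.0, 2.5),
    s("red river hog",            60, "LC", "ungulates",  0.045, 3.0, 2.5),
    s("yellow-backed duiker",     62, "NT", "ungulates",  0.020, 1.0, 2.5),
    s("sitatunga",                55, "LC", "ungulates",  0.008, 1.0, 2.5),
    s("aardvark",                 53, "LC", "other",      0.002, 1.0, 2.5),
    # 10-30 kg (multiplier 3.5)
    s("bay duiker",               20, "NT", "ungulates",  0.120, 1.1, 3.5),
    s("Peters's duiker",          16, "LC", "ungulates",  0.100, 1.1, 3.5),
    s("white-bellied duiker",     15, "NT", "ungulates",  0.030, 1.0, 3.5),
    s("giant pangolin",           30, "EN", "pangolins",  0.004, 1.0, 3.5),
    s("mandrill",                 18, "VU", "primates",   0.015, 4.0, 3.5),
    s("African golden cat",       11, "VU", "carnivores", 0.006, 1.0, 3.5),
    s("water chevrotain",         11, "LC", "ungulates",  0.025, 1.0, 3.5),
    # 1-10 kg (no certification effect)
    s("blue duiker",             4.5, "LC", "ungulates",  0.250, 1.2, 1.0),
    s("brush-tailed porcupine",  3.0, "LC", "rodents",    0.120, 1.3, 1.0),
    s("white-bellied pangolin",  2.5, "EN", "pangolins",  0.008, 1.0, 1.0),
    s("African civet",          10.0, "LC", "carnivores", 0.020, 1.0, 1.0),
    s("servaline genet",         2.0, "LC", "carnivores", 0.030, 1.0, 1.0),
    s("greater cane rat",        4.5, "LC", "rodents",    0.040, 1.2, 1.0),
    s("marsh mongoose",          3.0, "LC", "carnivores", 0.035, 1.0, 1.0),
    s("putty-nosed monkey",      4.0, "LC", "primates",   0.030, 3.0, 1.0),
    s("tree hyrax",              2.5, "LC", "other",      0.003, 1.0, 1.0),
    # <= 1 kg small-mammal groups (no certification effect)
    s("squirrels",               0.5, "LC", "rodents",    0.150, 1.1, 1.0),
    s("rats and mice",          0.08, "LC", "rodents",    0.200, 1.2, 1.0),
    s("shrews",                 0.05, "LC", "rodents",    0.060, 1.0, 1.0)
  )
}

#' Survey design for the synthetic-data generator
#'
#' Mirrors the paired-concession camera-trap design: `n_pairs` blocks, each
#' with one certified and one non-certified concession, a systematic grid of
#' cameras per concession, and simultaneous deployments of fixed length.
#' Heterogeneity is log-normal and multiplicative on detection rates, with
#' independent normal deviates (log scale) at the pair, concession and camera
#' levels. Camera malfunction is a single terminal outage: an affected camera
#' stops recording (animal and status photos alike) some days early, and the
#' lost days are recovered downstream from the last status photo, so the
#' `downtime_days` column written by the generator stays 0.
#'
#' @param n_pairs Number of concession pairs (>= 1).
#' @param cameras_per_concession Integer range `c(min, max)`; each concession
#'   draws its camera count uniformly from this range.
#' @param deployment_days Scheduled deployment length in days (> 0).
#' @param start_date Date-time at which all deployments begin.
#' @param downtime_prob Probability a camera suffers a terminal outage.
#' @param downtime_days_dist Function `n -> integer vector` drawing the days
#'   lost by each failed camera.
#' @param sd_pair,sd_concession,sd_camera Standard deviations of the
#'   log-rate random effects (>= 0).
#' @param burst_size Photos emitted per trigger (default 3).
#' @param status_photo_interval_h Hours between scheduled status photos
#'   (default 12).
#' @param covariate_effects Optional named numeric vector of log-rate slopes
#'   for standard-normal camera-level geographic covariates (names among
#'   `elevation`, `dist_roads`, `dist_rivers`, `dist_settlements`,
#'   `dist_protected`); covariate columns are always written to the
#'   deployment table, with zero effect unless named here.
#' @param hunting_sign_rate Named numeric, Poisson mean of hunting-sign
#'   counts per camera approach in `non-FSC` and `FSC` concessions.
#' @param detection_trend Named numeric; relative detection intensity at the
#'   end versus the start of a deployment (1 = flat) for each status, used
#'   for habituation scenarios.
#' @param seed Integer seed; the generator is fully deterministic given it.
#'
#' @return A list of class `ctp_design`.
#' @export
sim_design <- function(n_pairs = 7,
                       cameras_per_concession = c(28, 36),
                       deployment_days = 80,
                       start_date = "2020-06-01",
                       downtime_prob = 0.15,
                       downtime_days_dist = function(n) sample.int(30L, n, replace = TRUE),
                       sd_pair = 0.3, sd_concession = 0.2, sd_camera = 0.4,
                       burst_size = 3,
                       status_photo_interval_h = 12,
                       covariate_effects = NULL,
                       hunting_sign_rate = c("non-FSC" = 1.5, "FSC" = 0.5),
                       detection_trend = c("non-FSC" = 1, "FSC" = 1),
                       seed = 1L) {
  if (!is.numeric(deployment_days) || deployment_days <= 0) {
    abort("`deployment_days` must be a positive number.")
  }
  stopifnot(
    n_pairs >= 1,
    length(cameras_per_concession) == 2L,
    cameras_per_concession[1] >= 1,
    cameras_per_concession[2] >= cameras_per_concession[1],
    downtime_prob >= 0, downtime_prob <= 1,
    sd_pair >= 0, sd_concession >= 0, sd_camera >= 0,
    burst_size >= 1, status_photo_interval_h > 0,
    all(detection_trend > 0)
  )
  structure(
    list(
      n_pairs = as.integer(n_pairs),
      cameras_per_concession = as.integer(cameras_per_concession),
      deployment_days = deployment_days,
      start_date = as_posixct_utc(start_date, "start_date"),
      downtime_prob = downtime_prob,
      downtime_days_dist = downtime_days_dist,
      sd_pair = sd_pair, sd_concession = sd_concession, sd_camera = sd_camera,
      burst_size = as.integer(burst_size),
      status_photo_interval_h = status_photo_interval_h,
      covariate_effects = covariate_effects,
      hunting_sign_rate = hunting_sign_rate,
      detection_trend = detection_trend,
      seed = as.integer(seed)
    ),
    class = "ctp_design"
  )
}

geo_covariates <- c(
  "elevation", "dist_roads", "dist_rivers", "dist_settlements", "dist_protected"
)

# Inverse-CDF sampling of event times on [0, total] under a linearly
# changing intensity: f(t) proportional to 1 + (trend - 1) * t / total.
draw_event_times <- function(n, total, trend) {
  if (n == 0L) return(numeric(0))
  u <- runif(n)
  if (abs(trend - 1) < 1e-12) return(u * total)
  a <- (trend - 1) / 2
  # CDF(t/total = x) = (x + a x^2) / (1 + a); solve a x^2 + x - u (1 + a) = 0
  x <- (-1 + sqrt(1 + 4 * a * u * (1 + a))) / (2 * a)
  x * total
}

#' Simulate a paired camera-trap survey
#'
#' Generates photo-level (or event-level) records, deployment metadata and a
#' species-trait table under the hierarchical model the downstream analysis
#' assumes: species `s` at camera `c` in concession `j` of pair `p` triggers
#' independent detections as a Poisson process with rate
#' `base_rate_s * multiplier_s^certified * exp(u_p + u_j + u_c + x_c' beta)`
#' per active day, with `u ~ Normal(0, sd^2)` on the log scale. Each
#' detection carries a group size drawn once per event; with
#' `emit = "photos"` it is expanded into a burst of `burst_size` photos 1-2 s
#' apart whose per-photo individual counts are at most the group size, with
#' the maximum attained at least once. Status photos are emitted on schedule
#' until the camera's (possibly truncated) active window ends.
#'
#' @param species Community table, e.g. [default_community()] or rows built
#'   with [species_spec()].
#' @param design A [sim_design()] object.
#' @param emit `"photos"` (default) for full photo streams valid as
#'   [load_photos()] input, or `"events"` for the faster event-level path
#'   (one row per independent detection, plus an exact effort table) used in
#'   simulation studies that do not exercise the photo-processing stage.
#'
#' @return A list of class `ctp_sim` with elements `photos` (or `events` and
#'   `effort`), `deployments`, `traits`; the design (including its seed) is
#'   attached as attribute `design`, the species truth as attribute
#'   `species`.
#' @export
#' @examples
#' sim <- simulate_dataset(default_community(),
#'   sim_design(n_pairs = 2, cameras_per_concession = c(4, 4),
#'              deployment_days = 20, seed = 7))
#' nrow(sim$photos)
simulate_dataset <- function(species, design = sim_design(),
                             emit = c("photos", "events")) {
  emit <- match.arg(emit)
  if (!inherits(design, "ctp_design")) abort("`design` must come from sim_design().")
  if (is.null(species) || nrow(species) == 0L) abort("`species` must contain at least one species.")
  assert_columns(species, c(
    "name", "mean_body_mass", "iucn", "taxon",
    "base_rate", "group_size_mean", "certification_multiplier"
  ), "species table")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(design$seed)

  ## ---- deployments ----------------------------------------------------
  conc <- tidyr::expand_grid(
    pair_id = sprintf("pair%02d", seq_len(design$n_pairs)),
    certified = c(TRUE, FALSE)
  )
  conc$concession_id <- paste0(conc$pair_id, ifelse(conc$certified, "_FSC", "_NON"))
  rng <- design$cameras_per_concession
  conc$n_cameras <- sample(seq(rng[1], rng[2]), nrow(conc), replace = TRUE)

  dep <- conc |>
    dplyr::rowwise() |>
    dplyr::mutate(camera = list(sprintf("%s_cam%02d", .data$concession_id, seq_len(.data$n_cameras)))) |>
    dplyr::ungroup() |>
    tidyr::unnest("camera") |>
    dplyr::rename(camera_id = "camera") |>
    dplyr::select(!"n_cameras")

  n_cam <- nrow(dep)
  dep$start <- design$start_date
  dep$end <- design$start_date + design$deployment_days * 86400

  # terminal outages
  failed <- runif(n_cam) < design$downtime_prob
  lost <- integer(n_cam)
  if (any(failed)) {
    lost[failed] <- pmin(
      pmax(as.integer(design$downtime_days_dist(sum(failed))), 0L),
      as.integer(floor(design$deployment_days)) - 1L
    )
  }
  dep$active_days <- design$deployment_days - lost
  dep$downtime_days <- 0 # outages are recovered from status photos downstream

  # site covariates
  dep$visibility <- sample(c("0-10 m", "11-20 m", ">20 m"), n_cam, TRUE, prob = c(0.5, 0.3, 0.2))
  dep$slope <- sample(c("0-5 deg", "5-20 deg", ">20 deg"), n_cam, TRUE, prob = c(0.6, 0.3, 0.1))
  dep$fruiting_tree_30m <- runif(n_cam) < 0.3
  dep$water_50m <- runif(n_cam) < 0.2
  dep$trail_type <- sample(
    c("elephant path", "skidder trail", "wildlife trail", "none"),
    n_cam, TRUE, prob = c(0.1, 0.15, 0.35, 0.4)
  )
  dep$hunting_signs <- rpois(
    n_cam,
    unname(design$hunting_sign_rate[ifelse(dep$certified, "FSC", "non-FSC")])
  )
  for (cv in geo_covariates) dep[[cv]] <- rnorm(n_cam)

  ## ---- hierarchical log-rate effects ----------------------------------
  pair_u <- setNames(rnorm(design$n_pairs, 0, design$sd_pair), unique(dep$pair_id))
  conc_u <- setNames(rnorm(nrow(conc), 0, design$sd_concession), conc$concession_id)
  cam_u <- rnorm(n_cam, 0, design$sd_camera)

  cov_eff <- rep(0, n_cam)
  if (!is.null(design$covariate_effects) && length(design$covariate_effects) > 0) {
    bad <- setdiff(names(design$covariate_effects), geo_covariates)
    if (length(bad) > 0) abort(paste0("unknown covariate effect(s): ", paste(bad, collapse = ", ")))
    for (cv in names(design$covariate_effects)) {
      cov_eff <- cov_eff + design$covariate_effects[[cv]] * dep[[cv]]
    }
  }
  dep$log_effect <- unname(pair_u[dep$pair_id]) + unname(conc_u[dep$concession_id]) +
    cam_u + cov_eff

  ## ---- events ---------------------------------------------------------
  grid <- tidyr::expand_grid(cam_row = seq_len(n_cam), sp_row = seq_len(nrow(species)))
  grid$camera_id <- dep$camera_id[grid$cam_row]
  grid$certified <- dep$certified[grid$cam_row]
  grid$active_days <- dep$active_days[grid$cam_row]
  grid$rate <- species$base_rate[grid$sp_row] *
    ifelse(grid$certified, species$certification_multiplier[grid$sp_row], 1) *
    exp(dep$log_effect[grid$cam_row])
  grid$n_events <- rpois(nrow(grid), grid$rate * grid$active_days)

  ev <- grid[rep.int(seq_len(nrow(grid)), grid$n_events), c("cam_row", "sp_row")]
  n_ev <- nrow(ev)
  trend <- unname(design$detection_trend[ifelse(dep$certified[ev$cam_row], "FSC", "non-FSC")])
  t_days <- numeric(n_ev)
  if (n_ev > 0) {
    u <- runif(n_ev)
    act <- dep$active_days[ev$cam_row]
    flat <- abs(trend - 1) < 1e-12
    t_days[flat] <- u[flat] * act[flat]
    if (any(!flat)) {
      a <- (trend[!flat] - 1) / 2
      x <- (-1 + sqrt(1 + 4 * a * u[!flat] * (1 + a))) / (2 * a)
      t_days[!flat] <- x * act[!flat]
    }
  }
  gs_mean <- species$group_size_mean[ev$sp_row]
  events <- tibble::tibble(
    camera_id = dep$camera_id[ev$cam_row],
    species_label = species$name[ev$sp_row],
    time = design$start_date + t_days * 86400,
    group_size = 1L + rpois(n_ev, pmax(gs_mean - 1, 0))
  )
  events <- dplyr::arrange(events, .data$camera_id, .data$species_label, .data$time)

  traits <- tibble::tibble(
    species_label = species$name,
    mean_body_mass = species$mean_body_mass,
    iucn = species$iucn,
    taxon = species$taxon
  )
  deployments <- dplyr::select(dep, !c("log_effect", "active_days"))

  out <- if (emit == "events") {
    list(
      events = tibble::tibble(
        camera_id = events$camera_id,
        species_label = events$species_label,
        start_time = events$time,
        end_time = events$time,
        group_size = events$group_size,
        n_photos = design$burst_size
      ),
      effort = tibble::tibble(
        camera_id = dep$camera_id,
        active_days = as.numeric(dep$active_days)
      ),
      deployments = deployments,
      traits = traits
    )
  } else {
    list(
      photos = emit_photos(events, dep, design),
      deployments = deployments,
      traits = traits
    )
  }
  structure(out, class = "ctp_sim", design = design, species = species, seed = design$seed)
}

# Expand events into triple-photo bursts plus scheduled status photos.
emit_photos <- function(events, dep, design) {
  b <- design$burst_size
  n_ev <- nrow(events)

  if (n_ev > 0) {
    idx <- rep.int(seq_len(n_ev), rep.int(b, n_ev))
    within <- rep.int(seq_len(b), n_ev)
    # photos 1-2 s apart within the burst
    gaps <- matrix(0, nrow = b, ncol = n_ev)
    if (b > 1) gaps[-1, ] <- matrix(runif((b - 1) * n_ev, 1, 2), nrow = b - 1)
    offs <- as.vector(apply(gaps, 2, cumsum))
    g <- events$group_size[idx]
    counts <- ifelse(runif(length(idx)) < 0.5, g, pmax(1L, as.integer(ceiling(runif(length(idx)) * g))))
    # force the maximum to be attained on one photo of each burst
    first_of_burst <- within == sample.int(b, n_ev, replace = TRUE)[idx]
    counts[first_of_burst] <- g[first_of_burst]
    animal <- tibble::tibble(
      camera_id = events$camera_id[idx],
      timestamp = events$time[idx] + offs,
      species_label = events$species_label[idx],
      n_individuals = as.integer(counts),
      is_status_photo = FALSE
    )
  } else {
    animal <- tibble::tibble(
      camera_id = character(0), timestamp = design$start_date[0],
      species_label = character(0), n_individuals = integer(0),
      is_status_photo = logical(0)
    )
  }

  iv_h <- design$status_photo_interval_h
  n_status <- floor(dep$active_days * 24 / iv_h)
  sidx <- rep.int(seq_len(nrow(dep)), n_status + 1L)
  ticks <- unlist(lapply(n_status, function(k) seq(0L, k)), use.names = FALSE)
  status <- tibble::tibble(
    camera_id = dep$camera_id[sidx],
    timestamp = dep$start[sidx] + ticks * iv_h * 3600,
    species_label = NA_character_,
    n_individuals = 0L,
    is_status_photo = TRUE
  )

  dplyr::bind_rows(animal, status) |>
    dplyr::arrange(.data$camera_id, .data$timestamp, .data$is_status_photo)
}

#' Write a simulated dataset to CSV tables
#'
#' Writes `photos.csv` (or `events.csv`/`effort.csv`), `deployments.csv` and
#' `traits.csv` into `dir`, together with a `metadata.yaml` recording the
#' seed and design parameters so a run can be reproduced exactly.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "ctp_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim)) {
    readr::write_csv(sim[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  design <- attr(sim, "design")
  meta <- design[setdiff(names(design), "downtime_days_dist")]
  meta$start_date <- format(meta$start_date, "%Y-%m-%d %H:%M:%S")
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}
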