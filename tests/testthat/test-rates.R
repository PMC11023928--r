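make_effort <- function(active = 100, cameras = "c1") {
  tibble::tibble(
    camera_id = cameras, concession_id = "A", pair_id = "p1",
    certified = TRUE, active_days = rep_len(active, length(cameras))
  )
}

events_fix <- tibble::tibble(
  camera_id = "c1", species_label = "sp1",
  start_time = t_origin + 1:3, end_time = t_origin + 1:3,
  group_size = c(2L, 3L, 1L), n_photos = 1L
)

traits2 <- load_traits(tibble::tibble(
  species_label = c("sp1", "sp2", "hyrax"),
  mean_body_mass = c(20, 15, 2.5),
  iucn = c("EN", "LC", "LC"),
  taxon = c("ungulates", "ungulates", "other")
))

test_that("encounter rate is group-size-weighted observations per camera-day", {
  r <- quiet(encounter_rate(events_fix, make_effort(100), level = "all"))
  expect_equal(r$encounter_rate, 0.06)
  expect_equal(r$n_observations, 6L)
})

test_that("no events means an explicit zero rate", {
  r <- quiet(encounter_rate(events_fix[0, ], make_effort(100), level = "all"))
  expect_equal(r$encounter_rate, 0)
})

test_that("rates are additive over disjoint species sets", {
  ev <- dplyr::bind_rows(
    events_fix,
    dplyr::mutate(events_fix, species_label = "sp2", group_size = 1L)
  )
  by_sp <- quiet(encounter_rate(ev, make_effort(100), traits2, "species"))
  by_class <- quiet(encounter_rate(ev, make_effort(100), traits2, "body_mass_class"))
  expect_equal(
    sum(by_sp$encounter_rate),
    by_class$encounter_rate[by_class$group == "10-30 kg"]
  )
  pooled <- quiet(encounter_rate(ev, make_effort(100), level = "all"))
  expect_equal(sum(by_sp$encounter_rate), pooled$encounter_rate)
})

test_that("scaling group sizes scales rates linearly", {
  ev2 <- dplyr::mutate(events_fix, group_size = group_size * 3L)
  r1 <- quiet(encounter_rate(events_fix, make_effort(100), level = "all"))
  r2 <- quiet(encounter_rate(ev2, make_effort(100), level = "all"))
  expect_equal(r2$encounter_rate, 3 * r1$encounter_rate)
})

test_that("the 'other' taxon is excluded from the taxon analysis only", {
  ev <- dplyr::bind_rows(
    events_fix,
    dplyr::mutate(events_fix[1, ], species_label = "hyrax")
  )
  by_taxon <- quiet(encounter_rate(ev, make_effort(100), traits2, "taxon"))
  expect_false("other" %in% by_taxon$group)
  pooled <- quiet(encounter_rate(ev, make_effort(100), level = "all"))
  expect_equal(pooled$n_observations, 8L) # hyrax still pooled
})

test_that("zero-effort cameras are dropped; missing traits error", {
  eff <- make_effort(c(100, 0), cameras = c("c1", "c2"))
  expect_message(
    r <- encounter_rate(events_fix, eff, level = "all", unit = "camera"),
    "zero-effort"
  )
  expect_equal(nrow(r), 1)
  stranger <- dplyr::mutate(events_fix, species_label = "nobody")
  expect_error(
    quiet(encounter_rate(stranger, make_effort(100), traits2, "species")),
    "nobody"
  )
})

test_that("camera-level rates complete the camera-by-group grid with zeros", {
  eff <- make_effort(c(50, 50), cameras = c("c1", "c2"))
  r <- quiet(encounter_rate(events_fix, eff, traits2, "body_mass_class",
                            unit = "camera"))
  expect_equal(nrow(r), 2 * 5) # 2 cameras x 5 classes
  expect_equal(sum(r$encounter_rate > 0), 1)
})

test_that("biomass index multiplies rates by body mass and is linear in effort", {
  ev <- tibble::tibble(
    camera_id = "c1", species_label = "sp1",
    start_time = t_origin, end_time = t_origin,
    group_size = 1L, n_photos = 1L
  )
  tr <- load_traits(tibble::tibble(
    species_label = "sp1", mean_body_mass = 2800,
    iucn = "CR", taxon = "elephants"
  ))
  r <- quiet(encounter_rate(ev, make_effort(100), tr, "species"))
  expect_equal(r$encounter_rate, 0.01)
  b <- biomass_proxy(r, tr)
  expect_equal(b$biomass_index, 28)
  # doubling effort halves the rate and the index
  r2 <- quiet(encounter_rate(ev, make_effort(200), tr, "species"))
  expect_equal(biomass_proxy(r2, tr)$biomass_index, 14)
  # zero rates give a zero index
  r0 <- quiet(encounter_rate(ev[0, ], make_effort(100), tr, "species"))
  expect_equal(biomass_proxy(r0, tr)$biomass_index, 0)
  # literal reading divides by effort once more
  expect_equal(biomass_proxy(r, tr, literal = TRUE)$biomass_index, 0.28)
})

test_that("concession rates recover rate x multiplier x mean group size when sds are 0", {
  sp <- species_spec("sp", 10, "LC", "ungulates", 0.2,
                     group_size_mean = 2, certification_multiplier = 1.5)
  set.seed(77)
  rates <- replicate(40, {
    s <- sample.int(1e6, 1)
    sim <- simulate_dataset(sp, sim_design(
      n_pairs = 1, cameras_per_concession = c(4, 4), deployment_days = 50,
      downtime_prob = 0, sd_pair = 0, sd_concession = 0, sd_camera = 0,
      seed = s
    ), emit = "events")
    r <- quiet(encounter_rate(sim$events, sim_effort(sim), level = "all",
                              unit = "concession"))
    c(fsc = r$encounter_rate[r$certified], non = r$encounter_rate[!r$certified])
  })
  truth <- c(fsc = 0.2 * 1.5 * 2, non = 0.2 * 2)
  for (arm in c("fsc", "non")) {
    m <- mean(rates[arm, ])
    se <- sd(rates[arm, ]) / sqrt(ncol(rates))
    expect_lt(abs(m - truth[[arm]]), 3 * se + 1e-9)
  }
})
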