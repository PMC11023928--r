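# Shared fixtures: all built in code at test time.

t_origin <- as.POSIXct("2020-06-01 00:00:00", tz = "UTC")

# A photo stream at the given offsets (minutes) for one camera and species.
photo_stream <- function(minutes, counts = 1L, camera = "c1", species = "sp1") {
  tibble::tibble(
    camera_id = camera,
    timestamp = t_origin + minutes * 60,
    species_label = species,
    n_individuals = as.integer(rep_len(counts, length(minutes))),
    is_status_photo = FALSE
  )
}

# Brute-force single-linkage clustering oracle: photos are nodes, edges join
# any two photos (same camera and species) less than the threshold apart;
# events are the connected components. Independent of the chain scan used by
# build_events().
oracle_cluster <- function(photos, threshold_minutes) {
  ph <- photos[!photos$is_status_photo, ]
  ph <- unique(ph[c("camera_id", "species_label", "timestamp", "n_individuals")])
  keys <- split(
    seq_len(nrow(ph)),
    paste(ph$camera_id, ph$species_label, sep = "\r")
  )
  out <- lapply(keys, function(idx) {
    t <- as.numeric(ph$timestamp[idx])
    adj <- abs(outer(t, t, "-")) < threshold_minutes * 60
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    data.frame(
      n_photos = as.vector(table(comp)),
      group_size = as.vector(tapply(ph$n_individuals[idx], comp, max))
    )
  })
  do.call(rbind, out)
}

# Tiny two-species community for fast end-to-end runs.
mini_community <- function(multiplier = 2) {
  dplyr::bind_rows(
    species_spec("big sp", 50, "EN", "ungulates", 0.15, 1.5, multiplier),
    species_spec("small sp", 2, "LC", "rodents", 0.25, 1.0, 1)
  )
}

mini_design <- function(seed, ...) {
  sim_design(
    n_pairs = 3, cameras_per_concession = c(5, 5), deployment_days = 30,
    downtime_prob = 0, seed = seed, ...
  )
}

# Effort table carrying deployment structure, from an event-level simulation.
sim_effort <- function(sim) {
  dplyr::inner_join(
    sim$effort,
    dplyr::select(sim$deployments, "camera_id", "concession_id", "pair_id", "certified"),
    by = "camera_id"
  )
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# Independent signed-rank oracle: full enumeration of every sign assignment.
brute_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  list(w = w_obs, p = min(1, 2 * min(p_le, p_ge)))
}
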