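
# Default classes excluded from all analyses: non-mammal or non-wild records
# occasionally annotated in camera-trap projects.
default_excluded_classes <- c(
  "human", "humans", "bird", "birds", "bat", "bats",
  "reptile", "reptiles", "domestic dog", "dog"
)

#' Load and validate photo-level camera-trap records
#'
#' Reads a photo annotation table (CSV path or data frame), applies the
#' standard labelling rules — excluded classes dropped, `"indet"`
#' (unidentifiable) records dropped, optional alias mapping of raw labels to
#' analysis labels such as the small-mammal groups `"squirrels"`,
#' `"rats and mice"` and `"shrews"` — and checks every retained species
#' label against the trait table.
#'
#' Required columns: `camera_id`, `timestamp`, `species_label`,
#' `n_individuals`, `is_status_photo`. Status photos are retained (they
#' carry effort information) but never count as animal records.
#'
#' @param photos CSV path or data frame of photo records.
#' @param traits Trait table with one row per retained `species_label`
#'   (see [load_traits()]).
#' @param aliases Optional alias table (CSV path or data frame) with columns
#'   `from`, `to`, applied to `species_label` before any other rule.
#' @param excluded_classes Labels dropped as non-target classes.
#' @param keep_indet Keep `"indet"` records? Defaults to `FALSE`: records
#'   that cannot be identified cannot be assigned a body mass, IUCN category
#'   or taxon, so they are excluded from every encounter-rate computation,
#'   including the all-mammal pooled rate. Set `TRUE` to retain them (they
#'   then enter pooled rates only).
#' @param strict If `TRUE` (default), a retained species label with no trait
#'   row is an error listing the offenders; if `FALSE`, such rows are
#'   dropped with a warning.
#'
#' @return A tibble of validated photo records with a `disposition`
#'   attribute: a named count of rows retained / excluded_class / indet /
#'   unknown_label / status.
#' @export
load_photos <- function(photos, traits, aliases = NULL,
                        excluded_classes = default_excluded_classes,
                        keep_indet = FALSE, strict = TRUE) {
  if (is.character(photos)) photos <- readr::read_csv(photos, show_col_types = FALSE)
  photos <- tibble::as_tibble(photos)
  assert_columns(photos, c(
    "camera_id", "timestamp", "species_label", "n_individuals", "is_status_photo"
  ), "photo table")
  if (nrow(photos) == 0L) {
    warn("photo table is empty")
    out <- photos
    attr(out, "disposition") <- c(
      retained = 0L, excluded_class = 0L, indet = 0L, unknown_label = 0L, status = 0L
    )
    return(out)
  }
  photos$timestamp <- as_posixct_utc(photos$timestamp)
  photos$is_status_photo <- as.logical(photos$is_status_photo)

  if (!is.null(aliases)) {
    if (is.character(aliases)) aliases <- readr::read_csv(aliases, show_col_types = FALSE)
    assert_columns(aliases, c("from", "to"), "alias table")
    m <- match(photos$species_label, aliases$from)
    photos$species_label[!is.na(m)] <- aliases$to[m[!is.na(m)]]
  }

  status <- photos$is_status_photo %in% TRUE
  lab <- tolower(trimws(photos$species_label))
  excl <- !status & lab %in% tolower(excluded_classes)
  indet <- !status & !excl & lab %in% "indet"
  known <- photos$species_label %in% traits$species_label
  unknown <- !status & !excl & !indet & !known

  if (any(unknown)) {
    offenders <- sort(unique(photos$species_label[unknown]))
    if (strict) {
      abort(paste0(
        "species label(s) with no trait row: ", paste(offenders, collapse = ", ")
      ))
    }
    warn(paste0(
      "dropping ", sum(unknown), " row(s) with unknown species label(s): ",
      paste(offenders, collapse = ", ")
    ))
  }

  keep <- status | (!excl & !unknown & (!indet | keep_indet))
  animal_kept <- keep & !status
  bad_counts <- animal_kept & (is.na(photos$n_individuals) | photos$n_individuals < 1)
  if (any(bad_counts)) {
    abort(sprintf("%d animal photo(s) have n_individuals < 1", sum(bad_counts)))
  }

  out <- photos[keep, , drop = FALSE]
  disposition <- c(
    retained = sum(animal_kept),
    excluded_class = sum(excl),
    indet = if (keep_indet) 0L else sum(indet),
    unknown_label = sum(unknown),
    status = sum(status)
  )
  attr(out, "disposition") <- disposition
  inform(sprintf(
    "photos: %d animal rows retained, %d excluded-class, %d indet, %d unknown, %d status",
    disposition[["retained"]], disposition[["excluded_class"]],
    disposition[["indet"]], disposition[["unknown_label"]], disposition[["status"]]
  ))
  out
}

#' Load and validate deployment metadata
#'
#' @param deployments CSV path or data frame with columns `camera_id`,
#'   `concession_id`, `pair_id`, `certified`, `start`, `end`,
#'   `downtime_days`, plus any site covariates (`visibility`, `slope`,
#'   `fruiting_tree_30m`, `water_50m`, `trail_type`, `hunting_signs`,
#'   geographic covariates).
#' @return A validated tibble.
#' @export
load_deployments <- function(deployments) {
  if (is.character(deployments)) deployments <- readr::read_csv(deployments, show_col_types = FALSE)
  deployments <- tibble::as_tibble(deployments)
  assert_columns(deployments, c(
    "camera_id", "concession_id", "pair_id", "certified",
    "start", "end", "downtime_days"
  ), "deployment table")
  deployments$start <- as_posixct_utc(deployments$start, "start")
  deployments$end <- as_posixct_utc(deployments$end, "end")
  deployments$certified <- as.logical(deployments$certified)
  if (anyDuplicated(deployments$camera_id)) {
    abort("duplicate camera_id in deployment table")
  }
  span <- days_between(deployments$start, deployments$end)
  if (any(span <= 0)) {
    zero <- deployments$camera_id[span <= 0]
    abort(paste0("deployment end must be after start for: ", paste(zero, collapse = ", ")))
  }
  if (any(deployments$downtime_days < 0 | deployments$downtime_days > span)) {
    abort("downtime_days must lie in [0, deployment span] for every camera")
  }
  deployments
}

#' Load the species-trait table and derive body-mass classes
#'
#' @param traits CSV path or data frame with columns `species_label`,
#'   `mean_body_mass` (kg, mean across sexes), `iucn`, `taxon`.
#' @param mass_edges Class edges passed to [assign_body_mass_class()].
#' @return A tibble with an added `body_mass_class` factor.
#' @export
load_traits <- function(traits, mass_edges = c(1, 10, 30, 100)) {
  if (is.character(traits)) traits <- readr::read_csv(traits, show_col_types = FALSE)
  traits <- tibble::as_tibble(traits)
  assert_columns(traits, c("species_label", "mean_body_mass", "iucn", "taxon"), "trait table")
  if (anyDuplicated(traits$species_label)) {
    abort("trait table must have exactly one row per species_label")
  }
  traits$body_mass_class <- assign_body_mass_class(traits$mean_body_mass, mass_edges)
  traits
}

#' Assign body-mass classes
#'
#' Bins species mean body mass into classes with the half-open convention
#' `(lower, upper]`: the default edges `c(1, 10, 30, 100)` give five classes
#' `(0,1]`, `(1,10]`, `(10,30]`, `(30,100]` and `(100, Inf)` kg, so a 30 kg
#' species belongs to the 10-30 kg class and anything above 100 kg to the
#' top class. The three upper classes match the conventional >100, 30-100
#' and 10-30 kg groupings; the two lower edges are configurable.
#'
#' @param mass_kg Numeric vector of masses (> 0).
#' @param edges Strictly increasing positive class edges.
#' @return A factor with one level per class, ordered light to heavy.
#' @export
#' @examples
#' assign_body_mass_class(c(0.05, 4.5, 30, 62, 2800))
assign_body_mass_class <- function(mass_kg, edges = c(1, 10, 30, 100)) {
  if (any(!is.finite(mass_kg) | mass_kg <= 0)) abort("body mass must be positive")
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0)) {
    abort("`edges` must be strictly increasing and positive")
  }
  labels <- body_mass_class_labels(edges)
  cut(mass_kg, breaks = c(0, edges, Inf), labels = labels, right = TRUE)
}

body_mass_class_labels <- function(edges = c(1, 10, 30, 100)) {
  lower <- c(0, edges)
  upper <- c(edges, Inf)
  ifelse(
    is.infinite(upper),
    paste0(">", lower, " kg"),
    paste0(lower, "-", upper, " kg")
  )
}
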