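#' Realized parasitism in one cell on one day
#'
#' The resident parasitoid females' combined expected attack for the day
#' (`capacity`, a sum of [eggs_on_day()] terms with the parasitoid's lifetime
#' total `theta`) is realized as a Poisson count, then capped by the
#' unparasitized host eggs actually present.  Capacity unused on a day is
#' forfeited; parasitized eggs never return to the attackable pool
#' (no superparasitism).
#'
#' @param available Unparasitized host eggs in the cell (`>= 0`).
#' @param capacity Expected eggs attacked today (`>= 0`).
#' @return Integer number of eggs parasitized, `<= available`.
#' @export
parasitize_cell <- function(available, capacity) {
  stopifnot(available >= 0, capacity >= 0)
  min(stats::rpois(1L, capacity), as.integer(available))
}

#' Adult parasitoids emerging from a parasitized-egg batch
#'
#' When a batch of parasitized host eggs completes the parasitoid's thermal
#' constant, each egg yields a fixed number of adult wasps; sex is assigned
#' binomially at the batch level and each adult receives an independent
#' Normal life span.
#'
#' @param n_eggs Eggs in the completed batch.
#' @param offspring_per_egg Adult wasps per parasitized egg.
#' @param sex_ratio Proportion of females among emerging adults.
#' @param longevity_mean,longevity_sd Adult life-span Normal parameters, days.
#' @return List with `count` (adults), `females`, and integer `longevity`
#'   per adult (females listed first).
#' @export
emerge_parasitoids <- function(n_eggs, offspring_per_egg, sex_ratio,
                               longevity_mean, longevity_sd) {
  stopifnot(n_eggs >= 0, offspring_per_egg >= 0,
            sex_ratio >= 0, sex_ratio <= 1)
  adults <- as.integer(n_eggs * offspring_per_egg)
  if (adults == 0L) {
    return(list(count = 0L, females = 0L, longevity = integer(0)))
  }
  females <- stats::rbinom(1L, adults, sex_ratio)
  list(count = adults,
       females = females,
       longevity = sample_longevity(adults, longevity_mean, longevity_sd))
}

#' Release-trigger latch
#'
#' Parasitoid releases start the first day the adult pest population (both
#' sexes) reaches the threshold `tau`; once triggered, the latch stays set and
#' the remaining releases follow at fixed intervals regardless of later
#' counts.
#'
#' @param adult_count Current adult pest count.
#' @param tau Trigger threshold (`>= 1`).
#' @param triggered Current latch state.
#' @return Updated latch state (logical).
#' @export
check_trigger <- function(adult_count, tau, triggered) {
  stopifnot(tau >= 1)
  isTRUE(triggered) || adult_count >= tau
}

#' Assign released parasitoids to cells of the release area
#'
#' The number released equals the per-hectare release density times the area
#' (in hectares) of the recorded release region, rounded; individuals are
#' spread over the region's cells by an equal-weight multinomial draw.
#'
#' @param area_cells 1-based indices of the release-area cells (non-empty).
#' @param density_per_ha Parasitoids per hectare for this release.
#' @param cell_size Cell side length, metres.
#' @return Integer vector with one cell index per released individual
#'   (expanded in area-cell order); length 0 when the rounded total is 0.
#' @export
apply_release <- function(area_cells, density_per_ha, cell_size = 1) {
  if (length(area_cells) == 0L) {
    stop("release area is empty: no host eggs were ever laid (degenerate run)")
  }
  stopifnot(density_per_ha >= 0, cell_size > 0)
  area_ha <- length(area_cells) * cell_size^2 / 1e4
  total <- as.integer(round(density_per_ha * area_ha))
  if (total == 0L) return(integer(0))
  counts <- stats::rmultinom(1L, total, rep(1, length(area_cells)))[, 1L]
  rep(area_cells, counts)
}

# Scheduled release days: trigger day, then weekly (or `interval`) steps.
schedule_releases <- function(trigger_day, n_releases, interval) {
  if (n_releases == 0L) return(integer(0))
  trigger_day + interval * (seq_len(n_releases) - 1L)
}
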