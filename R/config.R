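# Scenario configuration: defaults, merging, validation, fixtures.

default_config <- function() {
  list(
    grid = list(
      side_length = 1000L,   # cells; 1000 x 1000 m = 100 ha
      cell_size   = 1        # metres per cell side
    ),
    temperature = 30,        # constant mean temperature, deg C
    horizon     = 150L,      # days simulated
    replicates  = 20L,
    pest = list(
      # Sugarcane borer Diatraea saccharalis; thermal stages in cycle order.
      stages = list(
        egg   = list(K = 67.47,  T_T = 11.2),
        larva = list(K = 516.96, T_T = 7.3),
        pupa  = list(K = 126.08, T_T = 10.6)
      ),
      longevity_mean     = 8.60,
      longevity_sd       = 0.95,
      fecundity          = 84,      # see fecundity_mode
      fecundity_mode     = "net",   # "net": 84 daughters/female, lifetime eggs
                                    #   = 84 / sex_ratio; "total": 84 raw eggs
      rhythm             = 0.33,    # oviposition-rhythm decay, per day
      preoviposition     = 2.16,    # days (rounded up to whole days in use)
      sex_ratio          = 0.46,
      max_daily_distance = 50,      # metres
      dispersal_beta     = 0.2,     # per metre
      infestation_prob   = 0.01,    # daily background-arrival probability
      egg_draw           = "poisson",  # or "round" (deterministic)
      founders           = 4L
    ),
    parasitoid = list(
      # Egg parasitoid Trichogramma galloi; immature develops inside the egg.
      stages = list(
        immature = list(K = 130.98, T_T = 13.6)
      ),
      longevity_mean     = 8.9,
      longevity_sd       = 0.7,
      theta              = 57,      # lifetime parasitized eggs per female
      rhythm             = NULL,    # NULL: inherit the pest's rhythm
      preoviposition     = 0,
      offspring_per_egg  = 2L,
      sex_ratio          = 0.89,
      action_radius      = 10,      # metres
      dispersal_beta     = 0.2,     # fallback undirected kernel
      max_daily_distance = 10       # fallback cap = action radius
    ),
    release = list(
      tau            = 5L,          # adult-pest trigger threshold
      n_releases     = 3L,
      density_per_ha = 50000,
      interval_days  = 7L,
      area_rule      = "first-egg-region",  # or "central-square"
      square_side_m  = 30,
      all_female     = TRUE
    )
  )
}

# Recursive override merge; unknown keys are errors (typo safety).
merge_config <- function(base, overrides, path = "") {
  if (length(overrides) == 0L) return(base)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    stop("config overrides must be named (at '", path, "')")
  }
  for (nm in nms) {
    here <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base)) {
      stop("unknown config key: '", here, "'")
    }
    if (is.list(base[[nm]]) && !is.null(base[[nm]]) && is.list(overrides[[nm]]) &&
        nm != "stages") {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]], here)
    } else {
      base[nm] <- overrides[nm]   # [ ] keeps explicit NULLs
    }
  }
  base
}

chk <- function(cond, field, msg) {
  # `cond` is a lazy promise: malformed values (wrong length/type) that make
  # the check itself error are reported as validation failures too
  ok <- tryCatch(isTRUE(cond), error = function(e) FALSE)
  if (!ok) stop("invalid config: '", field, "' ", msg, call. = FALSE)
}

#' Validate a scenario configuration
#'
#' Checks every field against its admissible range and returns the
#' configuration with class `scenario_config`.  Error messages name the
#' offending field path.
#'
#' @param cfg A configuration list (see [scenario_config()]).
#' @return The validated configuration, classed `scenario_config`.
#' @export
validate_config <- function(cfg) {
  g <- cfg$grid
  chk(is.numeric(g$side_length) && g$side_length >= 3 &&
        g$side_length == floor(g$side_length), "grid$side_length",
      "must be an integer >= 3")
  chk(is.numeric(g$cell_size) && g$cell_size > 0, "grid$cell_size",
      "must be > 0")
  chk(is.numeric(cfg$temperature) && is.finite(cfg$temperature),
      "temperature", "must be finite")
  chk(is.numeric(cfg$horizon) && cfg$horizon >= 1, "horizon", "must be >= 1")
  chk(is.numeric(cfg$replicates) && cfg$replicates >= 1, "replicates",
      "must be >= 1")

  p <- cfg$pest
  for (snm in names(p$stages)) {
    st <- p$stages[[snm]]
    chk(is.numeric(st$K) && st$K > 0, paste0("pest$stages$", snm, "$K"),
        "must be > 0")
    chk(is.numeric(st$T_T) && st$T_T >= 0, paste0("pest$stages$", snm, "$T_T"),
        "must be >= 0")
  }
  chk(identical(names(p$stages), c("egg", "larva", "pupa")), "pest$stages",
      "must be the ordered stages egg, larva, pupa")
  chk(p$longevity_mean > 0, "pest$longevity_mean", "must be > 0")
  chk(p$longevity_sd >= 0, "pest$longevity_sd", "must be >= 0")
  chk(p$fecundity >= 0, "pest$fecundity", "must be >= 0")
  chk(p$fecundity_mode %in% c("net", "total"), "pest$fecundity_mode",
      "must be 'net' or 'total'")
  chk(p$rhythm > 0, "pest$rhythm", "must be > 0")
  chk(p$preoviposition >= 0, "pest$preoviposition", "must be >= 0")
  chk(p$sex_ratio >= 0 && p$sex_ratio <= 1, "pest$sex_ratio",
      "must be in [0, 1]")
  chk(p$sex_ratio > 0 || p$fecundity_mode == "total", "pest$sex_ratio",
      "must be > 0 when fecundity_mode is 'net'")
  chk(p$max_daily_distance >= 0, "pest$max_daily_distance", "must be >= 0")
  chk(p$dispersal_beta > 0, "pest$dispersal_beta", "must be > 0")
  chk(p$infestation_prob >= 0 && p$infestation_prob <= 1,
      "pest$infestation_prob", "must be in [0, 1]")
  chk(p$egg_draw %in% c("poisson", "round"), "pest$egg_draw",
      "must be 'poisson' or 'round'")
  chk(p$founders >= 0, "pest$founders", "must be >= 0")

  q <- cfg$parasitoid
  chk(identical(names(q$stages), "immature"), "parasitoid$stages",
      "must hold the single stage 'immature'")
  chk(q$stages$immature$K > 0, "parasitoid$stages$immature$K", "must be > 0")
  chk(q$stages$immature$T_T >= 0, "parasitoid$stages$immature$T_T",
      "must be >= 0")
  chk(q$longevity_mean > 0, "parasitoid$longevity_mean", "must be > 0")
  chk(q$longevity_sd >= 0, "parasitoid$longevity_sd", "must be >= 0")
  chk(q$theta >= 0, "parasitoid$theta", "must be >= 0")
  chk(is.null(q$rhythm) || q$rhythm > 0, "parasitoid$rhythm",
      "must be > 0 (or NULL to inherit the pest rhythm)")
  chk(q$preoviposition >= 0, "parasitoid$preoviposition", "must be >= 0")
  chk(q$offspring_per_egg >= 0, "parasitoid$offspring_per_egg",
      "must be >= 0")
  chk(q$sex_ratio >= 0 && q$sex_ratio <= 1, "parasitoid$sex_ratio",
      "must be in [0, 1]")
  chk(q$action_radius >= 0, "parasitoid$action_radius", "must be >= 0")
  chk(q$dispersal_beta > 0, "parasitoid$dispersal_beta", "must be > 0")
  chk(q$max_daily_distance >= 0, "parasitoid$max_daily_distance",
      "must be >= 0")

  r <- cfg$release
  chk(r$tau >= 1, "release$tau", "must be >= 1")
  chk(r$n_releases >= 0, "release$n_releases", "must be >= 0")
  chk(r$density_per_ha >= 0, "release$density_per_ha", "must be >= 0")
  chk(r$interval_days >= 1, "release$interval_days", "must be >= 1")
  chk(r$area_rule %in% c("first-egg-region", "central-square"),
      "release$area_rule", "must be 'first-egg-region' or 'central-square'")
  chk(r$square_side_m >= 1, "release$square_side_m", "must be >= 1")
  chk(is.logical(r$all_female), "release$all_female", "must be TRUE/FALSE")

  # normalize integer-valued fields
  cfg$grid$side_length <- as.integer(cfg$grid$side_length)
  cfg$horizon <- as.integer(cfg$horizon)
  cfg$replicates <- as.integer(cfg$replicates)
  cfg$pest$founders <- as.integer(cfg$pest$founders)
  cfg$release$tau <- as.integer(cfg$release$tau)
  cfg$release$n_releases <- as.integer(cfg$release$n_releases)
  cfg$release$interval_days <- as.integer(cfg$release$interval_days)
  cfg$parasitoid$offspring_per_egg <- as.integer(cfg$parasitoid$offspring_per_egg)
  class(cfg) <- "scenario_config"
  cfg
}

#' Build a scenario configuration
#'
#' Returns the default configuration (the reference field setup: 1000 x 1000
#' one-metre cells = 100 ha, 30 degrees C, 150 days, 20 replicates, three
#' weekly releases of 50,000 parasitoids per hectare) with any named
#' overrides applied.  Overrides may be nested lists mirroring the default
#' structure; unknown keys are rejected.
#'
#' @param ... Named overrides, e.g. `grid = list(side_length = 200)`,
#'   `release = list(n_releases = 5)`.
#' @return A validated `scenario_config`.
#' @examples
#' cfg <- scenario_config(horizon = 60, replicates = 2)
#' cfg$release$density_per_ha
#' @export
scenario_config <- function(...) {
  validate_config(merge_config(default_config(), list(...)))
}

#' Read a scenario configuration from a YAML file
#'
#' The file holds overrides of the default configuration (an empty file
#' yields the full default setup); unknown keys and out-of-range values are
#' errors naming the field.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `scenario_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  if (!is.list(overrides)) stop("config file must hold a YAML mapping")
  validate_config(merge_config(default_config(), overrides))
}

#' Bundled scenario fixtures
#'
#' Three tiers of the same model: `"smoke"` (10 x 10 cells, 20 days, one
#' replicate) for instant checks, `"desk"` (200 x 200 cells = 4 ha, 150
#' days, 10 replicates) for scaled-down scenario comparisons, and `"field"`
#' (the full 1000 x 1000 = 100 ha, 150 days, 20 replicates) for the
#' reference setting.
#'
#' @param name Fixture name.
#' @return A validated `scenario_config`.
#' @export
scenario_fixture <- function(name = c("smoke", "desk", "field")) {
  name <- match.arg(name)
  switch(name,
    smoke = scenario_config(grid = list(side_length = 10L),
                            horizon = 20L, replicates = 1L),
    desk  = scenario_config(grid = list(side_length = 200L),
                            horizon = 150L, replicates = 10L),
    field = scenario_config()
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  area_ha <- (x$grid$side_length * x$grid$cell_size)^2 / 1e4
  cat("<scenario_config>\n",
      sprintf("  grid: %d x %d cells (%.4g ha), %g C, %d days, %d replicates\n",
              x$grid$side_length, x$grid$side_length, area_ha,
              x$temperature, x$horizon, x$replicates),
      sprintf("  release: %d x %s per ha, every %d d, trigger tau = %d (%s)\n",
              x$release$n_releases,
              format(x$release$density_per_ha, big.mark = ","),
              x$release$interval_days, x$release$tau, x$release$area_rule),
      sep = "")
  invisible(x)
}
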