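# Daily-step simulation engine.
#
# State layout (environment `e`):
#  * adult insects are stored per individual in parallel vectors
#    (pest: px/py/p_emerge/p_death/p_female; parasitoid: qx/qy/q_*),
#    always appended in creation order and filtered (order-preserving) at
#    death -- this creation order is the canonical "id order" of the
#    random-draw protocol below;
#  * host eggs are cohorts in a rotating ncells x egg_dur count matrix
#    (one column per age class) plus a per-cell total cache `egg_tot` used
#    for parasitoid search weights;
#  * larvae, pupae and parasitized-egg batches neither move nor interact,
#    so they live in day-indexed molt/emergence schedules plus running
#    totals.
#
# Random-draw protocol (shared with the per-individual reference
# implementation used in the test suite; one day consumes, in order):
#   1a pest adult emergence, groups sorted by cell: rbinom female counts
#      (one per group, vectorized), then one Normal life span per adult in
#      group order, females first within each group;
#   1b parasitoid emergence from completed batches: same pattern;
#   3a pest movement: runif(n) distances (id order), then runif(n) angles
#      (nothing is consumed when the species' daily distance cap is 0);
#   3b parasitoid movement: one uniform per host-directed parasitoid (id
#      order), inverse-CDF over in-disk egg weights in ascending cell order;
#      then runif(m) distances + runif(m) angles for the undirected ones
#      (id order);
#   4  parasitism: cells holding attack capacity and >= 1 egg, ascending:
#      rpois(ncell, capacity) vectorized, then per cell (ascending) the
#      parasitized eggs are allocated over age classes oldest-first by
#      sequential hypergeometric draws;
#   5  oviposition: cells holding >= 1 laying female, ascending: one
#      Poisson egg count per cell (vectorized) -- a sum of independent
#      Poisson female contributions is Poisson in the summed mean;
#   6  immigration: one uniform (skipped when phi = 0), then landing cell,
#      then the arriving female's life span;
#   7  release (on release days): equal-weight multinomial over area cells,
#      then one life span per released individual (area-cell order);
#      released wasps act from the following day.

MAX_OVI_AGE <- 400L

new_sim_state <- function(cfg) {
  e <- new.env(parent = emptyenv())
  e$cfg <- cfg
  side <- cfg$grid$side_length
  e$side <- side
  e$ncells <- side * side
  Tc <- cfg$temperature
  p <- cfg$pest
  q <- cfg$parasitoid

  e$egg_dur   <- stage_duration_or_inf(p$stages$egg$K,   p$stages$egg$T_T,   Tc)
  e$larva_dur <- stage_duration_or_inf(p$stages$larva$K, p$stages$larva$T_T, Tc)
  e$pupa_dur  <- stage_duration_or_inf(p$stages$pupa$K,  p$stages$pupa$T_T,  Tc)
  e$imm_dur   <- stage_duration_or_inf(q$stages$immature$K,
                                       q$stages$immature$T_T, Tc)

  e$preovip_pest <- as.integer(ceiling(p$preoviposition))
  e$preovip_para <- as.integer(ceiling(q$preoviposition))
  lambda <- if (p$fecundity_mode == "net") p$fecundity / p$sex_ratio
            else p$fecundity
  rhythm_q <- if (is.null(q$rhythm)) p$rhythm else q$rhythm
  e$ovi_pest <- eggs_on_day(0:MAX_OVI_AGE, lambda, p$rhythm)
  e$ovi_para <- eggs_on_day(0:MAX_OVI_AGE, q$theta, rhythm_q)

  e$offs <- disk_offsets(q$action_radius)

  # adults of both species: growable individual buffers, first *_n slots
  # live; dense per-cell capacity buffers are refilled by the daily passes
  cap0 <- 1024L
  e$px <- integer(cap0); e$py <- integer(cap0)
  e$p_emerge <- integer(cap0); e$p_death <- integer(cap0)
  e$p_female <- logical(cap0)
  e$p_n <- 0L
  e$cap_buf <- numeric(e$ncells)    # pest oviposition capacity
  e$qx <- integer(cap0); e$qy <- integer(cap0)
  e$q_emerge <- integer(cap0); e$q_death <- integer(cap0)
  e$q_female <- logical(cap0)
  e$q_n <- 0L
  e$qcap_buf <- numeric(e$ncells)   # parasitoid attack capacity

  # host eggs: rotating age-class matrix + per-cell total cache
  ncol_eggs <- if (is.finite(e$egg_dur)) as.integer(e$egg_dur) else 1L
  e$egg_cols <- ncol_eggs
  e$egg_mat <- matrix(0L, nrow = e$ncells, ncol = ncol_eggs)
  e$egg_head <- 1L                       # column currently holding age 0
  e$egg_tot <- integer(e$ncells)
  e$eggs_total <- 0        # running totals kept as doubles (overflow safety)

  # molt / emergence schedules (day-indexed lists)
  slack <- sum(c(e$larva_dur, e$pupa_dur, e$imm_dur)[
    is.finite(c(e$larva_dur, e$pupa_dur, e$imm_dur))]) + 3L
  nsched <- cfg$horizon + as.integer(slack) + 2L
  e$sched_pupate <- vector("list", nsched)   # larva -> pupa
  e$sched_emerge <- vector("list", nsched)   # pupa -> pest adult
  e$sched_para   <- vector("list", nsched)   # batch -> parasitoid adults
  e$nsched <- nsched
  e$larvae_total <- 0
  e$pupae_total <- 0
  e$para_imm_total <- 0

  # release machinery
  e$triggered <- FALSE
  e$trigger_day <- NA_integer_
  e$release_day_set <- integer(0)
  e$released_days <- integer(0)
  e$released_counts <- integer(0)
  e$first_egg_seen <- FALSE
  cx <- side %/% 2L
  if (cfg$release$area_rule == "central-square") {
    s <- min(as.integer(cfg$release$square_side_m), side)
    lo <- max(0L, cx - s %/% 2L)
    hi <- min(side - 1L, lo + s - 1L)
    xs <- lo:hi
    e$area_cells <- sort(as.vector(outer(xs, xs * side, `+`)) + 1L)
  } else {
    e$area_cells <- integer(0)             # recorded at first oviposition
  }

  # bookkeeping
  e$day <- 0L
  ledger_cols <- c("eggs_laid", "eggs_hatched", "eggs_parasitized",
                   "pest_emerged", "pest_adult_deaths", "immigrants",
                   "para_emerged", "para_released", "para_adult_deaths",
                   "boundary_contacts")
  e$ledger <- matrix(0, nrow = cfg$horizon, ncol = length(ledger_cols),
                     dimnames = list(NULL, ledger_cols))
  e$series <- matrix(0, nrow = cfg$horizon + 1L, ncol = 6L,
                     dimnames = list(NULL, STAGE_COLS))
  e$audit <- TRUE

  # founders: mated adult females at the central cell, day 0
  nf <- cfg$pest$founders
  if (nf > 0L) {
    L <- sample_longevity(nf, p$longevity_mean, p$longevity_sd)
    pest_append(e, rep(cx, nf), rep(cx, nf), rep(0L, nf), 0L + L,
                rep(TRUE, nf))
  }
  e$series[1L, ] <- c(0L, 0L, 0L, nf, 0L, 0L)
  e
}

# Grow a species' buffers to hold `extra` more adults (amortized doubling;
# buffers are engine-private so no aliases exist).  `pre` is "p" or "q".
adult_ensure <- function(e, pre, extra) {
  nfield <- paste0(pre, "_n")
  xfield <- paste0(pre, "x")
  need <- e[[nfield]] + extra
  if (need > length(e[[xfield]])) {
    newcap <- max(need, 2L * length(e[[xfield]]))
    for (f in paste0(pre, c("x", "y", "_emerge", "_death", "_female"))) {
      v <- e[[f]]
      length(v) <- newcap
      e[[f]] <- v
    }
  }
  invisible(need)
}

# Append adults into the live buffer region (in place).
adult_append <- function(e, pre, x, y, emerge, death, female) {
  k <- length(x)
  if (k == 0L) return(invisible(NULL))
  adult_ensure(e, pre, k)
  nfield <- paste0(pre, "_n")
  start <- e[[nfield]] + 1L
  .buf_fill_int(e[[paste0(pre, "x")]], start, as.integer(x))
  .buf_fill_int(e[[paste0(pre, "y")]], start, as.integer(y))
  .buf_fill_int(e[[paste0(pre, "_emerge")]], start, as.integer(emerge))
  .buf_fill_int(e[[paste0(pre, "_death")]], start, as.integer(death))
  .buf_fill_lgl(e[[paste0(pre, "_female")]], start, female)
  e[[nfield]] <- e[[nfield]] + k
  invisible(NULL)
}

pest_append <- function(e, x, y, emerge, death, female) {
  adult_append(e, "p", x, y, emerge, death, female)
}

STAGE_COLS <- c("pest_egg", "pest_larva", "pest_pupa", "pest_adult",
                "para_immature", "para_adult")

egg_col_of_age <- function(e, age) ((e$egg_head - 1L + age) %% e$egg_cols) + 1L

sched_add <- function(sched, day_index, cells, counts) {
  if (day_index > length(sched)) {
    # event beyond the tracked window; horizon slack makes this unreachable
    return(sched)
  }
  sched[[day_index]] <- c(sched[[day_index]], list(list(cell = cells,
                                                        count = counts)))
  sched
}

sched_pop <- function(sched, day_index) {
  if (day_index > length(sched) || is.null(sched[[day_index]])) return(NULL)
  entries <- sched[[day_index]]
  cells <- unlist(lapply(entries, `[[`, "cell"))
  counts <- unlist(lapply(entries, `[[`, "count"))
  agg <- rowsum(counts, cells)               # sorted ascending by cell
  list(cell = as.integer(rownames(agg)), count = as.integer(agg[, 1L]))
}

# Emergence of a set of adult groups (cells ascending) straight into a
# species' buffers.  Draw order: all female-count binomials (group order),
# then one Normal life span per adult in group order (females first within
# each group); the C++ appender's norm_rand() sequence equals rnorm(total).
emerge_groups <- function(e, pre, cells, counts, sex_ratio,
                          longevity_mean, longevity_sd, day, side) {
  females <- stats::rbinom(length(cells), counts, sex_ratio)
  total <- sum(counts)
  adult_ensure(e, pre, total)
  nfield <- paste0(pre, "_n")
  .append_emergents_cpp(e[[paste0(pre, "x")]], e[[paste0(pre, "y")]],
                        e[[paste0(pre, "_emerge")]],
                        e[[paste0(pre, "_death")]],
                        e[[paste0(pre, "_female")]],
                        e[[nfield]] + 1L, cells, counts, females,
                        day, longevity_mean, longevity_sd, side)
  e[[nfield]] <- e[[nfield]] + total
  total
}

sim_step <- function(e) {
  cfg <- e$cfg
  p <- cfg$pest
  q <- cfg$parasitoid
  r <- cfg$release
  side <- e$side
  day <- e$day + 1L
  led <- numeric(10L)
  names(led) <- colnames(e$ledger)
  emerged_eggs <- 0

  ## (1) development & molting -------------------------------------------
  # 1a pest adults emerge from pupae
  g <- sched_pop(e$sched_emerge, day)
  if (!is.null(g)) {
    total <- emerge_groups(e, "p", g$cell, g$count, p$sex_ratio,
                           p$longevity_mean, p$longevity_sd, day, side)
    e$pupae_total <- e$pupae_total - total
    led["pest_emerged"] <- total
  }
  # 1b parasitoid adults emerge from completed parasitized-egg batches
  g <- sched_pop(e$sched_para, day)
  if (!is.null(g)) {
    emerged_eggs <- sum(as.numeric(g$count))
    adults <- g$count * q$offspring_per_egg
    total <- emerge_groups(e, "q", g$cell, adults, q$sex_ratio,
                           q$longevity_mean, q$longevity_sd, day, side)
    e$para_imm_total <- e$para_imm_total - emerged_eggs
    led["para_emerged"] <- total
  }
  # 1c larvae -> pupae
  g <- sched_pop(e$sched_pupate, day)
  if (!is.null(g)) {
    n <- sum(as.numeric(g$count))
    e$larvae_total <- e$larvae_total - n
    e$pupae_total <- e$pupae_total + n
    if (is.finite(e$pupa_dur)) {
      e$sched_emerge <- sched_add(e$sched_emerge, day + e$pupa_dur,
                                  g$cell, g$count)
    }
  }
  # 1d eggs -> larvae (oldest age class completes its thermal constant)
  if (is.finite(e$egg_dur)) {
    old_col <- egg_col_of_age(e, e$egg_cols - 1L)
    hatch_cells <- which(e$egg_mat[, old_col] > 0L)
    if (length(hatch_cells)) {
      hatch_n <- e$egg_mat[hatch_cells, old_col]
      n <- sum(as.numeric(hatch_n))
      e$egg_mat[hatch_cells, old_col] <- 0L
      e$egg_tot[hatch_cells] <- e$egg_tot[hatch_cells] - hatch_n
      e$eggs_total <- e$eggs_total - n
      e$larvae_total <- e$larvae_total + n
      if (is.finite(e$larva_dur)) {
        e$sched_pupate <- sched_add(e$sched_pupate, day + e$larva_dur,
                                    hatch_cells, hatch_n)
      }
      led["eggs_hatched"] <- n
    }
    e$egg_head <- old_col     # emptied column becomes today's age-0 class
  }

  ## (2)+(3a) pest deaths, movement, per-cell fecundity (one C++ pass) ----
  contacts <- 0L
  pd <- .pest_day_cpp(e$px, e$py, e$p_emerge, e$p_death, e$p_female,
                      e$p_n, day, p$dispersal_beta, p$max_daily_distance,
                      side, e$preovip_pest, e$ovi_pest, e$cap_buf)
  e$p_n <- pd$n
  led["pest_adult_deaths"] <- pd$deaths
  contacts <- contacts + pd$contacts
  ## (2b)+(3b) parasitoid deaths, movement, attack capacity (C++ pass) ----
  qd <- .para_day_cpp(e$qx, e$qy, e$q_emerge, e$q_death, e$q_female,
                      e$q_n, day, e$egg_tot, side, e$offs$dx, e$offs$dy,
                      q$dispersal_beta, q$max_daily_distance,
                      e$preovip_para, e$ovi_para, e$qcap_buf,
                      e$eggs_total > 0)
  e$q_n <- qd$n
  led["para_adult_deaths"] <- qd$deaths
  contacts <- contacts + qd$contacts

  ## (4) parasitism in-cell ------------------------------------------------
  if (e$q_n > 0L && e$eggs_total > 0L) {
    cells <- which(e$qcap_buf > 0)
    has <- e$egg_tot[cells] > 0L
    cells <- cells[has]
    capv <- e$qcap_buf[cells]
    if (length(cells)) {
      k <- stats::rpois(length(cells), capv)
      taken <- pmin(k, e$egg_tot[cells])
      hit <- which(taken > 0L)
      if (length(hit)) {
        age_cols <- egg_col_of_age(e, (e$egg_cols - 1L):0L)  # oldest first
        .remove_eggs_cpp(e$egg_mat, e$egg_tot, cells[hit], taken[hit],
                         age_cols)
        n_par <- sum(as.numeric(taken[hit]))
        e$eggs_total <- e$eggs_total - n_par
        e$para_imm_total <- e$para_imm_total + n_par
        if (is.finite(e$imm_dur)) {
          e$sched_para <- sched_add(e$sched_para, day + e$imm_dur,
                                    cells[hit], taken[hit])
        }
        led["eggs_parasitized"] <- n_par
      }
    }
  }

  ## (5) pest oviposition in-cell -----------------------------------------
  # capacities were accumulated per cell during the pest pass (post-move
  # positions); eggs laid today become attackable the following day
  cells <- which(e$cap_buf > 0)
  if (length(cells)) {
    eggs <- if (p$egg_draw == "poisson") {
      stats::rpois(length(cells), e$cap_buf[cells])
    } else {
      as.integer(round(e$cap_buf[cells]))
    }
    pos <- which(eggs > 0L)
    if (length(pos)) {
      cc <- cells[pos]
      h <- e$egg_head
      e$egg_mat[cc, h] <- e$egg_mat[cc, h] + eggs[pos]
      e$egg_tot[cc] <- e$egg_tot[cc] + eggs[pos]
      laid <- sum(as.numeric(eggs[pos]))
      e$eggs_total <- e$eggs_total + laid
      led["eggs_laid"] <- laid
    }
    if (!e$first_egg_seen && e$eggs_total > 0L) {
      record_first_egg_area(e)
    }
  }

  ## (6) background infestation -------------------------------------------
  if (p$infestation_prob > 0) {
    cell <- sample_immigration(e$ncells, p$infestation_prob)
    if (cell > 0L) {
      L <- sample_longevity(1L, p$longevity_mean, p$longevity_sd)
      pest_append(e, (cell - 1L) %% side, (cell - 1L) %/% side,
                  day, day + L, TRUE)
      led["immigrants"] <- 1L
    }
  }

  ## (7) trigger check / release ------------------------------------------
  # the trigger arms only once the pest is reported in the field (first
  # eggs observed): before that, no release area exists to be targeted
  if (!e$triggered && e$first_egg_seen && check_trigger(e$p_n, r$tau, FALSE)) {
    e$triggered <- TRUE
    e$trigger_day <- day
    e$release_day_set <- schedule_releases(day, r$n_releases, r$interval_days)
  }
  if (e$triggered && day %in% e$release_day_set) {
    rel_cells <- apply_release(e$area_cells, r$density_per_ha,
                               cfg$grid$cell_size)
    nrel <- length(rel_cells)
    if (nrel > 0L) {
      L <- sample_longevity(nrel, q$longevity_mean, q$longevity_sd)
      fem <- if (r$all_female) rep(TRUE, nrel) else {
        f <- stats::rbinom(1L, nrel, q$sex_ratio)
        c(rep(TRUE, f), rep(FALSE, nrel - f))
      }
      # active (searching/attacking, ageing) from the day after release
      adult_append(e, "q", (rel_cells - 1L) %% side,
                   (rel_cells - 1L) %/% side,
                   rep(day + 1L, nrel), day + 1L + L, fem)
    }
    e$released_days <- c(e$released_days, day)
    e$released_counts <- c(e$released_counts, nrel)
    led["para_released"] <- nrel
  }

  ## (8) record ------------------------------------------------------------
  led["boundary_contacts"] <- contacts
  e$ledger[day, ] <- led
  e$series[day + 1L, ] <- c(e$eggs_total, e$larvae_total, e$pupae_total,
                            e$p_n, e$para_imm_total, e$q_n)
  if (e$audit) audit_day(e, day, led, emerged_eggs)
  e$day <- day
  invisible(e)
}

record_first_egg_area <- function(e) {
  if (e$cfg$release$area_rule == "first-egg-region") {
    ec <- which(e$egg_tot > 0L)
    xs <- (ec - 1L) %% e$side
    ys <- (ec - 1L) %/% e$side
    bx <- range(xs)
    by <- range(ys)
    e$area_cells <- sort(as.vector(
      outer(bx[1L]:bx[2L], (by[1L]:by[2L]) * e$side, `+`)) + 1L)
  }
  e$first_egg_seen <- TRUE
  invisible(NULL)
}

# Conservation audit: the day's ledger must explain the day's change in each
# species' total count.
audit_day <- function(e, day, led, emerged_eggs) {
  prev <- e$series[day, ]
  now <- e$series[day + 1L, ]
  d_pest <- sum(now[1:4]) - sum(prev[1:4])
  expect_pest <- led[["eggs_laid"]] + led[["immigrants"]] -
    led[["pest_adult_deaths"]] - led[["eggs_parasitized"]]
  d_para <- sum(now[5:6]) - sum(prev[5:6])
  expect_para <- led[["eggs_parasitized"]] + led[["para_released"]] -
    led[["para_adult_deaths"]] + led[["para_emerged"]] - emerged_eggs
  if (d_pest != expect_pest || d_para != expect_para) {
    stop(sprintf(paste0(
      "conservation audit failed on day %d: pest delta %d (ledger %d), ",
      "parasitoid delta %d (ledger %d)"),
      day, d_pest, expect_pest, d_para, expect_para))
  }
  invisible(NULL)
}

#' Run one simulation replicate
#'
#' Initializes the lattice with the configured founder females at the central
#' cell, then advances the daily state machine over the whole horizon.  Each
#' day applies, in fixed order: immature development and molting (including
#' parasitoid emergence from completed parasitized-egg batches), adult
#' deaths, adult movement (pest undirected, parasitoid host-directed),
#' parasitism, pest oviposition, background infestation, the release
#' trigger/scheduler, and recording.  Identical `(config, seed)` pairs give
#' bit-identical output.
#'
#' @param config A `scenario_config` (see [scenario_config()]).
#' @param seed Integer RNG seed for this replicate.
#' @param audit Run the daily conservation audit (cheap; aborts with
#'   diagnostics on any bookkeeping imbalance)?
#' @return A `sim_result`: list with `series` (a `(horizon+1) x 6` matrix of
#'   daily stage totals, days 0..horizon in rows), `ledger` (daily event
#'   counts), `trigger_day`, `release_days`, `release_counts`, `area_cells`,
#'   `boundary_contacts`, `seed` and `config`.
#' @examples
#' res <- run_sim(scenario_fixture("smoke"), seed = 1)
#' tail(res$series)
#' @export
run_sim <- function(config, seed, audit = TRUE) {
  cfg <- if (inherits(config, "scenario_config")) config
         else validate_config(config)
  set.seed(as.integer(seed))
  e <- new_sim_state(cfg)
  e$audit <- isTRUE(audit)
  # release the compiled passes' reusable scratch afterwards, so replicate
  # sequences do not accumulate the memory high-water marks of large runs
  on.exit({
    .free_para_scratch()
    .free_pest_scratch()
  }, add = TRUE)
  for (d in seq_len(cfg$horizon)) sim_step(e)
  res <- list(
    series = e$series,
    ledger = as.data.frame(e$ledger),
    trigger_day = e$trigger_day,
    release_days = e$released_days,
    release_counts = e$released_counts,
    area_cells = e$area_cells,
    boundary_contacts = sum(e$ledger[, "boundary_contacts"]),
    seed = as.integer(seed),
    config = cfg
  )
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  h <- nrow(x$series) - 1L
  cat(sprintf("<sim_result> %d days, seed %d\n", h, x$seed))
  cat(sprintf("  final: %s larvae, %s adult pests, %s adult parasitoids\n",
              format(x$series[h + 1L, "pest_larva"], big.mark = ","),
              format(x$series[h + 1L, "pest_adult"], big.mark = ","),
              format(x$series[h + 1L, "para_adult"], big.mark = ",")))
  if (!is.na(x$trigger_day)) {
    cat(sprintf("  trigger day %d; releases on %s\n", x$trigger_day,
                paste(x$release_days, collapse = ", ")))
  } else cat("  trigger never reached\n")
  invisible(x)
}

#' Run replicated simulations of one scenario
#'
#' Replicate `i` uses seed `base_seed + i - 1`, so two scenarios run with the
#' same `base_seed` share random streams replicate-by-replicate (common
#' random numbers).
#'
#' @param config A `scenario_config`.
#' @param n Number of replicates (default: `config$replicates`).
#' @param base_seed Base seed; replicate seeds are derived from it.
#' @param label Scenario label carried into summaries.
#' @inheritParams run_sim
#' @return A `scenario_result`: list with `counts` (array `day x stage x
#'   replicate`), `label`, `config`, `seeds`, `trigger_days`,
#'   `release_days` (list), and `boundary_contacts`.
#' @export
run_replicates <- function(config, n = NULL, base_seed = 1L, label = "scenario",
                           audit = TRUE) {
  cfg <- if (inherits(config, "scenario_config")) config
         else validate_config(config)
  if (is.null(n)) n <- cfg$replicates
  stopifnot(n >= 1)
  seeds <- as.integer(base_seed) + seq_len(n) - 1L
  runs <- lapply(seeds, function(s) {
    r <- run_sim(cfg, s, audit = audit)
    gc(verbose = FALSE)   # return large per-replicate allocations promptly
    r
  })
  counts <- array(0, dim = c(cfg$horizon + 1L, 6L, n),
                  dimnames = list(NULL, STAGE_COLS, NULL))
  for (i in seq_len(n)) counts[, , i] <- runs[[i]]$series
  out <- list(
    label = label,
    config = cfg,
    counts = counts,
    seeds = seeds,
    trigger_days = vapply(runs, `[[`, integer(1), "trigger_day"),
    release_days = lapply(runs, `[[`, "release_days"),
    boundary_contacts = vapply(runs, `[[`, numeric(1), "boundary_contacts")
  )
  class(out) <- "scenario_result"
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  h <- dim(x$counts)[1L] - 1L
  n <- dim(x$counts)[3L]
  fin <- mean(x$counts[h + 1L, "pest_larva", ])
  cat(sprintf("<scenario_result> '%s': %d replicates x %d days\n",
              x$label, n, h))
  cat(sprintf("  mean final larvae: %.1f; first release day: %s\n", fin,
              paste(unique(vapply(x$release_days, function(d)
                if (length(d)) d[1L] else NA_integer_, integer(1))),
                collapse = "/")))
  invisible(x)
}

#' Long-format daily series of a run
#'
#' @param x A `sim_result` or `scenario_result`.
#' @return A data frame with columns `day`, `species`, `stage`, `count`,
#'   `replicate`, ordered by (day, species, stage, replicate).
#' @export
series_df <- function(x) {
  stage_map <- data.frame(
    col = STAGE_COLS,
    species = c("pest", "pest", "pest", "pest", "parasitoid", "parasitoid"),
    stage = c("egg", "larva", "pupa", "adult", "immature", "adult"),
    stringsAsFactors = FALSE
  )
  mats <- if (inherits(x, "sim_result")) {
    list(x$series)
  } else if (inherits(x, "scenario_result")) {
    lapply(seq_len(dim(x$counts)[3L]), function(i) x$counts[, , i])
  } else stop("series_df() needs a sim_result or scenario_result")
  rows <- lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    do.call(rbind, lapply(seq_len(nrow(stage_map)), function(k) {
      data.frame(day = 0:(nrow(m) - 1L),
                 species = stage_map$species[k],
                 stage = stage_map$stage[k],
                 count = as.numeric(m[, stage_map$col[k]]),
                 replicate = i,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  df[order(df$day, df$species, df$stage, df$replicate), , drop = FALSE]
}
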