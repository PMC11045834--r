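# Per-individual reference simulator.
#
# Independent re-implementation of the daily state machine that keeps one
# record per insect (every egg, larva, pupa and adult separately) and
# accumulates degree-days day by day, instead of the engine's cohort
# matrices, molt schedules and closed-form stage durations.  It follows the
# same published random-draw protocol, so on identical (config, seed) the
# two implementations must produce identical daily series -- the
# representation-invariance oracle.

individual_sim <- function(cfg, seed) {
  set.seed(as.integer(seed))
  side <- cfg$grid$side_length
  ncells <- side * side
  temp <- cfg$temperature
  p <- cfg$pest
  q <- cfg$parasitoid
  r <- cfg$release

  energy <- function(tt) max(0, temp - tt)
  E_egg <- energy(p$stages$egg$T_T)
  E_lar <- energy(p$stages$larva$T_T)
  E_pup <- energy(p$stages$pupa$T_T)
  E_imm <- energy(q$stages$immature$T_T)
  K_egg <- p$stages$egg$K
  K_lar <- p$stages$larva$K
  K_pup <- p$stages$pupa$K
  K_imm <- q$stages$immature$K

  preov_p <- as.integer(ceiling(p$preoviposition))
  preov_q <- as.integer(ceiling(q$preoviposition))
  lam <- if (p$fecundity_mode == "net") p$fecundity / p$sex_ratio else
    p$fecundity
  eta_p <- p$rhythm
  eta_q <- if (is.null(q$rhythm)) p$rhythm else q$rhythm
  maxa <- 400L
  ovi_p <- lam * (exp(-eta_p * (0:maxa)) - exp(-eta_p * ((0:maxa) + 1)))
  ovi_q <- q$theta * (exp(-eta_q * (0:maxa)) - exp(-eta_q * ((0:maxa) + 1)))

  longev <- function(n, mu, sdv) pmax(1L, as.integer(round(rnorm(n, mu, sdv))))

  # disk offsets in the engine's candidate order (dy, then dx)
  rad <- floor(q$action_radius)
  og <- expand.grid(dx = -rad:rad, dy = -rad:rad)
  og <- og[og$dx^2 + og$dy^2 <= q$action_radius^2, ]
  og <- og[order(og$dy, og$dx), ]

  # individual records -----------------------------------------------------
  # pest immatures: stage 1 egg / 2 larva / 3 pupa
  im_stage <- integer(0); im_cell <- integer(0); im_acc <- numeric(0)
  # parasitoid immatures (inside parasitized eggs)
  pim_cell <- integer(0); pim_acc <- numeric(0)
  # adults (0-based coordinates)
  ax <- integer(0); ay <- integer(0)
  a_emerge <- integer(0); a_death <- integer(0); a_fem <- logical(0)
  bx <- integer(0); by <- integer(0)
  b_emerge <- integer(0); b_death <- integer(0); b_fem <- logical(0)

  cx <- side %/% 2L
  nf <- p$founders
  if (nf > 0L) {
    L <- longev(nf, p$longevity_mean, p$longevity_sd)
    ax <- rep(cx, nf); ay <- rep(cx, nf)
    a_emerge <- rep(0L, nf); a_death <- 0L + L; a_fem <- rep(TRUE, nf)
  }

  triggered <- FALSE
  release_days <- integer(0)
  first_egg_seen <- FALSE
  if (r$area_rule == "central-square") {
    s <- min(as.integer(r$square_side_m), side)
    lo <- max(0L, cx - s %/% 2L)
    hi <- min(side - 1L, lo + s - 1L)
    xs <- lo:hi
    area_cells <- sort(as.vector(outer(xs, xs * side, `+`)) + 1L)
  } else {
    area_cells <- integer(0)
  }

  series <- matrix(0, cfg$horizon + 1L, 6L)
  series[1L, ] <- c(0, 0, 0, nf, 0, 0)

  for (day in seq_len(cfg$horizon)) {
    ## (1) development: every immature gains one day of thermal energy ----
    if (length(im_acc)) im_acc <- im_acc +
        c(E_egg, E_lar, E_pup)[im_stage]
    if (length(pim_acc)) pim_acc <- pim_acc + E_imm

    # molt rule: a stage completes on the day its accumulated energy
    # reaches K - E/2 (nearest-day discretization of K/E)
    # 1a pest pupae that completed K: adult emergence (cells ascending)
    done <- which(im_stage == 3L & im_acc >= K_pup - E_pup / 2)
    if (length(done)) {
      cells <- sort(unique(im_cell[done]))
      counts <- vapply(cells, function(cc) sum(im_cell[done] == cc),
                       integer(1))
      females <- integer(length(cells))
      for (gi in seq_along(cells)) {
        females[gi] <- rbinom(1L, counts[gi], p$sex_ratio)
      }
      L <- longev(sum(counts), p$longevity_mean, p$longevity_sd)
      k <- 0L
      for (gi in seq_along(cells)) {
        ng <- counts[gi]
        fem <- c(rep(TRUE, females[gi]), rep(FALSE, ng - females[gi]))
        ax <- c(ax, rep((cells[gi] - 1L) %% side, ng))
        ay <- c(ay, rep((cells[gi] - 1L) %/% side, ng))
        a_emerge <- c(a_emerge, rep(day, ng))
        a_death <- c(a_death, day + L[k + seq_len(ng)])
        a_fem <- c(a_fem, fem)
        k <- k + ng
      }
      im_stage <- im_stage[-done]; im_cell <- im_cell[-done]
      im_acc <- im_acc[-done]
    }

    # 1b parasitoid immatures that completed K: wasp emergence
    done <- which(pim_acc >= K_imm - E_imm / 2)
    if (length(done)) {
      cells <- sort(unique(pim_cell[done]))
      counts <- vapply(cells, function(cc) sum(pim_cell[done] == cc),
                       integer(1))
      adults <- counts * q$offspring_per_egg
      females <- integer(length(cells))
      for (gi in seq_along(cells)) {
        females[gi] <- rbinom(1L, adults[gi], q$sex_ratio)
      }
      L <- longev(sum(adults), q$longevity_mean, q$longevity_sd)
      k <- 0L
      for (gi in seq_along(cells)) {
        ng <- adults[gi]
        fem <- c(rep(TRUE, females[gi]), rep(FALSE, ng - females[gi]))
        bx <- c(bx, rep((cells[gi] - 1L) %% side, ng))
        by <- c(by, rep((cells[gi] - 1L) %/% side, ng))
        b_emerge <- c(b_emerge, rep(day, ng))
        b_death <- c(b_death, day + L[k + seq_len(ng)])
        b_fem <- c(b_fem, fem)
        k <- k + ng
      }
      pim_cell <- pim_cell[-done]; pim_acc <- pim_acc[-done]
    }

    # 1c larvae -> pupae (energy surplus discarded at the molt)
    done <- which(im_stage == 2L & im_acc >= K_lar - E_lar / 2)
    if (length(done)) {
      im_stage[done] <- 3L
      im_acc[done] <- 0
    }
    # 1d eggs -> larvae
    done <- which(im_stage == 1L & im_acc >= K_egg - E_egg / 2)
    if (length(done)) {
      im_stage[done] <- 2L
      im_acc[done] <- 0
    }

    ## (2) adult deaths ----------------------------------------------------
    keep <- a_death > day
    ax <- ax[keep]; ay <- ay[keep]
    a_emerge <- a_emerge[keep]; a_death <- a_death[keep]
    a_fem <- a_fem[keep]
    keep <- b_death > day
    bx <- bx[keep]; by <- by[keep]
    b_emerge <- b_emerge[keep]; b_death <- b_death[keep]
    b_fem <- b_fem[keep]

    ## (3a) pest movement: all distances (id order), then all angles ------
    n <- length(ax)
    if (n > 0L && p$max_daily_distance > 0) {
      c1 <- 1 - exp(-p$dispersal_beta * p$max_daily_distance)
      d <- -log(1 - runif(n) * c1) / p$dispersal_beta
      for (i in seq_len(n)) {
        a <- runif(1) * 2 * pi
        nx <- ax[i] + round(d[i] * cos(a))
        ny <- ay[i] + round(d[i] * sin(a))
        ax[i] <- min(max(nx, 0L), side - 1L)
        ay[i] <- min(max(ny, 0L), side - 1L)
      }
    }

    ## (3b) parasitoid movement ------------------------------------------
    m <- length(bx)
    if (m > 0L) {
      eggcnt <- tabulate(im_cell[im_stage == 1L], ncells)
      disk <- function(x0, y0) {
        nx <- x0 + og$dx
        ny <- y0 + og$dy
        ok <- nx >= 0L & nx < side & ny >= 0L & ny < side
        w <- numeric(nrow(og))
        w[ok] <- eggcnt[nx[ok] + ny[ok] * side + 1L]
        w
      }
      wlist <- lapply(seq_len(m), function(i) disk(bx[i], by[i]))
      tots <- vapply(wlist, sum, numeric(1))
      directed <- tots > 0
      if (any(directed)) {
        di <- which(directed)
        u <- runif(length(di)) * tots[di]
        for (k in seq_along(di)) {
          i <- di[k]
          j <- which(cumsum(wlist[[i]]) > u[k])[1L]
          bx[i] <- bx[i] + og$dx[j]
          by[i] <- by[i] + og$dy[j]
        }
      }
      if (any(!directed)) {
        ui <- which(!directed)
        if (q$max_daily_distance > 0) {
          c1 <- 1 - exp(-q$dispersal_beta * q$max_daily_distance)
          d <- -log(1 - runif(length(ui)) * c1) / q$dispersal_beta
          for (k in seq_along(ui)) {
            i <- ui[k]
            a <- runif(1) * 2 * pi
            nx <- bx[i] + round(d[k] * cos(a))
            ny <- by[i] + round(d[k] * sin(a))
            bx[i] <- min(max(nx, 0L), side - 1L)
            by[i] <- min(max(ny, 0L), side - 1L)
          }
        }
      }
    }

    ## (4) parasitism ----------------------------------------------------
    if (length(bx) > 0L && any(im_stage == 1L)) {
      alpha <- day - b_emerge - preov_q
      act <- which(b_fem & alpha >= 0L)
      if (length(act)) {
        # id-order, plain double accumulation per cell
        capq <- numeric(ncells)
        for (i in act) {
          cc <- bx[i] + by[i] * side + 1L
          capq[cc] <- capq[cc] + ovi_q[min(alpha[i], maxa) + 1L]
        }
        cells <- which(capq > 0)
        eggs_here <- vapply(cells, function(cc)
          sum(im_stage == 1L & im_cell == cc), integer(1))
        has <- eggs_here > 0L
        cells <- cells[has]
        capv <- capq[cells]
        if (length(cells)) {
          kdraw <- rpois(length(cells), capv)
          taken <- pmin(kdraw, eggs_here[has])
          for (ci in which(taken > 0L)) {
            cc <- cells[ci]
            need <- taken[ci]
            idx <- which(im_stage == 1L & im_cell == cc)
            # age classes oldest first (higher accumulated energy = older)
            accs <- sort(unique(im_acc[idx]), decreasing = TRUE)
            rem <- length(idx)
            kill <- integer(0)
            for (acl in accs) {
              if (need == 0L) break
              class_idx <- idx[im_acc[idx] == acl]
              m_t <- length(class_idx)
              rem <- rem - m_t
              take <- if (rem == 0L) need else rhyper(1L, m_t, rem, need)
              if (take > 0L) {
                kill <- c(kill, class_idx[seq_len(take)])
                need <- need - take
              }
            }
            pim_cell <- c(pim_cell, rep(cc, length(kill)))
            pim_acc <- c(pim_acc, rep(0, length(kill)))
            im_stage <- im_stage[-kill]
            im_cell <- im_cell[-kill]
            im_acc <- im_acc[-kill]
          }
        }
      }
    }

    ## (5) oviposition ------------------------------------------------------
    n <- length(ax)
    if (n > 0L) {
      capd <- numeric(ncells)
      for (i in seq_len(n)) {          # id order, plain double accumulation
        if (a_fem[i]) {
          alpha <- day - a_emerge[i] - preov_p
          if (alpha >= 0L) {
            cc <- ax[i] + ay[i] * side + 1L
            capd[cc] <- capd[cc] + ovi_p[min(alpha, maxa) + 1L]
          }
        }
      }
      cells <- which(capd > 0)
      if (length(cells)) {
        eggs <- if (p$egg_draw == "poisson") rpois(length(cells), capd[cells])
                else as.integer(round(capd[cells]))
        for (ci in which(eggs > 0L)) {
          im_stage <- c(im_stage, rep(1L, eggs[ci]))
          im_cell <- c(im_cell, rep(cells[ci], eggs[ci]))
          im_acc <- c(im_acc, rep(0, eggs[ci]))
        }
        if (!first_egg_seen && any(im_stage == 1L)) {
          ec <- unique(im_cell[im_stage == 1L])
          xs <- range((ec - 1L) %% side)
          ys <- range((ec - 1L) %/% side)
          if (r$area_rule == "first-egg-region") {
            area_cells <- sort(as.vector(
              outer(xs[1L]:xs[2L], (ys[1L]:ys[2L]) * side, `+`)) + 1L)
          }
          first_egg_seen <- TRUE
        }
      }
    }

    ## (6) background infestation ------------------------------------------
    if (p$infestation_prob > 0) {
      if (runif(1) < p$infestation_prob) {
        cc <- sample.int(ncells, 1L)
        L <- longev(1L, p$longevity_mean, p$longevity_sd)
        ax <- c(ax, (cc - 1L) %% side)
        ay <- c(ay, (cc - 1L) %/% side)
        a_emerge <- c(a_emerge, day)
        a_death <- c(a_death, day + L)
        a_fem <- c(a_fem, TRUE)
      }
    }

    ## (7) trigger / releases ----------------------------------------------
    if (!triggered && first_egg_seen && length(ax) >= r$tau) {
      triggered <- TRUE
      release_days <- day + r$interval_days * (seq_len(r$n_releases) - 1L)
    }
    if (triggered && day %in% release_days) {
      if (length(area_cells) == 0L) stop("release area is empty")
      total <- as.integer(round(r$density_per_ha * length(area_cells) *
                                  cfg$grid$cell_size^2 / 1e4))
      if (total > 0L) {
        counts <- rmultinom(1L, total, rep(1, length(area_cells)))[, 1L]
        rel <- rep(area_cells, counts)
        L <- longev(total, q$longevity_mean, q$longevity_sd)
        fem <- if (r$all_female) rep(TRUE, total) else {
          f <- rbinom(1L, total, q$sex_ratio)
          c(rep(TRUE, f), rep(FALSE, total - f))
        }
        bx <- c(bx, (rel - 1L) %% side)
        by <- c(by, (rel - 1L) %/% side)
        b_emerge <- c(b_emerge, rep(day + 1L, total))
        b_death <- c(b_death, day + 1L + L)
        b_fem <- c(b_fem, fem)
      }
    }

    ## (8) record -----------------------------------------------------------
    series[day + 1L, ] <- c(sum(im_stage == 1L), sum(im_stage == 2L),
                            sum(im_stage == 3L), length(ax),
                            length(pim_cell), length(bx))
  }
  colnames(series) <- c("pest_egg", "pest_larva", "pest_pupa", "pest_adult",
                        "para_immature", "para_adult")
  series
}

# tiny configuration used by the representation-equivalence tests
equivalence_config <- function(area_rule = "central-square") {
  scenario_config(
    grid = list(side_length = 12L),
    horizon = 32L,
    replicates = 1L,
    pest = list(fecundity = 6, fecundity_mode = "total",
                max_daily_distance = 4, infestation_prob = 0.15,
                founders = 2L),
    parasitoid = list(action_radius = 3, max_daily_distance = 3),
    release = list(tau = 3L, n_releases = 2L, interval_days = 5L,
                   density_per_ha = 1e5, area_rule = area_rule,
                   square_side_m = 4)
  )
}
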