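# Scenario comparison layer: replicate summaries, larval ratio series,
# fold reductions, and the release-strategy scenario matrix.

stage_col <- function(species, stage) {
  col <- paste0(switch(species, pest = "pest", parasitoid = "para"),
                "_", stage)
  if (!col %in% STAGE_COLS) {
    stop("unknown species/stage combination: ", species, "/", stage)
  }
  col
}

stage_matrix <- function(x, species, stage) {
  stopifnot(inherits(x, "scenario_result"))
  m <- x$counts[, stage_col(species, stage), , drop = FALSE]
  matrix(m, nrow = dim(m)[1L])     # day x replicate
}

#' Pointwise replicate mean and 95% confidence band
#'
#' Daily mean over replicates with a Normal-approximation confidence
#' interval, `mean +/- z * SE` (`z = qnorm(0.975)` at the default level).
#' With a single replicate the band has width zero.  A percentile bootstrap
#' over replicates is available as an alternative.
#'
#' @param x A `scenario_result`.
#' @param species `"pest"` or `"parasitoid"`.
#' @param stage Stage name (`"egg"`, `"larva"`, `"pupa"`, `"adult"` for the
#'   pest; `"immature"`, `"adult"` for the parasitoid).
#' @param level Confidence level.
#' @param method `"normal"` (default) or `"boot"` (percentile bootstrap).
#' @param boot_n Bootstrap resamples when `method = "boot"`.
#' @return Data frame with `day`, `mean`, `lower`, `upper`, `n`.
#' @export
summarize_replicates <- function(x, species = "pest", stage = "larva",
                                 level = 0.95,
                                 method = c("normal", "boot"),
                                 boot_n = 1000L) {
  method <- match.arg(method)
  m <- stage_matrix(x, species, stage)
  n <- ncol(m)
  mu <- rowMeans(m)
  if (method == "normal") {
    se <- if (n > 1L) apply(m, 1L, stats::sd) / sqrt(n) else rep(0, nrow(m))
    z <- stats::qnorm(1 - (1 - level) / 2)
    lower <- mu - z * se
    upper <- mu + z * se
  } else {
    qs <- t(apply(m, 1L, function(v) {
      bm <- replicate(boot_n, mean(sample(v, n, replace = TRUE)))
      stats::quantile(bm, c((1 - level) / 2, 1 - (1 - level) / 2))
    }))
    lower <- qs[, 1L]
    upper <- qs[, 2L]
  }
  data.frame(day = 0:(nrow(m) - 1L), mean = mu, lower = lower, upper = upper,
             n = n)
}

#' Daily ratio of a modified protocol to the standard protocol
#'
#' `N(t)` is the mean larval population under the modified release protocol
#' divided by the mean under the standard protocol, day by day.  `N = 1`
#' means the two protocols perform alike; days where the standard mean is
#' zero are emitted as `NA` (undefined), never as numbers.
#'
#' @param modified,standard `scenario_result` objects over equal horizons.
#' @inheritParams summarize_replicates
#' @return Data frame with `day` and `ratio` (`NA` where undefined).
#' @export
ratio_n <- function(modified, standard, species = "pest", stage = "larva") {
  mm <- rowMeans(as.matrix(stage_matrix(modified, species, stage)))
  ms <- rowMeans(as.matrix(stage_matrix(standard, species, stage)))
  if (length(mm) != length(ms)) stop("scenarios have different horizons")
  ratio <- ifelse(ms == 0, NA_real_, mm / ms)
  data.frame(day = seq_along(mm) - 1L, ratio = ratio)
}

#' Fold reduction of one scenario relative to another
#'
#' Mean larval population of the baseline scenario divided by that of the
#' improved scenario, evaluated at one day (default: the end of the
#' horizon) or, with `average = TRUE`, on the time-averaged means over the
#' window from the baseline's first release day to the horizon.  An
#' improved mean of zero is reported as `Inf` with a warning (complete
#' suppression).
#'
#' @param baseline,improved `scenario_result` objects.
#' @param day Evaluation day (0-based; default the final day).  Ignored
#'   when `average = TRUE`.
#' @param average Use the post-first-release time-averaged means instead of
#'   a single day?
#' @inheritParams summarize_replicates
#' @return A single fold value (`>= 0`, possibly `Inf`).
#' @export
fold_reduction <- function(baseline, improved, day = NULL, average = FALSE,
                           species = "pest", stage = "larva") {
  b <- rowMeans(as.matrix(stage_matrix(baseline, species, stage)))
  i <- rowMeans(as.matrix(stage_matrix(improved, species, stage)))
  if (isTRUE(average)) {
    t0 <- suppressWarnings(min(vapply(baseline$release_days, function(d)
      if (length(d)) d[1L] else NA_integer_, integer(1)), na.rm = TRUE))
    if (!is.finite(t0)) t0 <- 0L
    win <- (t0 + 1L):length(b)
    bi <- mean(b[win])
    ii <- mean(i[win])
    day <- NA_integer_
  } else {
    if (is.null(day)) day <- length(b) - 1L
    stopifnot(day >= 0, day <= length(b) - 1L, day <= length(i) - 1L)
    bi <- b[day + 1L]
    ii <- i[day + 1L]
  }
  if (ii == 0) {
    warning("improved scenario mean is 0: infinite fold reduction")
    return(Inf)
  }
  bi / ii
}

# OLS slope of log(mean larvae + 1) from the first release day to the
# horizon; negative slope marks a population driven to negative growth.
post_release_slope <- function(x, species = "pest", stage = "larva") {
  mu <- rowMeans(as.matrix(stage_matrix(x, species, stage)))
  t0 <- suppressWarnings(min(vapply(x$release_days, function(d)
    if (length(d)) d[1L] else NA_integer_, integer(1)), na.rm = TRUE))
  if (!is.finite(t0)) t0 <- 0L
  days <- t0:(length(mu) - 1L)
  fit <- stats::lm(log(mu[days + 1L] + 1) ~ days)
  unname(stats::coef(fit)[2L])
}

#' Run the five-scenario release-strategy matrix
#'
#' Simulates the standard protocol (three weekly releases of 50,000
#' parasitoids per hectare) together with its density variants (100,000 and
#' 200,000 per hectare at three releases) and its frequency variants (four
#' and five releases at 50,000 per hectare), sharing random streams
#' replicate-by-replicate (common random numbers) so scenario contrasts are
#' paired.
#'
#' @param config Base `scenario_config` (its release block supplies the
#'   standard density/frequency; grid, horizon and replicates are shared).
#' @param base_seed Base seed for the common random-number streams.
#' @param n Replicates per scenario (default: `config$replicates`).
#' @param densities Per-release densities explored at the standard frequency.
#' @param frequencies Release counts explored at the standard density.
#' @inheritParams run_sim
#' @return A `release_matrix`: list with `results` (named `scenario_result`
#'   list) and `table`, a data frame with one row per scenario holding the
#'   release number and density, the total parasitoids per hectare, the mean
#'   final larval count, the fold reduction versus the standard protocol,
#'   the post-release log-slope, and a negative-growth flag.
#' @export
run_release_matrix <- function(config, base_seed = 1L, n = NULL,
                               densities = c(50000, 100000, 200000),
                               frequencies = c(3, 4, 5),
                               audit = TRUE) {
  cfg <- if (inherits(config, "scenario_config")) config
         else validate_config(config)
  if (is.null(n)) n <- cfg$replicates
  std_density <- densities[1L]
  std_freq <- frequencies[1L]

  scen <- unique(rbind(
    data.frame(n_releases = std_freq, density = densities),
    data.frame(n_releases = frequencies, density = std_density)
  ))
  scen$label <- sprintf("%dx%sk", scen$n_releases, scen$density / 1000)

  results <- list()
  for (i in seq_len(nrow(scen))) {
    cfg_i <- cfg
    cfg_i$release$n_releases <- as.integer(scen$n_releases[i])
    cfg_i$release$density_per_ha <- scen$density[i]
    results[[scen$label[i]]] <- run_replicates(cfg_i, n = n,
                                               base_seed = base_seed,
                                               label = scen$label[i],
                                               audit = audit)
  }

  std_label <- sprintf("%dx%sk", std_freq, std_density / 1000)
  std <- results[[std_label]]
  horizon <- dim(std$counts)[1L] - 1L
  tab <- do.call(rbind, lapply(scen$label, function(lb) {
    x <- results[[lb]]
    slope <- post_release_slope(x)
    data.frame(
      label = lb,
      n_releases = scen$n_releases[scen$label == lb],
      density_per_ha = scen$density[scen$label == lb],
      total_per_ha = scen$n_releases[scen$label == lb] *
        scen$density[scen$label == lb],
      final_larvae = mean(x$counts[horizon + 1L, "pest_larva", ]),
      fold_vs_standard = fold_reduction(std, x),
      post_release_slope = slope,
      negative_growth = slope < 0,
      stringsAsFactors = FALSE
    )
  }))
  out <- list(results = results, table = tab, standard = std_label,
              base_seed = base_seed, n = n)
  class(out) <- "release_matrix"
  out
}

#' @export
print.release_matrix <- function(x, ...) {
  cat(sprintf("<release_matrix> %d scenarios x %d replicates (standard: %s)\n",
              nrow(x$table), x$n, x$standard))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot scenario mean curves with confidence bands
#'
#' Larval mean series with its confidence ribbon and dashed markers at the
#' release days, in the style of release-strategy comparison figures.
#' Requires ggplot2.
#'
#' @param x A `scenario_result` or a named list of them.
#' @inheritParams summarize_replicates
#' @return A ggplot object.
#' @export
plot_scenario <- function(x, species = "pest", stage = "larva",
                          level = 0.95) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_scenario() requires the ggplot2 package")
  }
  xs <- if (inherits(x, "scenario_result")) {
    stats::setNames(list(x), x$label)
  } else x
  dfs <- do.call(rbind, lapply(names(xs), function(nm) {
    s <- summarize_replicates(xs[[nm]], species, stage, level)
    s$scenario <- nm
    s
  }))
  rel <- unique(unlist(lapply(xs, function(s)
    vapply(s$release_days, function(d) if (length(d)) d[1L] else NA_integer_,
           integer(1)))))
  gg <- ggplot2::ggplot(dfs, ggplot2::aes(x = .data$day, y = .data$mean,
                                          colour = .data$scenario,
                                          fill = .data$scenario)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day", y = sprintf("mean %s %s", species, stage))
  rel <- rel[is.finite(rel)]
  if (length(rel)) {
    gg <- gg + ggplot2::geom_vline(xintercept = min(rel), linetype = "dashed")
  }
  gg
}

#' Plot a modified-to-standard larval ratio series
#'
#' The daily ratio `N(t)` from [ratio_n()] with the `N = 1` reference line
#' (equal performance of the two protocols).  Requires ggplot2.
#'
#' @inheritParams ratio_n
#' @return A ggplot object.
#' @export
plot_ratio <- function(modified, standard, species = "pest",
                       stage = "larva") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ratio() requires the ggplot2 package")
  }
  df <- ratio_n(modified, standard, species, stage)
  ggplot2::ggplot(df[!is.na(df$ratio), ],
                  ggplot2::aes(x = .data$day, y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "day",
                  y = "modified / standard mean larval population")
}
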