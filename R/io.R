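# CSV series output with provenance header, and round-trip summaries.

# Small polynomial rolling hash of the deparsed configuration; identifies a
# configuration in output headers (not cryptographic).
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  ints <- utf8ToInt(s)
  h <- 0
  for (b in ints) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

output_header <- function(cfg, seed) {
  c(sprintf("# trichosim %s", as.character(utils::packageVersion("trichosim"))),
    sprintf("# config_hash: %s", config_hash(cfg)),
    sprintf("# seed: %s", paste(seed, collapse = ",")))
}

#' Write a daily series to CSV
#'
#' One row per (day, species, stage, replicate), deterministic row order,
#' preceded by comment lines recording the package version, a configuration
#' hash and the seed(s) -- identical `(config, seed)` runs produce
#' byte-identical files.
#'
#' @param x A `sim_result` or `scenario_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  df <- series_df(x)
  seed <- if (inherits(x, "sim_result")) x$seed else x$seeds
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(x$config, seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily series written by [write_series_csv()]
#'
#' @param path CSV path.
#' @return Data frame with `day`, `species`, `stage`, `count`, `replicate`.
#' @export
read_series_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Summaries from a long-format series data frame
#'
#' The file-based counterpart of [summarize_replicates()]: computes the same
#' daily mean and Normal-approximation confidence band from a series data
#' frame, so that config -> run -> CSV -> summarize reproduces the in-memory
#' path exactly.
#'
#' @param df Data frame from [read_series_csv()] / [series_df()].
#' @inheritParams summarize_replicates
#' @return Data frame with `day`, `mean`, `lower`, `upper`, `n`.
#' @export
summarize_series <- function(df, species = "pest", stage = "larva",
                             level = 0.95) {
  sel <- df[df$species == species & df$stage == stage, , drop = FALSE]
  if (!nrow(sel)) stop("no rows for ", species, "/", stage)
  reps <- sort(unique(sel$replicate))
  days <- sort(unique(sel$day))
  m <- matrix(NA_real_, length(days), length(reps))
  for (j in seq_along(reps)) {
    sj <- sel[sel$replicate == reps[j], ]
    m[, j] <- sj$count[order(sj$day)]
  }
  n <- length(reps)
  mu <- rowMeans(m)
  se <- if (n > 1L) apply(m, 1L, stats::sd) / sqrt(n) else rep(0, length(mu))
  z <- stats::qnorm(0.975)
  data.frame(day = days, mean = mu, lower = mu - z * se, upper = mu + z * se,
             n = n)
}

#' Ratio series from two long-format series data frames
#'
#' @param modified,standard Data frames from [read_series_csv()].
#' @inheritParams summarize_series
#' @return Data frame with `day` and `ratio` (`NA` where the standard mean
#'   is zero).
#' @export
ratio_series <- function(modified, standard, species = "pest",
                         stage = "larva") {
  sm <- summarize_series(modified, species, stage)
  ss <- summarize_series(standard, species, stage)
  if (nrow(sm) != nrow(ss)) stop("series have different horizons")
  data.frame(day = sm$day,
             ratio = ifelse(ss$mean == 0, NA_real_, sm$mean / ss$mean))
}

write_matrix_outputs <- function(mx, dir, cfg, seed) {
  tab_csv <- file.path(dir, "matrix.csv")
  con <- file(tab_csv, "w")
  writeLines(output_header(cfg, seed), con)
  utils::write.csv(mx$table, con, row.names = FALSE, quote = FALSE)
  close(con)
  jsonlite::write_json(mx$table, file.path(dir, "matrix.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (nm in names(mx$results)) {
    write_series_csv(mx$results[[nm]],
                     file.path(dir, paste0("series_", nm, ".csv")))
  }
  invisible(tab_csv)
}
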