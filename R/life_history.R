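#' Daily thermal energy gain (degree-days)
#'
#' Energy accumulated by an immature insect in one day at a constant mean
#' temperature, under the classical linear degree-day model: the positive part
#' of the difference between the environmental temperature and the stage's
#' lower development threshold.  No development takes place at or below the
#' threshold.
#'
#' @param temperature Environmental mean temperature, degrees Celsius.
#' @param threshold Lower development threshold of the stage, degrees Celsius.
#' @return Degree-days gained in one day (never negative).  Vectorized.
#' @examples
#' daily_energy(30, 11.2)   # sugarcane borer egg at 30 degrees: 18.8 DD/day
#' daily_energy(10, 13.6)   # below threshold: 0
#' @export
daily_energy <- function(temperature, threshold) {
  stopifnot(all(is.finite(temperature)), all(is.finite(threshold)))
  pmax(0, temperature - threshold)
}

#' Stage duration in whole days at a constant temperature
#'
#' The thermal requirement divided by the daily gain, discretized to the
#' nearest whole day: the stage completes on day `n = max(1, ceil(K/E - 1/2))`
#' where `E = T - T_T`, i.e. a final development day that is more than half
#' filled counts as complete.  Equivalently, the day-by-day accumulation loop
#' molts once the accumulated energy reaches `K - E/2`.  This nearest-day
#' convention reproduces the reference event timing of the system (first F1
#' borer emergence — and hence the first parasitoid release — on day 36 at
#' 30 degrees under the default life history), where always rounding up
#' would delay every generation by one day per stage.
#'
#' @param K Thermal constant of the stage, degree-days.
#' @param threshold Lower development threshold, degrees Celsius.
#' @param temperature Constant environmental temperature, degrees Celsius.
#' @return Integer number of days (`>= 1`).
#' @examples
#' stage_duration(67.47, 11.2, 30)   # borer egg: 4 days
#' stage_duration(126.08, 10.6, 30)  # borer pupa: 6 days
#' stage_duration(130.98, 13.6, 30)  # parasitoid immature: 8 days
#' @export
stage_duration <- function(K, threshold, temperature) {
  stopifnot(all(K > 0))
  energy <- daily_energy(temperature, threshold)
  if (any(energy <= 0)) {
    stop("no development: temperature is at or below the stage threshold")
  }
  pmax(1L, as.integer(ceiling(K / energy - 0.5)))
}

# Engine-internal variant: Inf instead of an error when the stage cannot
# complete at this temperature (individuals then persist in the stage).
stage_duration_or_inf <- function(K, threshold, temperature) {
  energy <- daily_energy(temperature, threshold)
  if (energy <= 0) Inf else max(1, ceiling(K / energy - 0.5))
}

#' Sample adult life spans
#'
#' Adult longevity is Normal with species-specific mean and standard
#' deviation; sampled values are rounded to whole days and truncated below at
#' one day (every emerging adult lives at least the day of emergence).
#'
#' @param n Number of adults.
#' @param mean Mean adult life span, days.
#' @param sd Standard deviation of the life span, days.
#' @return Integer vector of `n` life spans, each `>= 1`.
#' @examples
#' sample_longevity(5, 8.9, 0.7)
#' @export
sample_longevity <- function(n, mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  pmax(1L, as.integer(round(stats::rnorm(n, mean, sd))))
}

#' Expected eggs laid (or host eggs attacked) on a given adult day
#'
#' Daily reproductive output declines exponentially with the female's
#' oviposition age: a female of age `age` (days since the onset of laying,
#' starting at 0) is expected to lay
#' `fecundity * (exp(-rhythm * age) - exp(-rhythm * (age + 1)))` eggs that
#' day.  Summed over all ages this telescopes to `fecundity`, the lifetime
#' total; the rhythm constant controls how front-loaded laying is.  The same
#' schedule with `fecundity = theta` gives a parasitoid female's daily attack
#' capacity.
#'
#' @param age Days since oviposition onset (integer, `>= 0`).  Vectorized.
#' @param fecundity Lifetime eggs per female (for the parasitoid: lifetime
#'   parasitized host eggs per female).
#' @param rhythm Per-day decay constant of the oviposition rhythm (`> 0`).
#' @return Expected eggs for that day (real, `>= 0`).
#' @examples
#' eggs_on_day(0, 84, 0.3)        # 21.77 eggs on the first laying day
#' sum(eggs_on_day(0:500, 84, 0.3))  # converges to 84
#' @export
eggs_on_day <- function(age, fecundity, rhythm) {
  stopifnot(all(age >= 0), fecundity >= 0, rhythm > 0)
  fecundity * (exp(-rhythm * age) - exp(-rhythm * (age + 1)))
}
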