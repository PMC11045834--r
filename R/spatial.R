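#' Sample daily movement distances from the truncated exponential kernel
#'
#' Undirected daily displacement follows an exponential distance kernel
#' `D(d) = exp(-beta * d)` normalized on `[0, d_max]`, where `d_max` is the
#' species' maximum distance travelled per day.  Sampling is by inverse CDF
#' on the truncated distribution.
#'
#' @param n Number of draws.
#' @param beta Exponential kernel parameter, per metre (`> 0`).
#' @param d_max Maximum daily distance, metres (`>= 0`).
#' @param round_to_cell Round draws to the nearest whole metre (= lattice
#'   cell)?  The engine keeps distances continuous and rounds the x/y
#'   components at displacement instead; the continuous draws are also what
#'   distributional tests should use.
#' @return Numeric (or integer-valued) vector of `n` distances in
#'   `[0, d_max]`.
#' @examples
#' sample_move_distance(5, beta = 0.2, d_max = 50)
#' @export
sample_move_distance <- function(n, beta, d_max, round_to_cell = TRUE) {
  stopifnot(beta > 0, d_max >= 0)
  if (n == 0) return(numeric(0))
  if (d_max == 0) return(rep(0, n))
  u <- stats::runif(n)
  d <- -log(1 - u * (1 - exp(-beta * d_max))) / beta
  if (round_to_cell) round(d) else d
}

# Closed-form mean of the truncated exponential kernel on [0, d_max];
# independent check target for the sampler.
truncated_exp_mean <- function(beta, d_max) {
  if (d_max == 0) return(0)
  1 / beta - d_max * exp(-beta * d_max) / (1 - exp(-beta * d_max))
}

#' Displace lattice positions by a polar move
#'
#' Destination is `origin + (round(d cos a), round(d sin a))`, clipped to the
#' grid.  Coordinates are 0-based; a move whose un-clipped destination falls
#' outside the lattice counts one boundary contact (the reference field is
#' chosen large enough that contacts stay at zero; on small test grids they
#' are logged).
#'
#' @param x,y Integer 0-based coordinates (vectors of equal length).
#' @param distance Move distances, metres (continuous allowed).
#' @param angle Move angles, radians.
#' @param side Grid side length, cells.
#' @return List with clipped integer `x`, `y` and the number of boundary
#'   `contacts`.
#' @export
displace <- function(x, y, distance, angle, side) {
  nx <- x + as.integer(round(distance * cos(angle)))
  ny <- y + as.integer(round(distance * sin(angle)))
  out <- nx < 0L | nx >= side | ny < 0L | ny >= side
  list(x = pmin(pmax(nx, 0L), side - 1L),
       y = pmin(pmax(ny, 0L), side - 1L),
       contacts = sum(out))
}

# Offsets of all lattice cells within Euclidean distance `radius` of the
# origin, ordered by (dy, dx) so that destination cell indices come out in
# ascending order for any origin.
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= radius^2, ]
  g <- g[order(g$dy, g$dx), ]
  list(dx = as.integer(g$dx), dy = as.integer(g$dy))
}

#' Host-directed destination choice for a searching parasitoid
#'
#' The parasitoid examines every lattice cell within its action radius
#' (Euclidean disk) of its current position and moves to one of them with
#' probability proportional to that cell's count of unparasitized host eggs.
#' If no cell in the disk holds eggs it falls back to undirected movement:
#' a truncated-exponential distance (capped at `d_max`) in a uniform
#' direction.
#'
#' The directed draw consumes one uniform deviate mapped through the inverse
#' CDF of the cell weights (cells in ascending index order); the fallback
#' consumes one distance and one angle deviate.  The engine applies exactly
#' the same scheme, vectorized.
#'
#' @param x,y 0-based position of the parasitoid.
#' @param egg_counts Integer vector of unparasitized host-egg counts, one per
#'   lattice cell (cell index = `x + y * side + 1`).
#' @param side Grid side length, cells.
#' @param radius Action radius, metres.
#' @param beta,d_max Fallback kernel parameters (see
#'   [sample_move_distance()]).
#' @return List with destination `x`, `y`, logical `directed`, and boundary
#'   `contacts` (0 for directed moves).
#' @export
parasitoid_choose_cell <- function(x, y, egg_counts, side, radius, beta, d_max) {
  offs <- disk_offsets(radius)
  nx <- x + offs$dx
  ny <- y + offs$dy
  ok <- nx >= 0L & nx < side & ny >= 0L & ny < side
  nx <- nx[ok]
  ny <- ny[ok]
  w <- egg_counts[nx + ny * side + 1L]
  tot <- sum(w)
  if (tot > 0) {
    u <- stats::runif(1) * tot
    j <- which(cumsum(w) > u)[1L]
    list(x = nx[j], y = ny[j], directed = TRUE, contacts = 0L)
  } else {
    d <- sample_move_distance(1, beta, d_max, round_to_cell = FALSE)
    a <- stats::runif(1) * 2 * pi
    mv <- displace(x, y, d, a, side)
    list(x = mv$x, y = mv$y, directed = FALSE, contacts = mv$contacts)
  }
}

#' Draw the daily background-infestation event
#'
#' Each day there is one Bernoulli trial with probability `prob` that a new
#' mated adult female pest arrives from outside the field; on success her
#' landing cell is uniform over the lattice.  With `prob = 0` the step
#' consumes no randomness.
#'
#' @param ncells Number of lattice cells.
#' @param prob Daily probability of a new infestation, in `[0, 1]`.
#' @return The landing cell index (1-based), or `0L` if no arrival.
#' @export
sample_immigration <- function(ncells, prob) {
  stopifnot(prob >= 0, prob <= 1, ncells >= 1)
  if (prob == 0) return(0L)
  if (stats::runif(1) < prob) sample.int(ncells, 1L) else 0L
}
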