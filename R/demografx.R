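# X-versus-autosome scaling: the neutral X mutation rate under a
# male-to-female mutation-rate ratio alpha, its inversion with the
# feasibility bound, and NeX/NeA ratio trajectories over stepwise Ne
# estimates (PSMC-style step functions; deliberately no interpolation).

#' Scale the autosomal mutation rate to the X chromosome
#'
#' `mu_X = mu_A * 2 (2 + alpha) / (3 (1 + alpha))`, where `alpha` is the
#' male-to-female mutation rate ratio. With `alpha = 2` and
#' `mu_A = 2.34e-8` this gives `mu_X = 2.08e-8`.
#'
#' @param mu_a Autosomal mutation rate per site per generation.
#' @param alpha Male-to-female mutation rate ratio (> 0).
#' @return The X-linked rate in the same units.
#' @export
scale_mu_x <- function(mu_a, alpha) {
  stopifnot(mu_a > 0)
  if (alpha <= 0) stop("alpha must be positive")
  mu_a * 2 * (2 + alpha) / (3 * (1 + alpha))
}

#' Invert the X/autosome rate ratio for alpha
#'
#' Solves `r = 2 (2 + alpha) / (3 (1 + alpha))` for `alpha`:
#' `alpha = (4 - 3 r) / (3 r - 2)`. The attainable range of `r` over
#' `alpha > 0` is the open interval (2/3, 4/3); ratios outside it return
#' `"infeasible"` (no positive alpha exists), which is how a fitted X rate
#' far below two-thirds of the autosomal rate is recognised as
#' biologically unrealistic.
#'
#' @param ratio Observed `mu_X / mu_A` (> 0).
#' @return The implied alpha, or the character `"infeasible"`.
#' @export
invert_alpha <- function(ratio) {
  stopifnot(ratio > 0)
  if (ratio <= 2 / 3 || ratio >= 4 / 3) return("infeasible")
  (4 - 3 * ratio) / (3 * ratio - 2)
}

#' Stepwise Ne trajectory
#'
#' An ordered step function of effective population size against time
#' (years before present), as drawn from PSMC-style output: the value at
#' time `t` is the Ne of the last step starting at or before `t`
#' (right-continuous; no interpolation).
#'
#' @param time Strictly increasing step start times (years).
#' @param ne Positive effective sizes, one per step.
#' @param marker `"autosome"` or `"x_chromosome"`.
#' @param mu_used,generation_time_years Bookkeeping fields.
#' @return An `ne_trajectory`.
#' @export
ne_trajectory <- function(time, ne, marker = c("autosome", "x_chromosome"),
                          mu_used = NA_real_,
                          generation_time_years = NA_real_) {
  marker <- match.arg(marker)
  stopifnot(length(time) == length(ne), length(time) >= 1,
            all(diff(time) > 0), all(ne > 0))
  structure(list(steps = data.frame(time_start = time, ne = ne),
                 marker = marker, mu_used = mu_used,
                 generation_time_years = generation_time_years),
            class = "ne_trajectory")
}

# evaluate the step function on a grid
eval_trajectory <- function(traj, grid) {
  s <- traj$steps
  i <- findInterval(grid, s$time_start)
  if (any(i == 0)) stop("grid point before the trajectory's first step")
  s$ne[i]
}

#' NeX/NeA ratio trajectory
#'
#' Evaluates two stepwise trajectories on a common grid and reports their
#' ratio, with a summary of the minimum, maximum, and the grid times where
#' the ratio crosses 0.75 (the neutral X/autosome expectation under equal
#' breeding sex ratios).
#'
#' @param auto,x `ne_trajectory` objects (autosome and X).
#' @param grid Time points (years) covered by both trajectories.
#' @return List with `series` (data frame: time, ne_auto, ne_x, ratio) and
#'   `summary` (list: min, max, crossings_075 - grid times where the
#'   series crosses 0.75 in either direction).
#' @export
ne_ratio_trajectory <- function(auto, x, grid) {
  stopifnot(inherits(auto, "ne_trajectory"), inherits(x, "ne_trajectory"))
  na <- eval_trajectory(auto, grid)
  nx <- eval_trajectory(x, grid)
  ratio <- nx / na
  cross <- which(diff(sign(ratio - 0.75)) != 0)
  list(series = data.frame(time = grid, ne_auto = na, ne_x = nx,
                           ratio = ratio),
       summary = list(min = min(ratio), max = max(ratio),
                      crossings_075 = grid[cross + 1L]))
}
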