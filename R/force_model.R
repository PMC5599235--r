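#' Per-limb force profile over one stride
#'
#' Evaluates the three mass-specific force components of one limb on the
#' uniform circular time grid of the configuration. Within stance (local
#' stance time `t` in `[0, Tstance)`):
#' \itemize{
#'   \item vertical: `Fz = Az * sin(pi * t / Tstance)`, a half-sine with the
#'     weight-supporting amplitude of [vertical_amplitude()];
#'   \item fore-aft: `Fx = s * Ax * sin(2 * pi * t / Tstance) +
#'     b * Ax_bias * sin(pi * t / Tstance)` where `s = -1` for upright
#'     walking (decelerate-then-accelerate) and `+1` for suspended
#'     progression, and `b = +1` for hind limbs, `-1` for fore limbs;
#'   \item medial: `Fy = m * Ay * sin(pi * t / Tstance)`, directed toward the
#'     body midline. With the +y axis to the animal's left, left limbs push
#'     the center of mass rightward (`m = -1`) and right limbs leftward
#'     (`m = +1`); costs are invariant under the mirrored convention.
#' }
#' All components are zero outside stance.
#'
#' @param config A [gait_config()].
#' @param limb One of `"LH"`, `"LF"`, `"RH"`, `"RF"`.
#' @return An object of class `force_series`: a list with the limb id, its
#'   contact `onset` (stride fraction), the `time_fraction` grid, and numeric
#'   vectors `fx`, `fy`, `fz`.
#' @export
#' @examples
#' fs <- limb_force_series(gait_config(0.7, 25), "LH")
#' range(fs$fz)  # vertical force is a non-negative half-sine
limb_force_series <- function(config, limb) {
  stopifnot(inherits(config, "gait_config"))
  limb <- match.arg(limb, .LIMBS)
  df <- config$duty_factor
  n <- config$samples_per_stride
  tf <- (0:(n - 1)) / n
  onset <- footfall_schedule(config$phase_pct)[[limb]]
  u <- (tf - onset) %% 1
  in_stance <- u < df
  tau <- (u / df) * in_stance           # local stance time, 0 outside stance
  half_sine <- sin(pi * tau) * in_stance
  full_sine <- sin(2 * pi * tau) * in_stance

  az <- vertical_amplitude(df, config$gravity)
  s <- if (config$orientation == "suspended") 1 else -1
  b <- if (substr(limb, 2, 2) == "H") 1 else -1
  m <- if (substr(limb, 1, 1) == "L") -1 else 1

  structure(list(
    limb = limb,
    onset = onset,
    time_fraction = tf,
    fx = s * config$fore_aft_ratio * az * full_sine +
         b * config$bias_ratio * az * half_sine,
    fy = m * config$medial_ratio * az * half_sine,
    fz = az * half_sine,
    duty_factor = df,
    stride_period = config$stride_period
  ), class = "force_series")
}

#' Force profiles of all four limbs
#'
#' @param config A [gait_config()].
#' @return Named list of four [limb_force_series()] objects
#'   (`LH`, `LF`, `RH`, `RF`).
#' @export
all_limb_forces <- function(config) {
  out <- lapply(.LIMBS, function(l) limb_force_series(config, l))
  names(out) <- .LIMBS
  out
}

# stride integral of a periodic sampled series: on a uniform circular grid the
# trapezoid rule reduces to the sample mean times the period
.integral_circular <- function(y, period) mean(y) * period

# cumulative trapezoidal integral on a uniform grid (v[1] = 0)
.cumtrapz <- function(y, dt) drop(pracma::cumtrapz(y)) * dt

#' Center-of-mass velocities from the limb forces
#'
#' Integrates the summed mass-specific limb forces (minus gravity, for the
#' vertical component) over the stride with a cumulative trapezoidal rule,
#' subtracts the stride mean of each component so that vertical and lateral
#' velocities fluctuate about zero, and adds the mean forward speed to the
#' fore-aft component.
#'
#' @param forces List of the four limb `force_series` (see
#'   [all_limb_forces()]).
#' @param config The [gait_config()] the forces were built from.
#' @return An object of class `com_state`: the `time_fraction` grid, velocity
#'   components `vx`, `vy`, `vz`, and the `mean_forward_speed` used.
#'   An error is raised if the fore-aft velocity is not strictly positive at
#'   every sample; supply a larger `mean_forward_speed` in that case.
#' @export
#' @examples
#' cfg <- gait_config(0.8, 50)
#' com <- com_velocities(all_limb_forces(cfg), cfg)
#' c(mean(com$vz), mean(com$vy))  # zero mean vertical and lateral velocity
com_velocities <- function(forces, config) {
  stopifnot(inherits(config, "gait_config"), length(forces) == 4L)
  n <- config$samples_per_stride
  if (!all(vapply(forces, function(f) length(f$fz) == n, logical(1))))
    stop("force series do not share the configuration's time grid")
  tot_fx <- Reduce(`+`, lapply(forces, `[[`, "fx"))
  tot_fy <- Reduce(`+`, lapply(forces, `[[`, "fy"))
  tot_fz <- Reduce(`+`, lapply(forces, `[[`, "fz"))
  dt <- config$stride_period / n
  vx <- .cumtrapz(tot_fx, dt)
  vy <- .cumtrapz(tot_fy, dt)
  vz <- .cumtrapz(tot_fz - config$gravity, dt)
  vx <- vx - mean(vx)
  vy <- vy - mean(vy)
  vz <- vz - mean(vz)
  v0 <- .resolve_v0(config)
  vx <- vx + v0
  if (any(vx <= 0))
    stop("instantaneous fore-aft velocity is not always forward; ",
         "increase mean_forward_speed (currently ", format(v0), ")")
  structure(list(
    time_fraction = forces[[1]]$time_fraction,
    vx = vx, vy = vy, vz = vz,
    mean_forward_speed = v0,
    stride_period = config$stride_period
  ), class = "com_state")
}

#' Instantaneous power of one limb on the center of mass
#'
#' The elementwise dot product of the limb force and the center-of-mass
#' velocity. Components cancel within a limb before any rectification: a
#' positive vertical power coinciding with an equal negative fore-aft power
#' costs nothing, so a passive vaulting action demands no limb power.
#'
#' @param force_series A [limb_force_series()].
#' @param com_state A [com_velocities()] result on the same grid.
#' @return Numeric vector of mass-specific power over the stride grid.
#' @export
limb_power_series <- function(force_series, com_state) {
  stopifnot(inherits(force_series, "force_series"),
            inherits(com_state, "com_state"))
  if (length(force_series$fx) != length(com_state$vx) ||
      force_series$stride_period != com_state$stride_period)
    stop("force series and CoM state are not on a common time grid")
  force_series$fx * com_state$vx +
    force_series$fy * com_state$vy +
    force_series$fz * com_state$vz
}

#' Positive limb work of one stride
#'
#' The mechanical work "cost" of a configured stride: the sum over the four
#' limbs of the stride integral of the positive part of each limb's power.
#' Negative work by one limb cannot power positive work by another, and no
#' elastic recovery is assumed, so all positive limb work is costly.
#'
#' @param config A [gait_config()].
#' @return Non-negative mass-specific work per stride (units
#'   `g^2 Tstride^3` per unit mass; dimensionless in the default units).
#'   Deterministic for a fixed configuration and grid.
#' @export
#' @examples
#' # evenly spaced footfalls are cheapest at moderate duty factors
#' stride_work_cost(gait_config(0.65, 25)) <
#'   stride_work_cost(gait_config(0.65, 50))
stride_work_cost <- function(config) {
  forces <- all_limb_forces(config)
  com <- com_velocities(forces, config)
  total <- 0
  for (f in forces) {
    p <- limb_power_series(f, com)
    total <- total + .integral_circular(pmax(p, 0), config$stride_period)
  }
  total
}

# costs of one duty-factor row across a vector of phases, sharing the
# configuration (and hence the mean forward speed) so phases are comparable
.row_costs <- function(config, phases) {
  vapply(phases, function(p) {
    cfg <- config
    cfg$phase_pct <- p %% 100
    stride_work_cost(cfg)
  }, numeric(1))
}
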