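#' Net impulse of one limb over a stride
#'
#' Componentwise stride integral of a limb's mass-specific force. In the base
#' model each limb's fore-aft impulse is zero (the full sine integrates out);
#' with a fore-aft bias the hind limbs carry a net forward impulse balanced
#' by the fore limbs. Summed over limbs, the impulses always equal gravity's
#' impulse `(0, 0, g * Tstride)`.
#'
#' @param force_series A [limb_force_series()].
#' @return Object of class `impulse_vector`: list with the `limb` id and a
#'   named numeric vector `components` (`x`, `y`, `z`).
#' @export
#' @examples
#' cfg <- gait_variant("bias", duty_factor = 0.7, phase_pct = 25)
#' net_limb_impulse(limb_force_series(cfg, "LH"))$components["x"]  # forward
net_limb_impulse <- function(force_series) {
  stopifnot(inherits(force_series, "force_series"))
  tp <- force_series$stride_period
  structure(list(
    limb = force_series$limb,
    components = c(x = .integral_circular(force_series$fx, tp),
                   y = .integral_circular(force_series$fy, tp),
                   z = .integral_circular(force_series$fz, tp))
  ), class = "impulse_vector")
}

#' Angle between limb force and center-of-mass velocity
#'
#' Collision-mechanics diagnostic: per stance sample, the angle between the
#' limb's force vector and the center-of-mass velocity vector. Losses shrink
#' as this angle approaches perpendicular; an angle above 90 degrees is
#' exactly an instant of negative limb power. Samples where either vector's
#' magnitude falls below 1e-12 are skipped.
#'
#' @param force_series A [limb_force_series()].
#' @param com_state The matching [com_velocities()] state.
#' @return Data frame with `time_fraction`, `angle_deg` and the instantaneous
#'   `power`, restricted to stance samples.
#' @export
force_velocity_angle_series <- function(force_series, com_state) {
  stopifnot(inherits(force_series, "force_series"),
            inherits(com_state, "com_state"))
  if (length(force_series$fx) != length(com_state$vx) ||
      force_series$stride_period != com_state$stride_period)
    stop("force series and CoM state are not on a common time grid")
  tf <- force_series$time_fraction
  u <- (tf - force_series$onset) %% 1
  stance <- u < force_series$duty_factor
  fmag <- sqrt(force_series$fx^2 + force_series$fy^2 + force_series$fz^2)
  vmag <- sqrt(com_state$vx^2 + com_state$vy^2 + com_state$vz^2)
  keep <- stance & fmag > 1e-12 & vmag > 1e-12
  dot <- force_series$fx * com_state$vx + force_series$fy * com_state$vy +
    force_series$fz * com_state$vz
  cosang <- pmin(pmax(dot[keep] / (fmag[keep] * vmag[keep]), -1), 1)
  data.frame(time_fraction = tf[keep],
             angle_deg = acos(cosang) * 180 / pi,
             power = dot[keep])
}

#' Sign of the early-stance vertical center-of-mass velocity
#'
#' The sign of the mean vertical center-of-mass velocity over the first half
#' of the left-hind stance window. At trot phasing (50%) the sign reverses
#' with duty factor: downward (-1) at low duty factors, upward (+1) at high
#' duty factors, because overlapping limb forces at high duty factor shift
#' the timing of peak vertical force on the body away from the peak of any
#' single limb.
#'
#' @param config A [gait_config()] (trot phasing, `phase_pct = 50`, is the
#'   intended use; any phase is accepted).
#' @return `+1` (upward), `-1` (downward), or `0` if exactly balanced.
#' @export
#' @examples
#' early_stance_vertical_velocity_sign(gait_config(0.65, 50))  # -1
#' early_stance_vertical_velocity_sign(gait_config(0.80, 50))  # +1
early_stance_vertical_velocity_sign <- function(config) {
  stopifnot(inherits(config, "gait_config"))
  forces <- all_limb_forces(config)
  com <- com_velocities(forces, config)
  first_half <- com$time_fraction < config$duty_factor / 2  # LH onset is 0
  sign(mean(com$vz[first_half]))
}
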