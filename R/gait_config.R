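#' Configure one point of the quadrupedal walking model
#'
#' A `gait_config` fully parameterizes the sinusoidal limb-force model at one
#' (duty factor, limb phase) point. All quantities are mass-specific and, by
#' default, nondimensionalized with gravity `g = 1` and stride period
#' `Tstride = 1`, so forces are in units of body weight and work in units of
#' `m g Tstride^2` per stride.
#'
#' @param duty_factor Fraction of the stride period each limb spends in ground
#'   contact, identical for all four limbs. Must lie strictly between 0.5 and
#'   1 (a walking gait keeps at least one foot of each pair on the ground).
#' @param phase_pct Hildebrand limb phase: the percentage of the stride period
#'   by which the ipsilateral forefoot contact follows the hindfoot contact.
#'   Treated circularly (reduced modulo 100).
#' @param fore_aft_ratio Amplitude of the fore-aft full-sine force as a
#'   fraction of the vertical amplitude. The default 0.2 corresponds to a
#'   stance sweep angle of roughly 30 degrees (see [stance_angle()]).
#' @param bias_ratio Amplitude of the fore-aft half-sine bias (net forward
#'   impulse from the hindlimbs, balanced by the forelimbs) as a fraction of
#'   the vertical amplitude. 0 for the base model, 0.1 for the biased variant.
#' @param medial_ratio Amplitude of the medial half-sine force as a fraction
#'   of the vertical amplitude. 0 for the base model, 0.05 for the full
#'   variant.
#' @param orientation `"upright"` for normal walking (each limb decelerates
#'   then accelerates the body) or `"suspended"` for below-branch, sloth-like
#'   progression, which reverses the sign of the fore-aft full-sine component
#'   only.
#' @param gravity Mass-specific weight, default 1 (dimensionless model units).
#' @param stride_period Stride period, default 1.
#' @param mean_forward_speed Mean fore-aft center-of-mass speed added to the
#'   fore-aft velocity fluctuation. `NULL` (the default) resolves to
#'   `0.25 * gravity * stride_period`, a mid-range dimensionless walking
#'   speed; any value keeping the instantaneous fore-aft velocity strictly
#'   positive gives the same phase ranking of costs.
#' @param samples_per_stride Size of the uniform circular time grid on which
#'   forces and velocities are evaluated; at least 256, default 2048.
#'
#' @return An object of class `gait_config`.
#' @seealso [gait_variant()] for the named model variants,
#'   [stride_work_cost()] for the cost of a configured stride.
#' @export
#' @examples
#' cfg <- gait_config(duty_factor = 0.65, phase_pct = 25)
#' stride_work_cost(cfg)
gait_config <- function(duty_factor, phase_pct,
                        fore_aft_ratio = 0.2,
                        bias_ratio = 0,
                        medial_ratio = 0,
                        orientation = c("upright", "suspended"),
                        gravity = 1,
                        stride_period = 1,
                        mean_forward_speed = NULL,
                        samples_per_stride = 2048) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(duty_factor), length(duty_factor) == 1L,
            is.finite(duty_factor),
            is.numeric(phase_pct), length(phase_pct) == 1L,
            is.finite(phase_pct))
  if (duty_factor <= 0.5 || duty_factor >= 1)
    stop("duty_factor must lie strictly between 0.5 and 1 (walking gait)")
  if (fore_aft_ratio < 0 || bias_ratio < 0 || medial_ratio < 0)
    stop("amplitude ratios must be non-negative")
  if (gravity <= 0) stop("gravity must be positive")
  if (stride_period <= 0) stop("stride_period must be positive")
  if (samples_per_stride < 256) stop("samples_per_stride must be >= 256")
  if (!is.null(mean_forward_speed) &&
      (!is.finite(mean_forward_speed) || mean_forward_speed <= 0))
    stop("mean_forward_speed must be positive (or NULL for the default)")
  structure(list(
    duty_factor        = duty_factor,
    phase_pct          = phase_pct %% 100,
    fore_aft_ratio     = fore_aft_ratio,
    bias_ratio         = bias_ratio,
    medial_ratio       = medial_ratio,
    orientation        = orientation,
    gravity            = gravity,
    stride_period      = stride_period,
    mean_forward_speed = mean_forward_speed,
    samples_per_stride = as.integer(samples_per_stride)
  ), class = "gait_config")
}

#' @export
print.gait_config <- function(x, ...) {
  cat(sprintf(
    "<gait_config> DF = %.3f, phase = %.1f%%, %s\n", x$duty_factor,
    x$phase_pct, x$orientation))
  cat(sprintf("  amplitude ratios: fore-aft %.3g, bias %.3g, medial %.3g\n",
              x$fore_aft_ratio, x$bias_ratio, x$medial_ratio))
  cat(sprintf("  g = %g, Tstride = %g, V0 = %s, samples = %d\n",
              x$gravity, x$stride_period,
              if (is.null(x$mean_forward_speed)) "auto"
              else format(x$mean_forward_speed),
              x$samples_per_stride))
  invisible(x)
}

#' Named model variants
#'
#' Convenience constructor for the four model variants: `"base"` (vertical
#' half-sine plus fore-aft full sine), `"sloth"` (suspended progression, the
#' fore-aft full sine reversed in sign), `"bias"` (base plus a net forward
#' hindlimb / backward forelimb impulse at 0.1 of the vertical amplitude) and
#' `"full"` (bias plus medial half-sine forces at 0.05 of the vertical
#' amplitude).
#'
#' @param variant One of `"base"`, `"sloth"`, `"bias"`, `"full"`.
#' @param duty_factor,phase_pct Passed to [gait_config()].
#' @param ... Further overrides passed to [gait_config()].
#' @return A `gait_config`.
#' @export
#' @examples
#' gait_variant("sloth", duty_factor = 0.85, phase_pct = 25)
gait_variant <- function(variant = c("base", "sloth", "bias", "full"),
                         duty_factor = 0.7, phase_pct = 25, ...) {
  variant <- match.arg(variant)
  defaults <- switch(variant,
    base  = list(),
    sloth = list(orientation = "suspended"),
    bias  = list(bias_ratio = 0.1),
    full  = list(bias_ratio = 0.1, medial_ratio = 0.05))
  args <- modifyList(defaults, list(...))
  cfg <- do.call(gait_config, c(list(duty_factor = duty_factor,
                                     phase_pct = phase_pct), args))
  attr(cfg, "variant") <- variant
  cfg
}

#' Footfall schedule of a symmetrical gait
#'
#' Contact onsets of the four limbs as fractions of the stride period, for a
#' given Hildebrand limb phase. The left hind limb defines the stride start;
#' the left fore follows by `phase_pct`/100 of a stride, and the right limbs
#' mirror the left half a stride later.
#'
#' @param phase_pct Limb phase in percent, in `[0, 100)`.
#' @return Named numeric vector of onsets (stride fractions) for
#'   `LH`, `LF`, `RH`, `RF`.
#' @export
#' @examples
#' footfall_schedule(25)  # evenly spaced footfalls: LH, LF, RH, RF
#' footfall_schedule(50)  # trot timing: diagonal pairs simultaneous
#' footfall_schedule(0)   # pace timing: ipsilateral pairs simultaneous
footfall_schedule <- function(phase_pct) {
  if (!is.numeric(phase_pct) || length(phase_pct) != 1L ||
      !is.finite(phase_pct) || phase_pct < 0 || phase_pct >= 100)
    stop("phase_pct must be a single value in [0, 100)")
  p <- phase_pct / 100
  c(LH = 0, LF = p, RH = 0.5, RF = (0.5 + p) %% 1)
}

#' Weight-supporting vertical force amplitude
#'
#' Amplitude of the half-sine vertical force such that four limbs, each in
#' contact for a fraction `duty_factor` of the stride, together support body
#' weight exactly: since a half-sine averages 2/pi of its amplitude over
#' stance, `Az = pi * gravity / (8 * duty_factor)`.
#'
#' @param duty_factor Duty factor, in `(0, 1]`.
#' @param gravity Mass-specific weight (default 1).
#' @return Mass-specific force amplitude `Az`.
#' @export
#' @examples
#' vertical_amplitude(1)    # pi/8
#' vertical_amplitude(0.5)  # pi/4
vertical_amplitude <- function(duty_factor, gravity = 1) {
  if (!is.numeric(duty_factor) || any(duty_factor <= 0) ||
      any(duty_factor > 1))
    stop("duty_factor must lie in (0, 1]")
  if (!is.numeric(gravity) || any(gravity <= 0))
    stop("gravity must be positive")
  pi * gravity / (8 * duty_factor)
}

#' Stance sweep angle implied by the fore-aft amplitude ratio
#'
#' Approximates the total leg sweep angle from the force balance a quarter of
#' the way through stance, assuming the combined fore-aft and vertical forces
#' act as pure compression along the leg and the leg sweeps at a constant
#' angular rate. At quarter-stance the full-sine fore-aft force is at its
#' (negative) peak `Ax` and the vertical half-sine is at `Az * sin(pi/4)`, so
#' the sweep angle is `2 * atan(ratio / sin(pi/4))`.
#'
#' @param fore_aft_ratio Fore-aft to vertical amplitude ratio (non-negative).
#' @return Sweep angle in degrees. A ratio of 0.2 gives roughly 30 degrees.
#' @export
#' @examples
#' stance_angle(0.2)
stance_angle <- function(fore_aft_ratio) {
  if (!is.numeric(fore_aft_ratio) || any(fore_aft_ratio < 0))
    stop("fore_aft_ratio must be non-negative")
  2 * atan(fore_aft_ratio / sin(pi / 4)) * 180 / pi
}

# resolved mean forward speed for a config
.resolve_v0 <- function(config) {
  if (is.null(config$mean_forward_speed))
    0.25 * config$gravity * config$stride_period
  else config$mean_forward_speed
}
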