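#' Generate synthetic footfall events
#'
#' Simulates the timed contact/lift events a video digitization of a walking
#' quadruped would yield: contacts follow the symmetrical-gait schedule of
#' [footfall_schedule()] scaled by the stride period, lifts follow each
#' contact by `duty_factor * stride_period`, and independent Gaussian timing
#' jitter emulates frame-timing measurement error. Jitter draws are capped at
#' just under half the smallest within-limb event gap so orderings cannot
#' invert; the result is validated by [footfall_events()].
#'
#' @param duty_factor Target duty factor, in (0, 1).
#' @param phase_pct Target limb phase in percent, `[0, 100)`.
#' @param stride_period Stride period in seconds (default 1).
#' @param n_strides Number of complete strides (>= 1).
#' @param timing_jitter_sd Standard deviation of the Gaussian event-time
#'   jitter, in seconds (>= 0).
#' @param seed Random seed; the output is deterministic given the seed.
#' @return A [footfall_events()] record with `8 * n_strides` events.
#' @export
#' @examples
#' ev <- generate_events(0.75, 25, n_strides = 1)
#' nrow(ev)  # 8 events: 4 contacts + 4 lifts
#' duty_factor_from_events(generate_events(0.78, 43, n_strides = 3))
generate_events <- function(duty_factor, phase_pct, stride_period = 1,
                            n_strides = 1, timing_jitter_sd = 0,
                            seed = NULL) {
  if (duty_factor <= 0 || duty_factor >= 1)
    stop("duty_factor must lie in (0, 1)")
  if (stride_period <= 0) stop("stride_period must be positive")
  if (n_strides < 1) stop("n_strides must be >= 1")
  if (timing_jitter_sd < 0) stop("timing_jitter_sd must be >= 0")
  onsets <- footfall_schedule(phase_pct) * stride_period
  rows <- do.call(rbind, lapply(.LIMBS, function(l) {
    contacts <- onsets[[l]] + (seq_len(n_strides) - 1L) * stride_period
    data.frame(limb = l,
               event = rep(c("contact", "lift"), each = n_strides),
               time_s = c(contacts, contacts + duty_factor * stride_period))
  }))
  if (timing_jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    cap <- 0.49 * min(duty_factor, 1 - duty_factor) * stride_period
    jit <- rnorm(nrow(rows), sd = timing_jitter_sd)
    rows$time_s <- rows$time_s + pmin(pmax(jit, -cap), cap)
  }
  footfall_events(rows)
}

#' Generate a synthetic species ensemble
#'
#' Draws per-species median gait parameters from Gaussian group
#' distributions, emulating the two-cluster structure of observed walking
#' quadrupeds (a high duty factor, phase 40-50% group and a lower duty
#' factor, phase near 25% group). Draws falling outside the valid ranges
#' (duty factor in (0.5, 0.999), phase in [0, 100)) are resampled rather than
#' clipped, to avoid boundary atoms. Group labels are retained as ground
#' truth.
#'
#' @param groups Data frame with one row per group and columns `group`
#'   (label), `mean_duty_factor`, `mean_phase_pct`, `sd_duty_factor`,
#'   `sd_phase_pct`, `n_species`.
#' @param seed Random seed; output is deterministic given the seed.
#' @return Data frame of class `species_table` with synthetic species names,
#'   the generating `group`, and `median_duty_factor` / `median_phase_pct`
#'   draws (`n = 1`, SDs `NA`).
#' @export
#' @examples
#' spec <- data.frame(group = c(1, 2),
#'                    mean_duty_factor = c(0.80, 0.68),
#'                    mean_phase_pct = c(44, 21),
#'                    sd_duty_factor = 0.03, sd_phase_pct = 3,
#'                    n_species = 20)
#' ens <- generate_species_ensemble(spec, seed = 7)
#' table(kmeans_two_groups(ens), ens$group)
generate_species_ensemble <- function(groups, seed = 1) {
  need <- c("group", "mean_duty_factor", "mean_phase_pct",
            "sd_duty_factor", "sd_phase_pct", "n_species")
  stopifnot(is.data.frame(groups), all(need %in% names(groups)))
  if (any(groups$mean_duty_factor <= 0.5 | groups$mean_duty_factor >= 1))
    stop("group mean duty factors must lie in (0.5, 1)")
  if (any(groups$mean_phase_pct < 0 | groups$mean_phase_pct >= 100))
    stop("group mean phases must lie in [0, 100)")
  if (any(groups$sd_duty_factor < 0 | groups$sd_phase_pct < 0) ||
      any(groups$n_species < 1))
    stop("group SDs must be >= 0 and n_species >= 1")
  set.seed(seed)
  draw_trunc <- function(mean, sd, lo, hi) {
    if (sd == 0) return(mean)
    for (i in 1:1000) {
      x <- rnorm(1, mean, sd)
      if (x > lo && x < hi) return(x)
    }
    stop("could not draw a value inside (", lo, ", ", hi,
         ") for mean ", mean, ", sd ", sd)
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    spec <- groups[g, ]
    do.call(rbind, lapply(seq_len(spec$n_species), function(i) {
      data.frame(
        species = sprintf("group%s_sp%02d", spec$group, i),
        group = spec$group,
        median_duty_factor = draw_trunc(spec$mean_duty_factor,
                                        spec$sd_duty_factor, 0.5, 0.999),
        median_phase_pct = draw_trunc(spec$mean_phase_pct,
                                      spec$sd_phase_pct, -1e-12, 100) %% 100,
        n = 1L, sd_duty_factor = NA_real_, sd_phase_pct = NA_real_)
    }))
  }))
  rownames(rows) <- NULL
  class(rows) <- c("species_table", "data.frame")
  rows
}
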