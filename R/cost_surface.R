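#' Limb-work cost surface over duty factor and limb phase
#'
#' Evaluates [stride_work_cost()] on a grid of duty factors and limb phases
#' for one model variant, and min-max rescales the cost within each
#' duty-factor row to `[0, 1]` for presentation (minima locations are
#' identical on raw and normalized rows).
#'
#' @param variant A [gait_config()] used as a template (its `duty_factor` and
#'   `phase_pct` are overridden per grid cell), or a variant name accepted by
#'   [gait_variant()].
#' @param df_grid Ordered duty factors, all strictly inside (0.5, 1). The
#'   default step of 0.005 places the symmetry-forced minima on grid nodes.
#' @param phase_grid Ordered phases in `[0, 100)`, default step 0.5.
#' @param ... Passed to [gait_variant()] when `variant` is a name.
#' @return Object of class `cost_surface`: list with `df_grid`, `phase_grid`,
#'   matrices `raw` and `normalized` (duty factors in rows), and the template
#'   config as `variant`.
#' @export
#' @examples
#' surf <- compute_cost_surface("base", df_grid = c(0.65, 0.85),
#'                              phase_grid = seq(0, 95, by = 5))
#' find_row_minima(surf, 0.65)
compute_cost_surface <- function(variant,
                                 df_grid = seq(0.55, 0.95, by = 0.005),
                                 phase_grid = seq(0, 99.5, by = 0.5),
                                 ...) {
  config <- if (is.character(variant)) gait_variant(variant, ...) else variant
  stopifnot(inherits(config, "gait_config"))
  if (any(df_grid <= 0.5) || any(df_grid >= 1))
    stop("df_grid values must lie strictly between 0.5 and 1")
  if (any(phase_grid < 0) || any(phase_grid >= 100))
    stop("phase_grid values must lie in [0, 100)")
  raw <- t(vapply(df_grid, function(df) {
    cfg <- config
    cfg$duty_factor <- df
    .row_costs(cfg, phase_grid)
  }, numeric(length(phase_grid))))
  normalized <- t(apply(raw, 1L, function(y) {
    rng <- max(y) - min(y)
    if (rng == 0) rep(0, length(y)) else (y - min(y)) / rng
  }))
  dimnames(raw) <- dimnames(normalized) <-
    list(format(df_grid), format(phase_grid))
  structure(list(df_grid = df_grid, phase_grid = phase_grid,
                 raw = raw, normalized = normalized, variant = config),
            class = "cost_surface")
}

#' @export
print.cost_surface <- function(x, ...) {
  cat(sprintf("<cost_surface> %d duty factors [%.3f, %.3f] x %d phases\n",
              length(x$df_grid), min(x$df_grid), max(x$df_grid),
              length(x$phase_grid)))
  gl <- global_minimum_line(x)
  cat("  global-minimum phase range:",
      sprintf("%.1f-%.1f%%", min(gl$phase), max(gl$phase)), "\n")
  invisible(x)
}

#' Heat-map of a cost surface
#'
#' Plots the per-duty-factor normalized cost with phase on the x axis and
#' duty factor descending on the y axis (low cost blue, high cost red).
#'
#' @param x A [compute_cost_surface()] result.
#' @param ... Passed to [graphics::image()].
#' @export
plot.cost_surface <- function(x, ...) {
  image(x = x$phase_grid, y = x$df_grid, z = t(x$normalized),
        col = hcl.colors(64, "RdYlBu", rev = TRUE),
        xlab = "limb phase (%)", ylab = "duty factor",
        ylim = rev(range(x$df_grid)), ...)
  box()
  invisible(x)
}

# relative tolerance used to call two costs equal (ties / plateaus)
.TIE_RTOL <- 1e-9

# circular local minima (indices) of a row, plateaus collapsed to their center
.circular_minima_idx <- function(y, eps) {
  n <- length(y)
  if (max(y) - min(y) <= eps) return(NULL)  # constant row
  prv <- c(n, seq_len(n - 1L))
  nxt <- c(seq_len(n)[-1L], 1L)
  cand <- which(y <= y[prv] + eps & y <= y[nxt] + eps)
  if (!length(cand)) return(integer(0))
  # group circularly adjacent candidates of equal value into plateaus
  grp <- cumsum(c(TRUE, diff(cand) != 1L | abs(diff(y[cand])) > eps))
  runs <- split(cand, grp)
  # merge a run ending at n with one starting at 1 (circular wrap)
  if (length(runs) > 1L) {
    first <- runs[[1L]]; last <- runs[[length(runs)]]
    if (first[1L] == 1L && last[length(last)] == n &&
        abs(y[first[1L]] - y[last[length(last)]]) <= eps) {
      runs[[1L]] <- c(last, first)
      runs[[length(runs)]] <- NULL
    }
  }
  out <- vapply(runs, function(run) {
    val <- min(y[run])
    before <- prv[run[1L]]
    after <- nxt[run[length(run)]]
    if (y[before] > val + eps && y[after] > val + eps)
      run[ceiling(length(run) / 2)]
    else NA_integer_
  }, integer(1))
  sort(out[!is.na(out)])
}

#' Local cost minima of one duty-factor row
#'
#' Circular local minima of the raw cost row at one duty factor of a
#' [compute_cost_surface()] result. Plateaus (values equal within a relative
#' tolerance of 1e-9) report their central phase; a constant row yields an
#' empty result with a warning. No interpolation between grid nodes is
#' performed; the duty factor must be a grid value.
#'
#' @param surface A `cost_surface`.
#' @param duty_factor A value of `surface$df_grid`.
#' @return Sorted numeric vector of minimizing phases (possibly empty).
#' @export
find_row_minima <- function(surface, duty_factor) {
  stopifnot(inherits(surface, "cost_surface"))
  i <- which(abs(surface$df_grid - duty_factor) < 1e-9)
  if (length(i) != 1L)
    stop("duty_factor ", format(duty_factor),
         " is not on the surface grid (no interpolation is performed)")
  y <- surface$raw[i, ]
  eps <- .TIE_RTOL * max(abs(y))
  idx <- .circular_minima_idx(y, eps)
  if (is.null(idx)) {
    warning("cost row at duty factor ", format(duty_factor),
            " is constant; no minima reported")
    return(numeric(0))
  }
  surface$phase_grid[idx]
}

#' Global-minimum line of a cost surface
#'
#' For every duty-factor row, the phase(s) attaining the global row minimum.
#' Costs equal within a relative tolerance of 1e-9 are reported as a tie set
#' rather than broken arbitrarily; planar variants (no medial forces) tie
#' every minimum with its 50%-shifted partner.
#'
#' @param surface A `cost_surface`.
#' @return Object of class `minima_line`: a data frame with one row per duty
#'   factor and columns `duty_factor`, `phase` (smallest tied phase), `cost`,
#'   `cost_normalized`, `tie` (logical) and `tie_phases` (all tied phases,
#'   `;`-separated). The full local-minima sets are attached as the
#'   `local_minima` attribute.
#' @export
global_minimum_line <- function(surface) {
  stopifnot(inherits(surface, "cost_surface"))
  rows <- lapply(seq_along(surface$df_grid), function(i) {
    y <- surface$raw[i, ]
    eps <- .TIE_RTOL * max(abs(y))
    ties <- surface$phase_grid[y <= min(y) + eps]
    data.frame(duty_factor = surface$df_grid[i],
               phase = min(ties),
               cost = min(y),
               cost_normalized = surface$normalized[i, which.min(y)],
               tie = length(ties) > 1L,
               tie_phases = paste(ties, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  attr(out, "local_minima") <- lapply(seq_along(surface$df_grid), function(i) {
    y <- surface$raw[i, ]
    idx <- .circular_minima_idx(y, .TIE_RTOL * max(abs(y)))
    if (is.null(idx)) numeric(0) else surface$phase_grid[idx]
  })
  class(out) <- c("minima_line", "data.frame")
  out
}

# which symmetric minima family the global row minimum is closest to,
# by circular distance: "05" = {0, 50}, "2575" = {25, 75}
.minima_family <- function(config, duty_factor, phase_grid) {
  cfg <- config
  cfg$duty_factor <- duty_factor
  costs <- .row_costs(cfg, phase_grid)
  pm <- phase_grid[which.min(costs)]
  circ <- function(a, b) pmin(abs(a - b), 100 - abs(a - b))
  if (min(circ(pm, c(0, 50))) < min(circ(pm, c(25, 75)))) "05" else "2575"
}

#' Critical duty factor of the minima-family switch
#'
#' For variants without medial forces the work-minimizing phases come in the
#' two symmetric families \{0, 50\} and \{25, 75\}, and the favored family
#' switches once as the duty factor crosses a critical value (near 0.75 for
#' the base variant, slightly higher for larger fore-aft amplitudes, and with
#' the families exchanged for suspended progression). This function locates
#' the switch by bisection on the duty factor.
#'
#' @param variant A planar (zero `medial_ratio`) [gait_config()] template, or
#'   a variant name for [gait_variant()].
#' @param tolerance Bisection tolerance on the duty factor (default 0.002).
#' @param df_range Search interval, default `c(0.55, 0.95)`; an error is
#'   raised if both ends favor the same family.
#' @param phase_step Phase grid step used to classify each row (default 0.5).
#' @param ... Passed to [gait_variant()] when `variant` is a name.
#' @return The switch duty factor, to within `tolerance`.
#' @export
#' @examples
#' \donttest{
#' critical_duty_factor("base")  # about 0.75-0.77
#' }
critical_duty_factor <- function(variant, tolerance = 0.002,
                                 df_range = c(0.55, 0.95), phase_step = 0.5,
                                 ...) {
  config <- if (is.character(variant)) gait_variant(variant, ...) else variant
  stopifnot(inherits(config, "gait_config"))
  if (config$medial_ratio != 0)
    stop("critical_duty_factor requires a variant without medial forces ",
         "(symmetric minima families)")
  if (tolerance <= 0) stop("tolerance must be positive")
  phases <- seq(0, 100 - phase_step, by = phase_step)
  lo <- df_range[1]; hi <- df_range[2]
  f_lo <- .minima_family(config, lo, phases)
  f_hi <- .minima_family(config, hi, phases)
  if (f_lo == f_hi)
    stop("no minima-family switch inside (", lo, ", ", hi, ")")
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (.minima_family(config, mid, phases) == f_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
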