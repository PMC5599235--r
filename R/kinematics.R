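#' Validated footfall event log
#'
#' Constructs a footfall event table from per-limb contact and lift times,
#' checking the structural invariants the gait estimators rely on: known limb
#' ids, events alternating contact/lift within each limb, and strictly
#' increasing times per limb.
#'
#' @param data Data frame with columns `limb` (`LH`, `LF`, `RH`, `RF`),
#'   `event` (`contact` or `lift`) and `time_s` (seconds).
#' @return The validated data frame, ordered by time, with class
#'   `footfall_events`.
#' @export
#' @examples
#' ev <- footfall_events(data.frame(
#'   limb = c("LH", "LH", "LH"), event = c("contact", "lift", "contact"),
#'   time_s = c(0, 0.7, 1)))
#' duty_factor_from_events(ev)
footfall_events <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("limb", "event", "time_s") %in% names(data)))
  data$limb <- as.character(data$limb)
  data$event <- as.character(data$event)
  if (!all(data$limb %in% .LIMBS))
    stop("limb must be one of ", paste(.LIMBS, collapse = ", "))
  if (!all(data$event %in% c("contact", "lift")))
    stop("event must be 'contact' or 'lift'")
  if (!is.numeric(data$time_s) || anyNA(data$time_s))
    stop("time_s must be numeric and complete")
  data <- data[order(data$time_s), , drop = FALSE]
  for (l in unique(data$limb)) {
    ev <- data[data$limb == l, ]
    if (any(diff(ev$time_s) <= 0))
      stop("event times for limb ", l, " are not strictly increasing")
    if (any(ev$event[-1] == ev$event[-nrow(ev)]))
      stop("events for limb ", l, " do not alternate contact/lift")
  }
  rownames(data) <- NULL
  class(data) <- c("footfall_events", "data.frame")
  data
}

#' Read a footfall event CSV
#'
#' @param path CSV file with columns `limb`, `event`, `time_s`.
#' @return A [footfall_events()] object.
#' @export
read_footfall_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  footfall_events(read.csv(path, stringsAsFactors = FALSE))
}

# event times of one limb/event kind
.event_times <- function(events, limb, kind) {
  events$time_s[events$limb == limb & events$event == kind]
}

#' Duty factor from footfall events
#'
#' The proportion of the stride cycle the reference limb spends in ground
#' contact: (contact duration) / (stride period), averaged over all complete
#' strides of the record. The hind limb is the conventional reference.
#'
#' @param events A [footfall_events()] record spanning at least one complete
#'   stride of the reference limb (two contacts).
#' @param limb Reference limb, default `"LH"`.
#' @return Duty factor (arithmetic mean over strides).
#' @export
duty_factor_from_events <- function(events, limb = "LH") {
  stopifnot(inherits(events, "footfall_events"))
  limb <- match.arg(limb, .LIMBS)
  contacts <- .event_times(events, limb, "contact")
  lifts <- .event_times(events, limb, "lift")
  if (length(contacts) < 2L)
    stop("at least two contacts of limb ", limb,
         " are required to define a stride period")
  per_stride <- vapply(seq_len(length(contacts) - 1L), function(i) {
    l <- lifts[lifts > contacts[i] & lifts < contacts[i + 1L]]
    if (length(l) != 1L)
      stop("no lift of limb ", limb, " between contacts at ",
           contacts[i], " and ", contacts[i + 1L])
    (l - contacts[i]) / (contacts[i + 1L] - contacts[i])
  }, numeric(1))
  mean(per_stride)
}

#' Limb phase from footfall events
#'
#' Hildebrand limb phase: the percentage of the stride period by which the
#' ipsilateral forefoot contact follows the hindfoot contact, averaged over
#' the complete hind-limb strides of the record.
#'
#' @param events A [footfall_events()] record.
#' @param side `"left"` or `"right"` (which ipsilateral pair to use).
#' @return Phase in percent, in `[0, 100)`.
#' @export
limb_phase_from_events <- function(events, side = c("left", "right")) {
  stopifnot(inherits(events, "footfall_events"))
  side <- match.arg(side)
  hind <- if (side == "left") "LH" else "RH"
  fore <- if (side == "left") "LF" else "RF"
  hc <- .event_times(events, hind, "contact")
  fc <- .event_times(events, fore, "contact")
  if (length(hc) < 2L)
    stop("at least two contacts of limb ", hind,
         " are required to measure the stride period")
  per_stride <- vapply(seq_len(length(hc) - 1L), function(i) {
    period <- hc[i + 1L] - hc[i]
    f <- fc[fc >= hc[i] & fc < hc[i + 1L]]
    if (!length(f))
      stop("no ", fore, " contact within one stride of the ", hind,
           " contact at ", hc[i])
    100 * ((f[1L] - hc[i]) %% period) / period
  }, numeric(1))
  mean(per_stride) %% 100
}

#' Packaged species gait table
#'
#' Median walking duty factor and limb phase for 52 quadrupedal species, with
#' the printed two-group classification (group 1: high duty factor, phase
#' 40-50%, including reptiles, amphibians, mouse and hippo; group 2: the
#' "normal mammalian" grouping with lower duty factor and phase around or
#' below 25%), observation counts and, where multiple observations exist,
#' standard deviations.
#'
#' @param path Optional path to an alternative CSV with the same columns;
#'   default is the table shipped with the package.
#' @return Data frame of class `species_table` with columns `species`,
#'   `group`, `median_duty_factor`, `median_phase_pct`, `n`,
#'   `sd_duty_factor`, `sd_phase_pct`.
#' @export
#' @examples
#' tab <- load_species_table()
#' nrow(tab)  # 52
load_species_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "species_gaits.csv", package = "quadgait")
  if (!nzchar(path) || !file.exists(path))
    stop("species gait table not found")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "group", "median_duty_factor", "median_phase_pct", "n")
  if (!all(need %in% names(tab)))
    stop("species gait table is corrupt: missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (any(tab$median_duty_factor <= 0.5 | tab$median_duty_factor >= 1))
    stop("species gait table is corrupt: duty factors outside (0.5, 1)")
  if (any(tab$median_phase_pct < 0 | tab$median_phase_pct >= 100) ||
      any(tab$n < 1))
    stop("species gait table is corrupt: invalid phase or n")
  class(tab) <- c("species_table", "data.frame")
  tab
}

#' Two-group k-means classification of gait parameters
#'
#' Clusters species records into two groups on (median duty factor, median
#' phase). Features are z-score standardized before clustering so the
#' percent-scale phase does not dominate the Euclidean distance; the run is
#' seeded and restarted 50 times. Cluster 1 is, by convention, the cluster
#' with the higher mean duty factor.
#'
#' @param records Data frame with columns `median_duty_factor` and
#'   `median_phase_pct` (e.g. [load_species_table()] or
#'   [generate_species_ensemble()]).
#' @param seed Random seed for the restarts.
#' @return Integer vector of group labels (1 or 2), named by species when a
#'   `species` column is present.
#' @export
#' @examples
#' tab <- load_species_table()
#' table(kmeans_two_groups(tab, seed = 17), tab$group)
kmeans_two_groups <- function(records, seed = 1) {
  stopifnot(is.data.frame(records),
            all(c("median_duty_factor", "median_phase_pct") %in%
                  names(records)))
  if (nrow(records) < 2L) stop("at least two records are required")
  x <- cbind(records$median_duty_factor, records$median_phase_pct)
  if (nrow(unique(x)) < 2L)
    stop("degenerate input: all records are identical points")
  xs <- apply(x, 2L, function(col) {
    s <- sd(col)
    if (s == 0) col - mean(col) else (col - mean(col)) / s
  })
  set.seed(seed)
  km <- kmeans(xs, centers = 2L, nstart = 50L)
  hi <- which.max(tapply(records$median_duty_factor, km$cluster, mean))
  labels <- ifelse(km$cluster == hi, 1L, 2L)
  if (!is.null(records$species)) names(labels) <- records$species
  labels
}

#' Phase-on-duty-factor regression
#'
#' Unweighted ordinary least squares of median limb phase (%) on median duty
#' factor across species records. On the packaged table this reproduces the
#' relationship phase ~ 130 DF - 66.
#'
#' @param records Data frame with columns `median_duty_factor` and
#'   `median_phase_pct`; at least 3 rows.
#' @return List with `slope`, `intercept` and the fitted `model`.
#' @export
#' @examples
#' fit <- fit_phase_df_regression(load_species_table())
#' c(fit$slope, fit$intercept)
fit_phase_df_regression <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("median_duty_factor", "median_phase_pct") %in%
                  names(records)))
  if (nrow(records) < 3L) stop("at least three records are required")
  fit <- lm(median_phase_pct ~ median_duty_factor, data = records)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       model = fit)
}
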