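# independent oracles used across tests

# brute-force weight-supporting amplitude: sample four overlapping unit
# half-sines on a fine grid and solve for the amplitude whose stride-mean
# total equals gravity
oracle_vertical_amplitude <- function(duty_factor, gravity = 1,
                                      phase_pct = 25, n = 20001) {
  tf <- seq(0, 1, length.out = n)
  onsets <- c(0, phase_pct / 100, 0.5, (0.5 + phase_pct / 100) %% 1)
  total <- rowSums(sapply(onsets, function(o) {
    u <- (tf - o) %% 1
    ifelse(u < duty_factor, sin(pi * u / duty_factor), 0)
  }))
  mean_unit <- pracma::trapz(tf, total)  # stride-mean of unit-amplitude total
  gravity / mean_unit
}

# straight-line species records for exact-fit regression checks
records_on_line <- function(slope, intercept, df = seq(0.6, 0.9, by = 0.05)) {
  data.frame(median_duty_factor = df,
             median_phase_pct = slope * df + intercept)
}

# event log built directly from explicit times
events_from_times <- function(...) {
  rows <- list(...)
  footfall_events(do.call(rbind, lapply(rows, function(r)
    data.frame(limb = r[[1]], event = r[[2]],
               time_s = as.numeric(r[[3]])))))
}
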