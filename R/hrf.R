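#' Canonical double-gamma hemodynamic response function
#'
#' The standard SPM-style parameterization: a gamma density peaking near
#' 5 s minus a scaled gamma undershoot near 15 s, rescaled to unit peak.
#'
#' @param t_seconds time(s) since the driving event, in seconds (`t >= 0`)
#' @param peak_delay,undershoot_delay gamma shape parameters (rate 1/s)
#' @param undershoot_ratio relative amplitude of the undershoot
#' @return response amplitude(s); `canonical_hrf(0)` is 0
#' @export
canonical_hrf <- function(t_seconds, peak_delay = 6, undershoot_delay = 16,
                          undershoot_ratio = 1 / 6) {
  stopifnot(all(t_seconds >= 0))
  h <- function(t) {
    stats::dgamma(t, shape = peak_delay, rate = 1) -
      undershoot_ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
  }
  grid <- seq(0, 32, by = 0.01)
  h(t_seconds) / max(h(grid))
}

# Convolve per-event boxcars with the canonical HRF and sample at frame
# times. `onsets`/`durations` in seconds on the same clock as `frame_times`.
convolve_events <- function(onsets, durations, frame_times, dt = 0.1) {
  if (length(onsets) == 0) return(numeric(length(frame_times)))
  t_max <- max(frame_times) + dt
  n <- ceiling(t_max / dt) + 1
  stim <- numeric(n)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1
    b <- min(n, ceiling((onsets[i] + max(durations[i], dt)) / dt))
    stim[a:b] <- stim[a:b] + 1
  }
  hk <- canonical_hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(stim, rev(hk), type = "open")[seq_len(n)] * dt
  conv[pmin(n, floor(frame_times / dt) + 1)]
}
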