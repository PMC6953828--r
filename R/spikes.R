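#' Detect spike potentials in an impedance waveform
#'
#' Spikes lack an agreed objective definition; this package operationalizes
#' them as brief excursions of the residual after removing the respiratory
#' component. The respiratory trend is estimated in two stages: a short
#' running median (7 samples) deletes transients of a few frames, then a
#' Savitzky-Golay quadratic smoother (window about 20% of the respiratory
#' period) tracks the tidal swing -- including its peaks and troughs, where
#' a plain moving median or average leaves curvature bumps that masquerade
#' as events. The residual (original minus trend) is matched-filtered with a
#' three-frame moving average -- the width of a cardiac transient -- and
#' samples exceeding `k_mad` times the MAD of that filtered residual are
#' flagged; flags closer than `refractory_s` are merged into a single event
#' at the extremal sample.
#' Both polarities are reported (cardiac heart-wall contact produces
#' impedance drops; air entry produces rises).
#'
#' @param waveform a waveform object (`samples`, `frame_rate`) or numeric
#'   vector (then `frame_rate` is required)
#' @param k_mad threshold in MAD units (default 4)
#' @param refractory_s merge window in seconds (default 0.25)
#' @param respiratory_period_s respiratory period, seconds (default 3,
#'   i.e. 20 breaths/min); the smoothing window is 20% of it
#' @param frame_rate Hz for bare vectors
#' @return data.frame with columns `frame_index`, `amplitude` (absolute
#'   residual), `polarity` ("drop" or "rise"); zero rows when quiet
#' @export
detect_spikes <- function(waveform, k_mad = 4, refractory_s = 0.25,
                          respiratory_period_s = 3, frame_rate = NULL) {
  if (inherits(waveform, "roi_waveform")) {
    x <- waveform$samples; fs <- waveform$frame_rate
  } else {
    x <- as.numeric(waveform)
    if (is.null(frame_rate)) stop("frame_rate required for a bare vector")
    fs <- frame_rate
  }
  if (length(x) < 10 * fs) stop("need at least 10 s of signal")

  kd <- min(7L, length(x) - (1 - length(x) %% 2))
  despiked <- stats::runmed(x, kd)
  k <- max(11L, round(0.2 * respiratory_period_s * fs))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, length(x))
  trend <- sg_smooth(despiked, k)
  res <- x - trend
  # matched filter for ~3-frame transients
  rs <- as.numeric(stats::filter(c(res[1], res, res[length(res)]),
                                 rep(1 / 3, 3), sides = 2))[2:(length(res) + 1)]
  m <- stats::mad(rs)
  if (m == 0) m <- .Machine$double.eps
  flag <- which(abs(rs) > k_mad * m)
  # trend estimates inside one smoothing window of either end rest on
  # padded data; excursions there are not trustworthy
  flag <- flag[flag > k & flag <= length(x) - k]
  if (!length(flag))
    return(data.frame(frame_index = integer(0), amplitude = numeric(0),
                      polarity = character(0), stringsAsFactors = FALSE))

  gap <- max(1L, round(refractory_s * fs))
  grp <- cumsum(c(1L, diff(flag) > gap))
  out <- do.call(rbind, lapply(split(flag, grp), function(ix) {
    j <- ix[which.max(abs(res[ix]))]
    data.frame(frame_index = j, amplitude = abs(res[j]),
               polarity = if (res[j] < 0) "drop" else "rise",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Savitzky-Golay quadratic smoothing by convolution; ends are padded by
# repeating the terminal values.
#' @keywords internal
sg_smooth <- function(x, k) {
  m <- (k - 1L) %/% 2L
  i <- -m:m
  X <- cbind(1, i, i^2)
  w <- (solve(crossprod(X)) %*% t(X))[1, ]
  xp <- c(rep(x[1], m), x, rep(x[length(x)], m))
  as.numeric(stats::filter(xp, rev(w), sides = 2))[(m + 1):(m + length(x))]
}

#' Spike event rate and dominant inter-event interval
#'
#' @param events data.frame from [detect_spikes()]
#' @param frame_rate Hz
#' @param duration recording length in seconds (> 0)
#' @return list: `rate_per_min`, `dominant_interval_s` (median inter-event
#'   interval; NA with fewer than 2 events)
#' @export
spike_rate <- function(events, frame_rate, duration) {
  if (duration <= 0) stop("duration must be positive")
  n <- nrow(events)
  interval <- if (n >= 2)
    stats::median(diff(sort(events$frame_index))) / frame_rate
  else NA_real_
  list(rate_per_min = 60 * n / duration, dominant_interval_s = interval)
}

#' Does the spike rate match the cardiac frequency?
#'
#' TRUE when at least 3 events were seen and the event rate is within
#' `tolerance_frac` of the heart rate.
#'
#' @param analysis list with `rate_per_min` and `n_events` (or the
#'   `spike_analysis` object from [analyze_spikes()])
#' @param heart_rate beats per minute (> 0)
#' @param tolerance_frac relative tolerance (default 0.1)
#' @return logical
#' @export
cardiac_match <- function(analysis, heart_rate, tolerance_frac = 0.1) {
  if (heart_rate <= 0) stop("heart_rate must be positive")
  if (is.null(analysis$n_events) || analysis$n_events < 3) return(FALSE)
  abs(analysis$rate_per_min - heart_rate) <= tolerance_frac * heart_rate
}

#' Full spike-potential analysis of a waveform
#'
#' Convenience wrapper: [detect_spikes()], [spike_rate()] and, when a heart
#' rate is supplied, [cardiac_match()].
#'
#' @inheritParams detect_spikes
#' @param heart_rate beats/min for cardiac matching (NA to skip)
#' @param tolerance_frac relative tolerance for the cardiac match
#' @return object of class `spike_analysis`: `events`, `n_events`,
#'   `rate_per_min`, `dominant_interval_s`, `cardiac_match`,
#'   `heart_rate_used`
#' @export
analyze_spikes <- function(waveform, heart_rate = NA, k_mad = 4,
                           refractory_s = 0.25, respiratory_period_s = 3,
                           tolerance_frac = 0.1, frame_rate = NULL) {
  fs <- if (inherits(waveform, "roi_waveform")) waveform$frame_rate
        else frame_rate
  nsamp <- if (inherits(waveform, "roi_waveform"))
    length(waveform$samples) else length(waveform)
  ev <- detect_spikes(waveform, k_mad = k_mad, refractory_s = refractory_s,
                      respiratory_period_s = respiratory_period_s,
                      frame_rate = frame_rate)
  sr <- spike_rate(ev, fs, nsamp / fs)
  res <- list(events = ev, n_events = nrow(ev),
              rate_per_min = sr$rate_per_min,
              dominant_interval_s = sr$dominant_interval_s,
              heart_rate_used = heart_rate)
  res$cardiac_match <- if (is.na(heart_rate)) NA else
    cardiac_match(res, heart_rate, tolerance_frac)
  structure(res, class = "spike_analysis")
}
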