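#' Dynamics configuration for a simulated EIT recording
#'
#' Defaults describe a mechanically ventilated pig: 50 Hz acquisition over
#' three minutes, respiratory rate 20/min, heart rate 90/min, a 30%
#' fractional tidal conductivity swing of lung tissue, and additive Gaussian
#' tissue noise with SD equal to 1% of the background conductivity. By
#' default there is no gas movement inside a lesion
#' (`lesion_ventilation_fraction = 0`): entrapped pleural air produces a
#' static ventilation defect.
#'
#' @param frame_rate frames per second (Hz)
#' @param duration recording length, seconds
#' @param respiratory_rate breaths per minute
#' @param tidal_modulation fractional conductivity swing of lung tissue per
#'   breath (0-1)
#' @param heart_rate beats per minute
#' @param spike_enabled inject cardiac conductivity transients when a lesion
#'   allows heart / chest-wall contact
#' @param spike_magnitude fractional conductivity increase along the
#'   heart-chest-wall path during a spike. The default 0.5 is the relative
#'   step from soft tissue (0.4 S/m) to blood/myocardium (0.6 S/m): systolic
#'   contact replaces the tissue path with near-blood conductivity
#' @param lesion_ventilation_fraction in `[0, 1]`; 0 means no gas movement in
#'   the lesion, 1 means gas swings comparable to lung tidal swings
#' @param lesion_phase_lag radians; phase shift of lesion gas movement
#'   relative to tidal ventilation (asynchrony)
#' @param noise_sd_frac additive Gaussian conductivity noise SD as a fraction
#'   of the background conductivity
#' @param seed integer seed for the noise stream
#' @return object of class `dynamics_config`
#' @export
dynamics_config <- function(frame_rate = 50,
                            duration = 180,
                            respiratory_rate = 20,
                            tidal_modulation = 0.3,
                            heart_rate = 90,
                            spike_enabled = FALSE,
                            spike_magnitude = 0.5,
                            lesion_ventilation_fraction = 0,
                            lesion_phase_lag = 0,
                            noise_sd_frac = 0.01,
                            seed = 1L) {
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (lesion_ventilation_fraction < 0 || lesion_ventilation_fraction > 1)
    stop("lesion_ventilation_fraction must be in [0, 1]")
  structure(list(frame_rate = frame_rate, duration = duration,
                 respiratory_rate = respiratory_rate,
                 tidal_modulation = tidal_modulation,
                 heart_rate = heart_rate,
                 spike_enabled = isTRUE(spike_enabled),
                 spike_magnitude = spike_magnitude,
                 lesion_ventilation_fraction = lesion_ventilation_fraction,
                 lesion_phase_lag = lesion_phase_lag,
                 noise_sd_frac = noise_sd_frac,
                 seed = as.integer(seed)),
            class = "dynamics_config")
}

#' Baseline (end-expiration) conductivity field of a phantom
#'
#' @param phantom a `thorax_phantom`
#' @param lesions optional list of `ptx_lesion`; each contributes a
#'   partial-volume-attenuated air-like region
#' @return numeric matrix of conductivities (S/m), NA outside the body
#' @export
baseline_field <- function(phantom, lesions = list()) {
  sig <- matrix(NA_real_, phantom$grid_shape, phantom$grid_shape)
  sig[phantom$body_mask] <- phantom$background_conductivity
  lung <- phantom$lung_masks$right | phantom$lung_masks$left |
    phantom$lung_masks$accessory
  sig[lung] <- phantom$lung_conductivity_expiration
  sig[phantom$heart_mask] <- phantom$heart_conductivity
  for (les in lesions) {
    w <- partial_volume_weight(les$craniocaudal_extent)
    sig[les$in_plane_mask] <- w * les$conductivity +
      (1 - w) * phantom$lung_conductivity_expiration
  }
  sig
}

#' Time-resolved conductivity series with respiratory and cardiac dynamics
#'
#' Lung conductivity oscillates between its end-expiration value and
#' `(1 - tidal_modulation)` times that value at the respiratory rate
#' (inspiration lowers conductivity). Lesion pixels take an air-like
#' conductivity attenuated by the partial-volume weight; gas movement inside
#' the lesion modulates this mixing toward lung tissue with amplitude
#' `lesion_ventilation_fraction * tidal_modulation`, phase-shifted by
#' `lesion_phase_lag`. When spikes are enabled and a lesion permits
#' heart / chest-wall contact, a <= 3-frame conductivity-increase transient
#' along the heart-to-sternum path is injected once per cardiac cycle.
#'
#' @param phantom a `thorax_phantom`
#' @param lesions list of `ptx_lesion` (possibly empty)
#' @param dynamics a `dynamics_config`
#' @return object of class `cond_series`: `sigma` (n_body_pixels x n_frames),
#'   `mask` (body mask), `body_index` (pixel indices of rows of `sigma`),
#'   `phantom`, `dynamics`, `times`, and `spike_frames` (first frame of each
#'   injected transient; integer(0) if none)
#' @export
conductivity_series <- function(phantom, lesions = list(),
                                dynamics = dynamics_config()) {
  stopifnot(inherits(phantom, "thorax_phantom"),
            inherits(dynamics, "dynamics_config"))
  truth <- case_truth(phantom, lesions)
  if (dynamics$spike_enabled && length(lesions) == 0)
    stop("spikes require heart contact: provide at least one lesion")

  n <- phantom$grid_shape
  nt <- round(dynamics$frame_rate * dynamics$duration)
  times <- (seq_len(nt) - 1) / dynamics$frame_rate
  body <- which(phantom$body_mask)

  base <- baseline_field(phantom)
  lung <- (phantom$lung_masks$right | phantom$lung_masks$left |
             phantom$lung_masks$accessory)
  les_all <- matrix(FALSE, n, n)
  for (les in lesions) les_all <- les_all | les$in_plane_mask
  lung_free <- lung & !les_all

  # respiratory phase signal, 0 at end-expiration, 1 at end-inspiration
  fr <- dynamics$respiratory_rate / 60
  s_t <- (1 - cos(2 * pi * fr * times)) / 2

  sig0 <- base[body]
  is_lung <- lung_free[body]
  sigma <- matrix(rep(sig0, nt), length(body), nt)
  # lung pixels swing from sigma_exp down to (1 - tidal_modulation) * sigma_exp
  sigma[is_lung, ] <- outer(rep(phantom$lung_conductivity_expiration,
                                sum(is_lung)),
                            1 - dynamics$tidal_modulation * s_t)

  # Lesion pixels are a partial-volume mixture: the fraction w of the
  # EIT-sensitive slab occupied by pleural air is static (or modulated by
  # gas movement when lesion_ventilation_fraction > 0), while the remaining
  # (1 - w) is out-of-plane lung that keeps ventilating -- which is exactly
  # the partial volume effect attenuating small-cc lesions.
  if (length(lesions)) {
    s_lag <- (1 - cos(2 * pi * fr * times - dynamics$lesion_phase_lag)) / 2
    sig_exp <- phantom$lung_conductivity_expiration
    lungt <- sig_exp * (1 - dynamics$tidal_modulation * s_t)
    for (les in lesions) {
      w <- partial_volume_weight(les$craniocaudal_extent)
      idx <- which(les$in_plane_mask[phantom$body_mask])
      core <- les$conductivity +
        dynamics$lesion_ventilation_fraction * dynamics$tidal_modulation *
        (sig_exp - les$conductivity) * (1 - s_lag)
      vals <- (1 - w) * lungt + w * core
      sigma[idx, ] <- matrix(rep(vals, each = length(idx)), length(idx), nt)
    }
  }

  # cardiac spikes: brief conductivity increase on the heart-chest-wall path
  spike_frames <- integer(0)
  if (dynamics$spike_enabled && truth$heart_contact) {
    path <- heart_wall_path(phantom)
    pidx <- which(path[phantom$body_mask])
    fh <- dynamics$heart_rate / 60
    beat_t <- seq(0.3, dynamics$duration, by = 1 / fh)
    dmag <- dynamics$spike_magnitude * phantom$background_conductivity
    # systolic contact lasts ~0.06 s: <= 3 frames at the native 50 Hz rate
    nf <- max(1L, min(3L, round(0.06 * dynamics$frame_rate)))
    for (bt in beat_t) {
      f0 <- floor(bt * dynamics$frame_rate) + 1
      ff <- f0:min(f0 + nf - 1L, nt)
      ff <- ff[ff >= 1 & ff <= nt]
      if (!length(ff)) next
      sigma[pidx, ff] <- sigma[pidx, ff] + dmag
      spike_frames <- c(spike_frames, ff[1])
    }
  }

  # measurement-independent tissue noise
  if (dynamics$noise_sd_frac > 0) {
    sdn <- dynamics$noise_sd_frac * phantom$background_conductivity
    noise <- local_rng(dynamics$seed, function()
      matrix(rnorm(length(body) * nt, 0, sdn), length(body), nt))
    sigma <- sigma + noise
  }
  sigma[sigma <= 0] <- 1e-4  # conductivity must stay positive

  structure(list(sigma = sigma, mask = phantom$body_mask, body_index = body,
                 phantom = phantom, dynamics = dynamics, truth = truth,
                 times = times, spike_frames = spike_frames),
            class = "cond_series")
}

# Strip of body pixels between the heart and the ventral chest wall.
#' @keywords internal
heart_wall_path <- function(phantom) {
  n <- phantom$grid_shape
  h <- which(phantom$heart_mask, arr.ind = TRUE)
  hc <- colMeans(h)
  hr_top <- min(h[, 1])
  path <- matrix(FALSE, n, n)
  cols <- max(1, round(hc[2]) - 2):min(n, round(hc[2]) + 2)
  rows <- seq_len(max(1, hr_top))
  path[rows, cols] <- TRUE
  path & phantom$body_mask & !phantom$heart_mask
}

#' Extract one frame of a conductivity series as a full grid
#'
#' @param series a `cond_series`
#' @param t frame index
#' @return conductivity matrix (NA outside the body)
#' @export
series_field <- function(series, t) {
  stopifnot(inherits(series, "cond_series"))
  n <- series$phantom$grid_shape
  sig <- matrix(NA_real_, n, n)
  sig[series$body_index] <- series$sigma[, t]
  sig
}
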