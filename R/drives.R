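# Theta-nested external drives.
#
# EC2/EC3 are inhomogeneous Poisson sources whose rate is a theta envelope
# multiplied by a faster gamma carrier; the two layers are locked in
# antiphase (strong EC2 input coincides with weak EC3 input).  The septal
# source is a deterministic theta-locked burst generator modelling the
# disinhibitory GABAergic projection onto hippocampal interneurons.

#' Specify a theta/gamma-patterned external drive
#'
#' @param source `"EC2"`, `"EC3"` or `"septum"`.
#' @param theta_frequency Theta frequency in Hz, within 4-12.
#' @param gamma_frequency Gamma carrier frequency in Hz (must exceed theta).
#' @param theta_phase_offset Theta phase of this source, radians.
#' @param mean_rate Time-averaged rate per target, spikes/s.
#' @param theta_depth,gamma_depth Modulation depths in `[0, 1]`.
#' @param seed_offset Offset mixed into the simulation seed so each source
#'   has an independent stream.
#' @return A list of class `drive_spec`.
#' @export
drive_spec <- function(source = c("EC2", "EC3", "septum"),
                       theta_frequency = 8, gamma_frequency = 40,
                       theta_phase_offset = 0, mean_rate = 40,
                       theta_depth = 1, gamma_depth = 0.5, seed_offset = 0) {
  source <- match.arg(source)
  if (theta_frequency < 4 || theta_frequency > 12)
    stopf("theta_frequency must lie in the 4-12 Hz theta band")
  if (gamma_frequency <= theta_frequency)
    stopf("gamma_frequency must exceed theta_frequency")
  assert_scalar_num(mean_rate, "mean_rate", lower = 1e-12)
  structure(list(source = source, theta_frequency = theta_frequency,
                 gamma_frequency = gamma_frequency,
                 theta_phase_offset = theta_phase_offset,
                 mean_rate = mean_rate, theta_depth = theta_depth,
                 gamma_depth = gamma_depth, seed_offset = seed_offset),
            class = "drive_spec")
}

.drive_rate <- function(drive, t_ms) {
  th <- 2 * pi * drive$theta_frequency * t_ms / 1000 - drive$theta_phase_offset
  ga <- 2 * pi * drive$gamma_frequency * t_ms / 1000
  drive$mean_rate / 1000 *
    (1 + (drive$theta_depth %||% 1) * cos(th)) *
    (1 + (drive$gamma_depth %||% 0.5) * cos(ga))
}

#' Generate theta-nested Poisson drive spike trains
#'
#' Draws one independent inhomogeneous Poisson train per target by thinning
#' a homogeneous train at the peak rate.  The rate is
#' `mean_rate * (1 + d_theta cos(theta)) * (1 + d_gamma cos(gamma))`, so
#' spikes cluster in gamma packets riding the theta envelope.  Identical
#' seeds give identical trains.
#'
#' @param drive A `drive_spec` (or the equivalent named list).
#' @param n_targets Number of independent trains to draw.
#' @param duration Duration in ms (at least one theta period).
#' @param dt Unused by the generator (spike times are continuous) but kept
#'   for interface symmetry with the integrator.
#' @param seed Integer seed.
#' @return A list of `n_targets` numeric vectors of spike times in ms,
#'   each sorted and within `[0, duration)`.
#' @export
#' @examples
#' d <- drive_spec("EC2", mean_rate = 20)
#' trains <- generate_drive_trains(d, 3, duration = 500, seed = 1)
generate_drive_trains <- function(drive, n_targets, duration, dt = 0.1,
                                  seed = 1L) {
  if (duration < 1000 / drive$theta_frequency)
    stopf("duration must cover at least one theta period")
  if (identical(drive$source, "septum"))
    return(septal_trains(drive, n_targets, duration))
  rmax <- drive$mean_rate / 1000 *
    (1 + (drive$theta_depth %||% 1)) * (1 + (drive$gamma_depth %||% 0.5))
  withr::with_seed(seed, {
    lapply(seq_len(n_targets), function(i) {
      n_cand <- rpois(1, rmax * duration)
      cand <- sort(runif(n_cand, 0, duration))
      keep <- runif(n_cand) < .drive_rate(drive, cand) / rmax
      cand[keep]
    })
  })
}

#' Deterministic septal theta burst trains
#'
#' The medial-septal GABAergic population is modelled as a deterministic
#' pacemaker: on every theta cycle each target receives a short burst of
#' spikes at a fixed theta phase, rhythmically silencing interneurons and
#' thereby imposing theta-locked disinhibition on the principal cells.
#'
#' @param drive Drive list with `theta_frequency`, `theta_phase_offset`,
#'   `spikes_per_cycle` and `intra_burst_isi` (ms).
#' @param n_targets Number of (identical) trains.
#' @param duration Duration in ms.
#' @return List of spike-time vectors.
#' @export
septal_trains <- function(drive, n_targets, duration) {
  period <- 1000 / drive$theta_frequency
  k <- drive$spikes_per_cycle %||% 4
  isi <- drive$intra_burst_isi %||% 3
  phase_ms <- (drive$theta_phase_offset %||% 0) / (2 * pi) * period
  onsets <- seq(phase_ms, duration, by = period)
  times <- as.vector(outer(onsets, (0:(k - 1)) * isi, `+`))
  times <- sort(times[times >= 0 & times < duration])
  rep(list(times), n_targets)
}

#' Circular mean phase of spike times with respect to an oscillation
#'
#' @param times Spike times, ms.
#' @param frequency Oscillation frequency, Hz.
#' @return Mean phase in radians, in `(-pi, pi]`.
#' @export
circular_mean_phase <- function(times, frequency) {
  ph <- 2 * pi * frequency * times / 1000
  Arg(mean(exp(1i * ph)))
}
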