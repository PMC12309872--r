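#' PCASL labeling pulse-train parameters
#'
#' Container for the parameters of the PCASL labeling pulse train: the
#' slice-selective gradient played during each RF pulse, the mean gradient
#' over one RF interval (which sets the aliased labeling-plane spacing), the
#' RF pulse duration and repetition interval, and the per-pulse flip angle.
#'
#' @param g_max Gradient amplitude during the RF pulses, mT/m.
#' @param g_mean Mean gradient over one RF interval, mT/m. Must not exceed
#'   `g_max`.
#' @param rf_duration RF pulse duration, microseconds.
#' @param rf_interval Interval from one RF pulse start to the next,
#'   microseconds. Must exceed `rf_duration`.
#' @param flip_angle On-resonance flip angle of a single labeling pulse,
#'   degrees.
#' @param rf_shape RF envelope identifier. Only `"hann"` is implemented.
#' @return An object of class `pcasl_params`.
#' @examples
#' optimal_pcasl_params()
#' duty_cycle(870, 1560)
#' @export
pcasl_params <- function(g_max, g_mean, rf_duration, rf_interval, flip_angle,
                         rf_shape = "hann") {
  stopifnot(is.numeric(g_max), is.numeric(g_mean), is.numeric(rf_duration),
            is.numeric(rf_interval), is.numeric(flip_angle))
  if (g_max <= 0) stop("g_max must be positive")
  if (g_mean <= 0 || g_mean > g_max) stop("g_mean must lie in (0, g_max]")
  if (rf_duration <= 0 || rf_duration >= rf_interval)
    stop("need 0 < rf_duration < rf_interval")
  if (flip_angle <= 0 || flip_angle >= 180)
    stop("flip_angle must lie in (0, 180) degrees")
  if (!identical(rf_shape, "hann"))
    stop("unsupported rf_shape: ", rf_shape)
  structure(list(g_max = g_max, g_mean = g_mean, rf_duration = rf_duration,
                 rf_interval = rf_interval, flip_angle = flip_angle,
                 rf_shape = rf_shape),
            class = "pcasl_params")
}

#' @export
print.pcasl_params <- function(x, ...) {
  cat("PCASL parameters:\n")
  cat(sprintf("  g_max       %6.2f mT/m\n", x$g_max))
  cat(sprintf("  g_mean      %6.2f mT/m\n", x$g_mean))
  cat(sprintf("  rf_duration %6.0f us\n", x$rf_duration))
  cat(sprintf("  rf_interval %6.0f us  (duty cycle %.1f%%)\n",
              x$rf_interval, 100 * duty_cycle(x$rf_duration, x$rf_interval)))
  cat(sprintf("  flip_angle  %6.1f deg (%s envelope)\n", x$flip_angle,
              x$rf_shape))
  cat(sprintf("  effective width %.2f mm, alias spacing %.1f mm\n",
              effective_width(x$g_max, x$rf_duration),
              aliasing_spacing(x$g_mean, x$rf_interval)))
  invisible(x)
}

#' Conventional ("default") PCASL labeling parameters
#'
#' The widely used neck-labeling parameter set: 6 mT/m maximum gradient,
#' 0.8 mT/m mean gradient, 500 us pulses every 1000 us, 20 degree flip angle.
#' @return A `pcasl_params` object.
#' @export
default_pcasl_params <- function() pcasl_params(6, 0.8, 500, 1000, 20)

#' Optimized thin-plane PCASL labeling parameters
#'
#' The thin labeling-plane parameter set selected by the grid search in
#' [optimize_pcasl()]: 9 mT/m maximum gradient, 0.45 mT/m mean gradient,
#' 870 us pulses every 1560 us, 30 degree flip angle. The effective labeling
#' width is just under 6 mm, which keeps tortuous vessels approximately
#' point-like within the labeling plane.
#' @return A `pcasl_params` object.
#' @export
optimal_pcasl_params <- function() pcasl_params(9, 0.45, 870, 1560, 30)

#' Relaxation properties of arterial blood
#'
#' @param t1 Longitudinal relaxation time, ms.
#' @param t2 Transverse relaxation time, ms. Must be shorter than `t1`.
#' @param gamma_bar Gyromagnetic ratio over two pi, MHz/T.
#' @return An object of class `blood_properties`.
#' @export
blood_properties <- function(t1 = 1650, t2 = 200,
                             gamma_bar = GAMMA_BAR_MHZ_T) {
  if (!(t1 > t2 && t2 > 0)) stop("need t1 > t2 > 0")
  if (gamma_bar <= 0) stop("gamma_bar must be positive")
  structure(list(t1 = t1, t2 = t2, gamma_bar = gamma_bar),
            class = "blood_properties")
}

#' RF duty cycle
#'
#' Fraction of each RF interval occupied by the pulse.
#' @param rf_duration RF pulse duration, microseconds.
#' @param rf_interval RF repetition interval, microseconds.
#' @return Duty cycle as a fraction in (0, 1).
#' @examples
#' duty_cycle(870, 1560) # 0.558
#' @export
duty_cycle <- function(rf_duration, rf_interval) {
  if (any(rf_duration <= 0) || any(rf_duration >= rf_interval))
    stop("need 0 < rf_duration < rf_interval")
  rf_duration / rf_interval
}

#' Effective width of the PCASL labeling plane
#'
#' The approximate effective labeling thickness `z = 2 / (gamma_bar * G_max *
#' RF_duration)`: twice the reciprocal of the excitation bandwidth expressed
#' as a distance under the slice-select gradient. Strictly decreasing in both
#' the gradient amplitude and the pulse duration.
#'
#' @param g_max Gradient amplitude during RF, mT/m.
#' @param rf_duration RF pulse duration, microseconds.
#' @param gamma_bar Gyromagnetic ratio over two pi, MHz/T.
#' @return Width in mm.
#' @examples
#' effective_width(9, 870)  # just under 6 mm
#' effective_width(6, 500)  # about 15.7 mm
#' @export
effective_width <- function(g_max, rf_duration,
                            gamma_bar = GAMMA_BAR_MHZ_T) {
  if (any(g_max <= 0) || any(rf_duration <= 0) || gamma_bar <= 0)
    stop("all arguments must be positive")
  # gamma_bar [Hz/T] * g [T/m] * dur [s] has units 1/m
  denom <- (gamma_bar * 1e6) * (g_max * 1e-3) * (rf_duration * 1e-6)
  2 / denom * 1e3
}

#' Spacing of aliased labeling planes
#'
#' The pulsed PCASL train replays the labeling condition wherever the
#' per-interval phase accrued under the mean gradient is a multiple of two
#' pi, producing aliased labeling planes at a regular spacing
#' `1 / (gamma_bar * G_mean * interval)`.
#'
#' @param g_mean Mean gradient over one RF interval, mT/m.
#' @param rf_interval RF repetition interval, microseconds.
#' @param gamma_bar Gyromagnetic ratio over two pi, MHz/T.
#' @return Alias spacing in mm.
#' @export
aliasing_spacing <- function(g_mean, rf_interval,
                             gamma_bar = GAMMA_BAR_MHZ_T) {
  if (any(g_mean <= 0) || any(rf_interval <= 0))
    stop("all arguments must be positive")
  denom <- (gamma_bar * 1e6) * (g_mean * 1e-3) * (rf_interval * 1e-6)
  1 / denom * 1e3
}

#' Search space for the PCASL parameter optimization
#'
#' Ranges, grid steps and constraint thresholds for [optimize_pcasl()].
#' Defaults are the published search: `g_max` 1.0-9.0 mT/m (0.5 steps),
#' `g_mean` 0.1-0.9 mT/m (0.05 steps), RF duration 50-950 us (10 us steps),
#' flip angle 8-30 degrees (2 degree steps), fixed 1560 us RF interval;
#' effective width below 6 mm, laminar-average inversion efficiency of at
#' least 85% for mean velocities 5-50 cm/s, and the first aliased labeling
#' plane at least 30 mm from the plane center.
#'
#' @param g_max,g_mean,rf_duration,flip_angle Numeric vectors of candidate
#'   grid values.
#' @param rf_interval Fixed RF interval, microseconds.
#' @param width_limit_mm Maximum admissible effective width, mm.
#' @param efficiency_floor Minimum admissible laminar-average inversion
#'   efficiency, fraction.
#' @param velocities_cm_s Mean velocities at which the efficiency floor is
#'   enforced, cm/s.
#' @param alias_min_mm Minimum admissible distance of the first aliased
#'   labeling plane from the plane center, mm.
#' @return An object of class `pcasl_search_space`.
#' @export
pcasl_search_space <- function(g_max = seq(1, 9, by = 0.5),
                               g_mean = seq(0.1, 0.9, by = 0.05),
                               rf_duration = seq(50, 950, by = 10),
                               flip_angle = seq(8, 30, by = 2),
                               rf_interval = 1560,
                               width_limit_mm = 6,
                               efficiency_floor = 0.85,
                               velocities_cm_s = seq(5, 50, by = 5),
                               alias_min_mm = 30) {
  stopifnot(length(g_max) > 0, length(g_mean) > 0, length(rf_duration) > 0,
            length(flip_angle) > 0, rf_interval > 0, width_limit_mm > 0,
            efficiency_floor > 0, efficiency_floor < 1,
            all(velocities_cm_s > 0), alias_min_mm >= 0)
  structure(list(g_max = sort(g_max), g_mean = sort(g_mean),
                 rf_duration = sort(rf_duration),
                 flip_angle = sort(flip_angle), rf_interval = rf_interval,
                 width_limit_mm = width_limit_mm,
                 efficiency_floor = efficiency_floor,
                 velocities_cm_s = velocities_cm_s,
                 alias_min_mm = alias_min_mm),
            class = "pcasl_search_space")
}
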