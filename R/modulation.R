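#' Simulate the spatial modulation of inversion efficiency
#'
#' Vessel-encoding transverse gradient blips make the inversion efficiency
#' vary across the labeling plane. A position `x` in the plane maps to an
#' encoding phase `theta = k . x + phi` accrued per RF interval; this
#' function Bloch-simulates a spin for each phase on a grid over
#' `[0, 2*pi)` and tabulates the resulting relative longitudinal
#' magnetization. Values are normalized to the nonselective control outcome
#' at the same settings, so the profile lives on the ideal +1 (control) to
#' about -(2*alpha - 1) (label) scale, with `theta = 0` the control center
#' and `theta = pi` the label center.
#'
#' For the unipolar polarity the blip phase is added every interval, so
#' off-resonance shifts the whole modulation pattern; for the bipolar
#' polarity the blip sign alternates between intervals, which leaves the
#' pattern centered but attenuates the labeling efficiency under
#' off-resonance.
#'
#' @param params A [pcasl_params()] object.
#' @param blood A [blood_properties()] object.
#' @param polarity `"bipolar"` or `"unipolar"`.
#' @param velocity Spin velocity, cm/s (30 cm/s is the conventional value
#'   for encoding-matrix simulation).
#' @param off_resonance Off-resonance, Hz.
#' @param n_theta Number of phase samples (at least 16).
#' @param dt Bloch integration step, microseconds.
#' @return An object of class `modulation_profile` with fields `theta`
#'   (radians), `value` (relative Mz), and provenance (`params`, `polarity`,
#'   `velocity`, `off_resonance`).
#' @export
simulate_modulation <- function(params, blood = blood_properties(),
                                polarity = c("bipolar", "unipolar"),
                                velocity = 30, off_resonance = 0,
                                n_theta = 64, dt = 5) {
  polarity <- match.arg(polarity)
  if (n_theta < 16) stop("n_theta must be at least 16")
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  raw <- vapply(theta, function(th) {
    r <- simulate_spin(params, blood,
                       spin_trajectory(velocity,
                                       off_resonance = off_resonance),
                       condition = "control", enc_theta = th,
                       polarity = polarity, dt = dt)
    1 - (1 - r$mz) * exp((r$t_end - r$t_cross) / (blood$t1 * 1e-3))
  }, numeric(1))
  ctrl <- raw[1] # theta = 0 is the nonselective control by construction
  structure(list(theta = theta, value = raw / ctrl, polarity = polarity,
                 velocity = velocity, off_resonance = off_resonance,
                 params = params, analytic = NULL),
            class = "modulation_profile")
}

#' Ideal cosine modulation profile
#'
#' Analytic stand-in profile `value(theta) = cos(theta)`: the ideal
#' modulation that makes a perfectly realized encoding matrix exactly equal
#' its Hadamard target. Useful for tests and for design without a Bloch
#' simulation.
#'
#' @param n_theta Number of tabulated samples (interpolation is bypassed and
#'   the exact cosine is evaluated).
#' @return A `modulation_profile` object.
#' @export
cosine_profile <- function(n_theta = 64) {
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  structure(list(theta = theta, value = cos(theta), polarity = "bipolar",
                 velocity = NA_real_, off_resonance = 0, params = NULL,
                 analytic = "cosine"),
            class = "modulation_profile")
}

#' @export
print.modulation_profile <- function(x, ...) {
  if (identical(x$analytic, "cosine")) {
    cat("Modulation profile: analytic cosine\n")
  } else {
    cat(sprintf(paste0("Modulation profile: %s, v = %g cm/s, ",
                       "off-resonance %g Hz, %d samples\n"),
                x$polarity, x$velocity, x$off_resonance, length(x$theta)))
    cat(sprintf("  control value %.3f, label value %.3f\n",
                modulation_at(x, 0), modulation_at(x, pi)))
  }
  invisible(x)
}

#' Evaluate a modulation profile at arbitrary encoding phases
#'
#' Periodic linear interpolation on the tabulated phase grid (exact at grid
#' nodes); the analytic cosine profile is evaluated in closed form.
#'
#' @param profile A `modulation_profile`.
#' @param theta Encoding phase(s), radians (any real value; the profile is
#'   2*pi-periodic).
#' @return Interpolated relative Mz value(s).
#' @export
modulation_at <- function(profile, theta) {
  stopifnot(inherits(profile, "modulation_profile"))
  if (identical(profile$analytic, "cosine")) return(cos(theta))
  th <- theta %% (2 * pi)
  grid <- c(profile$theta, 2 * pi)
  val <- c(profile$value, profile$value[1])
  approx(grid, val, xout = th, method = "linear", rule = 2)$y
}

# theta-extent of the label region (value < 0), by linear interpolation of
# the sign changes on the periodic grid
label_region_width <- function(profile) {
  th <- c(profile$theta, 2 * pi)
  v <- c(profile$value, profile$value[1])
  width <- 0
  for (i in seq_len(length(th) - 1)) {
    v1 <- v[i]; v2 <- v[i + 1]; d <- th[i + 1] - th[i]
    if (v1 < 0 && v2 < 0) {
      width <- width + d
    } else if (v1 < 0 || v2 < 0) {
      frac <- abs(if (v1 < 0) v1 else v2) / abs(v2 - v1)
      width <- width + d * frac
    }
  }
  width
}

#' Compare label-region widths of the two blip polarities
#'
#' Simulates the bipolar and unipolar modulation profiles at matched
#' settings and reports the extent of the label region (where the relative
#' Mz is negative) for each. With a thin labeling plane the unipolar label
#' region is much narrower than the bipolar one, which makes bipolar
#' encoding the robust choice for arbitrary vessel geometries.
#'
#' @param params A [pcasl_params()] object.
#' @param blood A [blood_properties()] object.
#' @param velocity Spin velocity, cm/s.
#' @param n_theta Phase samples per profile.
#' @param dt Bloch integration step, microseconds.
#' @return A list with per-polarity widths (radians) and the two profiles.
#' @export
compare_polarity_widths <- function(params, blood = blood_properties(),
                                    velocity = 30, n_theta = 64, dt = 5) {
  bi <- simulate_modulation(params, blood, "bipolar", velocity,
                            n_theta = n_theta, dt = dt)
  uni <- simulate_modulation(params, blood, "unipolar", velocity,
                             n_theta = n_theta, dt = dt)
  list(bipolar_width = label_region_width(bi),
       unipolar_width = label_region_width(uni),
       bipolar = bi, unipolar = uni)
}
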