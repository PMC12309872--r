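.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  if (!all(keep)) return(NULL)
  s$v %*% (t(s$u) / s$d)
}

#' Theoretical per-vessel SNR efficiency of an encoding matrix
#'
#' Decoding a vessel-encoded acquisition pseudo-inverts the encoding matrix,
#' so the noise amplification for vessel `j` is the 2-norm of row `j` of the
#' pseudoinverse. The SNR efficiency is defined as
#' `1 / (sqrt(n_cycles) * ||pinv(A)\[j, \]||)`, normalized so that an ideal
#' +/-1 Hadamard encoding scores exactly 1 for every vessel.
#'
#' @param A Encoding matrix (cycles x vessels+tissue; the last column is
#'   assumed to be the static-tissue column and is not reported).
#' @param n_cycles Normalization count (defaults to `nrow(A)`).
#' @return Named vector of per-vessel efficiencies in \[0, 1\]. A
#'   rank-deficient matrix yields zeros with a warning.
#' @examples
#' snr_efficiency(hadamard(8)) # all ones
#' @export
snr_efficiency <- function(A, n_cycles = nrow(A)) {
  P <- .pinv(A)
  nv <- ncol(A) - 1
  nm <- colnames(A)[seq_len(nv)] %||% paste0("v", seq_len(nv))
  if (is.null(P)) {
    warning("encoding matrix is rank deficient; efficiencies set to 0")
    return(setNames(rep(0, nv), nm))
  }
  eff <- 1 / (sqrt(n_cycles) * sqrt(rowSums(P^2)))
  setNames(eff[seq_len(nv)], nm)
}

#' Mean SNR efficiency of an encoding scheme
#'
#' @param scheme An `encoding_scheme`.
#' @param include_ns_label Include the appended nonselective label cycle in
#'   the decoding matrix (it is excluded by default so that an exactly
#'   realized Hadamard design scores 1).
#' @return Named per-vessel efficiencies (attribute `mean` holds the mean).
#' @export
scheme_snr_efficiency <- function(scheme, include_ns_label = FALSE) {
  A <- scheme_matrix(scheme, include_ns_label = include_ns_label)
  eff <- snr_efficiency(A)
  attr(eff, "mean") <- mean(eff)
  eff
}

#' Motion robustness of an encoding design
#'
#' Monte-Carlo study of SNR efficiency under rigid head motion between the
#' planning scan and the VEASL scan: the designed cycles are kept fixed
#' while the vessel coordinates are perturbed by a shared random translation
#' (and optionally a rotation about the plane center), the realized
#' encoding matrix is re-simulated and its mean SNR efficiency recorded.
#'
#' @param scheme An `encoding_scheme`.
#' @param vessels The [vessel_set()] the scheme was designed for.
#' @param profile Modulation profile used for re-simulation.
#' @param sd_grid Translation standard deviations, mm.
#' @param n_rep Monte-Carlo repetitions per SD.
#' @param seed Optional RNG seed.
#' @param rot_sd Rotation SD about the plane center, degrees (0 disables).
#' @return Data frame of class `motion_study` with columns `sd_mm` and
#'   `mean_efficiency`; the unperturbed baseline is the `sd = 0` entry.
#' @export
motion_robustness <- function(scheme, vessels, profile = cosine_profile(),
                              sd_grid = seq(0, 6, by = 0.5), n_rep = 100,
                              seed = NULL, rot_sd = 0) {
  stopifnot(inherits(scheme, "encoding_scheme"),
            inherits(vessels, "vessel_set"))
  if (!is.null(seed)) set.seed(seed)
  cycles <- scheme$cycles[seq_len(scheme$n_design_cycles)]
  eval_at <- function(vs) {
    A <- simulate_encoding_matrix(cycles, vs, profile)
    mean(snr_efficiency(A))
  }
  base <- eval_at(vessels)
  out <- vapply(sd_grid, function(s) {
    if (s == 0) return(base)
    mean(vapply(seq_len(n_rep), function(r) {
      vs <- vessels
      shift <- rnorm(2, sd = s)
      vs$x_mm <- vs$x_mm + shift[1]
      vs$y_mm <- vs$y_mm + shift[2]
      if (rot_sd > 0) {
        a <- rnorm(1, sd = rot_sd) * pi / 180
        xy <- cbind(vs$x_mm, vs$y_mm) %*%
          matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
        vs$x_mm <- xy[, 1]; vs$y_mm <- xy[, 2]
      }
      eval_at(vs)
    }, numeric(1)))
  }, numeric(1))
  structure(data.frame(sd_mm = sd_grid, mean_efficiency = out),
            class = c("motion_study", "data.frame"))
}

#' Duty-cycle and off-resonance study of the mean SNR efficiency
#'
#' For each RF interval a fresh design is made with the interval's own
#' zero-off-resonance modulation profile; entries of vessels marked as
#' anterior cerebral arteries (ACAs) are then re-simulated with the
#' off-resonance profiles (B0 inhomogeneity near the frontal sinus affects
#' the ACAs first) and the mean SNR efficiency recorded per
#' (interval, offset) pair.
#'
#' @param vessels A [vessel_set()].
#' @param aca Indices (or names) of the ACA vessels.
#' @param params Base [pcasl_params()]; only the RF interval is varied.
#' @param blood A [blood_properties()] object.
#' @param intervals RF intervals to study, microseconds.
#' @param offsets ACA off-resonance values, Hz.
#' @param n_iter IOES iterations per interval.
#' @param M,seed,n_theta,dt Passed to the design/profile simulation.
#' @return Data frame with `rf_interval_us`, `off_resonance_hz`,
#'   `mean_efficiency`.
#' @export
off_resonance_study <- function(vessels, aca, params = optimal_pcasl_params(),
                                blood = blood_properties(),
                                intervals = c(1560, 1380, 1200),
                                offsets = c(0, 50, 100), n_iter = 100,
                                M = 4, seed = NULL, n_theta = 64, dt = 5) {
  stopifnot(inherits(vessels, "vessel_set"))
  if (is.character(aca)) aca <- match(aca, vessels$name)
  if (any(is.na(aca)) || length(aca) == 0) stop("unknown ACA vessels")
  rows <- list()
  for (ti in intervals) {
    p <- pcasl_params(params$g_max, params$g_mean, params$rf_duration, ti,
                      params$flip_angle)
    prof0 <- simulate_modulation(p, blood, "bipolar", n_theta = n_theta,
                                 dt = dt)
    scheme <- ioes(vessels, prof0, n_iter = n_iter, M = M, seed = seed)
    cycles <- scheme$cycles[seq_len(scheme$n_design_cycles)]
    for (off in offsets) {
      A <- scheme_matrix(scheme, include_ns_label = FALSE)
      if (off != 0) {
        prof_off <- simulate_modulation(p, blood, "bipolar",
                                        off_resonance = off,
                                        n_theta = n_theta, dt = dt)
        A_off <- simulate_encoding_matrix(cycles, vessels, prof_off)
        A[, aca] <- A_off[, aca]
      }
      rows[[length(rows) + 1]] <- data.frame(
        rf_interval_us = ti, off_resonance_hz = off,
        mean_efficiency = mean(snr_efficiency(A)))
    }
  }
  do.call(rbind, rows)
}

#' Relative inversion efficiency of a vessel-encoded cycle
#'
#' `(nonselective control - selective label) /
#'  (nonselective control - nonselective label)`: the per-cycle signal
#' modulation normalized to the full nonselective control-label difference.
#' Affine-invariant: adding a constant to all three signals leaves the
#' result unchanged.
#'
#' @param ns_control,ns_label,selective_label Signals (vectors are handled
#'   elementwise).
#' @return Relative inversion efficiency (1 = fully labeled, 0 = fully
#'   controlled).
#' @export
relative_inversion_efficiency <- function(ns_control, ns_label,
                                          selective_label) {
  denom <- ns_control - ns_label
  if (any(denom == 0))
    stop("nonselective control and label signals must differ")
  (ns_control - selective_label) / denom
}

#' Measured versus designed signal modulation within a territory
#'
#' Extracts the mean signal per encoding cycle within a territory mask and
#' pairs it with the design-predicted modulation of the mask's dominant
#' vessel (the vessel with the largest decoded perfusion amplitude inside
#' the mask, unless given). The predicted perfusion weight
#' `(1 - A\[c, j\]) / 2` is put on the measured scale by an affine
#' least-squares fit, so a noiseless synthetic stack matches exactly.
#'
#' @param stack A [vti_stack()].
#' @param mask Logical/0-1 array matching the stack's spatial dimensions.
#' @param vessel Optional vessel index or name; default: dominant vessel.
#' @return Data frame with `cycle`, `measured`, `predicted`, plus the chosen
#'   vessel as attribute `vessel`.
#' @export
territory_signal_curve <- function(stack, mask, vessel = NULL) {
  stopifnot(inherits(stack, "vti_stack"))
  mask <- array(as.logical(mask), dim = dim(stack$data)[1:3])
  if (!any(mask)) stop("territory mask is empty")
  nc <- dim(stack$data)[4]
  measured <- vapply(seq_len(nc), function(ci) {
    v <- stack$data[, , , ci, drop = FALSE]
    mean(v[mask])
  }, numeric(1))
  if (is.null(vessel)) {
    dec <- decode_linear(stack)
    amps <- vapply(seq_len(dim(dec$perfusion)[4]), function(j) {
      v <- dec$perfusion[, , , j, drop = FALSE]
      mean(v[mask])
    }, numeric(1))
    vessel <- which.max(amps)
  } else if (is.character(vessel)) {
    vessel <- match(vessel, stack$vessel_names)
  }
  w <- (1 - stack$matrix[, vessel]) / 2
  fit <- stats::lm.fit(cbind(1, w), measured)
  predicted <- as.vector(cbind(1, w) %*% fit$coefficients)
  out <- data.frame(cycle = seq_len(nc), measured = measured,
                    predicted = predicted)
  attr(out, "vessel") <- vessel
  out
}
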