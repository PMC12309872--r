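.vessel_templates <- list(
  # four brain-feeding arteries in the neck: carotids anterior, vertebrals
  # posterior, approximating a rectangle with mild anatomical asymmetry
  neck4 = data.frame(
    name = c("RICA", "LICA", "RVA", "LVA"),
    x_mm = c(-27.5, 26.5, -23.0, 24.0),
    y_mm = c(9.0, 7.5, -25.5, -24.5),
    stringsAsFactors = FALSE),
  # nine arterial branches above the circle of Willis: midline ACA, three
  # MCA branches per side laterally, two PCAs posteriorly
  cow9 = data.frame(
    name = c("ACA", "RMCA1", "RMCA2", "RMCA3",
             "LMCA1", "LMCA2", "LMCA3", "RPCA", "LPCA"),
    x_mm = c(0, 38, 42, 40, -38, -42, -40, 10, -10),
    y_mm = c(32, 14, 4, -6, 14, 4, -6, -30, -30),
    stringsAsFactors = FALSE))

#' Synthetic vessel geometries
#'
#' Template vessel layouts for testing and simulation: `"neck4"`, the four
#' major brain-feeding arteries in the neck arranged close to a rectangle,
#' and `"cow9"`, nine arterial branches above the circle of Willis (midline
#' ACA, three MCA branches per side, two PCAs). Coordinates are fixture
#' constants resembling typical anatomy, not measurements. Optional Gaussian
#' jitter perturbs the template reproducibly.
#'
#' @param template `"neck4"` or `"cow9"`.
#' @param jitter_sd SD of isotropic Gaussian jitter added to each
#'   coordinate, mm.
#' @param seed Optional RNG seed (jitter is deterministic given the seed).
#' @return A [vessel_set()].
#' @examples
#' make_vessels("neck4")
#' @export
make_vessels <- function(template = c("neck4", "cow9"), jitter_sd = 0,
                         seed = NULL) {
  template <- match.arg(template)
  df <- .vessel_templates[[template]]
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    df$x_mm <- df$x_mm + rnorm(nrow(df), sd = jitter_sd)
    df$y_mm <- df$y_mm + rnorm(nrow(df), sd = jitter_sd)
  }
  vessel_set(df$name, df$x_mm, df$y_mm)
}

#' Specification of a synthetic perfusion phantom
#'
#' Describes the digital phantom used by [synthesize_stack()]: one compact
#' disc-shaped territory per vessel on a static-tissue background, a common
#' tissue baseline, per-average Gaussian noise and the number of signal
#' averages.
#'
#' @param grid Image dimensions (x, y, z) in voxels.
#' @param territory_radius Territory disc radius, voxels.
#' @param amplitude Perfusion amplitude (signal units); scalar or one value
#'   per vessel, all non-negative.
#' @param tissue Static-tissue baseline signal.
#' @param noise_sd Per-average Gaussian noise SD.
#' @param n_averages Number of signal averages.
#' @param seed RNG seed for the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(24, 24, 3), territory_radius = 3,
                         amplitude = 1, tissue = 10, noise_sd = 0.2,
                         n_averages = 8, seed = 1) {
  stopifnot(length(grid) == 3, all(grid[1:2] >= 8), grid[3] >= 1,
            territory_radius >= 1,
            all(amplitude >= 0), noise_sd >= 0, n_averages >= 1)
  structure(list(grid = grid, territory_radius = territory_radius,
                 amplitude = amplitude, tissue = tissue,
                 noise_sd = noise_sd, n_averages = n_averages, seed = seed),
            class = "phantom_spec")
}

#' Effective SNR of a phantom specification
#'
#' Perfusion amplitude divided by the noise SD after averaging.
#' @param phantom A [phantom_spec()].
#' @return Effective SNR (vector if per-vessel amplitudes were given).
#' @export
phantom_snr <- function(phantom) {
  if (phantom$noise_sd == 0) return(Inf)
  phantom$amplitude / (phantom$noise_sd / sqrt(phantom$n_averages))
}

# scale vessel coordinates into the phantom grid and stamp disc territories
.phantom_territories <- function(vessels, grid, radius) {
  X <- as.matrix(vessels[, c("x_mm", "y_mm")])
  n <- nrow(X)
  rng <- apply(X, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-6)
  margin <- radius + 1.5
  gx <- margin + (X[, 1] - rng[1, 1]) / span[1] * (grid[1] - 2 * margin)
  gy <- margin + (X[, 2] - rng[1, 2]) / span[2] * (grid[2] - 2 * margin)
  truth <- array(0L, grid)
  co <- expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]))
  d2 <- sapply(seq_len(n), function(j) (co$x - gx[j])^2 + (co$y - gy[j])^2)
  nearest <- max.col(-d2, ties.method = "first")
  inside <- d2[cbind(seq_len(nrow(d2)), nearest)] <= radius^2
  plane <- integer(nrow(co))
  plane[inside] <- nearest[inside]
  for (z in seq_len(grid[3])) truth[, , z] <- plane
  truth
}

#' Synthesize a vessel-encoded image stack with known ground truth
#'
#' Builds a digital perfusion phantom for an encoding scheme: each vessel
#' owns a compact territory; the voxel signal at cycle `c` inside territory
#' `j` is `tissue + amplitude_j * (1 - A[c, j]) / 2` (control entries
#' contribute no perfusion signal, label entries the full amplitude), plus
#' independent Gaussian noise per signal average, averaged over
#' `n_averages`. The scheme's full simulated matrix (including any appended
#' nonselective label cycle) drives the signal and is attached to the stack
#' for decoding.
#'
#' @param vessels A [vessel_set()] (count must match the scheme).
#' @param scheme An `encoding_scheme`.
#' @param phantom A [phantom_spec()].
#' @param return_averages Also return the 5D per-average data.
#' @return A list with `stack` (a [vti_stack()]), `truth` (3D integer
#'   ground-truth territory labels, 0 = static), `amplitude` (per-vessel
#'   amplitudes) and optionally `averages`.
#' @export
synthesize_stack <- function(vessels, scheme, phantom = phantom_spec(),
                             return_averages = FALSE) {
  stopifnot(inherits(vessels, "vessel_set"),
            inherits(scheme, "encoding_scheme"),
            inherits(phantom, "phantom_spec"))
  A <- scheme_matrix(scheme, include_ns_label = TRUE)
  nv <- ncol(A) - 1
  if (nv != nrow(vessels))
    stop("scheme and vessel set disagree on the number of vessels")
  amp <- rep(phantom$amplitude, length.out = nv)
  truth <- .phantom_territories(vessels, phantom$grid,
                                phantom$territory_radius)
  nc <- nrow(A)
  nvox <- prod(phantom$grid)
  W <- rbind(rep(0, nc), t((1 - A[, seq_len(nv), drop = FALSE]) / 2) * amp)
  clean <- matrix(phantom$tissue, nvox, nc) + W[as.vector(truth) + 1L, ]
  set.seed(phantom$seed)
  na <- phantom$n_averages
  if (return_averages) {
    avg <- array(NA_real_, c(phantom$grid, nc, na))
    acc <- matrix(0, nvox, nc)
    for (a in seq_len(na)) {
      noisy <- clean + matrix(rnorm(nvox * nc, sd = phantom$noise_sd),
                              nvox, nc)
      avg[, , , , a] <- array(noisy, c(phantom$grid, nc))
      acc <- acc + noisy
    }
    dat <- array(acc / na, c(phantom$grid, nc))
  } else {
    noise <- matrix(rnorm(nvox * nc, sd = phantom$noise_sd / sqrt(na)),
                    nvox, nc)
    dat <- array(clean + noise, c(phantom$grid, nc))
    avg <- NULL
  }
  out <- list(stack = vti_stack(dat, A, vessel_names = vessels$name),
              truth = truth, amplitude = amp)
  if (return_averages) out$averages <- avg
  out
}
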