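SCHEME_SCHEMA_VERSION <- "1.0"

#' Read vessel coordinates from CSV or JSON
#'
#' CSV files must carry the header `name,x_mm,y_mm`; JSON files an object or
#' record array with the same fields. Vessels closer than 1 mm are merged
#' with a warning.
#'
#' @param path File path (`.csv` or `.json`).
#' @param merge_tol Merge tolerance, mm.
#' @return A [vessel_set()].
#' @examples
#' read_vessels(system.file("extdata", "cow9_vessels.csv",
#'                          package = "veasl"))
#' @export
read_vessels <- function(path, merge_tol = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("name", "x_mm", "y_mm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("vessel file is missing column(s): ", paste(missing, collapse = ", "))
  vessel_set(df$name, df$x_mm, df$y_mm, merge_tol = merge_tol)
}

#' Write vessel coordinates to CSV
#'
#' @param vessels A [vessel_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vessels <- function(vessels, path) {
  stopifnot(inherits(vessels, "vessel_set"))
  write.csv(as.data.frame(vessels), path, row.names = FALSE)
  invisible(path)
}

#' Serialize an encoding scheme to JSON
#'
#' The JSON carries a schema version, per-cycle kind / spatial frequency
#' (rad/mm) / direction (degrees) / wavelength (mm) / phase (radians), the
#' ideal and simulated matrices at full double precision, the diagnostics
#' (condition number, minimum wavelength, cost, `M`), and provenance (seed,
#' iteration count, package version).
#'
#' @param scheme An `encoding_scheme`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  cyc <- lapply(scheme$cycles, function(cy) list(
    kind = cy$kind, k_rad_mm = cy$k,
    direction_deg = if (cy$kind == "selective")
      atan2(cy$k[2], cy$k[1]) * 180 / pi else NA,
    wavelength_mm = cy$lambda, phase_rad = cy$phase))
  obj <- list(schema_version = SCHEME_SCHEMA_VERSION,
              package_version = as.character(packageVersion("veasl")),
              vessel_names = scheme$vessel_names,
              m_mm = scheme$M,
              n_design_cycles = scheme$n_design_cycles,
              hadamard_order = scheme$hadamard_order,
              hadamard_columns = scheme$hadamard_columns,
              cost_form = scheme$cost_form,
              seed = scheme$seed, n_iter = scheme$n_iter,
              condition_number = scheme$condition_number,
              lambda_min_mm = scheme$lambda_min, cost = scheme$cost,
              cycles = cyc,
              ideal = scheme$ideal, simulated = scheme$simulated,
              iteration_log = scheme$iteration_log)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Read an encoding scheme from JSON
#'
#' @param path JSON file written by [write_scheme()].
#' @return An `encoding_scheme`.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("failed to parse scheme JSON '", path, "': ",
                         conditionMessage(e)))
  ver <- obj$schema_version
  if (is.null(ver) || !identical(ver, SCHEME_SCHEMA_VERSION))
    stop("unsupported scheme schema version: ",
         ver %||% "<missing>", " (expected ", SCHEME_SCHEMA_VERSION, ")")
  cycles <- lapply(seq_len(nrow(obj$cycles)), function(i) {
    kind <- obj$cycles$kind[i]
    k <- if (kind == "selective") as.numeric(obj$cycles$k_rad_mm[[i]])
         else c(NA_real_, NA_real_)
    new_encoding_cycle(kind, k = k, phase = obj$cycles$phase_rad[i])
  })
  ideal <- as.matrix(obj$ideal)
  storage.mode(ideal) <- "double" # +/-1 entries parse as integer
  sim <- as.matrix(obj$simulated)
  storage.mode(sim) <- "double"
  colnames(ideal) <- colnames(sim) <- c(obj$vessel_names, "tissue")
  structure(list(cycles = cycles, ideal = ideal, simulated = sim,
                 condition_number = obj$condition_number,
                 lambda_min = obj$lambda_min_mm, cost = obj$cost,
                 M = obj$m_mm, n_design_cycles = obj$n_design_cycles,
                 vessel_names = obj$vessel_names,
                 hadamard_order = obj$hadamard_order,
                 hadamard_columns = obj$hadamard_columns,
                 cost_form = obj$cost_form, seed = obj$seed,
                 n_iter = obj$n_iter,
                 iteration_log = obj$iteration_log),
            class = "encoding_scheme")
}

#' Write a modulation profile to CSV (with a JSON provenance sidecar)
#'
#' The CSV holds `theta_rad,value`; a `<path>.json` sidecar records the
#' polarity, velocity, off-resonance and PCASL parameters.
#'
#' @param profile A `modulation_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "modulation_profile"))
  write.csv(data.frame(theta_rad = profile$theta, value = profile$value),
            path, row.names = FALSE)
  meta <- list(polarity = profile$polarity, velocity_cm_s = profile$velocity,
               off_resonance_hz = profile$off_resonance,
               analytic = profile$analytic,
               params = if (!is.null(profile$params))
                 unclass(profile$params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), na = "null")
  invisible(path)
}

#' Read a modulation profile written by [write_profile()]
#'
#' @param path CSV path (the `.json` sidecar is read when present).
#' @return A `modulation_profile`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path)
  if (!all(c("theta_rad", "value") %in% names(df)))
    stop("profile CSV must have columns theta_rad,value")
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path)
          else list()
  params <- if (!is.null(meta$params))
    do.call(pcasl_params, meta$params[c("g_max", "g_mean", "rf_duration",
                                        "rf_interval", "flip_angle",
                                        "rf_shape")])
  structure(list(theta = df$theta_rad, value = df$value,
                 polarity = meta$polarity %||% "bipolar",
                 velocity = meta$velocity_cm_s %||% NA_real_,
                 off_resonance = meta$off_resonance_hz %||% 0,
                 params = params, analytic = meta$analytic),
            class = "modulation_profile")
}

#' Write a VTI stack as NIfTI (with a JSON sidecar for the matrix)
#'
#' @param stack A [vti_stack()].
#' @param path Output `.nii`/`.nii.gz` path; the encoding matrix and vessel
#'   names go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "vti_stack"))
  img <- RNifti::asNifti(stack$data,
                         pixdim = c(stack$voxel_size_mm, 1))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(matrix = stack$matrix,
                            vessel_names = stack$vessel_names,
                            voxel_size_mm = stack$voxel_size_mm),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' Read a VTI stack written by [write_stack()] (or with a scheme JSON)
#'
#' @param path NIfTI path.
#' @param scheme Optional `encoding_scheme` supplying the matrix when no
#'   `<path>.json` sidecar exists.
#' @return A [vti_stack()].
#' @export
read_stack <- function(path, scheme = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dat <- as.array(RNifti::readNifti(path))
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    A <- as.matrix(meta$matrix)
    colnames(A) <- c(meta$vessel_names, "tissue")
    vti_stack(dat, A, as.numeric(meta$voxel_size_mm), meta$vessel_names)
  } else if (!is.null(scheme)) {
    vti_stack(dat, scheme_matrix(scheme), vessel_names = scheme$vessel_names)
  } else {
    stop("no matrix sidecar found; supply an encoding scheme")
  }
}

#' Read a run configuration YAML
#'
#' Known top-level blocks: `paths`, `seeds`, `pcasl`, `search`, `design`,
#' `evaluation`, `phantom`. Unknown keys are rejected to catch typos.
#'
#' @param path YAML file.
#' @return Named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("paths", "seeds", "pcasl", "search", "design", "evaluation",
             "phantom")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg
}

# provenance block written next to every CLI output
write_provenance <- function(path, seed = NULL, config = NULL) {
  obj <- list(tool = "veasl",
              package_version = as.character(packageVersion("veasl")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed)
  if (!is.null(config)) {
    tf <- tempfile()
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
    obj$config_md5 <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null")
  invisible(path)
}
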