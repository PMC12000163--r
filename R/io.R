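#' Load a validated configuration file
#'
#' Reads a YAML configuration with sections `particle`, `buffer`, `syringe`,
#' `flow`, `sim`, `analysis`, `constants`, `model`. Keys carry explicit unit
#' suffixes in the customary laboratory units and are converted to SI, so a
#' bare number can never be silently misread:
#'
#' * particle: `radius_um`, `density_g_cm3`
#' * buffer: `density_g_cm3`, `viscosity_mPa_s`
#' * syringe: `barrel_radius_mm`, `barrel_length_mm`, `outlet_radius_mm`,
#'   `outlet_length_mm`, `outlet_offset_mm` (optional, default 0; the string
#'   `"bottom"` or `"top"` may be used for edge-flush outlets)
#' * flow: `rate_ul_min`, `backend` (optional)
#' * sim: `n_particles`, `dt_s`, `max_time_s`, `seed`, `integrator`
#'   (all optional)
#' * analysis: `lowpass_cutoff_hz`, `threshold_sigmas`, `min_separation_s`,
#'   `bin_width_s`, `initial_window_s`, `smooth_window_bins` (all optional)
#' * constants: `g_m_s2` (optional, default 9.81)
#' * model: `k_s` (optional; when absent only the half-life bounds are
#'   reported)
#'
#' @param path Path to the YAML file.
#' @return A named list with validated spec objects (`particle`, `buffer`,
#'   `syringe`, `constants`) plus `Q` (m^3/s), `backend`, `sim`, `analysis`,
#'   `K_S` and the raw `config` with its `config_hash`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  problems <- character(0)
  need <- function(section, key) {
    v <- cfg[[section]][[key]]
    if (is.null(v)) {
      problems <<- c(problems, sprintf("%s.%s (missing)", section, key))
      return(NA_real_)
    }
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      problems <<- c(problems, sprintf("%s.%s (not a number)", section, key))
      return(NA_real_)
    }
    v
  }
  optional <- function(section, key, default) {
    v <- cfg[[section]][[key]]
    if (is.null(v)) default else v
  }

  r_um <- need("particle", "radius_um")
  rho_p <- need("particle", "density_g_cm3")
  rho_b <- need("buffer", "density_g_cm3")
  eta <- need("buffer", "viscosity_mPa_s")
  rs_mm <- need("syringe", "barrel_radius_mm")
  ls_mm <- need("syringe", "barrel_length_mm")
  ro_mm <- need("syringe", "outlet_radius_mm")
  lo_mm <- need("syringe", "outlet_length_mm")
  q_ulmin <- need("flow", "rate_ul_min")
  if (length(problems))
    stop("invalid configuration, offending keys: ",
         paste(problems, collapse = ", "), call. = FALSE)

  off <- optional("syringe", "outlet_offset_mm", 0)
  specs <- tryCatch({
    s0 <- syringe_spec(rs_mm * 1e-3, ls_mm * 1e-3, ro_mm * 1e-3,
                       lo_mm * 1e-3,
                       outlet_offset = if (is.character(off)) 0 else
                         off * 1e-3)
    if (is.character(off)) s0 <- with_outlet(s0, off)
    list(
      particle = particle_spec(r_um * 1e-6, rho_p * 1e3),
      buffer = buffer_spec(rho_b * 1e3, eta * 1e-3),
      syringe = s0,
      constants = model_constants(optional("constants", "g_m_s2", 9.81)))
  }, error = function(e)
    stop("invalid configuration: ", conditionMessage(e), call. = FALSE))

  sim <- sim_config(
    n_particles = optional("sim", "n_particles", 2000),
    dt = optional("sim", "dt_s", 0.05),
    max_time = optional("sim", "max_time_s", 1200),
    seed = optional("sim", "seed", 1),
    integrator = optional("sim", "integrator", "euler"))
  analysis <- list(
    cutoff = optional("analysis", "lowpass_cutoff_hz", 100),
    threshold_sigmas = optional("analysis", "threshold_sigmas", 5),
    min_separation = optional("analysis", "min_separation_s", 1e-3),
    bin_width = optional("analysis", "bin_width_s", 1),
    initial_window = optional("analysis", "initial_window_s", 20),
    smooth_window = optional("analysis", "smooth_window_bins", 21))

  c(specs, list(
    Q = ul_min(q_ulmin),
    backend = optional("flow", "backend", "superposition"),
    sim = sim, analysis = analysis,
    K_S = cfg[["model"]][["k_s"]],
    config = cfg,
    config_hash = config_hash(cfg)))
}

# md5 of the canonical deparse of a config list
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg, control = "all"), tmp)
  unname(tools::md5sum(tmp))
}

provenance_header <- function(meta = list()) {
  fields <- c(list(package = paste("syrsed", package_version_string())),
              meta)
  vapply(names(fields), function(k)
    sprintf("# %s: %s", k, paste(format(fields[[k]]), collapse = " ")),
    character(1))
}

#' Write / read a concentration curve as tabular text
#'
#' Two tab-separated columns `time_s` and `ratio`, preceded by `#` header
#' comments recording the package version, source, configuration hash and
#' seed where available, so any curve file can be traced back to what
#' produced it.
#'
#' @param curve A [concentration_curve()].
#' @param path File path.
#' @param extra Named list of extra provenance header fields.
#' @return `write_curve` returns `path` invisibly; `read_curve` returns a
#'   [concentration_curve()] (source restored from the header, defaulting
#'   to `"measured"`).
#' @export
write_curve <- function(curve, path, extra = list()) {
  stopifnot(inherits(curve, "concentration_curve"))
  meta <- curve$meta
  head_meta <- c(list(source = curve$source), extra)
  for (k in c("seed", "bin_width", "normalization_window", "smooth_window",
              "kind", "n_initial", "Q"))
    if (!is.null(meta[[k]])) head_meta[[k]] <- meta[[k]]
  writeLines(c(provenance_header(head_meta), "time_s\tratio"), path)
  utils::write.table(data.frame(curve$times, curve$ratio), path,
                     append = TRUE, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  src <- sub("^# source: ", "", grep("^# source: ", hdr, value = TRUE))
  if (!length(src)) src <- "measured"
  dat <- utils::read.table(path, comment.char = "#", header = TRUE,
                           sep = "\t")
  concentration_curve(dat[[1]], dat[[2]], source = src)
}

#' Write / read a detector trace as tabular text
#'
#' `write_trace` stores the sampling rate in a `# sampling_rate_hz:` header
#' followed by one signal sample per line. `read_trace` also accepts
#' two-column `time signal` files (whitespace- or tab-separated, optional
#' header line), inferring the sampling rate from the time column.
#'
#' @param trace A [counter_trace()].
#' @param path File path.
#' @param extra Named list of extra provenance header fields.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [counter_trace()].
#' @export
write_trace <- function(trace, path, extra = list()) {
  stopifnot(inherits(trace, "counter_trace"))
  writeLines(c(provenance_header(c(list(sampling_rate_hz =
                                          trace$sampling_rate), extra)),
               format(trace$samples, digits = 8, trim = TRUE, scientific = NA)),
             path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fs_line <- grep("^# sampling_rate_hz:", hdr, value = TRUE)
  # drop a non-numeric header row if present
  first_fields <- strsplit(trimws(body[1]), "[\t ,]+")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first_fields)))))
    body <- body[-1]
  fields <- strsplit(trimws(body), "[\t ,]+")
  ncol <- length(fields[[1]])
  if (ncol >= 2) {
    tt <- as.numeric(vapply(fields, `[[`, character(1), 1))
    xx <- as.numeric(vapply(fields, `[[`, character(1), 2))
    fs <- 1 / stats::median(diff(tt))
    counter_trace(xx, fs)
  } else {
    if (!length(fs_line))
      stop("single-column trace requires a '# sampling_rate_hz:' header",
           call. = FALSE)
    fs <- as.numeric(sub("^# sampling_rate_hz: *", "", fs_line[1]))
    counter_trace(as.numeric(unlist(fields)), fs)
  }
}

#' Write a pooled simulation result as tabular text
#'
#' One event per row with columns `time_s` and `event`
#' (`exit` or `capture`), preceded by provenance headers (seed, flow-rate,
#' backend, population size).
#'
#' @param r A `sim_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sim_result <- function(r, path) {
  stopifnot(inherits(r, "sim_result"))
  hdr <- provenance_header(list(
    seed = r$config$seed, n_initial = r$n_initial, Q_m3_s = r$Q,
    backend = r$backend, dt_s = r$config$dt, end_time_s = r$end_time))
  events <- rbind(
    data.frame(time_s = r$exit_times,
               event = rep("exit", length(r$exit_times))),
    data.frame(time_s = r$capture_times,
               event = rep("capture", length(r$capture_times))))
  events <- events[order(events$time_s), , drop = FALSE]
  writeLines(c(hdr, "time_s\tevent"), path)
  utils::write.table(events, path, append = TRUE, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
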