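#' Run configuration
#'
#' A run is described by a JSON object with the keys below; unknown keys
#' are rejected so typos cannot silently change a run.
#'
#' ```
#' {
#'   "mode": "arks" | "golden" | "random" | "equispaced",
#'   "n_shots": 5, "n_segments": 6, "tr_s": 0.0028, "seed": 1,
#'   "duration_s": 90,
#'   "ecg": {"rr_mean_s": 1.0, "rr_sd_s": 0.05, "p_ectopic": 0,
#'           "noise_sd": 0.02, "baseline_amp": 0, "baseline_freq_hz": 0.25,
#'           "fs_hz": 400, "path": "optional.csv"},
#'   "match": {"window_s": 0.3, "min_score": 0.8, "min_separation_s": 0.3},
#'   "geometry": {"n_readout": 128, "fov_m": 0.34, "grid_size": 256},
#'   "metrics": {"psf": true, "psf_frames": 200},
#'   "phantom": {"period_s": 1.0, "contraction": 0.15, "n_frames": 24}
#' }
#' ```
#'
#' @param x path to a JSON file, a JSON string, or a list.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(x) {
  cfg <- if (is.list(x)) x
  else jsonlite::fromJSON(x, simplifyVector = TRUE)
  schema <- list(
    mode = "character", n_shots = "numeric", n_segments = "numeric",
    tr_s = "numeric", seed = "numeric", duration_s = "numeric",
    ecg = list(rr_mean_s = "numeric", rr_sd_s = "numeric",
               p_ectopic = "numeric", noise_sd = "numeric",
               baseline_amp = "numeric", baseline_freq_hz = "numeric",
               fs_hz = "numeric", path = "character"),
    match = list(window_s = "numeric", min_score = "numeric",
                 min_separation_s = "numeric"),
    geometry = list(n_readout = "numeric", fov_m = "numeric",
                    grid_size = "numeric"),
    metrics = list(psf = "logical", psf_frames = "numeric"),
    phantom = list(period_s = "numeric", contraction = "numeric",
                   n_frames = "numeric"))
  check_keys <- function(obj, sch, path) {
    extra <- setdiff(names(obj), names(sch))
    if (length(extra))
      stop(sprintf("config error: unknown key '%s%s'", path, extra[1]),
           call. = FALSE)
    for (nm in names(obj)) {
      if (is.list(sch[[nm]])) {
        if (!is.list(obj[[nm]]))
          stop(sprintf("config error: '%s%s' must be an object", path, nm),
               call. = FALSE)
        check_keys(obj[[nm]], sch[[nm]], paste0(path, nm, "."))
      } else if (!inherits(obj[[nm]], sch[[nm]]) &&
                 !(sch[[nm]] == "numeric" && is.numeric(obj[[nm]]))) {
        stop(sprintf("config error: '%s%s' must be %s", path, nm, sch[[nm]]),
             call. = FALSE)
      }
    }
  }
  check_keys(cfg, schema, "")
  for (req in c("mode", "n_shots", "n_segments", "tr_s", "seed"))
    if (is.null(cfg[[req]]))
      stop(sprintf("config error: missing key '%s'", req), call. = FALSE)
  if (!cfg$mode %in% c("arks", "golden", "random", "equispaced"))
    stop("config error: invalid mode", call. = FALSE)
  if (is.null(cfg$duration_s)) cfg$duration_s <- 90
  structure(cfg, class = c("run_config", "list"))
}

# 64-bit-ish FNV-1a over the canonical JSON text; identifies a config in
# artifact headers without an external hashing dependency
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(txt)
  h1 <- 2166136261 %% 2^31; h2 <- 40389   # FNV-1a basis folded into int range
  for (b in bytes) {
    h1 <- (bitwXor(as.integer(h1), b) * 16777619) %% 2^31
    h2 <- (h2 * 31 + b) %% 2^31
  }
  sprintf("%08x%08x", h1, h2)
}

ecg_from_config <- function(cfg) {
  e <- if (is.null(cfg$ecg)) list() else cfg$ecg
  if (!is.null(e$path)) return(read_ecg_csv(e$path))
  grab <- function(nm, def) if (is.null(e[[nm]])) def else e[[nm]]
  spec <- rhythm_spec(rr_mean = grab("rr_mean_s", 1.0),
                      rr_sd = grab("rr_sd_s", 0.05),
                      p_ectopic = grab("p_ectopic", 0),
                      noise_sd = grab("noise_sd", 0.02),
                      baseline_amp = grab("baseline_amp", 0),
                      baseline_freq = grab("baseline_freq_hz", 0.25),
                      seed = cfg$seed)
  generate_ecg(spec, cfg$duration_s, fs = grab("fs_hz", 400))
}

match_from_config <- function(cfg) {
  m <- if (is.null(cfg$match)) list() else cfg$match
  grab <- function(nm, def) if (is.null(m[[nm]])) def else m[[nm]]
  match_config(window_s = grab("window_s", 0.3),
               min_score = grab("min_score", 0.8),
               min_separation_s = grab("min_separation_s", 0.3))
}

geom_from_config <- function(cfg) {
  g <- if (is.null(cfg$geometry)) list() else cfg$geometry
  grab <- function(nm, def) if (is.null(g[[nm]])) def else g[[nm]]
  nr <- grab("n_readout", 128)
  radial_geometry(n_readout = nr, fov = grab("fov_m", 0.34),
                  grid_size = grab("grid_size", 2 * nr))
}

#' Run a simulation from a configuration
#'
#' Generates (or loads) the ECG, runs the acquisition, evaluates the
#' metrics, and writes `viewlog.csv` and `metrics.json` into `out_dir`.
#' Both artifacts carry the config hash and seed; identical configurations
#' produce byte-identical artifacts.
#'
#' @param config a [read_run_config()] input (path, JSON string or list).
#' @param out_dir output directory (created if needed).
#' @return list with the log, the uniformity result, the metrics list and
#'   the artifact paths, invisibly.
#' @export
cmd_simulate <- function(config, out_dir = ".") {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ecg <- ecg_from_config(cfg)
  scheme <- segmentation_scheme(cfg$n_shots, cfg$n_segments, cfg$tr_s)
  log <- run_acquisition(ecg, scheme, cfg$mode, match = match_from_config(cfg),
                         seed = cfg$seed)
  message(sprintf("phase transitions: %s",
                  paste(sprintf("%s@%.3fs", unique(log$phase),
                                log$time_s[!duplicated(log$phase)]),
                        collapse = ", ")))
  us <- uniformity_series(log, scheme)
  hash <- config_hash(cfg)
  metrics <- list(scheme = list(n_views = scheme$n_views,
                                n_shots = scheme$n_shots,
                                n_segments = scheme$n_segments),
                  mode = cfg$mode,
                  mean_uniformity_pct = round(100 * us$mean, 6),
                  sd_uniformity_pct = round(100 * us$sd, 6),
                  n_frames = us$n_frames, seed = cfg$seed,
                  config_hash = hash)
  want_psf <- !is.null(cfg$metrics$psf) && isTRUE(cfg$metrics$psf)
  if (want_psf) {
    geom <- geom_from_config(cfg)
    nfr <- if (is.null(cfg$metrics$psf_frames)) 200 else cfg$metrics$psf_frames
    fr <- frame_angle_list(log, scheme, n_frames = nfr)
    pr <- psf_profile_and_ratio(psf_average(fr, geom), geom)
    metrics$psf_ratio_pct <- round(100 * pr$ratio, 6)
  }
  log_path <- file.path(out_dir, "viewlog.csv")
  met_path <- file.path(out_dir, "metrics.json")
  write_viewlog_csv(log, log_path,
                    comment = sprintf("arksim config_hash=%s seed=%d", hash,
                                      as.integer(cfg$seed)))
  jsonlite::write_json(metrics, met_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(log = log, uniformity = us, metrics = metrics,
                 paths = c(viewlog = log_path, metrics = met_path)))
}

#' Standalone re-analysis of a view log
#'
#' @param viewlog path to a `viewlog.csv` (possibly produced elsewhere).
#' @param config a [read_run_config()] input describing the scheme and,
#'   for multi-shot schemes, the ECG that collates the frames.
#' @param out optional path for `metrics.json`.
#' @return the metrics list, invisibly.
#' @export
cmd_metrics <- function(viewlog, config, out = NULL) {
  cfg <- read_run_config(config)
  log <- read_viewlog_csv(viewlog)
  scheme <- segmentation_scheme(cfg$n_shots, cfg$n_segments, cfg$tr_s)
  matches <- NULL
  if (scheme$n_shots > 1) {
    ecg <- ecg_from_config(cfg)
    ecg_tr <- resample_to_tr(ecg, scheme$tr)
    matches <- phase_match_series(ecg_tr, scheme, match_from_config(cfg))
  }
  us <- uniformity_series(log, scheme, matches = matches)
  metrics <- list(scheme = list(n_views = scheme$n_views,
                                n_shots = scheme$n_shots,
                                n_segments = scheme$n_segments),
                  mode = log$mode[1],
                  mean_uniformity_pct = round(100 * us$mean, 6),
                  sd_uniformity_pct = round(100 * us$sd, 6),
                  n_frames = us$n_frames, seed = cfg$seed,
                  config_hash = config_hash(cfg))
  if (!is.null(out))
    jsonlite::write_json(metrics, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(metrics)
}

#' Phantom reconstruction demo
#'
#' Acquires the dynamic phantom along the configured trajectory,
#' reconstructs one image per frame and writes the image series (flat
#' binary + JSON sidecar) and a ventricular projection map (CSV).
#'
#' @param config a [read_run_config()] input with a `phantom` block.
#' @param out_dir output directory.
#' @return list with images, projection map and paths, invisibly.
#' @export
cmd_recon <- function(config, out_dir = ".") {
  cfg <- read_run_config(config)
  if (is.null(cfg$phantom))
    stop("config error: missing 'phantom' block", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- geom_from_config(cfg)
  ph <- cardiac_phantom(fov = geom$fov,
                        period = if (is.null(cfg$phantom$period_s)) 1 else cfg$phantom$period_s,
                        contraction = if (is.null(cfg$phantom$contraction)) 0.15 else cfg$phantom$contraction)
  scheme <- segmentation_scheme(cfg$n_shots, cfg$n_segments, cfg$tr_s)
  ecg <- ecg_from_config(cfg)
  log <- run_acquisition(ecg, scheme, cfg$mode, match = match_from_config(cfg),
                         seed = cfg$seed)
  nfr <- if (is.null(cfg$phantom$n_frames)) 24 else cfg$phantom$n_frames
  from <- attr(log, "active_start")
  if (is.null(from) || is.na(from)) from <- scheme$n_views + 1L
  steps <- round(seq(max(from, scheme$n_views + 1), nrow(log), length.out = nfr))
  matches <- attr(log, "matches")
  images <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    i <- steps[f]
    ang <- if (scheme$n_shots == 1) log$angle_deg[(i - scheme$n_views):(i - 1)]
           else log$angle_deg[cpp_collate_one(i, matches$idx, scheme$n_segments,
                                              scheme$n_shots)]
    smp <- acquire_spoke_samples(ph, ang, log$time_s[i], geom)
    images[[f]] <- reconstruct_frame(smp, ang, geom)
  }
  proj <- ventricular_projection(images,
                                 line = list(x0 = -geom$fov / 4, y0 = 0.01,
                                             x1 = geom$fov / 4, y1 = 0.01),
                                 fov = geom$fov)
  hash <- config_hash(cfg)
  bin_path <- file.path(out_dir, "images.bin")
  con <- file(bin_path, "wb")
  for (im in images) writeBin(as.numeric(im), con, size = 8)
  close(con)
  jsonlite::write_json(list(shape = c(nrow(images[[1]]), ncol(images[[1]]), nfr),
                            dtype = "float64 column-major",
                            fov_m = geom$fov, config_hash = hash,
                            seed = cfg$seed),
                       file.path(out_dir, "images.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(proj, file.path(out_dir, "projection.csv"), row.names = FALSE)
  invisible(list(images = images, projection = proj,
                 paths = c(images = bin_path,
                           sidecar = file.path(out_dir, "images.json"),
                           projection = file.path(out_dir, "projection.csv"))))
}

#' Write a configured synthetic ECG to CSV
#'
#' @param config a [read_run_config()] input.
#' @param out output CSV path.
#' @return `out`, invisibly.
#' @export
cmd_ecg <- function(config, out) {
  cfg <- read_run_config(config)
  write_ecg_csv(ecg_from_config(cfg), out)
}
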