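# YAML-configured pipeline runner binding the stages together, with strict
# config validation, CSV outputs stamped with the config hash, and a plain
# text log.

pipeline_schema <- list(
  seed = c("seed"),
  simulate = c("n_movies", "frame_count", "roi", "pixel_size",
               "frame_interval", "stoichiometries", "n_assemblies",
               "diffusion", "background", "read_noise", "brightness",
               "brightness_cv", "bleach_rate", "psf_sigma"),
  detect = c("snr_threshold", "min_separation", "signal_radius",
             "background_box_halfwidth"),
  link = c("max_displacement", "max_gap", "min_track_length"),
  stoich = c("window", "late_stage_fraction", "n_initial_frames",
             "brightness_fallback"),
  mobility = c("n_lags", "threshold"),
  periodicity = c("kernel_sd", "grid_step", "peak_prominence_fraction")
)

validate_config <- function(config) {
  bad_top <- setdiff(names(config), names(pipeline_schema))
  if (length(bad_top)) {
    stop(sprintf("validation error: unknown config section(s): %s",
                 paste(bad_top, collapse = ", ")), call. = FALSE)
  }
  for (sec in setdiff(names(config), "seed")) {
    bad <- setdiff(names(config[[sec]]), pipeline_schema[[sec]])
    if (length(bad)) {
      stop(sprintf("validation error: unknown key(s) in `%s`: %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(config$seed)) {
    stop("validation error: config must set `seed`", call. = FALSE)
  }
  invisible(TRUE)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV (skipping the config-hash header comment)
#' @param path CSV path written by [run_pipeline()].
#' @export
read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run the tracking/stoichiometry pipeline on synthetic movies
#'
#' Executes the requested stages -- simulate, detect, track, stoich,
#' mobility, periodicity -- on the movies described by the YAML
#' configuration, writing stage outputs as CSV (each stamped with the config
#' hash) plus a plain-text log. Each simulated movie is treated as one
#' nucleus.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Unknown keys are rejected.
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run (later stages require the
#'   earlier ones in the same call).
#' @return Invisibly, a list of the stage result data frames.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "detect", "track", "stoich",
                                    "mobility", "periodicity")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  hash <- config_hash(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
        file = logf, append = TRUE)
  }
  cat(sprintf("config_hash: %s\nseed: %d\nslimspt: %s\n", hash,
              config$seed, as.character(utils::packageVersion("slimspt"))),
      file = logf)
  sim_cfg <- config$simulate %||% list()
  n_movies <- sim_cfg$n_movies %||% 3L
  cal <- movie_calibration(
    pixel_size = sim_cfg$pixel_size %||% 0.053,
    frame_interval = sim_cfg$frame_interval %||% 0.0125,
    frame_count = sim_cfg$frame_count %||% 60L,
    roi = unlist(sim_cfg$roi %||% c(128L, 96L)))
  emit <- emitter_model(
    brightness_b = sim_cfg$brightness %||% 110,
    brightness_cv = sim_cfg$brightness_cv %||% (15 / 110),
    bleach_rate = sim_cfg$bleach_rate %||% 0.02,
    psf_sigma = sim_cfg$psf_sigma %||% 0.130)
  noi <- noise_model(background_level = sim_cfg$background %||% 50,
                     read_noise_sd = sim_cfg$read_noise %||% 5)
  ap <- aperture_config(
    signal_radius = config$detect$signal_radius %||% 5L,
    background_box_halfwidth = config$detect$background_box_halfwidth %||% 8L,
    snr_threshold = config$detect$snr_threshold %||% 0.4,
    min_separation = config$detect$min_separation %||% 5)
  lk <- linking_config(
    max_displacement = config$link$max_displacement %||% 0.45,
    max_gap = config$link$max_gap %||% 1L,
    min_track_length = config$link$min_track_length %||% 3L)

  results <- list()
  sims <- list()
  if ("simulate" %in% stages) {
    set.seed(config$seed)
    ss <- unlist(sim_cfg$stoichiometries %||% c(4, 8, 12, 16))
    nA <- sim_cfg$n_assemblies %||% 6L
    for (mv in seq_len(n_movies)) {
      asm <- data.frame(S = sample(ss, nA, replace = TRUE),
                        D = sim_cfg$diffusion %||% 0.3)
      sims[[mv]] <- simulate_movie(cal, asm, emit, noi,
                                   seed = config$seed + 1000L * mv)
      write_simulation(sims[[mv]], out_dir, sprintf("movie_%02d", mv))
    }
    log_line("simulate: %d movies, %d assemblies each", n_movies, nA)
    results$truth <- do.call(rbind, lapply(seq_along(sims), function(mv)
      cbind(nucleus_id = mv, sims[[mv]]$truth)))
  }
  if ("detect" %in% stages || "track" %in% stages) {
    stopifnot(length(sims) > 0)
    all_foci <- list()
    for (mv in seq_along(sims)) {
      sim <- sims[[mv]]
      foci <- do.call(rbind, lapply(seq_len(dim(sim$movie)[3]), function(f) {
        fx <- detect_foci(sim$movie[, , f], ap, cal$pixel_size,
                          emit$psf_sigma)
        if (nrow(fx)) cbind(frame = f, fx) else NULL
      }))
      if (!is.null(foci)) all_foci[[mv]] <- cbind(nucleus_id = mv, foci)
    }
    foci <- do.call(rbind, all_foci)
    log_line("detect: %d foci across %d movies", nrow(foci), length(sims))
    write_stamped_csv(foci, file.path(out_dir, "foci.csv"), hash)
    results$foci <- foci
  }
  if ("track" %in% stages) {
    tracks <- do.call(rbind, lapply(split(results$foci,
                                          results$foci$nucleus_id),
                                    function(sub) {
      tr <- link_tracks(sub, lk)
      if (nrow(tr)) tr$track_id <- paste0(sub$nucleus_id[1], "_", tr$track_id)
      tr
    }))
    rownames(tracks) <- NULL
    log_line("track: %d tracks (%d foci kept)",
             length(unique(tracks$track_id)), nrow(tracks))
    write_stamped_csv(tracks, file.path(out_dir, "tracks.csv"), hash)
    results$tracks <- tracks
  }
  if ("stoich" %in% stages) {
    traces <- lapply(split(results$tracks, results$tracks$track_id),
                     function(tr) tr$intensity[order(tr$frame)])
    calib <- tryCatch(
      calibrate_brightness(traces,
        late_stage_fraction = config$stoich$late_stage_fraction %||% 0.5,
        window = config$stoich$window %||% 10L),
      error = function(e) {
        fb <- config$stoich$brightness_fallback %||% emit$brightness_b
        log_line("stoich: step calibration failed (%s); using fallback b = %g",
                 conditionMessage(e), fb)
        structure(list(b_modal = fb, b_sd = NA_real_, n_steps_used = 0L),
                  class = "brightness_calibration")
      })
    log_line("stoich: b_modal = %.1f from %d steps", calib$b_modal,
             calib$n_steps_used)
    yaml::write_yaml(list(b_modal = calib$b_modal, b_sd = calib$b_sd,
                          n_steps_used = calib$n_steps_used),
                     file.path(out_dir, "calibration.yaml"))
    st <- stoichiometry_table(results$tracks, calib,
                              stoich_config(config$stoich$n_initial_frames
                                            %||% 5L))
    write_stamped_csv(st, file.path(out_dir, "stoichiometry.csv"), hash)
    log_line("stoich: %d accepted tracks", nrow(st))
    results$stoichiometry <- st
    results$calibration <- calib
  }
  if ("mobility" %in% stages) {
    dt <- diffusion_table(results$tracks, cal$frame_interval,
                          config$mobility$n_lags %||% 4L)
    merged <- merge(results$stoichiometry, dt, by = "track_id")
    write_stamped_csv(merged, file.path(out_dir, "stoichiometry_mobility.csv"),
                      hash)
    grp <- mobility_by_stoichiometry(merged,
                                     config$mobility$threshold %||% 10)
    write_stamped_csv(grp, file.path(out_dir, "mobility_groups.csv"), hash)
    log_line("mobility: %d tracks with D estimates", nrow(dt))
    results$mobility <- merged
    results$mobility_groups <- grp
  }
  if ("periodicity" %in% stages) {
    pc <- periodicity_config(
      kernel_sd = config$periodicity$kernel_sd %||% 0.6,
      grid_step = config$periodicity$grid_step %||% 0.05,
      peak_prominence_fraction =
        config$periodicity$peak_prominence_fraction %||% 0.05)
    st <- results$stoichiometry
    st$nucleus_id <- sub("_.*", "", st$track_id)
    pr <- periodicity_by_nucleus(st, pc)
    out <- data.frame(P = pr$P, P_rounded = pr$P_rounded,
                      defined = pr$defined, n_nuclei_used = pr$n_nuclei_used,
                      n_intervals = length(pr$intervals))
    write_stamped_csv(out, file.path(out_dir, "periodicity.csv"), hash)
    log_line("periodicity: P = %s from %d intervals",
             format(pr$P), length(pr$intervals))
    results$periodicity <- pr
  }
  invisible(results)
}

#' Brunner-Munzel test on two CSV columns
#'
#' @param path CSV file (a `#` comment header is allowed).
#' @param col_x,col_y Column names holding the two samples.
#' @param method Passed to [brunner_munzel()].
#' @return A `bm_test`.
#' @export
cli_stats <- function(path, col_x, col_y, method = "t") {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c(col_x, col_y) %in% names(df))) {
    stop(sprintf("validation error: columns %s/%s not found", col_x, col_y),
         call. = FALSE)
  }
  brunner_munzel(df[[col_x]][!is.na(df[[col_x]])],
                 df[[col_y]][!is.na(df[[col_y]])], method = method)
}
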