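# File dialects. All CSVs are plain comma-separated with a header row and
# optional leading comment lines starting with '#'; writers stamp a
# '# config_hash=' comment, readers tolerate and ignore comments. Numbers
# are written with 15 significant digits so write -> read round-trips to
# at least 12 digits.

write_csv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste(names(df), collapse = ","), con)
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 15, format = "g") else
      as.character(col)
  })
  writeLines(do.call(paste, c(cols, sep = ",")), con)
}

read_csv_commented <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Fingerprint of a configuration
#'
#' Stable 32-bit hash of the canonical key=value rendering of a config
#' list; stamped into every CSV written by the package so outputs can be
#' traced to the settings that produced them.
#'
#' @param config a [run_config()] or any named list of scalars.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  drv <- config$driver
  # the preset label is a convenience alias; the driver fields determine it
  flat <- c(unclass(config)[!(names(config) %in% c("driver", "preset"))],
            if (!is.null(drv)) unclass(drv))
  flat <- flat[order(names(flat))]
  s <- paste(vapply(seq_along(flat), function(i) {
    v <- flat[[i]]
    paste0(names(flat)[i], "=",
           paste(format(v, digits = 15), collapse = ";"))
  }, character(1)), collapse = "|")
  fnv1a32(s)
}

#' Write / read an apical track CSV (`t,x,y`)
#'
#' @param track an [apical_track()].
#' @param path file path.
#' @param config optional config whose hash is stamped in a comment.
#' @return `read_track` returns an [apical_track()].
#' @export
write_track <- function(track, path, config = NULL) {
  comments <- if (!is.null(config)) paste0("config_hash=", config_hash(config))
  write_csv_commented(track[, c("t", "x", "y")], path, comments)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- read_csv_commented(path)
  stopifnot(all(c("t", "x", "y") %in% names(df)))
  apical_track(df$t, df$x, df$y)
}

#' Write / read organ-state fields CSV (`t,s,rest_length,C,psi_c`)
#'
#' Long format, one row per material segment per saved frame; the
#' `segment` column preserves material identity for Lagrangian analysis.
#'
#' @param sim a `nutation_sim` (or a data frame from [organ_fields()]).
#' @param path file path.
#' @param config optional config to stamp.
#' @return `read_organ_fields` returns the long-format data frame.
#' @export
write_organ_fields <- function(sim, path, config = NULL) {
  df <- if (inherits(sim, "nutation_sim")) organ_fields(sim) else sim
  if (is.null(config) && inherits(sim, "nutation_sim")) config <- sim$config
  comments <- if (!is.null(config)) paste0("config_hash=", config_hash(config))
  write_csv_commented(df[, c("t", "segment", "s", "rest_length", "C",
                             "psi_c")], path, comments)
  invisible(path)
}

#' @rdname write_organ_fields
#' @export
read_organ_fields <- function(path) {
  df <- read_csv_commented(path)
  stopifnot(all(c("t", "segment", "s", "rest_length", "C", "psi_c") %in%
                  names(df)))
  df
}

#' Write a reconstructed centerline CSV
#'
#' Columns `s,x,y,z,tx,ty,tz,d1x,d1y,d1z`.
#'
#' @param line a `centerline3d`.
#' @param path file path.
#' @export
write_centerline <- function(line, path) {
  df <- data.frame(s = line$s,
                   x = line$points[, 1], y = line$points[, 2],
                   z = line$points[, 3],
                   tx = line$tangents[, 1], ty = line$tangents[, 2],
                   tz = line$tangents[, 3],
                   d1x = line$d1[, 1], d1y = line$d1[, 2],
                   d1z = line$d1[, 3])
  write_csv_commented(df, path)
  invisible(path)
}

#' Write / read a driver + run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `read_config_json` returns a [run_config()].
#' @export
write_config_json <- function(config, path) {
  drv <- config$driver
  payload <- list(
    driver_type = drv$rule, omega = drv$omega, a = drv$a,
    psi_g0 = drv$psi_g0, delta_edot = drv$delta_edot, edot = drv$edot,
    gamma = drv$gamma,
    L_gz = if (is.finite(drv$L_gz)) drv$L_gz,  # omitted = whole organ grows
    zone_frac = drv$zone_frac, zone_omega = drv$zone_omega,
    zone_delta_edot = drv$zone_delta_edot,
    R = config$R, L0 = config$L0, n_segments = config$n_segments,
    C0 = config$C0, psi_c0 = config$psi_c0,
    dt = config$dt, t_end = config$t_end, save_stride = config$save_stride,
    noise_sd = config$noise_sd, seed = config$seed,
    method = config$method, keep_quadratic = config$keep_quadratic,
    config_hash = config_hash(config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  driver <- growth_driver(
    rule = p$driver_type,
    delta_edot = p$delta_edot %||% 0, edot = p$edot %||% 0,
    omega = p$omega %||% 0, a = p$a %||% 0, psi_g0 = p$psi_g0 %||% 0,
    zone_frac = p$zone_frac %||% c(0.5, 0.5),
    zone_omega = p$zone_omega, zone_delta_edot = p$zone_delta_edot,
    gamma = p$gamma %||% 0, L_gz = p$L_gz %||% Inf)
  run_config(driver = driver, R = p$R, L0 = p$L0,
             n_segments = p$n_segments, C0 = p$C0, psi_c0 = p$psi_c0,
             dt = p$dt, t_end = p$t_end, save_stride = p$save_stride,
             noise_sd = p$noise_sd %||% 0, seed = p$seed,
             method = p$method %||% "euler",
             keep_quadratic = isTRUE(p$keep_quadratic))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
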