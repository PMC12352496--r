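#' Write a sweep set as CSV plus a JSON sidecar
#'
#' The CSV has a `time_s` column followed by one `dirXXX_trialY` column per
#' (direction, trial); the sidecar records sampling rate, recording mode,
#' holding potential and units.
#'
#' @param sweeps A `sweep_set`.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, the CSV path.
#' @export
write_sweep_set <- function(sweeps, csv_path,
                            json_path = sub("\\.csv$", ".json", csv_path)) {
  cols <- list(time_s = sweeps$t)
  for (i in seq_along(sweeps$directions)) {
    m <- sweeps$traces[[i]]
    for (tr in seq_len(ncol(m))) {
      cols[[sprintf("dir%03d_trial%d", round(sweeps$directions[i]), tr)]] <-
        m[, tr]
    }
  }
  utils::write.csv(as.data.frame(cols), csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate_hz = sweeps$sampling_rate,
         recording_mode = sweeps$recording_mode,
         holding_mv = sweeps$holding_mv,
         units = sweeps$units,
         directions_deg = sweeps$directions),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(csv_path)
}

#' Read a sweep set written by [write_sweep_set()]
#'
#' @param csv_path,json_path Input paths.
#' @return A `sweep_set`.
#' @export
read_sweep_set <- function(csv_path,
                           json_path = sub("\\.csv$", ".json", csv_path)) {
  d <- utils::read.csv(csv_path, check.names = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  nm <- setdiff(names(d), "time_s")
  parts <- regmatches(nm, regexec("^dir([0-9]{3})_trial([0-9]+)$", nm))
  dirs <- as.numeric(vapply(parts, `[`, "", 2))
  traces <- lapply(sort(unique(dirs)), function(dd) {
    sel <- nm[dirs == dd]
    sel <- sel[order(as.integer(vapply(
      regmatches(sel, regexec("trial([0-9]+)$", sel)), `[`, "", 2
    )))]
    as.matrix(d[, sel, drop = FALSE])
  })
  names(traces) <- sprintf("dir%03d", sort(unique(dirs)))
  new_sweep_set(sort(unique(dirs)), traces, d$time_s,
                meta$sampling_rate_hz, meta$recording_mode, meta$units,
                if (is.null(meta$holding_mv)) NA_real_ else meta$holding_mv)
}

#' Write a marker table in the pose-estimation CSV dialect
#'
#' Three header rows (scorer / bodyparts / coords) followed by per-frame
#' rows: frame index then `x, y, likelihood` for each of the 8 pupil and 3
#' corneal-reflection markers.
#'
#' @param markers A `marker_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_marker_table <- function(markers, path) {
  bodyparts <- c(paste0("pupil", 1:8), paste0("refl", 1:3))
  header1 <- c("scorer", rep("dsokr-synthetic", 33))
  header2 <- c("bodyparts", rep(bodyparts, each = 3))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), 11))
  body <- matrix(NA_real_, markers$n_frames, 33)
  for (i in 1:8) {
    body[, (i - 1) * 3 + 1:3] <-
      cbind(markers$pupil_x[, i], markers$pupil_y[, i], markers$pupil_lik[, i])
  }
  for (i in 1:3) {
    body[, 24 + (i - 1) * 3 + 1:3] <-
      cbind(markers$refl_x[, i], markers$refl_y[, i], markers$refl_lik[, i])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header1, collapse = ","),
               paste(header2, collapse = ","),
               paste(header3, collapse = ",")), con)
  utils::write.table(
    cbind(seq_len(markers$n_frames) - 1L, body), con,
    sep = ",", row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a pose-estimation marker CSV
#'
#' @param path Input path.
#' @param fps Frame rate to record in the table, frames/s.
#' @param camera_id Camera label.
#' @return A `marker_table`.
#' @export
read_marker_table <- function(path, fps = 100, camera_id = "A") {
  header <- readLines(path, n = 3)
  bodyparts <- strsplit(header[2], ",")[[1]][-1]
  coords <- strsplit(header[3], ",")[[1]][-1]
  d <- utils::read.csv(path, skip = 3, header = FALSE)
  vals <- as.matrix(d[, -1, drop = FALSE])
  pick <- function(part, coord) {
    vals[, which(bodyparts == part & coords == coord), drop = TRUE]
  }
  grab <- function(parts, coord) {
    do.call(cbind, lapply(parts, pick, coord = coord))
  }
  pupils <- paste0("pupil", 1:8)
  refls <- paste0("refl", 1:3)
  new_marker_table(
    grab(pupils, "x"), grab(pupils, "y"), grab(pupils, "likelihood"),
    grab(refls, "x"), grab(refls, "y"), grab(refls, "likelihood"),
    fps, camera_id
  )
}
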