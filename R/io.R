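# Plain-text dialect readers and writers. The wearable-system dialect is
# one file per sensor with whitespace-separated decimals: 3 columns (Euler
# angles), 4 columns (quaternions) or 9 columns (raw
# accelerometer/gyroscope/magnetometer samples); there is no time column, so
# time is reconstructed as k / rate. The optical-reference dialect has a
# time column followed by per-rigid-body Y_Yaw_#, X_Pitch_#, Z_Roll_#
# columns. The kinematic output file has one column per analytical unit of
# movement plus a time column, written through a line buffer.

.parse_numeric_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  list(fields = fields, line_no = keep)
}

#' Read a per-sensor plain-text stream
#'
#' Parses the wearable-system dialect. The mode is declared or inferred
#' from the column count: 3 columns are Euler angles (degrees, intrinsic
#' order per `order`), 4 are quaternions (w x y z), 9 are raw sensor
#' samples (ax ay az gx gy gz mx my mz). Row order is preserved and the
#' sample index `k` assigned sequentially; time is `k / rate`.
#'
#' @param path File to read.
#' @param mode `"auto"` (default), `"euler"`, `"quaternion"` or `"raw"`.
#' @param rate Sampling rate in Hz used to reconstruct time.
#' @param order Euler axis order for 3-column files.
#' @param sensor_id Optional sensor id attached to the result.
#' @return For `"raw"`, an [imu_stream()] tibble; for `"euler"` a tibble
#'   `t, k, angle1, angle2, angle3`; for `"quaternion"` a tibble
#'   `t, k, qw, qx, qy, qz`.
#' @export
read_imu_file <- function(path, mode = c("auto", "euler", "quaternion", "raw"),
                        rate = 60, order = "ZYX", sensor_id = NA_integer_) {
  mode <- match.arg(mode)
  parsed <- .parse_numeric_lines(path)
  fields <- parsed$fields
  if (!length(fields)) {
    stop("File '", path, "' holds no data rows.", call. = FALSE)
  }
  widths <- lengths(fields)
  expected <- switch(mode, auto = widths[1L], euler = 3L, quaternion = 4L,
                     raw = 9L)
  if (mode == "auto" && !expected %in% c(3L, 4L, 9L)) {
    stop("Cannot infer mode: first row of '", path, "' has ", expected,
         " fields (expected 3, 4 or 9).", call. = FALSE)
  }
  bad <- which(widths != expected)
  if (length(bad)) {
    stop("Malformed row: line ", parsed$line_no[bad[1L]], " of '", path,
         "' has ", widths[bad[1L]], " fields, expected ", expected, ".",
         call. = FALSE)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = expected, byrow = TRUE)
  )
  if (anyNA(vals)) {
    bad_row <- which(apply(is.na(vals), 1L, any))[1L]
    stop("Parse error: non-numeric field on line ", parsed$line_no[bad_row],
         " of '", path, "'.", call. = FALSE)
  }
  n <- nrow(vals)
  k <- seq_len(n) - 1L
  t <- k / rate
  if (expected == 9L) {
    return(imu_stream(t, vals[, 1:3], vals[, 4:6], vals[, 7:9], rate = rate,
                      sensor_id = sensor_id))
  }
  out <- if (expected == 3L) {
    tibble::tibble(t = t, k = k, angle1 = vals[, 1], angle2 = vals[, 2],
                   angle3 = vals[, 3])
  } else {
    tibble::tibble(t = t, k = k, qw = vals[, 1], qx = vals[, 2],
                   qy = vals[, 3], qz = vals[, 4])
  }
  attr(out, "rate") <- rate
  attr(out, "sensor_id") <- sensor_id
  attr(out, "order") <- order
  out
}

#' Write a per-sensor plain-text stream
#'
#' Inverse of [read_imu_file()]. The columns written are chosen from the data:
#' nine raw channels for an `imu_stream`, four for a quaternion track
#' (`qw..qz`), three for an Euler table (`angle1..angle3`). Values are
#' space-separated with `digits` decimal places.
#'
#' @param x Tibble to write.
#' @param path Output file.
#' @param digits Decimal places (default 6).
#' @return `path`, invisibly.
#' @export
write_imu_file <- function(x, path, digits = 6) {
  cols <- if (all(c("ax", "gz", "mz") %in% names(x))) {
    c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  } else if (all(c("qw", "qz") %in% names(x))) {
    c("qw", "qx", "qy", "qz")
  } else if (all(c("angle1", "angle3") %in% names(x))) {
    c("angle1", "angle2", "angle3")
  } else {
    stop("Cannot infer dialect: need raw, quaternion or Euler columns.",
         call. = FALSE)
  }
  m <- as.matrix(x[, cols])
  lines <- apply(formatC(m, format = "f", digits = digits), 1L, paste,
                 collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

#' Read an optical-reference export
#'
#' Parses the optical-system dialect: a header row, a capture-time first
#' column, then per-rigid-body angle triplets named `Y_Yaw_<id>`,
#' `X_Pitch_<id>`, `Z_Roll_<id>` in degrees. Comma or whitespace separation
#' is auto-detected.
#'
#' @param path File to read.
#' @return A long tibble with columns `rigid_body`, `t`, `yaw`, `pitch`,
#'   `roll` (degrees).
#' @export
read_motive <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    stop("File '", path, "' is empty.", call. = FALSE)
  }
  sep <- if (grepl(",", lines[1L], fixed = TRUE)) "," else "[ \t]+"
  split1 <- function(s) trimws(strsplit(trimws(s), sep)[[1L]])
  header <- split1(lines[1L])
  ids <- unique(sub("^Y_Yaw_", "", grep("^Y_Yaw_", header, value = TRUE)))
  for (id in ids) {
    need <- paste0(c("Y_Yaw_", "X_Pitch_", "Z_Roll_"), id)
    if (!all(need %in% header)) {
      stop("Incomplete rigid body '", id, "': expected columns ",
           paste(need, collapse = ", "), ".", call. = FALSE)
    }
  }
  if (length(lines) == 1L) {
    return(tibble::tibble(rigid_body = character(), t = numeric(),
                          yaw = numeric(), pitch = numeric(),
                          roll = numeric()))
  }
  rows <- lapply(lines[-1L], split1)
  widths <- lengths(rows)
  if (any(widths != length(header))) {
    stop("Malformed row: data line ", which(widths != length(header))[1L],
         " has ", widths[widths != length(header)][1L], " fields, header has ",
         length(header), ".", call. = FALSE)
  }
  vals <- matrix(as.numeric(unlist(rows)), ncol = length(header),
                 byrow = TRUE)
  if (anyNA(vals)) {
    stop("Parse error: non-numeric field in '", path, "'.", call. = FALSE)
  }
  t <- vals[, 1L]
  if (any(diff(t) <= 0)) {
    stop("Ordering error: capture time must be strictly increasing.",
         call. = FALSE)
  }
  purrr::map_dfr(ids, function(id) {
    tibble::tibble(
      rigid_body = id, t = t,
      yaw = vals[, match(paste0("Y_Yaw_", id), header)],
      pitch = vals[, match(paste0("X_Pitch_", id), header)],
      roll = vals[, match(paste0("Z_Roll_", id), header)]
    )
  })
}

#' Write an optical-reference export
#'
#' Inverse of [read_motive()]: takes the long tibble and writes the wide
#' dialect with a time column and per-rigid-body Yaw/Pitch/Roll triplets.
#'
#' @param x Long tibble with `rigid_body`, `t`, `yaw`, `pitch`, `roll`.
#' @param path Output file.
#' @param sep Field separator, `","` (default) or `" "`.
#' @param digits Decimal places.
#' @return `path`, invisibly.
#' @export
write_motive <- function(x, path, sep = ",", digits = 6) {
  ids <- unique(x$rigid_body)
  wide <- NULL
  for (id in ids) {
    part <- x[x$rigid_body == id, c("t", "yaw", "pitch", "roll")]
    names(part) <- c("t", paste0(c("Y_Yaw_", "X_Pitch_", "Z_Roll_"), id))
    wide <- if (is.null(wide)) part else dplyr::full_join(wide, part,
                                                          by = "t")
  }
  wide <- dplyr::arrange(wide, .data$t)
  header <- paste(names(wide), collapse = sep)
  body <- apply(formatC(as.matrix(wide), format = "f", digits = digits), 1L,
                paste, collapse = sep)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a kinematic output file through a line buffer
#'
#' One row per sample with a time column and one column per analytical unit
#' of movement. Rows are accumulated in a buffer flushed to storage every
#' `buffer_lines` lines (the device-side convention that prevents data
#' loss), with the remainder flushed at close; the file content is
#' independent of the buffer size.
#'
#' @param series A `"joint_angles"` tibble.
#' @param path Output file.
#' @param buffer_lines Buffer size in lines (default 120).
#' @param digits Decimal places.
#' @return Invisibly, a list with `path`, `rows` and `flushes` (the number
#'   of full-buffer flushes performed before close).
#' @export
write_kinematic <- function(series, path, buffer_lines = 120, digits = 6) {
  stopifnot(buffer_lines >= 1)
  cols <- intersect(c("flexion_extension", "pronation_supination"),
                    names(series))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("t", cols), collapse = ","), con)
  n <- nrow(series)
  flushes <- 0L
  if (n > 0L) {
    m <- cbind(series$t, as.matrix(series[, cols]))
    lines <- apply(formatC(m, format = "f", digits = digits), 1L, paste,
                   collapse = ",")
    buf <- character(0)
    for (i in seq_len(n)) {
      buf <- c(buf, lines[i])
      if (length(buf) == buffer_lines) {
        writeLines(buf, con)
        flush(con)
        buf <- character(0)
        flushes <- flushes + 1L
      }
    }
    if (length(buf)) {
      writeLines(buf, con)
    }
  }
  invisible(list(path = path, rows = n, flushes = flushes))
}

#' Read a kinematic output file
#'
#' @param path File written by [write_kinematic()].
#' @return A `"joint_angles"` tibble (pose mode not stored in the dialect).
#' @export
read_kinematic <- function(path) {
  df <- utils::read.csv(path)
  out <- tibble::as_tibble(df)
  class(out) <- c("joint_angles", class(out))
  out
}

#' Serialize a calibration result to a key-value text file
#'
#' Writes the calibration matrices, mounting angles and static mean vectors
#' as YAML for session reuse; [read_calibration()] restores the object.
#'
#' @param calib An `"elbow_calibration"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  payload <- list(
    M1 = as.numeric(calib$M1), M2 = as.numeric(calib$M2),
    delta_arm = as.numeric(calib$mounts$arm$delta),
    delta_forearm = as.numeric(calib$mounts$forearm$delta),
    mean_a_arm = as.numeric(calib$mean_a$arm),
    mean_a_forearm = as.numeric(calib$mean_a$forearm),
    mean_b_arm = as.numeric(calib$mean_b$arm),
    mean_b_forearm = as.numeric(calib$mean_b$forearm),
    n = as.integer(calib$n)
  )
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}

#' @rdname write_calibration
#' @return `read_calibration()` returns the restored `"elbow_calibration"`.
#' @export
read_calibration <- function(path) {
  p <- yaml::read_yaml(path)
  mounts <- list(
    arm = mounting_rotation(1L, p$delta_arm),
    forearm = mounting_rotation(2L, p$delta_forearm)
  )
  out <- list(
    M1 = matrix(p$M1, 3, 3), M2 = matrix(p$M2, 3, 3), mounts = mounts,
    mean_a = list(arm = p$mean_a_arm, forearm = p$mean_a_forearm),
    mean_b = list(arm = p$mean_b_arm, forearm = p$mean_b_forearm),
    basis = NULL, n = c(arm = p$n[1], forearm = p$n[2])
  )
  class(out) <- "elbow_calibration"
  out
}

#' Write a simulated session to a directory
#'
#' Emits the raw 9-channel per-sensor streams in the wearable-system
#' dialect (`arm.txt`, `forearm.txt`), the ground-truth angles as
#' `truth.csv`, and a `session.yml` with the generating configuration.
#'
#' @param session An `"imu_session"`.
#' @param dir Output directory (created if missing).
#' @param digits Decimal places for the stream files.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, digits = 6) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  write_imu_file(session$arm, file.path(dir, "arm.txt"), digits = digits)
  write_imu_file(session$forearm, file.path(dir, "forearm.txt"),
               digits = digits)
  utils::write.csv(session$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  meta <- list(
    rate = session$rate, t_cal = session$t_cal,
    seed = if (is.null(session$seed)) NA else session$seed,
    delta_arm = as.numeric(session$mounts$arm$delta),
    delta_forearm = as.numeric(session$mounts$forearm$delta),
    duration = session$duration
  )
  yaml::write_yaml(meta, file.path(dir, "session.yml"), precision = 15)
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Session directory.
#' @return A list with `arm`, `forearm` streams, `truth` tibble (if
#'   present), and the metadata fields.
#' @export
read_session <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "session.yml"))
  arm <- read_imu_file(file.path(dir, "arm.txt"), mode = "raw",
                     rate = meta$rate, sensor_id = 1L)
  forearm <- read_imu_file(file.path(dir, "forearm.txt"), mode = "raw",
                         rate = meta$rate, sensor_id = 2L)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    out <- tibble::as_tibble(utils::read.csv(truth_path))
    class(out) <- c("joint_angles", class(out))
    out
  }
  list(arm = arm, forearm = forearm, truth = truth, rate = meta$rate,
       t_cal = meta$t_cal, seed = meta$seed,
       mounts = list(arm = mounting_rotation(1L, meta$delta_arm),
                     forearm = mounting_rotation(2L, meta$delta_forearm)),
       duration = meta$duration)
}
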