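# Two-system comparison: resample both angle series onto the coarser time
# grid, estimate the inter-system lag by normalized cross-correlation, and
# report RMSE, bias and range-of-motion difference per movement channel.

#' Align two angle time series
#'
#' Resamples both series (linear interpolation, after unwrapping) onto the
#' grid of the lower-rate series over their common time support, estimates
#' the lag of `b` relative to `a` by maximizing the normalized
#' cross-correlation over `+/- max_lag`, and shifts `b` by that lag.
#'
#' @param a,b Tibbles with a time column `t` and the angle column `channel`.
#' @param channel Name of the angle column (default `"flexion_extension"`).
#' @param max_lag Lag search half-window in seconds (default 2).
#' @return A tibble of class `"aligned_pair"` with columns `t`, `a`, `b`
#'   and attributes `lag` (s, the estimated delay of `b`), `rate` (Hz) and
#'   `degenerate` (flat-series flag).
#' @export
align_series <- function(a, b, channel = "flexion_extension", max_lag = 2) {
  if (nrow(a) < 1L || nrow(b) < 1L) {
    stop("Cannot align an empty series.", call. = FALSE)
  }
  xa <- unwrap_deg(a[[channel]])
  xb <- unwrap_deg(b[[channel]])
  ta <- a$t
  tb <- b$t
  rate_a <- 1 / stats::median(diff(ta))
  rate_b <- 1 / stats::median(diff(tb))
  rate <- min(rate_a, rate_b)
  dt <- 1 / rate

  lo <- max(min(ta), min(tb))
  hi <- min(max(ta), max(tb))
  if (hi <= lo) {
    stop("No overlap between the two series' time supports.", call. = FALSE)
  }
  grid <- seq(lo, hi, by = dt)
  fa <- stats::approx(ta, xa, xout = grid, rule = 2)$y
  fb <- stats::approx(tb, xb, xout = grid, rule = 2)$y

  degenerate <- stats::sd(fa) < 1e-9 || stats::sd(fb) < 1e-9
  lag <- 0
  if (!degenerate && max_lag > 0) {
    max_k <- min(length(grid) - 2L, as.integer(round(max_lag / dt)))
    best <- -Inf
    for (kk in seq(-max_k, max_k)) {
      if (kk >= 0) {
        u <- fa[seq_len(length(fa) - kk)]
        v <- fb[seq_len(length(fb) - kk) + kk]
      } else {
        u <- fa[seq_len(length(fa) + kk) - kk]
        v <- fb[seq_len(length(fb) + kk)]
      }
      if (length(u) < 3L || stats::sd(u) < 1e-12 || stats::sd(v) < 1e-12) {
        next
      }
      cc <- stats::cor(u, v)
      if (is.finite(cc) && cc > best) {
        best <- cc
        lag <- kk * dt
      }
    }
  }
  # shift b back by the estimated lag and re-interpolate onto the grid
  fb_shift <- stats::approx(tb - lag, xb, xout = grid, rule = 2)$y
  out <- tibble::tibble(t = grid, a = fa, b = fb_shift)
  attr(out, "lag") <- lag
  attr(out, "rate") <- rate
  attr(out, "degenerate") <- degenerate
  class(out) <- c("aligned_pair", class(out))
  out
}

#' Root mean square error between two aligned series
#'
#' `sqrt(mean((a - b)^2))` in degrees. Symmetric in its arguments and
#' invariant to a common additive shift; for a constant offset `c`,
#' `rmse(a, a + c) = |c|` exactly.
#'
#' @param x An `"aligned_pair"` from [align_series()], or a numeric vector.
#' @param y When `x` is numeric, the second series.
#' @return RMSE in degrees.
#' @examples
#' rmse(c(0, 3, 0, 3), c(0, 0, 0, 0)) # sqrt(4.5)
#' @export
rmse <- function(x, y = NULL) {
  if (inherits(x, "aligned_pair")) {
    a <- x$a
    b <- x$b
  } else {
    a <- as.numeric(x)
    b <- as.numeric(y)
  }
  if (!length(a) || length(a) != length(b)) {
    stop("RMSE needs two non-empty series of equal length.", call. = FALSE)
  }
  sqrt(mean((a - b)^2))
}

#' Compare an estimated angle series against a reference system
#'
#' Aligns each movement channel of the two series and reports RMSE, bias
#' (mean difference a - b), range-of-motion difference, estimated lag and
#' sample count per channel. This is the workflow used to validate the
#' wearable system against an optical reference.
#'
#' @param imu Estimated `"joint_angles"` (or any tibble with `t` and the
#'   channels).
#' @param ref Reference series with the same channels.
#' @param channels Channels to compare.
#' @param max_lag Lag search half-window in seconds.
#' @return An object of class `"rom_comparison"`: a tibble with one row per
#'   channel (`channel`, `rmse`, `bias`, `rom_a`, `rom_b`, `rom_diff`,
#'   `lag`, `n`).
#' @export
compare_systems <- function(imu, ref,
                            channels = c("flexion_extension",
                                         "pronation_supination"),
                            max_lag = 2) {
  channels <- intersect(channels, intersect(names(imu), names(ref)))
  if (!length(channels)) {
    stop("No common angle channels to compare.", call. = FALSE)
  }
  rows <- purrr::map_dfr(channels, function(ch) {
    pair <- align_series(imu, ref, channel = ch, max_lag = max_lag)
    rom_a <- max(pair$a) - min(pair$a)
    rom_b <- max(pair$b) - min(pair$b)
    tibble::tibble(
      channel = ch,
      rmse = rmse(pair),
      bias = mean(pair$a - pair$b),
      rom_a = rom_a, rom_b = rom_b, rom_diff = rom_a - rom_b,
      lag = attr(pair, "lag"),
      n = nrow(pair)
    )
  })
  class(rows) <- c("rom_comparison", class(rows))
  rows
}

#' @export
print.rom_comparison <- function(x, ...) {
  cat("<rom_comparison> per-channel agreement (degrees)\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) round(v, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Joint angles from an optical-reference export
#'
#' Reduces a two-rigid-body optical export to the same joint-angle series
#' as the wearable pipeline: per-body Euler triples are converted to
#' rotation matrices, the forearm body is expressed in the arm body's
#' frame, and the same extractors are applied, so both systems are reduced
#' to angles by identical math.
#'
#' @param motive Long tibble from [read_motive()].
#' @param arm_body,forearm_body Rigid-body ids of the arm and forearm.
#' @param order Intrinsic Euler order of the export's yaw/pitch/roll
#'   columns (default `"ZYX"`: yaw, then pitch, then roll).
#' @param pose_mode As in [angle_series()].
#' @return A `"joint_angles"` tibble.
#' @export
reference_angles <- function(motive, arm_body, forearm_body, order = "ZYX",
                             pose_mode = "upright") {
  arm <- motive[motive$rigid_body == arm_body, ]
  fore <- motive[motive$rigid_body == forearm_body, ]
  if (nrow(arm) != nrow(fore) || nrow(arm) == 0L) {
    stop("Arm and forearm rigid bodies must share the export's time base.",
         call. = FALSE)
  }
  to_q <- function(df) {
    t(vapply(seq_len(nrow(df)), function(i) {
      as.numeric(euler_to_quat(c(df$yaw[i], df$pitch[i], df$roll[i]),
                               order = order))
    }, numeric(4)))
  }
  angle_series(orientation_track(arm$t, to_q(arm)),
               orientation_track(fore$t, to_q(fore)),
               pose_mode = pose_mode)
}
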