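#' Read a triaxial accelerometer recording from CSV
#'
#' Reads a recording in the package's CSV dialect: header `t,x,y,z`, where
#' `t` is the sample timestamp in integer microseconds since epoch and
#' `x`, `y`, `z` are accelerations in g (multiples of standard gravity).
#' Rows are validated against the sensor contract: accelerations must lie
#' within the +/- 4 g scale range, timestamps must be non-negative and
#' strictly increasing. Violating rows are dropped with a warning giving
#' the counts; saturated samples are treated as unreliable rather than
#' clipped.
#'
#' @param path Path to a CSV file with columns `t,x,y,z`.
#' @param fs_expected Nominal sampling frequency in Hz used for a sanity
#'   check on the median sampling rate (a deviation beyond 20% warns).
#' @param range_g Sensor scale range in g. Default 4.
#'
#' @return A tibble with columns `t` (microseconds, numeric), `x`, `y`,
#'   `z` (g), ordered by time.
#' @export
#' @examples
#' walk <- simulate_walk(degradation_config(beta = 0.2, duration_s = 10, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_accel_csv(walk, f)
#' read_accel_csv(f)
read_accel_csv <- function(path, fs_expected = 25, range_g = 4) {
  if (!file.exists(path)) {
    stop_gaitspec(paste0("file not found: ", path), "format")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("t", "x", "y", "z")
  if (!all(needed %in% names(raw))) {
    stop_gaitspec(
      paste0("missing columns: ", paste(setdiff(needed, names(raw)), collapse = ", ")),
      "format"
    )
  }
  raw <- raw[needed]
  if (!all(vapply(raw, is.numeric, logical(1)))) {
    stop_gaitspec("columns t,x,y,z must be numeric", "format")
  }
  validate_accel(raw, fs_expected = fs_expected, range_g = range_g)
}

#' Validate an in-memory accelerometer table
#'
#' Applies the same row-level validation as [read_accel_csv()]: finite
#' values, accelerations within the scale range, non-negative strictly
#' increasing timestamps.
#'
#' @inheritParams read_accel_csv
#' @param accel Data frame with columns `t,x,y,z`.
#' @return A validated tibble.
#' @export
validate_accel <- function(accel, fs_expected = 25, range_g = 4) {
  accel <- as_tibble(accel)
  n0 <- nrow(accel)
  finite <- stats::complete.cases(accel) &
    is.finite(accel$t) & is.finite(accel$x) & is.finite(accel$y) & is.finite(accel$z)
  accel <- accel[finite, ]
  in_range <- abs(accel$x) <= range_g & abs(accel$y) <= range_g &
    abs(accel$z) <= range_g & accel$t >= 0
  accel <- accel[in_range, ]
  # strict monotonicity: drop any row not above the running max of its
  # predecessors (device retransmissions arrive out of order)
  prev_max <- cummax(dplyr::lag(accel$t, default = -Inf))
  monotone <- accel$t > prev_max
  accel <- accel[monotone, ]

  n_dropped <- c(
    nonfinite = sum(!finite),
    out_of_range = sum(!in_range),
    nonmonotone = sum(!monotone)
  )
  if (any(n_dropped > 0)) {
    warn(paste0(
      "dropped ", sum(n_dropped), " invalid row(s) of ", n0,
      " (non-finite: ", n_dropped[["nonfinite"]],
      ", out of range: ", n_dropped[["out_of_range"]],
      ", timestamp regression: ", n_dropped[["nonmonotone"]], ")"
    ))
  }
  if (nrow(accel) < 2) {
    stop_gaitspec("fewer than 2 valid samples", "input")
  }
  fs_obs <- 1e6 / median(diff(accel$t))
  if (is.finite(fs_obs) && abs(fs_obs - fs_expected) > 0.2 * fs_expected) {
    warn(sprintf(
      "observed sampling rate %.2f Hz deviates from expected %g Hz",
      fs_obs, fs_expected
    ))
  }
  accel
}

#' Write a recording to CSV
#'
#' Inverse of [read_accel_csv()]; timestamps are written as integer
#' microseconds so a write/read round trip is exact.
#'
#' @param accel Accelerometer tibble (`t,x,y,z`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(accel, path) {
  out <- tibble(
    t = sprintf("%.0f", accel$t),
    x = accel$x, y = accel$y, z = accel$z
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Sampling frequency implied by the timestamps, Hz.
accel_fs <- function(accel) {
  1e6 / median(diff(accel$t))
}

#' Resample a recording onto a uniform time grid
#'
#' The spectral analysis assumes samples at a constant step `delta = 1/fs`.
#' Real devices jitter; this puts the recording on an exactly uniform grid:
#'
#' * input already uniform at `fs_target` (within `jitter_tol` of a step):
#'   values pass through unchanged, timestamps snapped to the grid;
#' * input uniform at an integer multiple of `fs_target`: plain decimation
#'   (every r-th sample), mirroring a 100 to 25 Hz subsampling without an
#'   anti-alias filter — the aliasing risk of bare subsampling is accepted
#'   and documented;
#' * otherwise: linear interpolation of each axis onto the grid.
#'
#' The operation is idempotent at a fixed `fs_target`.
#'
#' @param accel Accelerometer tibble (`t,x,y,z`).
#' @param fs_target Target sampling frequency in Hz (> 0).
#' @param jitter_tol Tolerated relative deviation of successive steps from
#'   the nominal step before interpolation kicks in. Default 0.02.
#' @return A uniformly sampled tibble (`t,x,y,z`).
#' @export
regularize <- function(accel, fs_target = 25, jitter_tol = 0.02) {
  if (!is.numeric(fs_target) || length(fs_target) != 1 || fs_target <= 0) {
    stop_gaitspec("fs_target must be a single positive number", "parameter")
  }
  if (nrow(accel) < 2) {
    stop_gaitspec("need at least 2 samples", "input")
  }
  t0 <- accel$t[1]
  t_s <- (accel$t - t0) / 1e6
  dt <- diff(t_s)
  delta <- 1 / fs_target
  delta_in <- median(dt)
  uniform <- max(abs(dt - delta_in)) <= jitter_tol * delta_in

  if (uniform && abs(delta_in - delta) <= jitter_tol * delta) {
    # pass-through: snap timestamps to the uniform grid
    n <- nrow(accel)
    return(tibble(
      t = t0 + round((0:(n - 1)) * 1e6 / fs_target),
      x = accel$x, y = accel$y, z = accel$z
    ))
  }

  ratio <- delta / delta_in
  if (uniform && ratio >= 1 && abs(ratio - round(ratio)) < 1e-6) {
    idx <- seq(1L, nrow(accel), by = as.integer(round(ratio)))
    n <- length(idx)
    return(tibble(
      t = t0 + round((0:(n - 1)) * 1e6 / fs_target),
      x = accel$x[idx], y = accel$y[idx], z = accel$z[idx]
    ))
  }

  t_grid <- seq(0, t_s[length(t_s)] + delta * 1e-9, by = delta)
  t_grid <- t_grid[t_grid <= t_s[length(t_s)] + 1e-12]
  tibble(
    t = t0 + round(t_grid * 1e6),
    x = approx(t_s, accel$x, xout = t_grid)$y,
    y = approx(t_s, accel$y, xout = t_grid)$y,
    z = approx(t_s, accel$z, xout = t_grid)$y
  )
}

#' Acceleration magnitude
#'
#' Direction-independent intensity `sqrt(x^2 + y^2 + z^2)`, in g. Because
#' the magnitude is invariant under rotations of the device frame, it is
#' insensitive to how the watch sits on the wrist, which is why every
#' spectral index downstream is computed on it.
#'
#' @param accel Accelerometer tibble (`t,x,y,z`).
#' @return A tibble with `time_s` (seconds from recording start) and `mag` (g).
#' @export
#' @examples
#' magnitude(tibble::tibble(t = c(0, 4e4), x = c(3, 0), y = c(4, 0), z = c(0, 1)))
magnitude <- function(accel) {
  if (nrow(accel) < 1) {
    stop_gaitspec("empty series", "input")
  }
  tibble::new_tibble(
    list(
      time_s = (accel$t - accel$t[1]) / 1e6,
      mag = sqrt(accel$x^2 + accel$y^2 + accel$z^2)
    ),
    nrow = nrow(accel)
  )
}

#' Split a recording into fixed-length windows
#'
#' Cuts the recording into complete windows of `window_s` seconds with
#' `overlap_s` seconds of overlap (0 for the non-overlapping 30-s windows
#' used for activity recognition). A trailing partial window is discarded.
#'
#' @param accel Accelerometer tibble (`t,x,y,z`).
#' @param window_s Window length in seconds (> 0).
#' @param overlap_s Overlap between consecutive windows in seconds
#'   (`0 <= overlap_s < window_s`).
#' @return A tibble with one row per window: `window` (1-based index),
#'   `start_s` (window start, seconds from recording start) and `data`
#'   (list column of accelerometer tibbles).
#' @export
split_windows <- function(accel, window_s = 30, overlap_s = 0) {
  if (window_s <= 0 || overlap_s < 0 || overlap_s >= window_s) {
    stop_gaitspec("need window_s > 0 and 0 <= overlap_s < window_s", "parameter")
  }
  fs <- accel_fs(accel)
  w <- as.integer(round(window_s * fs))
  o <- as.integer(round(overlap_s * fs))
  n <- nrow(accel)
  if (w > n) {
    return(tibble(
      window = integer(), start_s = numeric(),
      data = list()
    ))
  }
  starts <- seq(1L, n - w + 1L, by = w - o)
  tibble(
    window = seq_along(starts),
    start_s = (accel$t[starts] - accel$t[1]) / 1e6,
    data = lapply(starts, function(i) accel[i:(i + w - 1L), ])
  )
}
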