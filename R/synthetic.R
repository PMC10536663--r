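#' Configuration for the spectral gait-degradation simulator
#'
#' Describes a synthetic quasi-periodic walk: a dominant stepping
#' frequency `f0` with harmonics, a gravity offset, broadband noise, and a
#' degradation parameter `beta` that moves spectral power from the
#' stepping harmonics to an emerging lower frequency `f_new` at constant
#' total band power. `beta` abstracts disease progression: harmonic
#' amplitudes are scaled by `sqrt(1 - beta * rho_transfer)` and the new
#' tone receives exactly the removed power, so the realized gait-band
#' power is independent of `beta`.
#'
#' `rho_transfer` caps the fraction of band power the emerging mode can
#' absorb. The default 0.4 keeps the fundamental dominant at every
#' `beta` — consistent with the modeling assumption that the new mode's
#' amplitude stays below the original one — and guarantees that spectral
#' entropy is strictly increasing and the weighted mean frequency strictly
#' decreasing in `beta` over `[0, 0.9]`: entropy of a
#' three-atom distribution turns over once the emerging mode holds more
#' than `1/(1 + exp(H))` of the power (`H` the entropy of the harmonic
#' amplitude split), so a full transfer would break monotonicity at high
#' `beta`.
#'
#' @param beta Degradation parameter in `[0, 1]`.
#' @param f0 Dominant stepping frequency, Hz. Default 1.8 (typical step
#'   rate).
#' @param f_new Emerging lower frequency, Hz; must satisfy
#'   `0 < f_new < f0`. Default 0.7.
#' @param p_total Total band power of the tones, as the mean square of the
#'   oscillatory magnitude signal in g^2. Default 0.04 (oscillation
#'   amplitudes of a few tenths of g, typical at the wrist).
#' @param harmonic_amps Relative amplitudes of the harmonics of `f0`.
#'   Default `c(1, 0.4)`.
#' @param rho_transfer Maximum transferable power fraction at `beta = 1`,
#'   in `(0, 1]`. Default 0.4.
#' @param noise_sd Per-axis white-noise SD, g. Default 0.05.
#' @param gravity Constant gravity offset, g. Default 1.
#' @param fs Sampling frequency, Hz. Default 25.
#' @param duration_s Walk duration, s. Default 120.
#' @param seed Integer seed for phases and noise; `NULL` uses the current
#'   RNG state.
#' @return A validated list of class `degradation_config`.
#' @export
degradation_config <- function(beta = 0, f0 = 1.8, f_new = 0.7,
                               p_total = 0.04, harmonic_amps = c(1, 0.4),
                               rho_transfer = 0.4, noise_sd = 0.05,
                               gravity = 1, fs = 25, duration_s = 120,
                               seed = NULL) {
  if (beta < 0 || beta > 1) {
    stop_gaitspec("beta must lie in [0, 1]", "parameter")
  }
  if (f_new <= 0 || f_new >= f0) {
    stop_gaitspec("need 0 < f_new < f0", "parameter")
  }
  if (f0 * length(harmonic_amps) >= fs / 2 || f_new >= fs / 2) {
    stop_gaitspec("tone frequencies must be below the Nyquist frequency", "parameter")
  }
  if (p_total <= 0 || rho_transfer <= 0 || rho_transfer > 1) {
    stop_gaitspec("need p_total > 0 and rho_transfer in (0, 1]", "parameter")
  }
  if (noise_sd < 0 || fs <= 0 || duration_s <= 0) {
    stop_gaitspec("noise_sd >= 0, fs > 0 and duration_s > 0 required", "parameter")
  }
  structure(
    list(
      beta = beta, f0 = f0, f_new = f_new, p_total = p_total,
      harmonic_amps = harmonic_amps, rho_transfer = rho_transfer,
      noise_sd = noise_sd, gravity = gravity, fs = fs,
      duration_s = duration_s, seed = seed
    ),
    class = "degradation_config"
  )
}

# Fixed device-orientation rotation (x then y axis). The magnitude is
# rotation-invariant, so the tones survive on it exactly while all three
# axes carry signal.
synthetic_rotation <- function() {
  ax <- 0.35
  ay <- 0.25
  rx <- rbind(
    c(1, 0, 0),
    c(0, cos(ax), -sin(ax)),
    c(0, sin(ax), cos(ax))
  )
  ry <- rbind(
    c(cos(ay), 0, sin(ay)),
    c(0, 1, 0),
    c(-sin(ay), 0, cos(ay))
  )
  ry %*% rx
}

#' Simulate one wrist-accelerometer walk
#'
#' Generates a triaxial recording whose acceleration magnitude carries the
#' configured spectral family: gravity offset plus stepping harmonics
#' scaled by `sqrt(1 - beta * rho_transfer)` plus the emerging tone at
#' `f_new` holding the transferred power, plus white noise, assembled
#' along the gravity axis and passed through a fixed device rotation.
#' At zero noise the realized gait-band power equals the configured
#' `p_total` (in mean-square units) for every `beta`.
#'
#' @param cfg A [degradation_config()].
#' @return An accelerometer tibble (`t` in microseconds, `x,y,z` in g) at
#'   `cfg$fs` Hz.
#' @export
#' @examples
#' walk <- simulate_walk(degradation_config(beta = 0.5, seed = 7))
#' walk_indices(magnitude(walk))
simulate_walk <- function(cfg) {
  stopifnot(inherits(cfg, "degradation_config"))
  n <- as.integer(round(cfg$fs * cfg$duration_s))
  t_s <- (0:(n - 1)) / cfg$fs

  # absolute harmonic amplitudes: sum(a^2)/2 = p_total at beta = 0
  a_base <- cfg$harmonic_amps * sqrt(2 * cfg$p_total / sum(cfg$harmonic_amps^2))
  q <- cfg$beta * cfg$rho_transfer
  a_harm <- a_base * sqrt(1 - q)
  a_new <- sqrt(q * sum(a_base^2))

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_tone <- length(a_harm) + 1
  phases <- runif(n_tone, 0, 2 * pi)

  s <- rep(0, n)
  for (i in seq_along(a_harm)) {
    s <- s + a_harm[i] * sin(2 * pi * i * cfg$f0 * t_s + phases[i])
  }
  s <- s + a_new * sin(2 * pi * cfg$f_new * t_s + phases[n_tone])

  noise <- if (cfg$noise_sd > 0) {
    matrix(rnorm(3 * n, sd = cfg$noise_sd), ncol = 3)
  } else {
    matrix(0, nrow = n, ncol = 3)
  }
  frame <- cbind(noise[, 1], noise[, 2], cfg$gravity + s + noise[, 3])
  xyz <- frame %*% t(synthetic_rotation())

  tibble::new_tibble(
    list(
      t = round(t_s * 1e6),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    ),
    nrow = n
  )
}

#' Simulate a monitoring cohort with programmed trends
#'
#' Generates per-participant walk schedules over a span of days with a
#' linear beta schedule per trend: improving participants go from
#' `beta_mid + beta_swing` down to `beta_mid - beta_swing`, deteriorating
#' participants the reverse, stable participants stay at `beta_mid`. One
#' walk per day. Per-walk random substreams are derived from the seed and
#' the (participant, day) counter, so regeneration is order-independent
#' and a fixed seed reproduces the cohort bit for bit.
#'
#' @param n_improving,n_deteriorating,n_stable Cohort composition.
#' @param days Span of the campaign in days (one walk per day). Default
#'   21, comfortably above the 10-walk eligibility minimum.
#' @param duration_s Walk duration, s. Default 60.
#' @param fs Sampling frequency, Hz. Default 25.
#' @param beta_mid,beta_swing Centre and half-range of the beta schedules.
#'   Defaults 0.3 and 0.15.
#' @param noise_sd Per-axis noise SD, g. Default 0.05.
#' @param start_date First walk date. Default `as.Date("2024-01-01")`.
#' @param seed Integer master seed. Default 1.
#' @param generate Materialize the recordings in a `data` list column
#'   (`TRUE`, default) or return the schedule only.
#' @return A tibble with one row per walk: `participant`, `trend`,
#'   `date`, `day`, `beta`, and `data` (when `generate = TRUE`).
#' @export
simulate_cohort <- function(n_improving = 11, n_deteriorating = 10,
                            n_stable = 0, days = 21, duration_s = 60,
                            fs = 25, beta_mid = 0.3, beta_swing = 0.15,
                            noise_sd = 0.05,
                            start_date = as.Date("2024-01-01"),
                            seed = 1, generate = TRUE) {
  n_total <- n_improving + n_deteriorating + n_stable
  if (n_total < 1) stop_gaitspec("need at least one participant", "parameter")
  trends <- rep(
    c("improving", "deteriorating", "stable"),
    c(n_improving, n_deteriorating, n_stable)
  )
  frac <- if (days > 1) (0:(days - 1)) / (days - 1) else 0

  schedule <- tidyr::expand_grid(
    participant = seq_len(n_total),
    day = 0:(days - 1)
  )
  schedule$trend <- trends[schedule$participant]
  schedule$date <- start_date + schedule$day
  f <- frac[schedule$day + 1]
  schedule$beta <- ifelse(
    schedule$trend == "improving", beta_mid + beta_swing * (1 - 2 * f),
    ifelse(schedule$trend == "deteriorating", beta_mid - beta_swing * (1 - 2 * f),
      beta_mid
    )
  )
  schedule$walk_seed <- walk_substream(seed, schedule$participant, schedule$day)
  if (generate) {
    schedule$data <- purrr::pmap(
      list(schedule$beta, schedule$walk_seed),
      function(b, s) {
        simulate_walk(degradation_config(
          beta = b, fs = fs, duration_s = duration_s,
          noise_sd = noise_sd, seed = s
        ))
      }
    )
  }
  schedule
}

# Deterministic per-walk substream seed below 2^31, order-independent.
walk_substream <- function(seed, participant, day) {
  as.integer((as.numeric(seed) * 100003 + participant * 1009 + day) %% 2147483647)
}

#' Write a simulated cohort as per-walk CSV files
#'
#' Writes each walk in the package CSV dialect as
#' `p<participant>_<date>.csv` plus a `ground_truth.json` file recording
#' each participant's programmed trend.
#'
#' @param cohort A generated cohort from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(nrow(cohort))) {
    write_accel_csv(
      cohort$data[[i]],
      file.path(dir, sprintf("p%03d_%s.csv", cohort$participant[i], cohort$date[i]))
    )
  }
  truth <- dplyr::distinct(cohort, .data$participant, .data$trend)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(dir)
}

#' Read a directory of per-walk CSV files
#'
#' Inverse of [write_cohort_dir()]: reads every `p<participant>_<date>.csv`
#' file into a walk table ready for [index_walks()].
#'
#' @param dir Directory of per-walk CSVs.
#' @param fs_expected Nominal sampling frequency, Hz.
#' @return A tibble with `participant`, `date` and a `data` list column.
#' @export
read_walk_dir <- function(dir, fs_expected = 25) {
  files <- sort(list.files(dir, pattern = "^p\\d+_\\d{4}-\\d{2}-\\d{2}.*\\.csv$"))
  if (length(files) == 0) {
    stop_gaitspec(paste0("no walk CSV files found in ", dir), "input")
  }
  m <- regmatches(files, regexec("^p(\\d+)_(\\d{4}-\\d{2}-\\d{2})", files))
  tibble(
    participant = as.integer(vapply(m, `[`, character(1), 2)),
    date = as.Date(vapply(m, `[`, character(1), 3)),
    data = lapply(file.path(dir, files), read_accel_csv, fs_expected = fs_expected)
  )
}

#' Simulate labeled activity windows for classifier training
#'
#' Builds a synthetic labeled fixture for the activity-classifier
#' contract: `walking` windows from the degradation simulator, `sleeping`
#' windows as a still device (gravity in a fixed orientation plus very
#' small noise), and `sit-stand` windows as slow posture transitions
#' (sub-gait-band orientation drift plus moderate noise). The classes are
#' separable by construction, which is the point — the fixture validates
#' the contract and the training plumbing, not any claim about real
#' free-living data.
#'
#' @param n_per_class Windows per class. Default 30.
#' @param window_s Window length, s. Default 30.
#' @param fs Sampling frequency, Hz. Default 25.
#' @param seed Integer master seed. Default 1.
#' @return A tibble with `label` and a `data` list column of
#'   accelerometer windows.
#' @export
simulate_activity_windows <- function(n_per_class = 30, window_s = 30,
                                      fs = 25, seed = 1) {
  n <- as.integer(round(window_s * fs))
  t_s <- (0:(n - 1)) / fs
  rot <- synthetic_rotation()
  one <- function(label, i) {
    set.seed(walk_substream(seed, match(label, c("walking", "sleeping", "sit-stand")), i))
    if (label == "walking") {
      b <- runif(1, 0, 0.6)
      return(simulate_walk(degradation_config(
        beta = b, fs = fs, duration_s = window_s, noise_sd = 0.05,
        seed = walk_substream(seed, 17L, i)
      )))
    }
    if (label == "sleeping") {
      tilt <- runif(1, -0.3, 0.3)
      frame <- cbind(
        rnorm(n, sd = 0.008),
        sin(tilt) + rnorm(n, sd = 0.008),
        cos(tilt) + rnorm(n, sd = 0.008)
      )
    } else { # sit-stand: slow orientation drift below the gait band
      f_slow <- runif(1, 0.05, 0.2)
      ang <- 0.6 * sin(2 * pi * f_slow * t_s + runif(1, 0, 2 * pi))
      frame <- cbind(
        rnorm(n, sd = 0.03),
        sin(ang) + rnorm(n, sd = 0.03),
        cos(ang) + rnorm(n, sd = 0.03)
      )
    }
    xyz <- frame %*% t(rot)
    tibble(t = round(t_s * 1e6), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  tidyr::expand_grid(
    label = c("walking", "sleeping", "sit-stand"),
    i = seq_len(n_per_class)
  ) |>
    dplyr::mutate(data = purrr::map2(.data$label, .data$i, one)) |>
    dplyr::select("label", "data")
}
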