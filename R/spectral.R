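#' Discrete Fourier spectrum of a signal
#'
#' Computes the unnormalized discrete Fourier transform
#' `d_hat[k+1] = sum_j exp(-2*pi*1i*j*k/N) d[j+1]`, `k = 0, ..., N-1`,
#' of a uniformly sampled signal and attaches the physical frequency axis
#' `s_k = k/T` with `T = N * delta`. The continuous-time transform of the
#' underlying signal is approximated by `delta * d_hat[k+1]`, an
#' approximation that is only meaningful up to the Nyquist index
#' `k <= N/2`; [band_select()] enforces that truncation.
#'
#' @param x A magnitude tibble from [magnitude()] (columns `time_s`, `mag`)
#'   or a bare numeric vector of samples.
#' @param fs Sampling frequency in Hz. Required when `x` is a numeric
#'   vector; inferred from `time_s` otherwise.
#' @return A tibble of class `gait_spectrum` with columns `k` (0-based
#'   index), `freq` (Hz), `coef` (complex DFT coefficient) and `power`
#'   (`Mod(coef)^2`), and attributes `N`, `delta` (s), `T` (s).
#' @export
#' @examples
#' w <- magnitude(simulate_walk(degradation_config(duration_s = 20, seed = 1)))
#' gait_spectrum(w)
gait_spectrum <- function(x, fs = NULL) {
  if (is.data.frame(x)) {
    if (is.null(fs)) fs <- 1 / median(diff(x$time_s))
    values <- x$mag
  } else {
    if (is.null(fs)) {
      stop_gaitspec("fs is required for a bare numeric vector", "parameter")
    }
    values <- as.numeric(x)
  }
  n <- length(values)
  if (n < 2) {
    stop_gaitspec("need at least 2 samples", "input")
  }
  if (!is.numeric(fs) || fs <= 0) {
    stop_gaitspec("fs must be positive", "parameter")
  }
  delta <- 1 / fs
  total_t <- n * delta
  coef <- fft(values)
  out <- tibble::new_tibble(
    list(
      k = 0:(n - 1),
      freq = (0:(n - 1)) / total_t,
      coef = coef,
      power = Mod(coef)^2
    ),
    nrow = n
  )
  structure(out,
    N = n, delta = delta, T = total_t,
    class = c("gait_spectrum", class(out))
  )
}

#' Restrict a spectrum to the gait band and normalize its power
#'
#' Retains coefficients with `f_min <= s_k <= f_max` and `k <= N/2`
#' (the Nyquist truncation below which the DFT approximates the
#' continuous transform), computes the total band power
#' `P = sum(|coef|^2)` and the normalized spectral amplitudes
#' `rho_k = |coef_k|^2 / P`, a discrete probability distribution over the
#' band frequencies. The default band 0.3–10 Hz with the DC bin excluded
#' targets human gait: gravity dominates DC and stepping harmonics live
#' below 10 Hz.
#'
#' @param spec A `gait_spectrum` from [gait_spectrum()].
#' @param f_min,f_max Band limits in Hz, `0 <= f_min < f_max <= fs/2`.
#' @param drop_dc Drop the `k = 0` (DC / gravity) bin. Default `TRUE`.
#' @return A tibble of class `power_dist` with columns `k`, `freq`,
#'   `power`, `rho` and attributes `P` (total band power), `n_bins`,
#'   `band`.
#' @export
band_select <- function(spec, f_min = 0.3, f_max = 10, drop_dc = TRUE) {
  fs <- 1 / attr(spec, "delta")
  n <- attr(spec, "N")
  if (f_min < 0 || f_min >= f_max || f_max > fs / 2 + 1e-12) {
    stop_gaitspec("need 0 <= f_min < f_max <= fs/2", "parameter")
  }
  keep <- spec$k <= floor(n / 2) & spec$freq >= f_min & spec$freq <= f_max
  if (drop_dc) keep <- keep & spec$k > 0
  if (!any(keep)) {
    stop_gaitspec("no frequencies in the requested band", "band")
  }
  power <- spec$power[keep]
  p_total <- sum(power)
  # degenerate signals (e.g. a constant with DC dropped) leave only
  # numerical dust in the band
  if (p_total <= 1e-10 * max(sum(spec$power), .Machine$double.xmin)) {
    stop_gaitspec("zero power in the selected band (degenerate signal)", "degenerate")
  }
  band <- tibble::new_tibble(
    list(
      k = spec$k[keep], freq = spec$freq[keep], power = power,
      rho = power / p_total
    ),
    nrow = sum(keep)
  )
  structure(band,
    P = p_total, n_bins = nrow(band), band = c(f_min, f_max),
    class = c("power_dist", class(band))
  )
}

#' Power-weighted mean frequency
#'
#' The first moment `mu_s = sum_k s_k * rho_k` of the band's normalized
#' power distribution, in Hz. Normalizing the squared amplitudes by the
#' total band power makes the weights sum to one, so `mu_s` is a true
#' frequency; under the model's power-conservation assumption this differs
#' from weighting by raw squared amplitudes only by the constant total
#' power. The weighted mean falls when spectral mass migrates to emerging
#' lower frequencies, i.e. with gait degradation.
#'
#' @param pd A `power_dist` from [band_select()], or any data frame with
#'   columns `freq` and `rho`.
#' @return Mean frequency in Hz.
#' @export
spectral_mean <- function(pd) {
  sum(pd$freq * pd$rho)
}

#' Frequency variance of the band power distribution
#'
#' `sigma_s^2 = sum_k s_k^2 rho_k - mu_s^2`, in Hz^2. The variance
#' responds only mildly to degradation compared with the entropy, because
#' its sensitivity is damped by how close the mean sits to the midpoint of
#' the exchanging frequencies.
#'
#' @inheritParams spectral_mean
#' @return Variance in Hz^2 (non-negative).
#' @export
spectral_variance <- function(pd) {
  mu <- spectral_mean(pd)
  max(0, sum(pd$freq^2 * pd$rho) - mu^2)
}

#' Spectral entropy of the band power distribution
#'
#' Shannon entropy `S = -sum_k rho_k * ln(rho_k)` (natural log, with
#' `0 * ln 0 = 0`). A pure tone gives 0; a flat spectrum gives
#' `ln(n_bins)`. A well-defined dominant stepping frequency therefore
#' yields low entropy, and the spreading of spectral mass that accompanies
#' gait degradation raises it — the package's headline gait-quality index.
#'
#' @inheritParams spectral_mean
#' @param normalize Divide by `ln(n_bins)` so the result lies in `[0, 1]`.
#'   Useful when comparing bands of different width; absolute entropies
#'   depend on the band and bin count and are comparable only within one
#'   analysis configuration. Default `FALSE`.
#' @return Entropy (dimensionless).
#' @export
#' @examples
#' spectral_entropy(tibble::tibble(freq = c(1, 2), rho = c(0.9, 0.1)))
spectral_entropy <- function(pd, normalize = FALSE) {
  r <- pd$rho[pd$rho > 0]
  s <- -sum(r * log(r))
  if (normalize) {
    nb <- nrow(pd)
    s <- if (nb > 1) s / log(nb) else 0
  }
  s
}

#' Mean kinetic energy of a walk from the acceleration spectrum
#'
#' Evaluates the spectral estimate of the mean kinetic energy over a walk
#' of duration `T` for a person of mass `m`:
#' `E = m/8 * (|ax(0)|^2 + |ay(0)|^2 + |az(0)|^2) +`
#' `m/(8 pi^2 T^2) * sum_{k != 0} (|ax(0)-ax(s_k)|^2 + |ay(0)-ay(s_k)|^2 +
#' |az(0)-az(s_k)|^2) / s_k^2`,
#' where `a(s_k)` is the continuous-transform approximation
#' `delta * fft(a)` of each axis in m/s^2 and the sum is truncated at the
#' Nyquist index `|k| <= N/2`.
#'
#' The estimate is flagged gravity-contaminated: a wrist device measures
#' gravity components in its own moving frame, which inflate the result by
#' orders of magnitude (hour-scale recordings of a resting device reach
#' the 1e9 J range), so the value is reported for completeness, not used
#' as a gait index. Removing gravity properly needs gyroscope data.
#'
#' @param accel Accelerometer tibble (`t,x,y,z`), uniformly sampled.
#' @param mass Body mass in kg.
#' @return Energy in joules, with attribute `gravity_contaminated = TRUE`.
#' @export
kinetic_energy <- function(accel, mass) {
  if (!all(c("x", "y", "z", "t") %in% names(accel))) {
    stop_gaitspec("need columns t,x,y,z", "input")
  }
  n <- nrow(accel)
  if (n < 2) stop_gaitspec("need at least 2 samples", "input")
  delta <- median(diff(accel$t)) / 1e6
  total_t <- n * delta
  # axis transforms in SI units; a_hat approximates the continuous transform
  ah <- lapply(c("x", "y", "z"), function(ax) delta * fft(accel[[ax]] * G_STANDARD))
  dc <- vapply(ah, function(a) a[1], complex(1))
  kmax <- floor(n / 2)
  if (kmax >= 1) {
    ks <- seq_len(kmax)
    sk2 <- (ks / total_t)^2
    series <- 0
    for (i in 1:3) {
      series <- series + sum(Mod(dc[i] - ah[[i]][ks + 1])^2 / sk2)
    }
    # real signal: |a(-s_k)| = |a(s_k)|, so the two-sided sum doubles
    series <- 2 * series
  } else {
    series <- 0
  }
  e <- mass * sum(Mod(dc)^2) / 8 + mass * series / (8 * pi^2 * total_t^2)
  structure(e, gravity_contaminated = TRUE)
}

#' Write a spectrum to CSV
#'
#' @param spec A `gait_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  readr::write_csv(
    tibble(
      freq = spec$freq, re = Re(spec$coef), im = Im(spec$coef),
      power = spec$power
    ),
    path,
    progress = FALSE
  )
  invisible(path)
}
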