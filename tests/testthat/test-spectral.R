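test_that("DFT of simple closed-form signals matches theory", {
  # constant sequence: all power in the DC coefficient
  sp <- gait_spectrum(rep(3, 8), fs = 8)
  expect_equal(Mod(sp$coef[1]), 24, tolerance = 1e-12)
  expect_lt(max(Mod(sp$coef[-1])), 1e-12)
  expect_equal(sp$freq, 0:7 / 1)

  # single cosine at one cycle per record: coefficients 2 and N land N/2
  x <- cos(2 * pi * (0:7) / 8)
  sp <- gait_spectrum(x, fs = 8)
  expect_equal(Mod(sp$coef[2]), 4, tolerance = 1e-9)
  expect_equal(Mod(sp$coef[8]), 4, tolerance = 1e-9)
  expect_lt(max(Mod(sp$coef[-c(2, 8)])), 1e-9)

  expect_error(gait_spectrum(1, fs = 25), class = "gaitspec_error_input")
})

test_that("fast transform equals the brute-force DFT oracle", {
  withr::local_seed(123)
  x <- rnorm(64)
  sp <- gait_spectrum(x, fs = 25)
  expect_lt(max(Mod(sp$coef - dft_oracle(x))), 1e-9)
})

test_that("Parseval's identity holds for random signals", {
  withr::local_seed(17)
  for (n in c(32, 100, 257)) {
    x <- rnorm(n)
    sp <- gait_spectrum(x, fs = 25)
    lhs <- sum(sp$power)
    rhs <- n * sum(x^2)
    expect_lt(abs(lhs - rhs) / rhs, 1e-8)
  }
})

test_that("band selection isolates tones and normalizes power", {
  # single 2 Hz tone: rho is one-hot at the 2 Hz bin
  x <- sin(2 * pi * 2 * (0:499) / 25)
  pd <- band_select(gait_spectrum(x, fs = 25), f_min = 0.5, f_max = 5)
  expect_equal(sum(pd$rho), 1, tolerance = 1e-12)
  expect_equal(pd$freq[which.max(pd$rho)], 2)
  expect_gt(max(pd$rho), 1 - 1e-9)

  # constant signal with DC dropped leaves a degenerate band
  expect_error(
    band_select(gait_spectrum(rep(2, 100), fs = 25)),
    class = "gaitspec_error_degenerate"
  )

  # two equal tones split the band power evenly (Parseval on the tones)
  x <- sin(2 * pi * 1 * (0:499) / 25) + sin(2 * pi * 3 * (0:499) / 25)
  pd <- band_select(gait_spectrum(x, fs = 25), f_min = 0.5, f_max = 5)
  on_tones <- sort(pd$rho, decreasing = TRUE)[1:2]
  expect_equal(on_tones, c(0.5, 0.5), tolerance = 1e-9)

  expect_error(
    band_select(gait_spectrum(x, fs = 25), f_min = 5, f_max = 1),
    class = "gaitspec_error_parameter"
  )
  # a record too short to place any bin inside the band
  expect_error(
    band_select(gait_spectrum(rnorm(4), fs = 25), f_min = 1, f_max = 5),
    class = "gaitspec_error_band"
  )
})

test_that("weighted mean and variance match a two-pass oracle", {
  one_hot <- tibble::tibble(freq = 1.8, rho = 1)
  expect_equal(spectral_mean(one_hot), 1.8)
  expect_equal(spectral_variance(one_hot), 0)

  half <- tibble::tibble(freq = c(1, 3), rho = c(0.5, 0.5))
  expect_equal(spectral_mean(half), 2)
  expect_equal(spectral_variance(half), 1)

  withr::local_seed(31)
  w <- runif(16)
  pd <- tibble::tibble(freq = sort(runif(16, 0.3, 10)), rho = w / sum(w))
  # independent two-pass oracle: explicit loops over the distribution
  mu_o <- 0
  for (i in 1:16) mu_o <- mu_o + pd$freq[i] * pd$rho[i]
  var_o <- 0
  for (i in 1:16) var_o <- var_o + (pd$freq[i] - mu_o)^2 * pd$rho[i]
  expect_equal(spectral_mean(pd), mu_o, tolerance = 1e-12)
  expect_equal(spectral_variance(pd), var_o, tolerance = 1e-12)
})

test_that("spectral entropy matches hand-computed values and bounds", {
  expect_equal(spectral_entropy(tibble::tibble(freq = 1, rho = 1)), 0)
  expect_equal(
    spectral_entropy(tibble::tibble(freq = 1:4, rho = rep(0.25, 4))),
    log(4)
  )
  expect_equal(
    spectral_entropy(tibble::tibble(freq = 1:2, rho = c(0.9, 0.1))),
    -0.9 * log(0.9) - 0.1 * log(0.1),
    tolerance = 1e-12
  )
  # 0 * ln 0 treated as 0
  expect_equal(
    spectral_entropy(tibble::tibble(freq = 1:3, rho = c(0.5, 0.5, 0))),
    log(2)
  )
  expect_equal(
    spectral_entropy(tibble::tibble(freq = 1:4, rho = rep(0.25, 4)), normalize = TRUE),
    1
  )
})

test_that("entropy is permutation-invariant and rises under equalizing transfers", {
  withr::local_seed(61)
  w <- runif(12)
  rho <- w / sum(w)
  base <- spectral_entropy(tibble::tibble(freq = 1:12, rho = rho))
  perm <- spectral_entropy(tibble::tibble(freq = 1:12, rho = sample(rho)))
  expect_equal(perm, base, tolerance = 1e-12)

  # moving mass from a larger to a smaller bin increases entropy
  for (i in 1:5) {
    hi <- which.max(rho)
    lo <- which.min(rho)
    eps <- (rho[hi] - rho[lo]) / 4
    rho2 <- rho
    rho2[hi] <- rho2[hi] - eps
    rho2[lo] <- rho2[lo] + eps
    s2 <- spectral_entropy(tibble::tibble(freq = 1:12, rho = rho2))
    expect_gt(s2, spectral_entropy(tibble::tibble(freq = 1:12, rho = rho)))
    rho <- rho2
  }
})

test_that("kinetic energy evaluates the spectral formula", {
  n <- 250
  zero <- make_accel(rep(0, n), rep(0, n), rep(0, n), fs = 25)
  expect_equal(as.numeric(kinetic_energy(zero, mass = 70)), 0)

  # constant acceleration: fft coefficients vanish off DC, so the formula
  # reduces to terms involving the DC transform alone; compare against a
  # direct evaluation of the printed expression
  const <- make_accel(rep(0.1, n), rep(0.2, n), rep(-0.05, n), fs = 25)
  e <- as.numeric(kinetic_energy(const, mass = 70))
  delta <- 1 / 25
  t_tot <- n * delta
  direct <- 0
  ah <- lapply(c(0.1, 0.2, -0.05), function(a) delta * fft(rep(a * 9.80665, n)))
  dc2 <- sum(vapply(ah, function(a) Mod(a[1])^2, numeric(1)))
  series <- 0
  for (k in 1:floor(n / 2)) {
    sk2 <- (k / t_tot)^2
    series <- series +
      sum(vapply(ah, function(a) Mod(a[1] - a[k + 1])^2, numeric(1))) / sk2
  }
  direct <- 70 * dc2 / 8 + 70 * 2 * series / (8 * pi^2 * t_tot^2)
  expect_equal(e, direct, tolerance = 1e-9)
  expect_true(attr(kinetic_energy(const, mass = 70), "gravity_contaminated"))
})

test_that("gravity-contaminated energy of a long resting recording is ~1e9 J", {
  # 20 min of a still device at 1 g: the gravity DC term alone drives the
  # estimate into the 1e9 J class, orders of magnitude beyond human energetics
  n <- 20 * 60 * 25
  still <- make_accel(rep(0, n), rep(0, n), rep(1, n), fs = 25)
  e <- as.numeric(kinetic_energy(still, mass = 70))
  expect_gt(log10(e), 8.5)
  expect_lt(log10(e), 10.5)
})
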