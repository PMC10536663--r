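# Independent oracles and small fixture builders shared across tests.

# Brute-force O(N^2) discrete Fourier transform: the reference the fast
# implementation is checked against. Kept deliberately naive.
dft_oracle <- function(x) {
  n <- length(x)
  j <- 0:(n - 1)
  vapply(0:(n - 1), function(k) {
    sum(x * exp(-2i * pi * j * k / n))
  }, complex(1))
}

# Uniformly sampled accelerometer tibble from axis vectors.
make_accel <- function(x, y, z, fs = 25, t0 = 0) {
  n <- length(x)
  tibble::tibble(
    t = t0 + round((0:(n - 1)) * 1e6 / fs),
    x = x, y = y, z = z
  )
}

# Pure-tone accelerometer series: tone of amplitude `amp` at `freq` Hz on
# the gravity axis.
make_tone_accel <- function(freq, fs = 25, duration_s = 60, amp = 0.2,
                            gravity = 1) {
  t_s <- (0:(round(fs * duration_s) - 1)) / fs
  make_accel(
    x = rep(0, length(t_s)),
    y = rep(0, length(t_s)),
    z = gravity + amp * sin(2 * pi * freq * t_s),
    fs = fs
  )
}

# Random 3-D rotation matrix via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Walk table (participant, date, entropy) with synthetic entropies; used
# by pipeline tests that do not need real spectra.
make_walk_table <- function(participant, dates, entropies) {
  tibble::tibble(
    participant = participant,
    date = as.Date(dates),
    entropy = entropies
  )
}

# Independent weighted F1 via an explicit confusion matrix.
f1_weighted_oracle <- function(truth, pred) {
  classes <- sort(unique(truth))
  cm <- table(factor(truth, classes), factor(pred, classes))
  f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    tp <- cm[i, i]
    prec <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec <- if (sum(cm[i, ]) > 0) tp / sum(cm[i, ]) else 0
    f1[i] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  sum(f1 * rowSums(cm)) / sum(cm)
}

# Oracle classifier satisfying the pluggable contract: windows with a wide
# magnitude IQR are walking. Valid on the synthetic fixture by construction.
predict.var_threshold_clf <- function(object, newdata, ...) {
  ifelse(newdata$q75 - newdata$q25 > object$cut, "walking", "sleeping")
}
registerS3method("predict", "var_threshold_clf", predict.var_threshold_clf)
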