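#' Feature registry for activity-recognition windows
#'
#' The named feature set computed on every 30-s window, grouped by type:
#' per-axis position quantiles, pairwise axis correlations, magnitude
#' quantiles, orientation-angle (motion) statistics and spectral (signal)
#' features. The registry has 39 names; the count is exposed so callers
#' can assert the contract.
#'
#' @return Character vector of feature names, in canonical order.
#' @export
har_feature_registry <- function() {
  c(
    # Position: per-axis quantiles
    "xmin", "xq25", "xmed", "xq75", "xmax",
    "ymin", "yq25", "ymed", "yq75", "ymax",
    "zmin", "zq25", "zmed", "zq75", "zmax",
    # Correlation
    "xycorr", "yzcorr", "zxcorr",
    # Statistical: magnitude quantiles
    "min", "q25", "med", "q75", "max",
    # Motion: orientation angles
    "rollg", "pitchg", "yawg",
    "avgroll", "avgpitch", "avgyaw",
    "sdroll", "sdpitch", "sdyaw",
    # Signal
    "pentropy", "f1", "f2", "p1", "p2", "numPeaks", "peakPromin"
  )
}

# Pearson correlation with a 0 fallback for constant axes; reports
# degeneracy through the second element.
safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    return(list(r = 0, degenerate = TRUE))
  }
  list(r = cor(a, b), degenerate = FALSE)
}

# 0.5 Hz 4th-order Butterworth low-pass (zero-phase), isolating the
# gravity component of each axis.
gravity_component <- function(v, fs, f_cut = 0.5) {
  bf <- signal::butter(4, f_cut / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, v))
}

# Local maxima of y with topographic prominence. Returns a tibble
# (index, height, prominence); boundaries are not peaks.
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) {
    return(tibble(index = integer(), height = numeric(), prominence = numeric()))
  }
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  prom <- vapply(idx, function(p) {
    left <- if (p > 1) y[(p - 1):1] else numeric()
    right <- if (p < n) y[(p + 1):n] else numeric()
    base_side <- function(side) {
      if (length(side) == 0) {
        return(min(y))
      }
      higher <- which(side > y[p])
      if (length(higher) == 0) min(side) else min(side[1:(higher[1] - 1)])
    }
    y[p] - max(base_side(left), base_side(right))
  }, numeric(1))
  tibble(index = idx, height = y[idx], prominence = prom)
}

#' Extract the activity-recognition feature vector from one window
#'
#' Computes the full feature registry on a complete window: per-axis and
#' magnitude quantiles (linear-interpolation convention), pairwise Pearson
#' correlations (0 with a degeneracy flag for constant axes), orientation
#' angles — roll `atan2(y, z)`, pitch `atan2(-x, sqrt(y^2 + z^2))` and a
#' horizontal-plane yaw proxy `atan2(y, x)` (true yaw is unobservable from
#' an accelerometer alone) — with the `*g` variants computed on the 0.5 Hz
#' low-pass gravity component and the `avg*`/`sd*` variants on the
#' full-rate angle series, and spectral features of the magnitude on the
#' gait band: spectral entropy (`pentropy`, shared with
#' [spectral_entropy()]), the frequencies and normalized powers of the two
#' largest peaks (`f1,f2,p1,p2`), the number of peaks with prominence at
#' least 5% of the largest peak (`numPeaks`) and the prominence of the
#' most prominent peak (`peakPromin`).
#'
#' A spectrally degenerate window (no power in the band, e.g. a perfectly
#' still device) gets zero signal features and the degeneracy flag.
#'
#' @param window Accelerometer tibble of exactly `window_s * fs` samples.
#' @param fs Sampling frequency, Hz. Default 25.
#' @param window_s Expected window length, s. Default 30.
#' @param f_min,f_max Spectral band for the signal features, Hz.
#' @param prominence_frac Prominence threshold for `numPeaks`, as a
#'   fraction of the largest peak. Default 0.05.
#' @return A one-row tibble with the registry columns, plus an attribute
#'   `degenerate` (TRUE if any correlation or the spectrum was
#'   degenerate).
#' @export
extract_features <- function(window, fs = 25, window_s = 30,
                             f_min = 0.3, f_max = 10,
                             prominence_frac = 0.05) {
  n_expected <- as.integer(round(window_s * fs))
  if (nrow(window) != n_expected) {
    stop_gaitspec(
      sprintf("window has %d samples, expected %d", nrow(window), n_expected),
      "input"
    )
  }
  x <- window$x
  y <- window$y
  z <- window$z
  probs <- c(0, 0.25, 0.5, 0.75, 1)
  qx <- quantile(x, probs, names = FALSE, type = 7)
  qy <- quantile(y, probs, names = FALSE, type = 7)
  qz <- quantile(z, probs, names = FALSE, type = 7)

  cxy <- safe_cor(x, y)
  cyz <- safe_cor(y, z)
  czx <- safe_cor(z, x)
  degenerate <- cxy$degenerate || cyz$degenerate || czx$degenerate

  mag <- sqrt(x^2 + y^2 + z^2)
  qm <- quantile(mag, probs, names = FALSE, type = 7)

  roll <- atan2(y, z)
  pitch <- atan2(-x, sqrt(y^2 + z^2))
  yaw <- atan2(y, x)
  xg <- gravity_component(x, fs)
  yg <- gravity_component(y, fs)
  zg <- gravity_component(z, fs)

  sigf <- tryCatch(
    {
      pd <- band_select(gait_spectrum(mag, fs = fs), f_min = f_min, f_max = f_max)
      peaks <- find_peaks(pd$rho)
      peaks <- dplyr::arrange(peaks, dplyr::desc(.data$height))
      top <- if (nrow(peaks) >= 1) peaks$index[1] else NA_integer_
      second <- if (nrow(peaks) >= 2) peaks$index[2] else NA_integer_
      max_height <- if (nrow(peaks) >= 1) peaks$height[1] else 0
      list(
        pentropy = spectral_entropy(pd),
        f1 = if (is.na(top)) 0 else pd$freq[top],
        f2 = if (is.na(second)) 0 else pd$freq[second],
        p1 = if (is.na(top)) 0 else pd$rho[top],
        p2 = if (is.na(second)) 0 else pd$rho[second],
        numPeaks = sum(peaks$prominence >= prominence_frac * max_height),
        peakPromin = if (nrow(peaks) >= 1) max(peaks$prominence) else 0
      )
    },
    gaitspec_error_degenerate = function(e) {
      degenerate <<- TRUE
      list(pentropy = 0, f1 = 0, f2 = 0, p1 = 0, p2 = 0, numPeaks = 0, peakPromin = 0)
    }
  )

  out <- tibble(
    xmin = qx[1], xq25 = qx[2], xmed = qx[3], xq75 = qx[4], xmax = qx[5],
    ymin = qy[1], yq25 = qy[2], ymed = qy[3], yq75 = qy[4], ymax = qy[5],
    zmin = qz[1], zq25 = qz[2], zmed = qz[3], zq75 = qz[4], zmax = qz[5],
    xycorr = cxy$r, yzcorr = cyz$r, zxcorr = czx$r,
    min = qm[1], q25 = qm[2], med = qm[3], q75 = qm[4], max = qm[5],
    rollg = mean(atan2(yg, zg)),
    pitchg = mean(atan2(-xg, sqrt(yg^2 + zg^2))),
    yawg = mean(atan2(yg, xg)),
    avgroll = mean(roll), avgpitch = mean(pitch), avgyaw = mean(yaw),
    sdroll = sd(roll), sdpitch = sd(pitch), sdyaw = sd(yaw),
    pentropy = sigf$pentropy, f1 = sigf$f1, f2 = sigf$f2,
    p1 = sigf$p1, p2 = sigf$p2,
    numPeaks = as.numeric(sigf$numPeaks), peakPromin = sigf$peakPromin
  )
  stopifnot(identical(names(out), har_feature_registry()))
  attr(out, "degenerate") <- degenerate
  out
}

#' Extract features for a table of windows
#'
#' Maps [extract_features()] over a window table (list column `data`),
#' carrying any `label` and window-position columns through.
#'
#' @param windows Tibble with a `data` list column of accelerometer
#'   windows (e.g. from [split_windows()] or
#'   [simulate_activity_windows()]).
#' @inheritParams extract_features
#' @return A feature tibble, one row per window.
#' @export
extract_all_features <- function(windows, fs = 25, window_s = 30,
                                 f_min = 0.3, f_max = 10) {
  feats <- purrr::map(windows$data, extract_features,
    fs = fs, window_s = window_s, f_min = f_min, f_max = f_max
  )
  meta <- windows[setdiff(names(windows), "data")]
  dplyr::bind_cols(meta, dplyr::bind_rows(feats))
}

# Weighted F1 across classes (weights = class support); undefined
# per-class precision/recall counts as 0.
f1_weighted <- function(truth, pred, classes = sort(unique(truth))) {
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0) {
      return(0)
    }
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  sum(f1 * support) / sum(support)
}

#' Train the reference activity classifier
#'
#' Fits a gradient-boosted-tree classifier (xgboost) on a labeled feature
#' table, searching a small hyperparameter grid by stratified K-fold
#' cross-validation (stratification addresses class imbalance) and
#' refitting the best configuration on all data. The result satisfies the
#' pluggable classifier contract: a deterministic `predict()` from a
#' feature row to an activity label. Any externally trained model exposing
#' the same contract can be substituted; the shipped classifier is trained
#' on the synthetic fixture only and makes no claim about free-living
#' data.
#'
#' @param features Tibble with a `label` column (>= 2 classes) and the
#'   registry feature columns.
#' @param folds Number of stratified CV folds (>= 2). Default 5.
#' @param seed Integer seed controlling fold assignment and fitting.
#' @param grid Data frame of hyperparameter combinations with columns
#'   `max_depth` and `nrounds`.
#' @param eta Learning rate. Default 0.3.
#' @return An object of class `har_classifier`: list with the fitted
#'   booster, `classes`, `feature_names`, the per-configuration CV table
#'   (`cv`) and the cross-validated weighted F1 of the selected
#'   configuration (`f1_cv`).
#' @export
train_reference_classifier <- function(features, folds = 5, seed = 42,
                                       grid = expand.grid(
                                         max_depth = c(2, 4),
                                         nrounds = c(30, 60)
                                       ),
                                       eta = 0.3) {
  if (!"label" %in% names(features)) {
    stop_gaitspec("features must contain a label column", "input")
  }
  y <- as.character(features$label)
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    stop_gaitspec("need at least 2 classes to train", "training")
  }
  if (folds < 2) stop_gaitspec("need folds >= 2", "parameter")
  feature_names <- intersect(har_feature_registry(), names(features))
  xmat <- as.matrix(features[feature_names])
  ynum <- match(y, classes) - 1L

  set.seed(seed)
  fold_idx <- caret::createFolds(factor(y), k = folds, list = TRUE)

  fit_one <- function(rows, max_depth, nrounds) {
    xgboost::xgb.train(
      params = list(
        objective = "multi:softprob", num_class = length(classes),
        max_depth = max_depth, eta = eta, nthread = 1, seed = seed,
        verbosity = 0
      ),
      data = xgboost::xgb.DMatrix(xmat[rows, , drop = FALSE], label = ynum[rows]),
      nrounds = nrounds, verbose = 0
    )
  }
  predict_labels <- function(booster, rows) {
    pr <- predict(booster, xgboost::xgb.DMatrix(xmat[rows, , drop = FALSE]))
    if (!is.matrix(pr)) pr <- matrix(pr, ncol = length(classes), byrow = TRUE)
    classes[max.col(pr, ties.method = "first")]
  }

  cv <- purrr::pmap(grid, function(max_depth, nrounds) {
    f1s <- vapply(fold_idx, function(heldout) {
      train_rows <- setdiff(seq_along(ynum), heldout)
      booster <- fit_one(train_rows, max_depth, nrounds)
      f1_weighted(y[heldout], predict_labels(booster, heldout), classes)
    }, numeric(1))
    tibble(max_depth = max_depth, nrounds = nrounds, f1_weighted = mean(f1s))
  }) |> dplyr::bind_rows()

  best <- cv[which.max(cv$f1_weighted), ]
  final <- fit_one(seq_along(ynum), best$max_depth, best$nrounds)
  structure(
    list(
      booster = final, classes = classes, feature_names = feature_names,
      cv = cv, f1_cv = best$f1_weighted,
      params = list(max_depth = best$max_depth, nrounds = best$nrounds, eta = eta)
    ),
    class = "har_classifier"
  )
}

#' @export
print.har_classifier <- function(x, ...) {
  cat(
    "Activity classifier (gradient-boosted trees):",
    length(x$classes), "classes,", length(x$feature_names), "features\n"
  )
  cat(sprintf(
    "  CV weighted F1 %.3f (max_depth %d, nrounds %d)\n",
    x$f1_cv, x$params$max_depth, x$params$nrounds
  ))
  invisible(x)
}

#' Predict activity labels for feature windows
#'
#' @param object A fitted `har_classifier`.
#' @param newdata Feature tibble with the registry columns.
#' @param ... Unused.
#' @return Character vector of activity labels.
#' @export
predict.har_classifier <- function(object, newdata, ...) {
  if (is.null(object$booster)) {
    stop_gaitspec("classifier is not fitted", "state")
  }
  if (nrow(newdata) == 0) {
    return(character())
  }
  xmat <- as.matrix(newdata[object$feature_names])
  pr <- predict(object$booster, xgboost::xgb.DMatrix(xmat))
  if (!is.matrix(pr)) {
    pr <- matrix(pr, ncol = length(object$classes), byrow = TRUE)
  }
  object$classes[max.col(pr, ties.method = "first")]
}

#' Label feature windows with an activity classifier
#'
#' Applies a classifier satisfying the contract (a `predict` method from
#' feature rows to labels) to every window; walking windows can then be
#' forwarded to the gait pipeline via [walks_from_labels()].
#'
#' @param features Feature tibble, one row per window.
#' @param clf A fitted classifier (e.g. from
#'   [train_reference_classifier()]).
#' @return `features` with a `label` column (replaced if present).
#' @export
label_windows <- function(features, clf) {
  if (inherits(clf, "har_classifier") && is.null(clf$booster)) {
    stop_gaitspec("classifier is not fitted", "state")
  }
  features$label <- predict(clf, features)
  features
}
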