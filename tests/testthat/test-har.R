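test_that("feature registry is complete and extraction fills it", {
  reg <- har_feature_registry()
  expect_length(reg, 39)
  expect_false(any(duplicated(reg)))

  w <- simulate_walk(degradation_config(beta = 0.2, duration_s = 30, seed = 1))
  f <- extract_features(w)
  expect_equal(names(f), reg)
  expect_equal(nrow(f), 1)
  expect_true(all(vapply(f, is.numeric, logical(1))))
  expect_false(attr(f, "degenerate"))

  expect_error(extract_features(w[1:100, ]), class = "gaitspec_error_input")
})

test_that("a constant window yields constant quantiles and degenerate flags", {
  n <- 750
  w <- make_accel(rep(0, n), rep(0, n), rep(1, n), fs = 25)
  f <- extract_features(w)
  expect_true(attr(f, "degenerate"))
  expect_equal(unlist(f[c("xmin", "xq25", "xmed", "xq75", "xmax")]),
    rep(0, 5),
    ignore_attr = TRUE
  )
  expect_equal(unlist(f[c("zmin", "zmax")]), rep(1, 2), ignore_attr = TRUE)
  expect_equal(f$xycorr, 0)
  expect_equal(f$numPeaks, 0)
  expect_equal(f$pentropy, 0)
  expect_equal(unlist(f[c("min", "q25", "med", "q75", "max")]),
    rep(1, 5),
    ignore_attr = TRUE
  )
})

test_that("identical axes give unit correlation", {
  withr::local_seed(12)
  v <- rnorm(750, sd = 0.1)
  w <- make_accel(v, v, 1 + rnorm(750, sd = 0.1), fs = 25)
  f <- extract_features(w)
  expect_equal(f$xycorr, 1, tolerance = 1e-12)
})

test_that("quantile features agree with a sort-based oracle", {
  withr::local_seed(23)
  x <- rnorm(750)
  w <- make_accel(x, rnorm(750), 1 + rnorm(750, sd = 0.1), fs = 25)
  f <- extract_features(w)
  # linear-interpolation convention, checked against explicit formula
  s <- sort(x)
  q_at <- function(p) {
    h <- (750 - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, 750)] - s[lo])
  }
  expect_equal(f$xmin, s[1])
  expect_equal(f$xq25, q_at(0.25), tolerance = 1e-12)
  expect_equal(f$xmed, q_at(0.5), tolerance = 1e-12)
  expect_equal(f$xq75, q_at(0.75), tolerance = 1e-12)
  expect_equal(f$xmax, s[750])
})

test_that("a 2 Hz tone drives the dominant-peak features", {
  w <- make_tone_accel(2, duration_s = 30, amp = 0.3)
  f <- extract_features(w)
  expect_equal(f$f1, 2, tolerance = 1 / 30 + 1e-9) # within one bin width
  expect_gt(f$p1, 0.99)
  expect_gte(f$numPeaks, 1)
  expect_gt(f$peakPromin, 0.9)

  # pentropy shares the spectral entropy implementation
  pd <- band_select(gait_spectrum(magnitude(w)))
  expect_equal(f$pentropy, spectral_entropy(pd), tolerance = 1e-9)
})

test_that("features are invariant to a shift of the window start time", {
  w <- simulate_walk(degradation_config(beta = 0.3, duration_s = 30, seed = 77))
  f0 <- extract_features(w)
  shifted <- dplyr::mutate(w, t = t + 123456789)
  f1 <- extract_features(shifted)
  expect_equal(f1, f0, ignore_attr = TRUE)
})

test_that("reference classifier separates the synthetic activities", {
  fixture <- simulate_activity_windows(n_per_class = 30, seed = 5)
  feats <- extract_all_features(fixture)

  # cleanly separable two-class subset: near-perfect held-out F1
  two <- dplyr::filter(feats, label %in% c("walking", "sleeping"))
  clf2 <- train_reference_classifier(two, folds = 3, seed = 1,
    grid = expand.grid(max_depth = 2, nrounds = 30)
  )
  expect_gte(clf2$f1_cv, 0.95)

  clf <- train_reference_classifier(feats, folds = 3, seed = 1,
    grid = expand.grid(max_depth = 2, nrounds = 30)
  )
  expect_s3_class(clf, "har_classifier")
  expect_gte(clf$f1_cv, 0.9)

  labeled <- label_windows(dplyr::select(feats, -label), clf)
  expect_gte(f1_weighted_oracle(fixture$label, labeled$label), 0.95)

  # deterministic predictions from a fitted artifact
  expect_identical(predict(clf, feats), predict(clf, feats))

  # empty input passes through
  expect_equal(nrow(label_windows(feats[0, ], clf)), 0)
})

test_that("label shuffling drops the cross-validated F1 to chance level", {
  withr::local_seed(2)
  fixture <- simulate_activity_windows(n_per_class = 15, seed = 15)
  feats <- extract_all_features(fixture)
  feats$label <- sample(feats$label)
  clf <- train_reference_classifier(feats, folds = 3, seed = 1,
    grid = expand.grid(max_depth = 2, nrounds = 20)
  )
  # 3 balanced classes: chance weighted F1 ~ 1/3; binomial noise bound
  expect_lt(clf$f1_cv, 0.62)
})

test_that("stratified folds preserve class proportions", {
  withr::local_seed(3)
  y <- factor(rep(c("walking", "sleeping", "sit-stand"), times = c(20, 15, 10)))
  folds <- caret::createFolds(y, k = 5)
  for (f in folds) {
    for (cl in levels(y)) {
      expected <- sum(y == cl) / 5
      expect_lte(abs(sum(y[f] == cl) - expected), 1)
    }
  }
})

test_that("training refuses degenerate inputs", {
  fixture <- simulate_activity_windows(n_per_class = 4, seed = 8)
  feats <- extract_all_features(fixture)
  one_class <- dplyr::filter(feats, label == "walking")
  expect_error(
    train_reference_classifier(one_class, folds = 2),
    class = "gaitspec_error_training"
  )
  expect_error(
    train_reference_classifier(feats, folds = 1),
    class = "gaitspec_error_parameter"
  )
  expect_error(
    train_reference_classifier(dplyr::select(feats, -label)),
    class = "gaitspec_error_input"
  )
})

test_that("an oracle threshold classifier recovers programmed walking spans", {
  # windows with known labels by construction: walking has high gait-band
  # power, rest does not; a magnitude-variance threshold is a valid oracle
  fixture <- simulate_activity_windows(n_per_class = 8, seed = 21)
  feats <- extract_all_features(fixture)
  thresh <- structure(list(cut = 0.1), class = "var_threshold_clf")
  labeled <- label_windows(dplyr::select(feats, -label), thresh)
  expect_equal(
    labeled$label == "walking",
    fixture$label == "walking"
  )
})
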