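#' Gait-quality indices for one walk
#'
#' Composes the spectral pipeline — DFT of the acceleration magnitude,
#' gait-band selection, normalized power distribution — into the per-walk
#' index set: weighted mean frequency `mu`, frequency variance `sigma2`,
#' spectral entropy `entropy`, total band power `power` and the number of
#' band bins `n_bins`.
#'
#' @param mag A magnitude tibble from [magnitude()], or a numeric vector
#'   of magnitude samples (then `fs` is required). At least 2 s of data.
#' @param fs Sampling frequency in Hz (inferred from `time_s` for tibbles).
#' @param f_min,f_max,drop_dc Band configuration, see [band_select()].
#' @param normalize_entropy Normalize entropy by `ln(n_bins)`; see
#'   [spectral_entropy()].
#' @return A one-row tibble: `mu`, `sigma2`, `entropy`, `power`, `n_bins`.
#' @export
#' @examples
#' walk <- simulate_walk(degradation_config(beta = 0, duration_s = 60, seed = 1))
#' walk_indices(magnitude(walk))
walk_indices <- function(mag, fs = NULL, f_min = 0.3, f_max = 10,
                         drop_dc = TRUE, normalize_entropy = FALSE) {
  spec <- gait_spectrum(mag, fs = fs)
  if (attr(spec, "T") < 2) {
    stop_gaitspec("need at least 2 s of data", "input")
  }
  pd <- band_select(spec, f_min = f_min, f_max = f_max, drop_dc = drop_dc)
  tibble::new_tibble(
    list(
      mu = spectral_mean(pd),
      sigma2 = spectral_variance(pd),
      entropy = spectral_entropy(pd, normalize = normalize_entropy),
      power = attr(pd, "P"),
      n_bins = attr(pd, "n_bins")
    ),
    nrow = 1L
  )
}

#' Compute indices for a table of walks
#'
#' Maps [walk_indices()] over a walk table (one row per walk with the raw
#' recording in a list column), as produced by [simulate_cohort()] or
#' [read_walk_dir()].
#'
#' @param walks Tibble with a list column `data` of accelerometer tibbles.
#' @param keep_data Keep the raw `data` column. Default `FALSE`.
#' @inheritParams walk_indices
#' @return `walks` with columns `mu`, `sigma2`, `entropy`, `power`,
#'   `n_bins` appended.
#' @export
index_walks <- function(walks, f_min = 0.3, f_max = 10, drop_dc = TRUE,
                        normalize_entropy = FALSE, keep_data = FALSE) {
  idx <- purrr::map(walks$data, function(a) {
    walk_indices(magnitude(a),
      f_min = f_min, f_max = f_max,
      drop_dc = drop_dc, normalize_entropy = normalize_entropy
    )
  })
  out <- dplyr::bind_cols(walks, dplyr::bind_rows(idx))
  if (!keep_data) out$data <- NULL
  out
}

#' Mean entropy over the initial or final period
#'
#' Arithmetic mean of walk entropies inside the first (respectively last)
#' `period_days` calendar days of a participant's record. The default of
#' 7 days compares the first and final week of data collection.
#'
#' @param walks Tibble with columns `date` (Date) and `entropy`, one row
#'   per walk.
#' @param period `"initial"` or `"final"`.
#' @param period_days Length of the period in calendar days. Default 7.
#' @return Mean entropy over the period.
#' @export
period_entropy <- function(walks, period = c("initial", "final"),
                           period_days = 7) {
  period <- match.arg(period)
  if (nrow(walks) < 1) {
    stop_gaitspec("no walks in record", "insufficient_data")
  }
  d <- as.Date(walks$date)
  sel <- if (period == "initial") {
    d < min(d) + period_days
  } else {
    d > max(d) - period_days
  }
  if (!any(sel)) {
    stop_gaitspec("no walks inside the requested period", "insufficient_data")
  }
  mean(walks$entropy[sel])
}

#' Percentage entropy variation between two periods
#'
#' `(final - initial) / initial * 100`. Positive values mean the entropy
#' rose, i.e. the gait deteriorated; negative values mean improvement;
#' exactly zero is classed stable.
#'
#' @param initial,final Period mean entropies; `initial` must be positive.
#' @return Percentage variation (vectorized).
#' @export
#' @examples
#' entropy_variation_pct(0.707, 0.726)
entropy_variation_pct <- function(initial, final) {
  if (any(!is.finite(initial)) || any(initial <= 0)) {
    stop_gaitspec("initial entropy must be positive", "domain")
  }
  (final - initial) / initial * 100
}

#' Per-participant trajectory summary
#'
#' Collapses an indexed walk table into one row per participant with the
#' entropy summary used for longitudinal reporting: number of walks,
#' min/max/mean entropy, the initial- and final-period means and the
#' percentage entropy variation between them.
#'
#' @param walks Tibble with columns `participant`, `date`, `entropy`.
#' @param period_days Initial/final period length in days. Default 7.
#' @return A tibble with columns `participant`, `n_walks`, `min_entropy`,
#'   `max_entropy`, `mean_entropy`, `initial_entropy`, `final_entropy`,
#'   `variation_pct`.
#' @export
summarize_participants <- function(walks, period_days = 7) {
  walks |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(w, key) {
      ini <- period_entropy(w, "initial", period_days)
      fin <- period_entropy(w, "final", period_days)
      tibble(
        n_walks = nrow(w),
        min_entropy = min(w$entropy),
        max_entropy = max(w$entropy),
        mean_entropy = mean(w$entropy),
        initial_entropy = ini,
        final_entropy = fin,
        variation_pct = entropy_variation_pct(ini, fin)
      )
    }) |>
    dplyr::ungroup()
}

#' Retain participants with enough walks
#'
#' Longitudinal comparisons need a minimum amount of data; participants
#' who recorded fewer than `min_walks` walks over the collection period
#' are excluded.
#'
#' @param x Either a participant summary (with an `n_walks` column, from
#'   [summarize_participants()]) or a walk-level tibble with a
#'   `participant` column.
#' @param min_walks Minimum number of walks to retain a participant.
#'   Default 10.
#' @return `x` filtered to eligible participants.
#' @export
eligibility_filter <- function(x, min_walks = 10) {
  if ("n_walks" %in% names(x)) {
    return(dplyr::filter(x, .data$n_walks >= min_walks))
  }
  if (!"participant" %in% names(x)) {
    stop_gaitspec("need an n_walks or participant column", "input")
  }
  dplyr::group_by(x, .data$participant) |>
    dplyr::filter(dplyr::n() >= min_walks) |>
    dplyr::ungroup()
}

#' Fit a longitudinal trend to a participant's gait index
#'
#' Ordinary least squares of an index (entropy or weighted mean frequency)
#' on days since the participant's first walk, with a pointwise confidence
#' band for the mean response from the t distribution with `n - 2` degrees
#' of freedom. A rising entropy trend together with a falling mean-
#' frequency trend is the longitudinal signature of gait deterioration.
#'
#' @param walks Tibble with columns `date` and the chosen index; at least
#'   3 walks.
#' @param index `"entropy"` or `"mu"`.
#' @param conf Confidence level for the band. Default 0.95.
#' @return An object of class `gait_trend`: list with the `lm` fit
#'   (`fit`), the per-walk data (`data`), the pointwise band (`band`),
#'   `index` and `conf`. Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @export
trend_fit <- function(walks, index = c("entropy", "mu"), conf = 0.95) {
  index <- match.arg(index)
  if (nrow(walks) < 3) {
    stop_gaitspec("need at least 3 walks to fit a trend", "insufficient_data")
  }
  d <- as.Date(walks$date)
  data <- tibble(
    date = d,
    days = as.numeric(d - min(d)),
    value = walks[[index]]
  )
  fit <- lm(value ~ days, data = data)
  grid <- tibble(days = seq(min(data$days), max(data$days), length.out = 100))
  ci <- predict(fit, newdata = grid, interval = "confidence", level = conf)
  band <- tibble(
    days = grid$days,
    fit = ci[, "fit"], lower = ci[, "lwr"], upper = ci[, "upr"]
  )
  structure(
    list(fit = fit, data = data, band = band, index = index, conf = conf),
    class = "gait_trend"
  )
}

#' @export
print.gait_trend <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  cat("Longitudinal trend of", x$index, "over", nrow(x$data), "walks\n")
  cat(sprintf(
    "  slope: %.6g per day (se %.3g, p = %.3g)\n",
    co["days", "Estimate"], co["days", "Std. Error"], co["days", "Pr(>|t|)"]
  ))
  cat(sprintf("  intercept: %.6g; %g%% pointwise band available\n",
    co["(Intercept)", "Estimate"], 100 * x$conf))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a longitudinal gait trend fit
#'
#' @param x A `gait_trend` object.
#' @param ... Passed to the underlying `lm` tidier.
#' @return A tibble of model terms (intercept and per-day slope).
#' @method tidy gait_trend
#' @export
tidy.gait_trend <- function(x, ...) {
  dplyr::mutate(broom::tidy(x$fit, ...), index = x$index, .before = 1)
}

#' One-row summary of a gait trend fit
#'
#' @inheritParams tidy.gait_trend
#' @return A one-row tibble with fit statistics plus the fitted index name
#'   and per-day slope.
#' @method glance gait_trend
#' @export
glance.gait_trend <- function(x, ...) {
  dplyr::mutate(broom::glance(x$fit, ...),
    index = x$index,
    slope_per_day = coef(x$fit)[["days"]],
    .before = 1
  )
}

#' Group labeled windows into walks
#'
#' A contiguous run of at least `min_run` consecutive walking-labeled
#' windows constitutes a walk; with the default 30-s windows the 2-window
#' minimum guarantees at least 60 s (1500 samples at 25 Hz) per walk
#' spectrum.
#'
#' @param windows Tibble with columns `window` (consecutive integer index)
#'   and `label`.
#' @param min_run Minimum run length of walking windows. Default 2.
#' @param walking_label Label that marks walking. Default `"walking"`.
#' @return A tibble with one row per walk: `walk`, `first_window`,
#'   `last_window`, `n_windows`.
#' @export
walks_from_labels <- function(windows, min_run = 2, walking_label = "walking") {
  if (nrow(windows) == 0) {
    return(tibble(
      walk = integer(), first_window = integer(),
      last_window = integer(), n_windows = integer()
    ))
  }
  windows <- dplyr::arrange(windows, .data$window)
  is_walk <- windows$label == walking_label &
    !is.na(windows$label)
  # breaks in window numbering interrupt a run even if both sides are walking
  contiguous <- c(TRUE, diff(windows$window) == 1)
  run_id <- cumsum(!(is_walk & c(is_walk[1], is_walk[-length(is_walk)]) & contiguous))
  runs <- split(seq_len(nrow(windows))[is_walk], run_id[is_walk])
  runs <- Filter(function(i) length(i) >= min_run, runs)
  if (length(runs) == 0) {
    return(tibble(
      walk = integer(), first_window = integer(),
      last_window = integer(), n_windows = integer()
    ))
  }
  tibble(
    walk = seq_along(runs),
    first_window = vapply(runs, function(i) windows$window[i[1]], integer(1),
      USE.NAMES = FALSE
    ),
    last_window = vapply(runs, function(i) windows$window[i[length(i)]], integer(1),
      USE.NAMES = FALSE
    ),
    n_windows = unname(lengths(runs))
  )
}

#' Serialize walk indices as JSON
#'
#' Deterministic JSON export of an indexed walk table (stable column
#' order, full precision), so identical inputs produce bit-identical
#' reports.
#'
#' @param indices Tibble of walk indices (e.g. from [index_walks()]).
#' @return A JSON string.
#' @export
indices_json <- function(indices) {
  as.character(jsonlite::toJSON(indices, digits = NA, dataframe = "rows"))
}
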