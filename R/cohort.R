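#' Classify participants by the sign of their entropy variation
#'
#' Negative percentage entropy variation means the entropy fell, i.e. the
#' gait improved; positive means deterioration; exactly zero is stable.
#'
#' @param variations Numeric vector of percentage entropy variations, one
#'   per participant.
#' @return A one-row tibble: `n_improved`, `n_deteriorated`, `n_stable`.
#' @export
#' @examples
#' classify_participants(c(-14.1, 2.7, 0, 5.7))
classify_participants <- function(variations) {
  if (any(!is.finite(variations))) {
    stop_gaitspec("variations must be finite", "input")
  }
  tibble(
    n_improved = sum(variations < 0),
    n_deteriorated = sum(variations > 0),
    n_stable = sum(variations == 0)
  )
}

#' Mean and SD of absolute entropy variation per direction
#'
#' Summarizes the magnitude of change in each direction: the arithmetic
#' mean and sample (n-1) standard deviation of `|variation|` over the
#' improved (negative) and deteriorated (positive) participants. Stable
#' (exactly zero) participants belong to neither group.
#'
#' @inheritParams classify_participants
#' @param allow_singleton Return `sd = 0` for a single-member group
#'   instead of erroring. Default `FALSE` (the sample SD is undefined).
#' @return A tibble with columns `group` (`"improved"`, `"deteriorated"`),
#'   `n`, `mean_pct`, `sd_pct`.
#' @export
group_stats <- function(variations, allow_singleton = FALSE) {
  if (any(!is.finite(variations))) {
    stop_gaitspec("variations must be finite", "input")
  }
  groups <- list(
    improved = abs(variations[variations < 0]),
    deteriorated = variations[variations > 0]
  )
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    if (length(v) == 0) {
      stop_gaitspec(paste0("no participants in group '", g, "'"), "insufficient_data")
    }
    if (length(v) == 1 && !allow_singleton) {
      stop_gaitspec(
        paste0("sample SD undefined for singleton group '", g, "'"),
        "insufficient_data"
      )
    }
    tibble(
      group = g, n = length(v), mean_pct = mean(v),
      sd_pct = if (length(v) > 1) sd(v) else 0
    )
  })
  dplyr::bind_rows(rows)
}

#' Confidence interval for the ratio of geometric means
#'
#' Compares the magnitude of deterioration and improvement: the absolute
#' percentage variations of the two groups are log-transformed and an
#' unpaired two-sample t interval for the difference of the log means is
#' computed; exponentiating the endpoints gives a confidence interval for
#' the ratio of geometric means `mu_D / mu_I`. The classical
#' pooled-variance interval (df `n1 + n2 - 2`) is the default; a Welch
#' variant is available since with near-equal spreads on the log scale the
#' two differ negligibly.
#'
#' @param deter Positive absolute variations of the deteriorated group
#'   (length >= 2).
#' @param improve Positive absolute variations of the improved group
#'   (length >= 2).
#' @param conf Confidence level. Default 0.80 — appropriate for the very
#'   small groups this is designed for, where higher levels are vacuous.
#' @param method `"pooled"` (classical equal-variance t) or `"welch"`.
#' @return A one-row tibble: `estimate` (ratio of geometric means),
#'   `lower`, `upper`, `conf`, `method`, `df`.
#' @export
#' @examples
#' gm_ratio_ci(c(66.2, 5.7, 27.0, 60.8, 36.4), c(11.0, 9.7, 31.1, 1.5, 19.2))
gm_ratio_ci <- function(deter, improve, conf = 0.80,
                        method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (length(deter) < 2 || length(improve) < 2) {
    stop_gaitspec("both groups need at least 2 values", "insufficient_data")
  }
  if (any(!is.finite(deter)) || any(!is.finite(improve)) ||
    any(deter <= 0) || any(improve <= 0)) {
    stop_gaitspec("variations must be positive (absolute percentages)", "domain")
  }
  ld <- log(deter)
  li <- log(improve)
  n1 <- length(ld)
  n2 <- length(li)
  d <- mean(ld) - mean(li)
  if (method == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * var(ld) + (n2 - 1) * var(li)) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- var(ld) / n1
    v2 <- var(li) / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tq <- qt(1 - (1 - conf) / 2, df)
  tibble(
    estimate = exp(d),
    lower = exp(d - tq * se),
    upper = exp(d + tq * se),
    conf = conf, method = method, df = df
  )
}

#' Cohort-level summary of entropy variations
#'
#' Aggregates per-participant percentage entropy variations into the
#' study-level result: improvement/deterioration/stable counts, mean and
#' SD of the absolute variation per direction, and (when both directions
#' have at least two members) the geometric-mean-ratio confidence
#' interval from [gm_ratio_ci()].
#'
#' @inheritParams classify_participants
#' @inheritParams gm_ratio_ci
#' @param allow_singleton Passed to [group_stats()].
#' @return An object of class `cohort_summary`: a list with tibbles
#'   `counts`, `groups` and `ci` (NULL when not computable). Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
cohort_summary <- function(variations, conf = 0.80, method = "pooled",
                           allow_singleton = FALSE) {
  counts <- classify_participants(variations)
  groups <- group_stats(variations, allow_singleton = allow_singleton)
  imp <- abs(variations[variations < 0])
  det <- variations[variations > 0]
  ci <- if (length(imp) >= 2 && length(det) >= 2) {
    gm_ratio_ci(det, imp, conf = conf, method = method)
  } else {
    NULL
  }
  structure(
    list(counts = counts, groups = groups, ci = ci, n = length(variations)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n, "participants:",
    x$counts$n_improved, "improved,",
    x$counts$n_deteriorated, "deteriorated,",
    x$counts$n_stable, "stable\n")
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf(
      "  %s: mean |variation| %.1f%% (sd %.1f), n = %d\n",
      g$group[i], g$mean_pct[i], g$sd_pct[i], g$n[i]
    ))
  }
  if (!is.null(x$ci)) {
    cat(sprintf(
      "  GM ratio deterioration/improvement: %.2f (%g%% CI %.2f-%.2f, %s)\n",
      x$ci$estimate, 100 * x$ci$conf, x$ci$lower, x$ci$upper, x$ci$method
    ))
  }
  invisible(x)
}

#' Tidy a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return The per-direction group statistics as a tibble.
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) {
  x$groups
}

#' One-row overview of a cohort summary
#'
#' @inheritParams tidy.cohort_summary
#' @return A one-row tibble with counts, group means/SDs and the CI
#'   endpoints (NA when no CI was computed).
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  g <- x$groups
  gi <- g[g$group == "improved", ]
  gd <- g[g$group == "deteriorated", ]
  tibble(
    n = x$n,
    n_improved = x$counts$n_improved,
    n_deteriorated = x$counts$n_deteriorated,
    n_stable = x$counts$n_stable,
    mean_improve_pct = gi$mean_pct, sd_improve_pct = gi$sd_pct,
    mean_deter_pct = gd$mean_pct, sd_deter_pct = gd$sd_pct,
    gm_ratio = if (is.null(x$ci)) NA_real_ else x$ci$estimate,
    ci_lower = if (is.null(x$ci)) NA_real_ else x$ci$lower,
    ci_upper = if (is.null(x$ci)) NA_real_ else x$ci$upper,
    conf = if (is.null(x$ci)) NA_real_ else x$ci$conf
  )
}

#' Write a cohort summary to JSON
#'
#' @param x A `cohort_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_json <- function(x, path) {
  jsonlite::write_json(
    list(counts = x$counts, groups = x$groups, ci = x$ci, n = x$n),
    path,
    auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows"
  )
  invisible(path)
}

#' Published per-participant entropy summaries
#'
#' Per-participant entropy summary tables for the two monitoring studies
#' the method was developed on (21 and 10 eligible participants), as
#' packaged plain-text fixtures: minimum, maximum and mean walk entropy,
#' initial- and final-period entropies and the percentage entropy
#' variation. Absolute entropy levels are study-specific (they depend on
#' the analysis band and normalization used on the raw data and are not
#' comparable across studies); the variation column drives all cohort
#' statistics.
#'
#' @param study `"first"` (21 participants) or `"second"` (10
#'   participants).
#' @return A tibble with columns `participant`, `min_entropy`,
#'   `max_entropy`, `mean_entropy`, `initial_entropy`, `final_entropy`,
#'   `variation_pct`.
#' @export
#' @examples
#' gait_study_table("first") |> dplyr::pull(variation_pct) |> cohort_summary()
gait_study_table <- function(study = c("first", "second")) {
  study <- match.arg(study)
  file <- if (study == "first") "table2.csv" else "table3.csv"
  path <- system.file("extdata", file, package = "gaitspec", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
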