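#' Extract environmental values under an observed factory footprint
#'
#' Pulls one value per cell where the observed map assigns the given factory
#' and the requested field is not missing. This is the sampling step of the
#' calibration chain: footprint samples feed the percentile summaries from
#' which thresholds, mid-points and spreads are derived.
#'
#' @param env An [env_stack()].
#' @param observed A factory map tibble (`lat`, `lon`, `factory`)
#'   co-registered with `env`.
#' @param factory Factory id to sample.
#' @param parameter One of `"sst"`, `"sss_class"`, `"prod"`.
#' @param season `"summer"` or `"winter"`.
#' @return Numeric vector of sampled values (possibly empty, with a warning
#'   if the factory is absent from the map).
#' @export
extract_values <- function(env, observed, factory,
                           parameter = c("sst", "sss_class", "prod"),
                           season = c("summer", "winter")) {
  parameter <- match.arg(parameter)
  season <- match.arg(season)
  stopifnot(is_env_stack(env))
  if (!identical(paste(observed$lat, observed$lon),
                 paste(env$lat, env$lon))) {
    stop("`observed` is not co-registered with `env`", call. = FALSE)
  }
  sel <- !is.na(observed$factory) & observed$factory == factory
  if (!any(sel)) {
    warning("factory '", factory, "' does not occur in the observed map")
    return(numeric(0))
  }
  vals <- env[[paste0(parameter, "_", season)]][sel]
  vals[!is.na(vals)]
}

#' Percentile summary of a footprint sample
#'
#' Computes the descriptive statistics used throughout calibration:
#' percentiles 1, 5, 25, 50, 75, 95, 99 (linear interpolation between order
#' statistics, R quantile type 7), the mean and the sample size. The whisker
#' convention is recorded per parameter: the 1st/99th percentiles bound
#' temperature and salinity, the 5th/95th bound productivity (whose
#' heavy-tailed satellite distribution makes the extreme percentiles
#' unstable).
#'
#' @param values Numeric sample (n >= 1).
#' @param parameter `"sst"`, `"sss_class"` or `"prod"` (sets the whisker
#'   convention).
#' @param factory,season Optional labels carried into the output row.
#' @return A one-row tibble of class `stats_summary` with columns `factory`,
#'   `parameter`, `season`, `p1`...`p99`, `mean`, `n`, `whisker_low`,
#'   `whisker_high`.
#' @examples
#' summarize_values(1:100, "sst")
#' @export
summarize_values <- function(values, parameter = c("sst", "sss_class", "prod"),
                             factory = NA_character_,
                             season = NA_character_) {
  parameter <- match.arg(parameter)
  values <- values[!is.na(values)]
  if (length(values) < 1) {
    stop("cannot summarize an empty sample", call. = FALSE)
  }
  probs <- c(0.01, 0.05, 0.25, 0.50, 0.75, 0.95, 0.99)
  q <- stats::quantile(values, probs, type = 7, names = FALSE)
  whisk <- if (parameter == "prod") c(5, 95) else c(1, 99)
  out <- tibble::tibble(
    factory = factory, parameter = parameter, season = season,
    p1 = q[1], p5 = q[2], p25 = q[3], p50 = q[4], p75 = q[5], p95 = q[6],
    p99 = q[7], mean = mean(values), n = length(values),
    whisker_low = whisk[1], whisker_high = whisk[2]
  )
  class(out) <- c("stats_summary", class(tibble::tibble()))
  out
}

#' Full percentile table for every factory, parameter and season
#'
#' Convenience wrapper running [extract_values()] and [summarize_values()]
#' over all observed factories, the three parameters and both seasons —
#' the box-and-whisker table of the spatial analysis.
#'
#' @inheritParams extract_values
#' @return A `stats_summary` tibble, one row per factory/parameter/season
#'   present in the observed map.
#' @export
factory_stats <- function(env, observed) {
  facs <- setdiff(unique(observed$factory[!is.na(observed$factory)]), "none")
  combos <- tidyr::expand_grid(factory = facs,
                               parameter = c("sst", "sss_class", "prod"),
                               season = c("summer", "winter"))
  out <- purrr::pmap_dfr(combos, function(factory, parameter, season) {
    vals <- suppressWarnings(
      extract_values(env, observed, factory, parameter, season))
    if (length(vals) == 0) return(NULL)
    summarize_values(vals, parameter, factory, season)
  })
  class(out) <- c("stats_summary", class(tibble::tibble()))
  out
}

#' Derive tolerance thresholds from seasonal percentile summaries
#'
#' For temperature and salinity, the *production* threshold is the summer
#' 1st percentile, the *persistence* threshold is the winter 1st percentile,
#' and the upper threshold is the larger seasonal 99th percentile. For
#' productivity the same construction uses the 5th/95th percentiles. The two
#' lower thresholds are averaged into the single lower bound (`lower`) that
#' the mid-point formula consumes.
#'
#' @param summary_summer,summary_winter One-row [summarize_values()] outputs
#'   for the same factory/parameter in the two seasons.
#' @return A list of class `threshold_pair` with elements `production`,
#'   `persistence`, `lower`, `upper`, `parameter`, `source`.
#' @export
derive_thresholds <- function(summary_summer, summary_winter) {
  for (s in list(summary_summer, summary_winter)) {
    stopifnot(inherits(s, "stats_summary"), nrow(s) == 1)
  }
  if (!identical(summary_summer$parameter, summary_winter$parameter) ||
      !identical(summary_summer$factory, summary_winter$factory)) {
    stop("seasonal summaries describe different factories or parameters",
         call. = FALSE)
  }
  if (summary_summer$parameter == "prod") {
    production <- summary_summer$p5
    persistence <- summary_winter$p5
    upper <- max(summary_summer$p95, summary_winter$p95)
    src <- "p5/p95"
  } else {
    production <- summary_summer$p1
    persistence <- summary_winter$p1
    upper <- max(summary_summer$p99, summary_winter$p99)
    src <- "p1/p99"
  }
  structure(list(
    production = production, persistence = persistence,
    lower = (production + persistence) / 2, upper = upper,
    parameter = summary_summer$parameter,
    source = paste0(src, " (production = summer, persistence = winter)")
  ), class = "threshold_pair")
}

#' Mid-point of a membership function from thresholds
#'
#' With both a lower and an upper threshold, the mid-point is their mean;
#' when two lower thresholds are supplied (production and persistence), they
#' are first averaged into the single lower bound. With only one threshold
#' available, the mid-point falls back to the mode of the descriptive
#' statistics.
#'
#' @param lower One or two lower threshold values (production, persistence).
#' @param upper Optional upper threshold.
#' @param mode Optional distribution mode, used when `upper` is absent.
#' @return The mid-point.
#' @examples
#' compute_midpoint(lower = c(24.15, 17.65), upper = 30.5)  # 25.7
#' @export
compute_midpoint <- function(lower = NULL, upper = NULL, mode = NULL) {
  if (!is.null(lower) && length(lower) == 2) lower <- mean(lower)
  if (!is.null(lower) && !is.null(upper)) {
    return((lower + upper) / 2)
  }
  one <- c(lower, upper)
  if (length(one) == 1 && !is.null(mode)) {
    return(mode)
  }
  stop("need either two thresholds, or one threshold plus a mode",
       call. = FALSE)
}

#' Solve the spread so the membership crosses 0.5 at a threshold
#'
#' The calibration rule fixes the spread of a symmetric membership so that
#' `f(threshold) = 0.5`: `S = log(2) / (threshold - midpoint)^2` for the
#' Gaussian and `S = 1 / (threshold - midpoint)^2` for the near-Gaussian.
#'
#' @param form `"gaussian"` or `"near_gaussian"`.
#' @param midpoint Mid-point of the function.
#' @param threshold_x Parameter value where the function must equal 0.5;
#'   must differ from `midpoint`.
#' @return The spread.
#' @examples
#' calibrate_spread("gaussian", 25.7, 30.5)  # ~0.03
#' @export
calibrate_spread <- function(form = c("gaussian", "near_gaussian"),
                             midpoint, threshold_x) {
  form <- match.arg(form)
  d <- threshold_x - midpoint
  if (abs(d) < .Machine$double.eps^0.5) {
    stop("threshold coincides with the midpoint; spread is undefined",
         call. = FALSE)
  }
  switch(form,
    gaussian = log(2) / d^2,
    near_gaussian = 1 / d^2
  )
}

#' Solve the large-sigmoid spread through a reference point
#'
#' Inverts `f(x) = 1 / (1 + (x/midpoint)^-S)` for `S` given one reference
#' evaluation `f(ref_x) = ref_f`:
#' `S = -log(1/ref_f - 1) / log(ref_x / midpoint)`.
#'
#' @param midpoint Sigmoid mid-point (where f = 0.5), positive.
#' @param ref_x Reference abscissa (> 0, != midpoint).
#' @param ref_f Reference susceptibility in (0, 1), != 0.5.
#' @return The spread.
#' @examples
#' fit_sigmoid_spread(30.5, 32, 0.9418)  # ~58
#' @export
fit_sigmoid_spread <- function(midpoint, ref_x, ref_f) {
  stopifnot(midpoint > 0, ref_x > 0, ref_f > 0, ref_f < 1)
  if (abs(ref_x - midpoint) < .Machine$double.eps^0.5) {
    stop("`ref_x` must differ from the midpoint", call. = FALSE)
  }
  if (abs(ref_f - 0.5) < 1e-12) {
    stop("`ref_f` = 0.5 away from the midpoint has no solution",
         call. = FALSE)
  }
  -log(1 / ref_f - 1) / log(ref_x / midpoint)
}

#' Calibrate one membership function from an observed footprint
#'
#' Runs the full chain for one factory and parameter: extract seasonal
#' values under the footprint, summarize percentiles, derive thresholds,
#' compute the mid-point and solve the spread at the upper threshold.
#'
#' @inheritParams extract_values
#' @param form `"gaussian"` or `"near_gaussian"`.
#' @return A list with the fitted [membership_spec()], the seasonal
#'   summaries and the [derive_thresholds()] result.
#' @export
calibrate_membership <- function(env, observed, factory,
                                 parameter = c("sst", "sss_class", "prod"),
                                 form = c("gaussian", "near_gaussian")) {
  parameter <- match.arg(parameter)
  form <- match.arg(form)
  ss <- summarize_values(extract_values(env, observed, factory, parameter,
                                        "summer"),
                         parameter, factory, "summer")
  sw <- summarize_values(extract_values(env, observed, factory, parameter,
                                        "winter"),
                         parameter, factory, "winter")
  thr <- derive_thresholds(ss, sw)
  mp <- compute_midpoint(lower = c(thr$production, thr$persistence),
                         upper = thr$upper)
  spread <- calibrate_spread(form, mp, thr$upper)
  list(spec = membership_spec(form, mp, spread),
       summer = ss, winter = sw, thresholds = thr)
}

#' Plot the calibration box-and-whisker summary
#'
#' @param object A [factory_stats()] table.
#' @param ... Unused.
#' @return A ggplot object faceted by parameter, whiskers at the recorded
#'   percentile convention.
#' @export
autoplot.stats_summary <- function(object, ...) {
  df <- dplyr::mutate(object,
    lo = ifelse(.data$whisker_low == 5, .data$p5, .data$p1),
    hi = ifelse(.data$whisker_high == 95, .data$p95, .data$p99),
    group = paste(.data$factory, .data$season)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.25) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$p50, ymin = .data$p25,
                                        ymax = .data$p75), fill = "grey90") +
    ggplot2::geom_point(ggplot2::aes(y = .data$p50), colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "parameter value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
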