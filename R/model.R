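new_factory_map <- function(df) {
  stopifnot(all(c("lat", "lon", "factory") %in% names(df)))
  df <- dplyr::arrange(tibble::as_tibble(df), .data$lat, .data$lon)
  class(df) <- c("factory_map", class(tibble::tibble()))
  df
}

#' Categorical factory map
#'
#' A `factory_map` is a tibble with one row per grid cell and a `factory`
#' column over `"none"`, `"biochemical"`, `"photozoan_T"`, `"photo_C"`,
#' `"heterozoan_C"`, with `NA` for land/masked cells. Use [as_factory_map()]
#' to validate a plain data frame (e.g. an observation map assembled from
#' bibliographic sources).
#'
#' @param df Data frame with columns `lat`, `lon`, `factory`.
#' @return A tibble of class `factory_map`.
#' @export
as_factory_map <- function(df) {
  valid <- c("none", names(factory_codes())[-1])
  bad <- !is.na(df$factory) & !(df$factory %in% valid)
  if (any(bad)) {
    stop("unknown factory categories: ",
         paste(unique(df$factory[bad]), collapse = ", "), call. = FALSE)
  }
  new_factory_map(df)
}

#' Seasonal input field for one parameter
#'
#' Collapses the two seasonal composites of an environmental parameter into
#' the single field a membership function sees. Salinity classes aggregated
#' with `"mean_of_seasons"` are kept fractional (classes 5 and 6 average to
#' 5.5); the membership functions are continuous, so re-rounding would only
#' discard information.
#'
#' @param env An [env_stack()].
#' @param parameter One of `"sst"`, `"sss_class"`, `"prod"`.
#' @param rule One of `"mean_of_seasons"`, `"warm_season"`, `"cool_season"`.
#' @return Numeric vector aligned with the rows of `env`.
#' @export
seasonal_input <- function(env, parameter = c("sst", "sss_class", "prod"),
                           rule = c("mean_of_seasons", "warm_season",
                                    "cool_season")) {
  parameter <- match.arg(parameter)
  rule <- match.arg(rule)
  s <- env[[paste0(parameter, "_summer")]]
  w <- env[[paste0(parameter, "_winter")]]
  switch(rule,
    mean_of_seasons = (s + w) / 2,
    warm_season = s,
    cool_season = w
  )
}

#' Susceptibility of occurrence of one carbonate factory
#'
#' Evaluates `F = a f(z) + b f(SST) + c f(SSS) + d f(P)` at every eligible
#' cell. The terrigenous term of the factory function is realized as the
#' eligibility mask: ineligible cells (too deep, land, or inhibiting
#' terrigenous category) get `NA` susceptibility, which is equivalent to
#' subtracting a binary terrigenous indicator and clamping. Zero-weighted
#' parameters are skipped, so gaps in a field the factory ignores never mask
#' a cell. The result is clamped to \[0, 1\] (the weighted sum of bounded
#' memberships on the weight simplex is already in \[0, 1\]; clamping guards
#' rounding).
#'
#' @param env An [env_stack()].
#' @param params A [factory_params()].
#' @param masks Optional [build_masks()] output on the same lattice; computed
#'   from `env` if omitted.
#' @return A tibble of class `susceptibility_map` with columns `lat`, `lon`,
#'   `susceptibility`, and attributes `factory` and `threshold`.
#' @examples
#' env <- generate_env(world_config(nlat = 24, nlon = 48))$env
#' susc <- susceptibility(env, default_factory_params()$photozoan_T)
#' dplyr::filter(susc, !is.na(susceptibility))
#' @export
susceptibility <- function(env, params, masks = NULL) {
  stopifnot(is_env_stack(env), inherits(params, "factory_params"))
  if (is.null(masks)) masks <- build_masks(env, list(params))
  if (!identical(paste(masks$lat, masks$lon), paste(env$lat, env$lon))) {
    stop("`masks` are not on the same lattice as `env`", call. = FALSE)
  }
  eligible <- masks[[paste0("eligible_", params$factory)]]
  if (is.null(eligible)) {
    stop("masks lack an eligibility column for factory ", params$factory,
         call. = FALSE)
  }
  w <- params$weights
  n <- nrow(env)
  total <- rep(0, n)

  term <- function(weight, values) {
    if (weight == 0) return(0)
    weight * values
  }
  # bathymetry: flat membership inside the masked depth interval
  f_z <- evaluate_membership(params$z, env$bathymetry)
  total <- total + term(w[["z"]], if (params$z$form == "independent")
    rep(1, n) else f_z)

  if (w[["sst"]] > 0) {
    f_sst <- if (params$sst_rule == "product_of_two_specs") {
      evaluate_membership(params$sst$production, env$sst_summer) *
        evaluate_membership(params$sst$persistence, env$sst_winter)
    } else {
      evaluate_membership(params$sst,
                          seasonal_input(env, "sst", params$sst_rule))
    }
    total <- total + term(w[["sst"]], f_sst)
  }
  if (w[["sss"]] > 0) {
    f_sss <- evaluate_membership(params$sss,
                                 seasonal_input(env, "sss_class",
                                                params$sss_rule))
    total <- total + term(w[["sss"]], f_sss)
  }
  if (w[["prod"]] > 0) {
    f_p <- evaluate_membership(params$prod,
                               seasonal_input(env, "prod", params$prod_rule))
    total <- total + term(w[["prod"]], f_p)
  }
  total <- pmin(pmax(total, 0), 1)
  total[!eligible] <- NA_real_
  out <- tibble::tibble(lat = env$lat, lon = env$lon, susceptibility = total)
  structure(out, factory = params$factory, threshold = params$threshold,
            class = c("susceptibility_map", class(tibble::tibble())))
}

#' Threshold a susceptibility map into presence/absence
#'
#' Presence is strict: a factory develops where its susceptibility is
#' *higher than* the threshold; a cell sitting exactly on the threshold is
#' absent, and masked (`NA`) cells are absent.
#'
#' @param susc A [susceptibility()] result.
#' @param threshold Susceptibility threshold; defaults to the factory's own.
#' @return A tibble `lat`, `lon`, `present` (logical).
#' @export
occurrence <- function(susc, threshold = attr(susc, "threshold")) {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  tibble::tibble(
    lat = susc$lat, lon = susc$lon,
    present = !is.na(susc$susceptibility) & susc$susceptibility > threshold
  )
}

#' Combine per-factory occurrences into one categorical map
#'
#' Non-background factories compete: where two or more are present in a cell,
#' the factory with the largest susceptibility margin above its own threshold
#' wins; exact ties break by the fixed priority order biochemical >
#' photozoan_T > photo_C. The background factory (heterozoan-C) is assigned
#' only where no other factory is present, its own presence bit is set, and
#' the seasonal-mean productivity reaches its floor (0.01 per m by default).
#' Ocean cells claiming no factory are `"none"`; land cells are `NA`.
#'
#' @param suscs Named list of [susceptibility()] results, one per factory.
#' @param params Named list of [factory_params()] matching `suscs`.
#' @param env The [env_stack()] (needed for the background productivity floor
#'   and the land/ocean distinction).
#' @return A [as_factory_map()] tibble.
#' @export
combine_factories <- function(suscs, params, env) {
  ids <- names(params)
  if (!setequal(names(suscs), ids)) {
    stop("`suscs` and `params` must cover the same factories", call. = FALSE)
  }
  priority <- c("biochemical", "photozoan_T", "photo_C", "heterozoan_C")
  ids <- ids[order(match(ids, priority))]
  n <- nrow(suscs[[1]])
  background_ids <- ids[purrr::map_lgl(ids, ~params[[.x]]$background)]
  if (length(background_ids) > 1) {
    stop("at most one factory may be the background factory", call. = FALSE)
  }
  fore <- setdiff(ids, background_ids)

  margin <- matrix(-Inf, n, length(fore),
                   dimnames = list(NULL, fore))
  for (f in fore) {
    s <- suscs[[f]]$susceptibility
    m <- s - params[[f]]$threshold
    m[is.na(s) | m <= 0] <- -Inf
    margin[, f] <- m
  }
  any_fore <- apply(margin, 1, function(r) any(is.finite(r)))
  # which.max returns the first maximum, i.e. the fixed priority order on ties
  winner <- rep(NA_character_, n)
  winner[any_fore] <- fore[apply(margin[any_fore, , drop = FALSE], 1,
                                 which.max)]

  out <- rep("none", n)
  out[any_fore] <- winner[any_fore]
  if (length(background_ids) == 1) {
    b <- background_ids
    present_b <- !is.na(suscs[[b]]$susceptibility) &
      suscs[[b]]$susceptibility > params[[b]]$threshold
    floor_ok <- TRUE
    if (is.finite(params[[b]]$productivity_floor)) {
      pmean <- seasonal_input(env, "prod", "mean_of_seasons")
      floor_ok <- !is.na(pmean) & pmean >= params[[b]]$productivity_floor
    }
    out[!any_fore & present_b & floor_ok] <- b
  }
  land <- is.na(env$bathymetry) | env$bathymetry < 0
  out[land] <- NA_character_
  new_factory_map(tibble::tibble(lat = env$lat, lon = env$lon, factory = out))
}

#' Predict the factory map from an environmental stack
#'
#' Runs the full deterministic pipeline: per-factory susceptibility,
#' thresholding, and combination with the background rule.
#'
#' @param env An [env_stack()].
#' @param params Named list of [factory_params()]; defaults to the shipped
#'   parameterization.
#' @param masks Optional [build_masks()] output; computed if omitted.
#' @return An object of class `carb_prediction`: a list with elements `map`
#'   (the combined [as_factory_map()]), `susceptibility` (long tibble with
#'   columns `lat`, `lon`, `factory`, `susceptibility`, `present`) and
#'   `params`. Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' world <- generate_env(world_config(nlat = 30, nlon = 60))
#' pred <- predict_factories(world$env)
#' glance(pred)
#' @export
predict_factories <- function(env, params = default_factory_params(),
                              masks = NULL) {
  stopifnot(is_env_stack(env))
  if (is.null(masks)) masks <- build_masks(env, params)
  suscs <- purrr::map(params, susceptibility, env = env, masks = masks)
  map <- combine_factories(suscs, params, env)
  long <- purrr::imap_dfr(suscs, function(s, id) {
    tibble::tibble(lat = s$lat, lon = s$lon, factory = id,
                   susceptibility = s$susceptibility,
                   present = !is.na(s$susceptibility) &
                     s$susceptibility > params[[id]]$threshold)
  })
  structure(list(map = map, susceptibility = long, params = params),
            class = "carb_prediction")
}

#' @export
print.carb_prediction <- function(x, ...) {
  tab <- table(x$map$factory, useNA = "ifany")
  cat("<carb_prediction>", nrow(x$map), "cells\n")
  print(tab)
  invisible(x)
}

#' Tidy a factory prediction
#'
#' `tidy()` returns the long per-factory susceptibility table; `glance()`
#' returns one row per factory with eligibility, presence and assignment
#' counts and susceptibility summaries.
#'
#' @param x A [predict_factories()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.carb_prediction <- function(x, ...) {
  x$susceptibility
}

#' @rdname tidy.carb_prediction
#' @export
glance.carb_prediction <- function(x, ...) {
  assigned <- x$map$factory
  x$susceptibility |>
    dplyr::group_by(.data$factory) |>
    dplyr::summarise(
      cells_eligible = sum(!is.na(.data$susceptibility)),
      cells_present = sum(.data$present),
      mean_susceptibility = mean(.data$susceptibility, na.rm = TRUE),
      max_susceptibility = suppressWarnings(max(.data$susceptibility,
                                                na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      max_susceptibility = ifelse(is.finite(.data$max_susceptibility),
                                  .data$max_susceptibility, NA_real_),
      threshold = purrr::map_dbl(.data$factory, ~x$params[[.x]]$threshold),
      cells_assigned = purrr::map_int(.data$factory,
                                      ~sum(assigned == .x, na.rm = TRUE))
    )
}

#' Plot factory maps and susceptibility maps
#'
#' @param object A `factory_map`, `susceptibility_map` or `carb_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.factory_map <- function(object, ...) {
  pal <- c(none = "grey85", biochemical = "#d95f02",
           photozoan_T = "#1b9e77", photo_C = "#7570b3",
           heterozoan_C = "#66a61e")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       fill = .data$factory)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, na.value = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "factory") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.factory_map
#' @export
autoplot.susceptibility_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       fill = .data$susceptibility)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude",
                  fill = paste0("F(", attr(object, "factory"), ")")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.factory_map
#' @export
autoplot.carb_prediction <- function(object, ...) {
  autoplot.factory_map(object$map, ...)
}
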