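#' Co-registered environmental stack
#'
#' An `env_stack` is a tibble with one row per grid cell on a regular
#' cell-centered latitude/longitude lattice, holding every field the factory
#' functions consume:
#'
#' * `sst_summer`, `sst_winter` — sea-surface temperature of the local warm
#'   and cool season (deg C);
#' * `sss_class_summer`, `sss_class_winter` — salinity class 1–8
#'   (see [reclassify_salinity()]);
#' * `prod_summer`, `prod_winter` — marine primary productivity as absorption
#'   due to phytoplankton (per metre, non-negative);
#' * `bathymetry` — water depth in metres, positive down; land cells are
#'   negative (or `NA`);
#' * `terrigenous` — terrigenous-deposit category, one of `"none"`, `"low"`,
#'   `"high"`, `"arctic"`.
#'
#' Validation enforces the lattice regularity, `sst_summer >= sst_winter` at
#' every ocean cell (seasons are local warm/cool composites, not calendar
#' months), non-negative productivity and salinity classes in 1–8.
#'
#' @param data A data frame with the columns listed above.
#' @param x Object to test.
#' @return A validated tibble of class `env_stack`.
#' @export
env_stack <- function(data) {
  need <- c("lat", "lon", "sst_summer", "sst_winter", "sss_class_summer",
            "sss_class_winter", "prod_summer", "prod_winter", "bathymetry",
            "terrigenous")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("env_stack is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- dplyr::arrange(tibble::as_tibble(data), .data$lat, .data$lon)
  grid_axes(data)
  ocean <- !is.na(data$bathymetry) & data$bathymetry >= 0
  both <- ocean & !is.na(data$sst_summer) & !is.na(data$sst_winter)
  if (any(data$sst_summer[both] < data$sst_winter[both] - 1e-9)) {
    stop("sst_summer < sst_winter at ",
         sum(data$sst_summer[both] < data$sst_winter[both] - 1e-9),
         " ocean cell(s); seasons must be local warm/cool composites",
         call. = FALSE)
  }
  for (p in c("prod_summer", "prod_winter")) {
    if (any(data[[p]] < 0, na.rm = TRUE)) {
      stop("negative productivity in ", p, call. = FALSE)
    }
  }
  for (s in c("sss_class_summer", "sss_class_winter")) {
    bad <- !is.na(data[[s]]) & !(data[[s]] >= 1 & data[[s]] <= 8)
    if (any(bad)) stop("salinity classes outside 1-8 in ", s, call. = FALSE)
  }
  terr_levels <- c("none", "low", "high", "arctic")
  bad_terr <- !is.na(data$terrigenous) & !(data$terrigenous %in% terr_levels)
  if (any(bad_terr)) {
    stop("terrigenous categories must be one of: ",
         paste(terr_levels, collapse = ", "), call. = FALSE)
  }
  class(data) <- c("env_stack", class(tibble::tibble()))
  data
}

#' @rdname env_stack
#' @export
is_env_stack <- function(x) inherits(x, "env_stack")

#' @export
print.env_stack <- function(x, ...) {
  ax <- grid_axes(x)
  ocean <- sum(!is.na(x$bathymetry) & x$bathymetry >= 0)
  cat(sprintf(
    "<env_stack> %d x %d cells (%.4g deg), lat %g..%g, lon %g..%g, %d ocean\n",
    length(ax$lat), length(ax$lon), ax$res_lat,
    min(ax$lat), max(ax$lat), min(ax$lon), max(ax$lon), ocean))
  NextMethod()
}

#' Resample named grids onto one lattice and assemble an environmental stack
#'
#' Each input grid (a `lat`/`lon`/`value` tibble, as returned by
#' [read_grid()]) is resampled to a common cell-centered lattice at
#' `target_resolution` degrees covering the intersection of all input
#' domains. Continuous fields are interpolated bilinearly; categorical fields
#' (`terrigenous` and salinity classes) use nearest-neighbour. Salinity may be
#' supplied either already classified (`sss_class_summer`/`sss_class_winter`)
#' or in psu (`sss_summer`/`sss_winter`), in which case it is interpolated in
#' psu and then passed through [reclassify_salinity()].
#'
#' @param grids Named list of grid tibbles. Recognized names:
#'   `sst_summer`, `sst_winter`, `sss_summer`, `sss_winter`,
#'   `sss_class_summer`, `sss_class_winter`, `prod_summer`, `prod_winter`,
#'   `bathymetry`, `terrigenous` (integer codes 0 none, 1 low, 2 high,
#'   3 arctic, or category strings).
#' @param target_resolution Cell size of the output lattice, degrees.
#' @return An [env_stack()].
#' @export
align_stack <- function(grids, target_resolution) {
  known <- c("sst_summer", "sst_winter", "sss_summer", "sss_winter",
             "sss_class_summer", "sss_class_winter", "prod_summer",
             "prod_winter", "bathymetry", "terrigenous")
  unknown <- setdiff(names(grids), known)
  if (length(unknown)) {
    stop("unknown field name(s) in align_stack: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  axes <- purrr::map(grids, grid_axes)
  lat_lo <- max(purrr::map_dbl(axes, ~min(.x$lat)))
  lat_hi <- min(purrr::map_dbl(axes, ~max(.x$lat)))
  lon_lo <- max(purrr::map_dbl(axes, ~min(.x$lon)))
  lon_hi <- min(purrr::map_dbl(axes, ~max(.x$lon)))
  if (lat_lo > lat_hi || lon_lo > lon_hi) {
    stop("input grids do not overlap; cannot build a common lattice",
         call. = FALSE)
  }
  res <- target_resolution
  t_lat <- seq(lat_lo, lat_hi + 1e-9, by = res)
  t_lon <- seq(lon_lo, lon_hi + 1e-9, by = res)

  categorical <- function(nm) {
    nm %in% c("terrigenous", "sss_class_summer", "sss_class_winter")
  }
  resample <- function(g, ax, cat) {
    is_char <- is.character(g$value) || is.factor(g$value)
    codes <- NULL
    if (is_char) {
      codes <- sort(unique(as.character(g$value)))
      g$value <- as.numeric(match(as.character(g$value), codes))
    }
    same <- length(ax$lat) == length(t_lat) && length(ax$lon) == length(t_lon) &&
      max(abs(ax$lat - t_lat)) < 1e-9 && max(abs(ax$lon - t_lon)) < 1e-9
    if (same) {
      out <- grid_matrix(g)
    } else if (cat || is_char || length(ax$lat) == 1 || length(ax$lon) == 1) {
      m <- grid_matrix(g)
      i <- pmin(pmax(round((t_lat - ax$lat[1]) /
                             ifelse(is.na(ax$res_lat), 1, ax$res_lat)) + 1, 1),
                length(ax$lat))
      j <- pmin(pmax(round((t_lon - ax$lon[1]) /
                             ifelse(is.na(ax$res_lon), 1, ax$res_lon)) + 1, 1),
                length(ax$lon))
      out <- m[i, j, drop = FALSE]
    } else {
      m <- grid_matrix(g)
      filled <- m
      filled[is.na(filled)] <- 0  # interp2 rejects NA; restore below
      pts <- expand.grid(yp = t_lat, xp = t_lon)
      v <- pracma::interp2(x = ax$lon, y = ax$lat, Z = filled,
                           xp = pts$xp, yp = pts$yp, method = "linear")
      out <- matrix(v, nrow = length(t_lat), ncol = length(t_lon))
      if (anyNA(m)) {
        # cells touching a missing source cell stay missing
        miss <- matrix(as.numeric(is.na(m)), nrow(m), ncol(m))
        w <- pracma::interp2(x = ax$lon, y = ax$lat, Z = miss,
                             xp = pts$xp, yp = pts$yp, method = "linear")
        out[matrix(w, length(t_lat), length(t_lon)) > 0] <- NA_real_
      }
    }
    if (is_char) {
      out_chr <- matrix(codes[round(as.vector(out))], nrow(out), ncol(out))
      return(out_chr)
    }
    out
  }
  fields <- purrr::imap(grids, function(g, nm) {
    resample(g, axes[[nm]], categorical(nm))
  })

  out <- tibble::tibble(
    lat = rep(t_lat, times = length(t_lon)),
    lon = rep(t_lon, each = length(t_lat))
  )
  for (nm in names(fields)) out[[nm]] <- as.vector(fields[[nm]])
  out <- dplyr::arrange(out, .data$lat, .data$lon)

  if ("sss_summer" %in% names(out) && !"sss_class_summer" %in% names(out)) {
    out$sss_class_summer <- reclassify_salinity(out$sss_summer)
    out$sss_summer <- NULL
  }
  if ("sss_winter" %in% names(out) && !"sss_class_winter" %in% names(out)) {
    out$sss_class_winter <- reclassify_salinity(out$sss_winter)
    out$sss_winter <- NULL
  }
  if ("terrigenous" %in% names(out) && is.numeric(out$terrigenous)) {
    out$terrigenous <- c("none", "low", "high",
                         "arctic")[round(out$terrigenous) + 1L]
  }
  if (!"terrigenous" %in% names(out)) out$terrigenous <- "none"
  # a field supplied for one season only is taken as season-invariant
  for (pair in list(c("sst_summer", "sst_winter"),
                    c("sss_class_summer", "sss_class_winter"),
                    c("prod_summer", "prod_winter"))) {
    have <- pair %in% names(out)
    if (xor(have[1], have[2])) out[[pair[!have]]] <- out[[pair[have]]]
  }
  env_stack(out)
}

#' Per-factory eligibility and shelf masks
#'
#' A factory can only be computed where the sea floor lies inside its depth
#' interval and terrigenous input does not overwhelm carbonate production.
#' For each factory the eligibility rule is:
#' `0 <= bathymetry <= depth_max`, terrigenous category not `"high"` or
#' `"arctic"`, and (`terrigenous != "low"` or the factory tolerates low
#' terrigenous input — only the heterozoan-C factory does). `depth_max` is
#' 100 m for the biochemical and photozoan-T factories and 200 m for the
#' photo-C and heterozoan-C factories. Land cells are never eligible.
#'
#' @param env An [env_stack()].
#' @param params Named list of [factory_params()]; defaults to the shipped
#'   parameterization.
#' @return A tibble of class `mask_set` with columns `lat`, `lon`,
#'   `shelf_100`, `shelf_200` and one logical `eligible_<factory>` column per
#'   factory.
#' @export
build_masks <- function(env, params = default_factory_params()) {
  stopifnot(is_env_stack(env))
  depth <- env$bathymetry
  terr <- ifelse(is.na(env$terrigenous), "none", env$terrigenous)
  out <- tibble::tibble(
    lat = env$lat, lon = env$lon,
    shelf_100 = !is.na(depth) & depth >= 0 & depth <= 100,
    shelf_200 = !is.na(depth) & depth >= 0 & depth <= 200
  )
  for (p in params) {
    elig <- !is.na(depth) & depth >= 0 & depth <= p$depth_max &
      !(terr %in% c("high", "arctic")) &
      (terr != "low" | p$tolerates_low_terrigenous)
    out[[paste0("eligible_", p$factory)]] <- elig
  }
  class(out) <- c("mask_set", class(tibble::tibble()))
  out
}

# ---- stack and categorical map IO ------------------------------------------

#' Read and write environmental stacks and factory maps
#'
#' An [env_stack()] is stored as a single long-format CSV (one row per cell)
#' plus a JSON sidecar (`<path>.json`) recording the lattice resolution. A
#' factory map is stored as an ESRI ASCII raster of integer codes
#' (0 none, 1 biochemical, 2 photozoan_T, 3 photo_C, 4 heterozoan_C,
#' -1 masked/land) with the code table in a JSON sidecar.
#'
#' @param env An [env_stack()].
#' @param map A factory-map tibble (`lat`, `lon`, `factory`).
#' @param path Output path (`.csv` for stacks, `.asc` for maps).
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name stack-io
NULL

#' @rdname stack-io
#' @export
write_env_stack <- function(env, path) {
  stopifnot(is_env_stack(env))
  utils::write.csv(env, path, row.names = FALSE)
  ax <- grid_axes(env)
  jsonlite::write_json(
    list(resolution = ax$res_lat, nlat = length(ax$lat),
         nlon = length(ax$lon)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname stack-io
#' @export
read_env_stack <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  env_stack(df)
}

factory_codes <- function() {
  c(none = 0L, biochemical = 1L, photozoan_T = 2L, photo_C = 3L,
    heterozoan_C = 4L)
}

#' @rdname stack-io
#' @export
write_factory_map <- function(map, path) {
  stopifnot(all(c("lat", "lon", "factory") %in% names(map)))
  codes <- factory_codes()
  g <- tibble::tibble(
    lat = map$lat, lon = map$lon,
    value = ifelse(is.na(map$factory), -1,
                   codes[as.character(map$factory)])
  )
  write_grid(g, path)
  jsonlite::write_json(
    list(codes = c(as.list(codes), list(masked = -1L))),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname stack-io
#' @export
read_factory_map <- function(path) {
  g <- read_grid(path)
  codes <- factory_codes()
  lookup <- names(codes)[match(g$value, codes)]
  lookup[!is.na(g$value) & g$value == -1] <- NA_character_
  out <- tibble::tibble(lat = g$lat, lon = g$lon, factory = lookup)
  new_factory_map(out)
}
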