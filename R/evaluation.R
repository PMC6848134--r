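#' Cell-by-cell agreement between observed and predicted factory maps
#'
#' Both maps are expanded into four binary presence layers (one per factory).
#' In each cell, every layer whose presence/absence matches between the maps
#' counts as a success, so the per-cell accuracy takes values 0, 25, 50, 75
#' or 100%: identical categories score 100%, an observed factory predicted as
#' `"none"` (or vice versa) scores 75% (one layer wrong), and two different
#' factories score 50% (two layers wrong). Cells that are masked (`NA`) in
#' either map get `NA` accuracy.
#'
#' @param observed,predicted Factory-map tibbles (`lat`, `lon`, `factory`) on
#'   the same lattice.
#' @return A tibble `lat`, `lon`, `accuracy` (percent).
#' @export
cell_accuracy <- function(observed, predicted) {
  if (!identical(paste(observed$lat, observed$lon),
                 paste(predicted$lat, predicted$lon))) {
    stop("observed and predicted maps are not co-registered", call. = FALSE)
  }
  facs <- names(factory_codes())[-1]
  matches <- rep(0L, nrow(observed))
  for (f in facs) {
    matches <- matches +
      as.integer((observed$factory == f) == (predicted$factory == f))
  }
  acc <- 25 * matches
  acc[is.na(observed$factory) | is.na(predicted$factory)] <- NA_real_
  tibble::tibble(lat = observed$lat, lon = observed$lon,
                 accuracy = as.numeric(acc))
}

#' Global accuracy over an evaluation domain
#'
#' The arithmetic mean of per-cell accuracies over the cells selected by the
#' evaluation mask (all non-missing cells by default).
#'
#' @param accuracy_grid A [cell_accuracy()] result.
#' @param evaluation_mask Optional logical vector aligned with the rows of
#'   `accuracy_grid` (e.g. [evaluation_domain()]).
#' @return Global accuracy in percent.
#' @export
global_accuracy <- function(accuracy_grid, evaluation_mask = NULL) {
  acc <- accuracy_grid$accuracy
  if (!is.null(evaluation_mask)) {
    stopifnot(length(evaluation_mask) == length(acc))
    acc <- acc[evaluation_mask]
  }
  acc <- acc[!is.na(acc)]
  if (length(acc) == 0) stop("evaluation mask selects no cells", call. = FALSE)
  mean(acc)
}

#' Default evaluation domain
#'
#' Cells where a factory could in principle occur: water depth between 0 and
#' 200 m and terrigenous category not `"high"` or `"arctic"`.
#'
#' @param env An [env_stack()].
#' @return Logical vector aligned with the rows of `env`.
#' @export
evaluation_domain <- function(env) {
  stopifnot(is_env_stack(env))
  terr <- ifelse(is.na(env$terrigenous), "none", env$terrigenous)
  !is.na(env$bathymetry) & env$bathymetry >= 0 & env$bathymetry <= 200 &
    !(terr %in% c("high", "arctic"))
}

#' Anomaly accounting between observed and predicted maps
#'
#' Counts, per factory layer, the overestimations (predicted but not
#' observed) and underestimations (observed but not predicted) over the
#' evaluation domain, and the repartition of all anomalies between the
#' factories (percent of total layer mismatches).
#'
#' @inheritParams cell_accuracy
#' @param evaluation_mask Optional logical vector selecting the evaluation
#'   domain.
#' @return An object of class `accuracy_report`: a list with
#'   `global_accuracy` (percent), `accuracy_grid`, `anomalies` (tibble with
#'   columns `factory`, `overestimated`, `underestimated`, `mismatches`,
#'   `repartition_pct`) and `n_cells`.
#' @export
anomaly_summary <- function(observed, predicted, evaluation_mask = NULL) {
  grid <- cell_accuracy(observed, predicted)
  keep <- !is.na(grid$accuracy)
  if (!is.null(evaluation_mask)) keep <- keep & evaluation_mask
  facs <- names(factory_codes())[-1]
  rows <- purrr::map_dfr(facs, function(f) {
    obs <- observed$factory[keep] == f
    pre <- predicted$factory[keep] == f
    tibble::tibble(
      factory = f,
      overestimated = sum(pre & !obs, na.rm = TRUE),
      underestimated = sum(obs & !pre, na.rm = TRUE)
    )
  })
  rows$mismatches <- rows$overestimated + rows$underestimated
  total <- sum(rows$mismatches)
  rows$repartition_pct <- if (total > 0) 100 * rows$mismatches / total else 0
  structure(list(
    global_accuracy = global_accuracy(grid, evaluation_mask),
    accuracy_grid = grid,
    anomalies = rows,
    n_cells = sum(keep)
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> global accuracy %.1f%% over %d cells\n",
              x$global_accuracy, x$n_cells))
  print(x$anomalies)
  invisible(x)
}

#' Tidy an accuracy report
#'
#' `tidy()` returns the per-factory anomaly table; `glance()` returns a
#' one-row summary with the global accuracy and total anomaly count.
#'
#' @param x An [anomaly_summary()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.accuracy_report <- function(x, ...) {
  x$anomalies
}

#' @rdname tidy.accuracy_report
#' @export
glance.accuracy_report <- function(x, ...) {
  tibble::tibble(
    global_accuracy = x$global_accuracy,
    n_cells = x$n_cells,
    total_mismatches = sum(x$anomalies$mismatches)
  )
}

#' @rdname tidy.accuracy_report
#' @param object An `accuracy_report`.
#' @export
autoplot.accuracy_report <- function(object, ...) {
  ggplot2::ggplot(object$accuracy_grid,
                  ggplot2::aes(x = .data$lon, y = .data$lat,
                               fill = .data$accuracy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), na.value = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "accuracy (%)") +
    ggplot2::theme_minimal()
}
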