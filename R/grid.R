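#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data :=
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# ---- internal lattice helpers ----------------------------------------------

# Axes of a regular lat-lon grid tibble; errors if spacing is not uniform.
grid_axes <- function(df, tol = 1e-9) {
  stopifnot(all(c("lat", "lon") %in% names(df)))
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  check_uniform <- function(ax, nm) {
    if (length(ax) < 2) return(NA_real_)
    d <- diff(ax)
    if (max(d) - min(d) > tol * max(abs(ax), 1)) {
      stop("`", nm, "` axis is not uniformly spaced", call. = FALSE)
    }
    mean(d)
  }
  list(lat = lat, lon = lon,
       res_lat = check_uniform(lat, "lat"),
       res_lon = check_uniform(lon, "lon"))
}

# Long tibble -> matrix with rows = ascending latitude, cols = ascending lon.
grid_matrix <- function(df, col = "value") {
  ax <- grid_axes(df)
  m <- matrix(NA_real_, length(ax$lat), length(ax$lon))
  i <- match(df$lat, ax$lat)
  j <- match(df$lon, ax$lon)
  m[cbind(i, j)] <- df[[col]]
  m
}

# Matrix (rows = ascending lat) -> long tibble sorted by lat then lon.
grid_tibble <- function(m, lat, lon, name = "value") {
  lat_col <- rep(lat, times = length(lon))
  lon_col <- rep(lon, each = length(lat))
  out <- tibble::tibble(lat = lat_col, lon = lon_col, !!name := as.vector(m))
  dplyr::arrange(out, .data$lat, .data$lon)
}

# ---- raster IO -------------------------------------------------------------

#' Read and write single-field rasters as plain text
#'
#' Grids are exchanged in two portable plain-text formats, selected by file
#' extension:
#'
#' * **`.asc`** — ESRI ASCII raster: a six-line header (`ncols`, `nrows`,
#'   `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#'   values from north to south. Coordinates are cell-centered plate-carree
#'   latitude/longitude in degrees.
#' * **`.csv`** — long format with columns `lat`, `lon`, `value`.
#'
#' On read, latitude is normalized to ascending order and the no-data sentinel
#' is mapped to `NA`. Categorical grids written by [write_factory_map()] carry
#' a JSON sidecar with their integer code table.
#'
#' @param path File path ending in `.asc` or `.csv`.
#' @param grid A tibble with columns `lat`, `lon`, `value` on a regular
#'   lattice.
#' @param nodata Sentinel written for missing cells in `.asc` output.
#' @param digits Significant digits written to `.asc` output.
#' @return `read_grid()` returns a tibble with columns `lat`, `lon`, `value`;
#'   `write_grid()` returns `path` invisibly.
#' @examples
#' g <- tidyr::expand_grid(lat = c(-0.5, 0.5), lon = c(10.5, 11.5))
#' g$value <- c(1, 2, NA, 4)
#' f <- tempfile(fileext = ".asc")
#' write_grid(g, f)
#' read_grid(f)
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read grid: file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path)
    if (!all(c("lat", "lon", "value") %in% names(df))) {
      stop("CSV grid ", path, " must have columns lat, lon, value",
           call. = FALSE)
    }
    out <- dplyr::arrange(tibble::as_tibble(df[c("lat", "lon", "value")]),
                          .data$lat, .data$lon)
    grid_axes(out)  # validates regularity
    return(out)
  }
  if (ext != "asc") {
    stop("unsupported grid format '", ext, "' for ", path,
         " (use .asc or .csv)", call. = FALSE)
  }
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", trimws(lines[i]))) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("ASCII raster ", path, " is missing georeferencing header fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows
  if (length(vals) != nc * nr) {
    stop("ASCII raster ", path, " has ", length(vals),
         " values but header declares ", nc * nr, call. = FALSE)
  }
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]  # north-first on disk -> ascending lat
  lat <- hdr$yllcorner + (seq_len(nr) - 0.5) * hdr$cellsize
  lon <- hdr$xllcorner + (seq_len(nc) - 0.5) * hdr$cellsize
  grid_tibble(m, lat, lon)
}

#' @rdname read_grid
#' @export
write_grid <- function(grid, path, nodata = -9999, digits = 10) {
  ax <- grid_axes(grid)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(dplyr::arrange(grid, .data$lat, .data$lon), path,
                     row.names = FALSE)
    return(invisible(path))
  }
  if (ext != "asc") {
    stop("unsupported grid format '", ext, "' for ", path,
         " (use .asc or .csv)", call. = FALSE)
  }
  res <- ax$res_lat
  if (is.na(res)) res <- ax$res_lon
  if (!is.na(ax$res_lon) && !is.na(ax$res_lat) &&
      abs(ax$res_lat - ax$res_lon) > 1e-9) {
    stop("ASCII raster output requires square cells; lat spacing ",
         ax$res_lat, " != lon spacing ", ax$res_lon, call. = FALSE)
  }
  m <- grid_matrix(grid)
  m[is.na(m)] <- nodata
  m <- m[nrow(m):1, , drop = FALSE]  # write north-first
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", length(ax$lon)),
    paste("nrows", length(ax$lat)),
    paste("xllcorner", format(min(ax$lon) - res / 2, digits = 15)),
    paste("yllcorner", format(min(ax$lat) - res / 2, digits = 15)),
    paste("cellsize", format(res, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  writeLines(apply(m, 1, function(r) {
    paste(format(r, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = " ")
  }), con)
  invisible(path)
}

# ---- salinity reclassification ---------------------------------------------

#' Reclassify practical salinity into the eight-class scheme
#'
#' Sea-surface salinity enters the factory functions as an ordinal class, not
#' in psu. The bins are left-closed, right-open, with an open top class:
#' 1 = 30–31.5, 2 = 31.5–33, 3 = 33–34, 4 = 34–35, 5 = 35–35.5, 6 = 35.5–36.5,
#' 7 = 36.5–37.5, 8 = ≥37.5 psu. Salinities below 30 psu clamp to class 1
#' (with a message) rather than being masked: brackish inhibition is carried
#' by the salinity membership functions, not by the classifier.
#'
#' @param psu Numeric vector of practical salinities.
#' @return Integer vector of classes 1–8; `NA` where `psu` is not finite.
#' @examples
#' reclassify_salinity(c(36, 37.6, 34.2))
#' @export
reclassify_salinity <- function(psu) {
  cls <- findInterval(psu, c(31.5, 33, 34, 35, 35.5, 36.5, 37.5)) + 1L
  low <- is.finite(psu) & psu < 30
  if (any(low)) {
    message(sum(low), " salinity value(s) below 30 psu clamped to class 1")
  }
  cls[!is.finite(psu)] <- NA_integer_
  as.integer(cls)
}
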