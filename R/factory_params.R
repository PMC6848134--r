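#' Parameterization of one carbonate factory function
#'
#' A factory function scores every eligible grid cell with a weighted sum of
#' fuzzy memberships,
#' `F = a f(z) + b f(SST) + c f(SSS) + d f(P)` with `a + b + c + d = 1`,
#' and declares the factory present where `F` strictly exceeds its final
#' threshold. This object carries everything one factory needs: the
#' membership specification per parameter, the seasonal aggregation rule per
#' parameter, the four weights, the presence threshold, the depth interval and
#' the terrigenous/background flags.
#'
#' Seasonal rules decide what value each membership sees:
#' `"mean_of_seasons"` averages the warm- and cool-season fields (salinity
#' classes are averaged fractionally, not re-rounded), `"warm_season"` and
#' `"cool_season"` pick one field, and `"product_of_two_specs"` (SST only)
#' evaluates a *production* spec on the warm season and a *persistence* spec
#' on the cool season and multiplies them, which preserves the seasonality
#' signal for factories defined by strong seasonal contrast.
#'
#' The bathymetry membership is flat (1) inside the factory's 0–`depth_max`
#' interval: the depth interval itself is enforced by the eligibility mask
#' (see [build_masks()]), and no depth trend is imposed within it.
#'
#' @param factory Factory identifier, e.g. `"photozoan_T"`.
#' @param sst,sss,prod A [membership_spec()] each; for
#'   `sst_rule = "product_of_two_specs"`, `sst` is a list with elements
#'   `production` and `persistence`.
#' @param z Bathymetry membership; defaults to independent (flat within the
#'   masked depth interval).
#' @param sst_rule,sss_rule,prod_rule Seasonal aggregation rule per parameter.
#' @param weights Named numeric vector `c(z=, sst=, sss=, prod=)`; must be
#'   non-negative and sum to 1.
#' @param threshold Final susceptibility threshold in (0, 1); presence is
#'   strict (`F > threshold`).
#' @param depth_max Maximum water depth (m) of the factory's habitat.
#' @param tolerates_low_terrigenous Whether `"low"` terrigenous cells remain
#'   eligible (only the heterozoan-C factory).
#' @param background Whether this factory is the opportunistic background,
#'   assigned only where no other factory occurs.
#' @param productivity_floor Minimum seasonal-mean productivity (per metre)
#'   required for a background factory to be assigned, or `NA` for none.
#' @return An object of class `factory_params`.
#' @seealso [default_factory_params()], [susceptibility()]
#' @export
factory_params <- function(factory,
                           sst, sss, prod,
                           z = membership_spec("independent"),
                           sst_rule = c("mean_of_seasons", "warm_season",
                                        "cool_season",
                                        "product_of_two_specs"),
                           sss_rule = c("mean_of_seasons", "warm_season",
                                        "cool_season"),
                           prod_rule = c("mean_of_seasons", "warm_season",
                                         "cool_season"),
                           weights,
                           threshold,
                           depth_max,
                           tolerates_low_terrigenous = FALSE,
                           background = FALSE,
                           productivity_floor = NA_real_) {
  sst_rule <- match.arg(sst_rule)
  sss_rule <- match.arg(sss_rule)
  prod_rule <- match.arg(prod_rule)
  if (sst_rule == "product_of_two_specs") {
    if (!is.list(sst) || !all(c("production", "persistence") %in% names(sst)) ||
        !inherits(sst$production, "membership_spec") ||
        !inherits(sst$persistence, "membership_spec")) {
      stop("for product_of_two_specs, `sst` must be list(production=, ",
           "persistence=) of membership_spec", call. = FALSE)
    }
  } else if (!inherits(sst, "membership_spec")) {
    stop("`sst` must be a membership_spec", call. = FALSE)
  }
  stopifnot(inherits(sss, "membership_spec"),
            inherits(prod, "membership_spec"),
            inherits(z, "membership_spec"))
  if (!is.numeric(weights) ||
      !setequal(names(weights), c("z", "sst", "sss", "prod"))) {
    stop("`weights` must be a named numeric vector c(z=, sst=, sss=, prod=)",
         call. = FALSE)
  }
  weights <- weights[c("z", "sst", "sss", "prod")]
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1 (got ", sum(weights), ")", call. = FALSE)
  }
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 1,
            is.numeric(depth_max), depth_max > 0)
  structure(list(
    factory = factory, sst = sst, sss = sss, prod = prod, z = z,
    sst_rule = sst_rule, sss_rule = sss_rule, prod_rule = prod_rule,
    weights = weights, threshold = as.numeric(threshold),
    depth_max = as.numeric(depth_max),
    tolerates_low_terrigenous = isTRUE(tolerates_low_terrigenous),
    background = isTRUE(background),
    productivity_floor = as.numeric(productivity_floor)
  ), class = "factory_params")
}

#' @export
print.factory_params <- function(x, ...) {
  cat(sprintf("<factory_params> %s  threshold %.2f  depth 0-%g m%s%s\n",
              x$factory, x$threshold, x$depth_max,
              if (x$background) "  [background]" else "",
              if (x$tolerates_low_terrigenous) "  [tolerates low terr]" else ""))
  w <- x$weights
  cat(sprintf("  weights: z %.2f  sst %.2f  sss %.2f  prod %.2f\n",
              w["z"], w["sst"], w["sss"], w["prod"]))
  invisible(x)
}

#' Published default parameterization of the four factories
#'
#' The shipped defaults encode the calibrated model:
#'
#' * **biochemical** (Persian-Gulf-type, chemically driven): SST large
#'   sigmoid (mid-point 30.5 deg C, spread 58) on the warm season — the factory
#'   needs very warm water during at least one season; salinity near-Gaussian
#'   on class 8 (>37.5 psu, spread 3) on the cool season — hypersaline all
#'   year round; productivity independent; weights z 0.10 / SST 0.45 /
#'   SSS 0.45 / P 0; threshold 0.6; depth 0–100 m.
#' * **photozoan_T** (tropical coral-reef): SST Gaussian (25.7, 0.03) on the
#'   seasonal mean, whose 0.5-crossings land on 20.9 and 30.5 deg C; salinity
#'   Gaussian (class 5, 0.043); productivity Gaussian (0.015 per m, 565);
#'   weights 0.03 / 0.64 / 0.06 / 0.27; threshold 0.7; depth 0–100 m.
#' * **photo_C** (warm-temperate, Mediterranean-type): SST as the product of a
#'   production Gaussian (25.25, 0.025) on the warm season and a persistence
#'   Gaussian (12.325, 0.0244) on the cool season; salinity Gaussian
#'   (class 7, 0.075); productivity Gaussian (0.0203, 2450); weights 0.04 /
#'   0.62 / 0.12 / 0.22; threshold 0.5; depth 0–200 m.
#' * **heterozoan_C** (filter-feeder, opportunistic background): SST and SSS
#'   independent; productivity near-Gaussian (0.06 per m, 625); weights
#'   0.10 / 0 / 0 / 0.90; threshold 0.5; depth 0–200 m; tolerates low
#'   terrigenous input; assigned only where no other factory occurs and
#'   seasonal-mean productivity is at least 0.01 per m.
#'
#' Bathymetry weights are the simplex remainder `1 - (b + c + d)` per factory,
#' with a flat depth membership inside the masked interval.
#'
#' @return Named list of [factory_params()], in the fixed priority order
#'   biochemical, photozoan_T, photo_C, heterozoan_C.
#' @examples
#' params <- default_factory_params()
#' params$photozoan_T
#' @export
default_factory_params <- function() {
  list(
    biochemical = factory_params(
      "biochemical",
      sst = membership_spec("sigmoid_large", 30.5, 58),
      sss = membership_spec("near_gaussian", 8, 3),
      prod = membership_spec("independent"),
      sst_rule = "warm_season", sss_rule = "cool_season",
      weights = c(z = 0.10, sst = 0.45, sss = 0.45, prod = 0),
      threshold = 0.6, depth_max = 100
    ),
    photozoan_T = factory_params(
      "photozoan_T",
      sst = membership_spec("gaussian", 25.7, 0.03),
      sss = membership_spec("gaussian", 5, 0.043),
      prod = membership_spec("gaussian", 0.015, 565),
      weights = c(z = 0.03, sst = 0.64, sss = 0.06, prod = 0.27),
      threshold = 0.7, depth_max = 100
    ),
    photo_C = factory_params(
      "photo_C",
      sst = list(production = membership_spec("gaussian", 25.25, 0.025),
                 persistence = membership_spec("gaussian", 12.325, 0.0244)),
      sss = membership_spec("gaussian", 7, 0.075),
      prod = membership_spec("gaussian", 0.0203, 2450),
      sst_rule = "product_of_two_specs",
      weights = c(z = 0.04, sst = 0.62, sss = 0.12, prod = 0.22),
      threshold = 0.5, depth_max = 200
    ),
    heterozoan_C = factory_params(
      "heterozoan_C",
      sst = membership_spec("independent"),
      sss = membership_spec("independent"),
      prod = membership_spec("near_gaussian", 0.06, 625),
      weights = c(z = 0.10, sst = 0, sss = 0, prod = 0.90),
      threshold = 0.5, depth_max = 200,
      tolerates_low_terrigenous = TRUE, background = TRUE,
      productivity_floor = 0.01
    )
  )
}

# ---- YAML serialization -----------------------------------------------------

spec_to_list <- function(spec) {
  if (spec$form == "independent") return(list(form = "independent"))
  list(form = spec$form, midpoint = spec$midpoint, spread = spec$spread)
}

spec_from_list <- function(x) {
  membership_spec(x$form, x$midpoint %||% NULL, x$spread %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write factory parameter configurations
#'
#' The full per-factory parameterization round-trips through a YAML file so
#' that every midpoint, spread, weight, rule and threshold can be overridden
#' without touching code.
#'
#' @param params Named list of [factory_params()].
#' @param path YAML file path.
#' @return `read_factory_params()` returns a named list of
#'   [factory_params()]; `write_factory_params()` returns `path` invisibly.
#' @export
write_factory_params <- function(params, path) {
  out <- purrr::map(params, function(p) {
    sst <- if (p$sst_rule == "product_of_two_specs") {
      list(production = spec_to_list(p$sst$production),
           persistence = spec_to_list(p$sst$persistence))
    } else {
      spec_to_list(p$sst)
    }
    list(factory = p$factory, sst = sst, sss = spec_to_list(p$sss),
         prod = spec_to_list(p$prod), z = spec_to_list(p$z),
         sst_rule = p$sst_rule, sss_rule = p$sss_rule,
         prod_rule = p$prod_rule, weights = as.list(p$weights),
         threshold = p$threshold, depth_max = p$depth_max,
         tolerates_low_terrigenous = p$tolerates_low_terrigenous,
         background = p$background,
         productivity_floor = if (is.na(p$productivity_floor)) NULL
                              else p$productivity_floor)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_factory_params
#' @export
read_factory_params <- function(path) {
  if (!file.exists(path)) {
    stop("parameter file does not exist: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  purrr::map(raw, function(p) {
    sst <- if (identical(p$sst_rule, "product_of_two_specs")) {
      list(production = spec_from_list(p$sst$production),
           persistence = spec_from_list(p$sst$persistence))
    } else {
      spec_from_list(p$sst)
    }
    factory_params(
      factory = p$factory, sst = sst, sss = spec_from_list(p$sss),
      prod = spec_from_list(p$prod), z = spec_from_list(p$z),
      sst_rule = p$sst_rule, sss_rule = p$sss_rule, prod_rule = p$prod_rule,
      weights = unlist(p$weights)[c("z", "sst", "sss", "prod")],
      threshold = p$threshold, depth_max = p$depth_max,
      tolerates_low_terrigenous = isTRUE(p$tolerates_low_terrigenous),
      background = isTRUE(p$background),
      productivity_floor = p$productivity_floor %||% NA_real_
    )
  })
}
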