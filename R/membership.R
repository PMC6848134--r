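#' Fuzzy membership functions for environmental suitability
#'
#' The susceptibility of a carbonate factory to a single environmental
#' parameter is expressed as a fuzzy membership value in \[0, 1\]: 0 means the
#' parameter value completely inhibits carbonate occurrence, 1 means it is
#' completely favourable. Three bounded functional forms are used, all
#' parameterized by a mid-point `midpoint` (in the parameter's units) and a
#' dimensionless shape parameter `spread`:
#'
#' * **Gaussian**: `f(x) = exp(-spread * (x - midpoint)^2)` — symmetric optimum
#'   between a lower and an upper tolerance threshold.
#' * **Near-Gaussian**: `f(x) = 1 / (1 + spread * (x - midpoint)^2)` — same
#'   optimum but heavier tails, giving more weight to marginal values.
#' * **Large sigmoid**: `f(x) = 1 / (1 + (x / midpoint)^(-spread))` — a
#'   monotonically increasing ramp for parameters with a minimum threshold but
#'   no upper limit; `f(midpoint) = 0.5` exactly.
#'
#' Non-finite inputs propagate as `NA`. The large sigmoid is undefined for
#' `x <= 0`; such values return 0 (total inhibition), since the form is only
#' used for sea-surface temperature where non-positive Celsius values are
#' outside any factory's habitat of interest.
#'
#' @param x Numeric vector of environmental parameter values.
#' @param midpoint Mid-point of the function, in the parameter's units.
#' @param spread Positive shape parameter.
#' @return Numeric vector of susceptibilities in \[0, 1\], `NA` where `x` is
#'   not finite.
#' @examples
#' fuzzy_gaussian(30.5, midpoint = 25.7, spread = 0.03)   # ~0.5
#' fuzzy_near_gaussian(7, midpoint = 8, spread = 3)        # 0.25
#' fuzzy_sigmoid_large(32, midpoint = 30.5, spread = 58)   # ~0.94
#' @name fuzzy-forms
NULL

#' @rdname fuzzy-forms
#' @export
fuzzy_gaussian <- function(x, midpoint, spread) {
  stopifnot(is.numeric(x), spread > 0, is.finite(midpoint))
  out <- exp(-spread * (x - midpoint)^2)
  out[!is.finite(x)] <- NA_real_
  out
}

#' @rdname fuzzy-forms
#' @export
fuzzy_near_gaussian <- function(x, midpoint, spread) {
  stopifnot(is.numeric(x), spread > 0, is.finite(midpoint))
  out <- 1 / (1 + spread * (x - midpoint)^2)
  out[!is.finite(x)] <- NA_real_
  out
}

#' @rdname fuzzy-forms
#' @export
fuzzy_sigmoid_large <- function(x, midpoint, spread) {
  stopifnot(is.numeric(x), spread > 0, midpoint > 0)
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x)
  pos <- ok & x > 0
  # log-space evaluation keeps the form stable for extreme spread values
  out[pos] <- 1 / (1 + exp(-spread * (log(x[pos]) - log(midpoint))))
  out[ok & x <= 0] <- 0
  out
}

#' Specify one fuzzy membership function
#'
#' Bundles a functional form with its mid-point and spread so that factory
#' parameterizations can be stored, serialized and evaluated uniformly. The
#' form `"independent"` denotes a parameter with no influence on the factory:
#' it evaluates to 1 for any input and needs no mid-point or spread.
#'
#' @param form One of `"gaussian"`, `"near_gaussian"`, `"sigmoid_large"`,
#'   `"independent"`.
#' @param midpoint Mid-point, required unless `form = "independent"`.
#' @param spread Positive spread, required unless `form = "independent"`.
#' @return An object of class `membership_spec`.
#' @seealso [evaluate_membership()], [fuzzy_gaussian()]
#' @examples
#' spec <- membership_spec("gaussian", midpoint = 25.7, spread = 0.03)
#' evaluate_membership(spec, c(20.9, 25.7, 30.5))
#' @export
membership_spec <- function(form = c("gaussian", "near_gaussian",
                                     "sigmoid_large", "independent"),
                            midpoint = NULL, spread = NULL) {
  form <- match.arg(form)
  if (form == "independent") {
    spec <- list(form = form, midpoint = NA_real_, spread = NA_real_)
  } else {
    if (is.null(midpoint) || !is.finite(midpoint)) {
      stop("`midpoint` must be a finite number for form '", form, "'",
           call. = FALSE)
    }
    if (is.null(spread) || !is.finite(spread) || spread <= 0) {
      stop("`spread` must be a positive number for form '", form, "'",
           call. = FALSE)
    }
    if (form == "sigmoid_large" && midpoint <= 0) {
      stop("`midpoint` must be positive for the large sigmoid", call. = FALSE)
    }
    spec <- list(form = form, midpoint = as.numeric(midpoint),
                 spread = as.numeric(spread))
  }
  structure(spec, class = "membership_spec")
}

#' @export
print.membership_spec <- function(x, ...) {
  if (x$form == "independent") {
    cat("<membership_spec> independent (constant 1)\n")
  } else {
    cat(sprintf("<membership_spec> %s  midpoint = %g  spread = %g\n",
                x$form, x$midpoint, x$spread))
  }
  invisible(x)
}

#' Evaluate a membership specification
#'
#' Dispatches on the functional form of a [membership_spec()] and evaluates it
#' elementwise. Missing inputs stay missing; the `"independent"` form returns
#' 1 for any observed value. (Zero-weighted parameters never reach evaluation
#' in the susceptibility sum, so gaps in an ignored field cannot mask a cell.)
#'
#' @param spec A [membership_spec()].
#' @param x Numeric vector of parameter values.
#' @return Numeric vector of susceptibilities in \[0, 1\].
#' @export
evaluate_membership <- function(spec, x) {
  stopifnot(inherits(spec, "membership_spec"))
  switch(spec$form,
    independent   = ifelse(is.na(x), NA_real_, 1),
    gaussian      = fuzzy_gaussian(x, spec$midpoint, spec$spread),
    near_gaussian = fuzzy_near_gaussian(x, spec$midpoint, spec$spread),
    sigmoid_large = fuzzy_sigmoid_large(x, spec$midpoint, spec$spread),
    stop("unknown membership form: ", spec$form, call. = FALSE)
  )
}

#' Half-width of a membership function at susceptibility 0.5
#'
#' For the symmetric forms, the distance from the mid-point to the parameter
#' value where the function crosses 0.5: `sqrt(log(2) / spread)` for the
#' Gaussian and `1 / sqrt(spread)` for the near-Gaussian. Useful for checking
#' that calibrated functions cross 0.5 at the intended tolerance thresholds.
#'
#' @param spec A [membership_spec()] with form `"gaussian"` or
#'   `"near_gaussian"`.
#' @return The half-width in the parameter's units.
#' @export
membership_half_width <- function(spec) {
  stopifnot(inherits(spec, "membership_spec"))
  switch(spec$form,
    gaussian      = sqrt(log(2) / spec$spread),
    near_gaussian = 1 / sqrt(spec$spread),
    stop("half-width is defined only for gaussian and near_gaussian forms",
         call. = FALSE)
  )
}

#' Plot membership functions
#'
#' Draws one or more membership specifications over a parameter range, with
#' the 0.5 susceptibility level marked.
#'
#' @param specs A single [membership_spec()] or a named list of them.
#' @param from,to Parameter range to draw.
#' @param n Number of evaluation points.
#' @return A ggplot object.
#' @export
plot_membership <- function(specs, from, to, n = 400) {
  if (inherits(specs, "membership_spec")) specs <- list(membership = specs)
  stopifnot(length(specs) > 0, all(purrr::map_lgl(specs, inherits,
                                                  "membership_spec")))
  if (is.null(names(specs))) names(specs) <- paste0("f", seq_along(specs))
  xs <- seq(from, to, length.out = n)
  df <- purrr::imap_dfr(specs, function(sp, nm) {
    tibble::tibble(curve = nm, x = xs, susceptibility =
                     evaluate_membership(sp, xs))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$susceptibility,
                                   colour = .data$curve)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "parameter value", y = "susceptibility",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
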