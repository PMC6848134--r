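#' Analytic-hierarchy-process weights from a pairwise-comparison matrix
#'
#' The inter-parameter weights of the factory functions can be derived from a
#' Saaty-style reciprocal pairwise-comparison matrix over the environmental
#' parameters: the weight vector is the normalized principal eigenvector,
#' computed here by power iteration to 1e-12. The matrix must be reciprocal
#' (`m[j, i] = 1 / m[i, j]`) with unit diagonal and positive entries.
#'
#' @param m Square numeric matrix of pairwise comparisons.
#' @param labels Optional parameter names (defaults to the matrix dimnames).
#' @return A list of class `ahp_weights` with elements `weights` (named,
#'   summing to 1), `lambda_max` (principal eigenvalue), `ci` (consistency
#'   index) and `cr` (consistency ratio).
#' @examples
#' m <- rbind(c(1, 3), c(1 / 3, 1))
#' ahp_weights(m)$weights  # 0.75, 0.25
#' @export
ahp_weights <- function(m, labels = NULL) {
  check_pairwise(m)
  n <- nrow(m)
  v <- rep(1 / n, n)
  lambda <- n
  for (it in 1:10000) {
    v_new <- as.vector(m %*% v)
    lambda_new <- sum(v_new) / sum(v)
    v_new <- v_new / sum(v_new)
    if (max(abs(v_new - v)) < 1e-12 && abs(lambda_new - lambda) < 1e-12) {
      v <- v_new; lambda <- lambda_new
      break
    }
    v <- v_new; lambda <- lambda_new
  }
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("p", seq_len(n))
  names(v) <- labels
  ci <- if (n > 2) (lambda - n) / (n - 1) else 0
  structure(list(weights = v, lambda_max = lambda, ci = ci,
                 cr = cr_from_ci(ci, n)),
            class = "ahp_weights")
}

check_pairwise <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || !is.numeric(m)) {
    stop("pairwise matrix must be square and numeric", call. = FALSE)
  }
  if (any(m <= 0)) stop("pairwise entries must be positive", call. = FALSE)
  if (any(abs(diag(m) - 1) > tol)) {
    stop("pairwise matrix must have unit diagonal", call. = FALSE)
  }
  if (any(abs(m * t(m) - 1) > tol * pmax(m, 1))) {
    stop("pairwise matrix is not reciprocal (m[j,i] != 1/m[i,j])",
         call. = FALSE)
  }
  invisible(m)
}

# Saaty random-index table for n = 1..10
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

cr_from_ci <- function(ci, n) {
  if (n <= 2) return(0)
  ci / saaty_ri[n]
}

#' Consistency ratio of a pairwise-comparison matrix
#'
#' `CI = (lambda_max - n) / (n - 1)` scaled by the Saaty random index for the
#' matrix size; judgments with `CR > 0.1` are conventionally considered too
#' inconsistent to use. Matrices of size 2 (and any fully consistent matrix)
#' have `CR = 0`.
#'
#' @param m Square reciprocal pairwise matrix, 2 <= n <= 10.
#' @return The consistency ratio.
#' @export
consistency_ratio <- function(m) {
  n <- nrow(m)
  if (n < 2 || n > length(saaty_ri)) {
    stop("consistency ratio is tabulated for 2 <= n <= 10", call. = FALSE)
  }
  ahp_weights(m)$cr
}

#' @export
print.ahp_weights <- function(x, ...) {
  cat("<ahp_weights> lambda_max =", format(x$lambda_max, digits = 8),
      " CR =", format(x$cr, digits = 4), "\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @rdname ahp_weights
#' @param x An `ahp_weights` object.
#' @param ... Unused.
#' @export
tidy.ahp_weights <- function(x, ...) {
  tibble::tibble(parameter = names(x$weights), weight = unname(x$weights))
}

#' Read a pairwise-comparison matrix from CSV
#'
#' Expects a square CSV with a header row and a first column of parameter
#' names mirroring the header.
#'
#' @param path CSV file path.
#' @return A labelled numeric matrix, validated as reciprocal.
#' @export
read_pairwise <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- rownames(df)
  check_pairwise(m)
  m
}
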