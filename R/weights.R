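#' Criterion weights by the row geometric-mean method
#'
#' `weight_i` is the geometric mean of row `i` of the comparison matrix,
#' normalized so the weights sum to 1. For a perfectly consistent matrix
#' (`a_ij = w_i/w_j`) this recovers `w` exactly and coincides with the
#' principal eigenvector.
#'
#' @param matrix A [pcmatrix()].
#' @return Named numeric weight vector summing to 1, with attribute
#'   `set_id`.
#' @seealso [eigenvector_weights()] for Saaty's eigenvector alternative.
#' @export
#' @examples
#' m <- pcmatrix(matrix(c(1, 3, 1/3, 1), 2, byrow = TRUE), c("A", "B"))
#' geometric_mean_weights(m) # 0.75, 0.25
geometric_mean_weights <- function(matrix) {
  stopifnot(inherits(matrix, "pcmatrix"))
  a <- unclass(matrix)
  gm <- exp(rowMeans(log(a)))
  w <- gm / sum(gm)
  names(w) <- rownames(a)
  attr(w, "set_id") <- attr(matrix, "set_id")
  w
}

#' Criterion weights by the principal eigenvector (power iteration)
#'
#' Saaty's original weight derivation: the normalized principal right
#' eigenvector of the comparison matrix, computed by power iteration.
#'
#' @param matrix A [pcmatrix()].
#' @param tolerance Convergence threshold on the max absolute change of the
#'   normalized weight vector between iterations.
#' @param max_iterations Iteration cap before a diagnostic error.
#' @return Named numeric weight vector summing to 1.
#' @export
eigenvector_weights <- function(matrix, tolerance = 1e-12,
                                max_iterations = 1000L) {
  stopifnot(inherits(matrix, "pcmatrix"))
  a <- unclass(matrix)
  n <- nrow(a)
  w <- rep(1 / n, n)
  for (it in seq_len(max_iterations)) {
    v <- as.vector(a %*% w)
    v <- v / sum(v)
    if (max(abs(v - w)) < tolerance) {
      names(v) <- rownames(a)
      attr(v, "set_id") <- attr(matrix, "set_id")
      return(v)
    }
    w <- v
  }
  stop("power iteration did not converge in ", max_iterations,
       " iterations (last change ", format(max(abs(v - w))), ")",
       call. = FALSE)
}

#' Saaty random-index table
#'
#' Expected consistency index of random reciprocal matrices on the 1-9
#' scale, by matrix order, used as the denominator of the consistency
#' ratio. Classic values for orders up to 10, extended through 15.
#'
#' @return Numeric vector; element `n` is the RI for an `n x n` matrix.
#' @export
saaty_random_index <- function() {
  c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
    1.51, 1.54, 1.56, 1.57, 1.59)
}

#' Consistency index and ratio of a comparison matrix
#'
#' Estimates the principal eigenvalue from the supplied weights as
#' `lambda_max = mean_i (A w)_i / w_i`, then `CI = (lambda_max - n)/(n - 1)`
#' and `CR = CI/RI(n)`. A matrix with `CR < 0.10` is conventionally
#' acceptable; 1x1 and 2x2 reciprocal matrices are always consistent
#' (`CR = 0`).
#'
#' @param matrix A [pcmatrix()].
#' @param weights Optional weight vector; defaults to
#'   [geometric_mean_weights()] so the ratio is well defined for either
#'   weighting method.
#' @param ri Random-index table; element `n` used for an order-`n` matrix.
#' @return List of class `consistency_report` with `lambda_max`, `ci`,
#'   `ri`, `cr`, `n` and `acceptable` (`cr < 0.10`).
#' @export
consistency <- function(matrix, weights = geometric_mean_weights(matrix),
                        ri = saaty_random_index()) {
  stopifnot(inherits(matrix, "pcmatrix"))
  a <- unclass(matrix)
  n <- nrow(a)
  if (any(weights <= 0)) stop("weights must be strictly positive", call. = FALSE)
  if (n > length(ri)) {
    stop("no random-index value for order ", n, " (table covers up to ",
         length(ri), ")", call. = FALSE)
  }
  lambda_max <- mean(as.vector(a %*% weights) / weights)
  if (n <= 2) {
    ci <- 0
    cr <- 0
  } else {
    ci <- (lambda_max - n) / (n - 1)
    cr <- ci / ri[n]
  }
  structure(
    list(lambda_max = lambda_max, ci = ci, ri = ri[n], cr = cr, n = n,
         acceptable = cr < 0.10),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "Consistency: lambda_max = %.4f, CI = %.4f, RI = %.2f, CR = %.4f (%s)\n",
    x$lambda_max, x$ci, x$ri, x$cr,
    if (x$acceptable) "acceptable, CR < 0.10" else "NOT acceptable, CR >= 0.10"
  ))
  invisible(x)
}

# Eigen-decomposition lambda_max, used as a cross-check of the
# row-ratio-mean estimate.
eigen_lambda_max <- function(matrix) {
  ev <- eigen(unclass(matrix), only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]))
}
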