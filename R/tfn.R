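#' Triangular fuzzy numbers
#'
#' A triangular fuzzy number (TFN) `(l, m, u)` has linear membership rising
#' from 0 at `l` to 1 at the mode `m` and back to 0 at `u`. Vectors of TFNs
#' are stored as three parallel numeric vectors; arithmetic (`*`, `/`, `^`)
#' follows the standard componentwise approximation for positive TFNs.
#'
#' @param l,m,u Numeric vectors (recycled) with `0 < l <= m <= u`.
#' @return An object of class `tfn`.
#' @export
#' @examples
#' tfn(2, 3, 4) * tfn(1, 1, 1)
tfn <- function(l, m = l, u = m) {
  n <- max(length(l), length(m), length(u))
  l <- rep_len(as.numeric(l), n)
  m <- rep_len(as.numeric(m), n)
  u <- rep_len(as.numeric(u), n)
  if (any(!is.finite(c(l, m, u))) || any(l <= 0)) {
    stop("TFN components must be positive finite numbers", call. = FALSE)
  }
  if (any(l > m + 1e-12) || any(m > u + 1e-12)) {
    stop("TFN requires l <= m <= u", call. = FALSE)
  }
  structure(list(l = l, m = m, u = u), class = "tfn")
}

#' @export
length.tfn <- function(x) length(x$l)

#' @export
print.tfn <- function(x, digits = 4, ...) {
  lab <- names(x$m)
  for (i in seq_along(x$l)) {
    cat(sprintf("%s(%.*g, %.*g, %.*g)\n",
                if (is.null(lab)) "" else paste0(lab[i], ": "),
                digits, x$l[i], digits, x$m[i], digits, x$u[i]))
  }
  invisible(x)
}

#' @export
`[.tfn` <- function(x, i) tfn(x$l[i], x$m[i], x$u[i])

#' @export
Ops.tfn <- function(e1, e2) {
  as_t <- function(e) if (inherits(e, "tfn")) e else tfn(e, e, e)
  switch(.Generic,
    "*" = {
      a <- as_t(e1); b <- as_t(e2)
      tfn(a$l * b$l, a$m * b$m, a$u * b$u)
    },
    "/" = {
      a <- as_t(e1); b <- as_t(e2)
      tfn(a$l / b$u, a$m / b$m, a$u / b$l)
    },
    "^" = {
      if (inherits(e2, "tfn")) stop("TFN exponent not supported", call. = FALSE)
      if (e2 >= 0) tfn(e1$l^e2, e1$m^e2, e1$u^e2)
      else tfn(e1$u^e2, e1$m^e2, e1$l^e2)
    },
    stop(sQuote(.Generic), " not defined for TFNs", call. = FALSE)
  )
}

#' Fuzzy reciprocal of a TFN
#'
#' `1/(l, m, u) = (1/u, 1/m, 1/l)`.
#'
#' @param x A [tfn()].
#' @return A [tfn()].
#' @export
tfn_reciprocal <- function(x) tfn(1 / x$u, 1 / x$m, 1 / x$l)

#' Fuzzify a Saaty intensity into a triangular fuzzy number
#'
#' The crisp judgment scale is widened by one scale step on each side:
#' equal importance stays crisp, `1 -> (1, 1, 1)`; an integer intensity
#' `x` becomes `(x - 1, x, x + 1)`, saturating at the scale ends so
#' `9 -> (8, 9, 9)` and `2 -> (1, 2, 3)`; a reciprocal `1/x` becomes the
#' fuzzy reciprocal `(1/(x+1), 1/x, 1/(x-1))`.
#'
#' @param intensity Numeric vector of Saaty intensities (integers 1-9 or
#'   their reciprocals).
#' @return A [tfn()] of the same length.
#' @export
#' @examples
#' tfn_scale(3)     # (2, 3, 4)
#' tfn_scale(1 / 7) # (1/8, 1/7, 1/6)
tfn_scale <- function(intensity) {
  one <- function(x) {
    if (!is.finite(x) || x <= 0) {
      stop("unsupported intensity: ", format(x), call. = FALSE)
    }
    if (abs(x - 1) < 1e-9) return(c(1, 1, 1))
    if (x > 1) {
      if (abs(x - round(x)) > 1e-9 || x > 9) {
        stop("unsupported intensity: ", format(x),
             " (expected an integer 1-9 or its reciprocal)", call. = FALSE)
      }
      x <- round(x)
      c(max(x - 1, 1), x, min(x + 1, 9))
    } else {
      r <- one(1 / x)
      rev(1 / r)
    }
  }
  comp <- vapply(intensity, one, numeric(3))
  tfn(comp[1, ], comp[2, ], comp[3, ])
}

# Componentwise fuzzy geometric mean of the rows of a fuzzified matrix,
# given as three ordinary matrices.
fuzzy_row_gm <- function(L, M, U) {
  tfn(exp(rowMeans(log(L))), exp(rowMeans(log(M))), exp(rowMeans(log(U))))
}

#' Fuzzify a crisp comparison matrix
#'
#' Applies a fuzzification scale entrywise, giving a matrix of triangular
#' fuzzy numbers stored as three component matrices.
#'
#' @param matrix A [pcmatrix()] on the supported Saaty scale.
#' @param scale Fuzzification function, see [buckley_fuzzy_weights()].
#' @return An object of class `fuzzy_pcmatrix` with components `l`, `m`,
#'   `u` and attribute `set_id`.
#' @export
fuzzify_matrix <- function(matrix, scale = tfn_scale) {
  stopifnot(inherits(matrix, "pcmatrix"))
  a <- unclass(matrix)
  n <- nrow(a)
  ft <- scale(as.vector(a))
  shape <- function(v) base::matrix(v, n, n, dimnames = dimnames(a))
  structure(list(l = shape(ft$l), m = shape(ft$m), u = shape(ft$u)),
            set_id = attr(matrix, "set_id"), class = "fuzzy_pcmatrix")
}

#' Aggregate fuzzified matrices across participants
#'
#' Fuzzy counterpart of [aggregate_group()]: each participant's crisp
#' matrix is fuzzified first, then the fuzzy matrices are combined by the
#' componentwise geometric mean. Fuzzifying before aggregating keeps every
#' entry on the supported fuzzification scale (the geometric mean of Saaty
#' intensities usually is not).
#'
#' @param matrices List of [pcmatrix()] objects (identical ordering), or of
#'   [fuzzify_matrix()] results.
#' @param scale Fuzzification function applied to crisp inputs.
#' @return A `fuzzy_pcmatrix`.
#' @export
aggregate_group_fuzzy <- function(matrices, scale = tfn_scale) {
  if (!length(matrices)) stop("need at least one matrix to aggregate", call. = FALSE)
  fms <- lapply(matrices, function(m) {
    if (inherits(m, "fuzzy_pcmatrix")) m else fuzzify_matrix(m, scale)
  })
  ref <- fms[[1]]
  for (f in fms[-1]) {
    if (!identical(dimnames(f$m), dimnames(ref$m))) {
      stop("matrices differ in order or criterion ordering", call. = FALSE)
    }
  }
  gm_of <- function(comp) {
    exp(Reduce(`+`, lapply(fms, function(f) log(f[[comp]]))) / length(fms))
  }
  structure(list(l = gm_of("l"), m = gm_of("m"), u = gm_of("u")),
            set_id = attr(ref, "set_id"), class = "fuzzy_pcmatrix")
}

#' Fuzzy criterion weights by Buckley's geometric-mean method
#'
#' Each crisp matrix entry is fuzzified with [tfn_scale()]; the fuzzy
#' geometric mean `r_i` of each row is computed componentwise, and the
#' fuzzy weight of criterion `i` is `r_i` divided by the fuzzy sum of all
#' row means using the extremal quotient: lower components over the sum of
#' uppers, modes over the sum of modes, uppers over the sum of lowers.
#' The modes therefore equal the crisp [geometric_mean_weights()] exactly,
#' and each triple brackets its mode.
#'
#' @param matrix A [pcmatrix()] whose entries lie on the supported Saaty
#'   scale, or an already-fuzzified [fuzzify_matrix()] /
#'   [aggregate_group_fuzzy()] result.
#' @param scale Fuzzification function mapping an intensity vector to a
#'   [tfn()]; replace with `function(x) tfn(x, x, x)` for the crisp
#'   (zero-spread) embedding.
#' @return A [tfn()] of fuzzy weights, named by criterion, with attribute
#'   `set_id`.
#' @export
buckley_fuzzy_weights <- function(matrix, scale = tfn_scale) {
  fm <- if (inherits(matrix, "fuzzy_pcmatrix")) matrix
        else fuzzify_matrix(matrix, scale)
  r <- fuzzy_row_gm(fm$l, fm$m, fm$u)
  w <- tfn(r$l / sum(r$u), r$m / sum(r$m), r$u / sum(r$l))
  names(w$l) <- names(w$m) <- names(w$u) <- rownames(fm$m)
  attr(w, "set_id") <- attr(fm, "set_id")
  w
}

#' Centroid defuzzification
#'
#' Collapses a triangular fuzzy number to the centroid of its membership
#' triangle, `(l + m + u)/3`.
#'
#' @param w A [tfn()].
#' @return Numeric vector of crisp values.
#' @export
#' @examples
#' defuzzify(tfn(0.49, 0.65, 0.86)) # 0.6667
defuzzify <- function(w) {
  stopifnot(inherits(w, "tfn"))
  out <- (w$l + w$m + w$u) / 3
  names(out) <- names(w$m)
  out
}

#' Normalize positive crisp values to sum 1
#'
#' Used on defuzzified fuzzy weights, whose centroids do not sum to 1 in
#' general.
#'
#' @param values Positive numeric vector.
#' @return Numeric vector summing to 1, names preserved.
#' @export
normalize_defuzzified <- function(values) {
  if (any(!is.finite(values) | values <= 0)) {
    stop("values must be positive to normalize", call. = FALSE)
  }
  values / sum(values)
}

#' Round half away from zero
#'
#' Display rounding used in weight reports (2 decimal places by default),
#' so 0.125 prints as 0.13 rather than banker's-rounded 0.12.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Full crisp + fuzzy weight report for one comparison matrix
#'
#' Runs the whole weighting pipeline on one matrix and tabulates, per
#' criterion: the crisp weight (geometric-mean by default, eigenvector
#' optionally), the Buckley fuzzy weight triple, its centroid-defuzzified
#' value, and the normalized defuzzified weight. Consistency diagnostics
#' are attached.
#'
#' @param matrix A [pcmatrix()].
#' @param method Crisp weighting method, `"gm"` or `"eigen"`.
#' @param display_digits If non-`NULL`, extra `*_2dp` display columns
#'   rounded half away from zero to this many places.
#' @param fuzzy_matrix Optional pre-fuzzified matrix used for the fuzzy
#'   columns; defaults to fuzzifying `matrix`. Group reports pass the
#'   [aggregate_group_fuzzy()] of the participant matrices here, since the
#'   crisp group matrix itself lies off the fuzzification scale.
#' @return Data frame of class `weight_report` with one row per criterion
#'   and attributes `consistency` (a `consistency_report`) and `set_id`.
#' @export
weight_report <- function(matrix, method = c("gm", "eigen"),
                          display_digits = 2, fuzzy_matrix = NULL) {
  method <- match.arg(method)
  crisp <- switch(method,
    gm = geometric_mean_weights(matrix),
    eigen = eigenvector_weights(matrix)
  )
  fw <- buckley_fuzzy_weights(if (is.null(fuzzy_matrix)) matrix
                              else fuzzy_matrix)
  dfz <- defuzzify(fw)
  ndfz <- normalize_defuzzified(dfz)
  out <- data.frame(
    criterion = rownames(matrix),
    weight = as.numeric(crisp),
    fuzzy_l = fw$l, fuzzy_m = fw$m, fuzzy_u = fw$u,
    defuzzified = as.numeric(dfz),
    normalized_defuzzified = as.numeric(ndfz),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(display_digits)) {
    for (col in c("weight", "fuzzy_l", "fuzzy_m", "fuzzy_u", "defuzzified",
                  "normalized_defuzzified")) {
      out[[paste0(col, "_2dp")]] <- round_half_up(out[[col]], display_digits)
    }
  }
  attr(out, "consistency") <- consistency(matrix, weights = crisp)
  attr(out, "set_id") <- attr(matrix, "set_id")
  attr(out, "method") <- method
  class(out) <- c("weight_report", "data.frame")
  out
}

#' @export
print.weight_report <- function(x, ...) {
  cs <- attr(x, "consistency")
  set <- attr(x, "set_id")
  cat(sprintf("Criterion weights%s (crisp method: %s)\n",
              if (is.null(set)) "" else paste0(" for set '", set, "'"),
              attr(x, "method")))
  shown <- x[, c("criterion", "weight", "fuzzy_l", "fuzzy_m", "fuzzy_u",
                 "defuzzified", "normalized_defuzzified")]
  num <- vapply(shown, is.numeric, logical(1))
  shown[num] <- lapply(shown[num], round, 4)
  print.data.frame(shown, row.names = FALSE)
  print(cs)
  invisible(x)
}
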