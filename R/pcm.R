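#' Construct a pairwise-comparison matrix
#'
#' A positive reciprocal matrix of relative-importance ratios over one
#' criterion set: `a[i, j]` is how many times more important criterion `i`
#' is than criterion `j`, so the diagonal is 1 and `a[j, i] = 1/a[i, j]`.
#'
#' @param x Square numeric matrix of positive ratios.
#' @param criteria Character vector of criterion ids fixing row/column order.
#' @param set_id Which criterion set the matrix belongs to.
#' @return A `pcmatrix` object (a numeric matrix with attributes).
#' @export
pcmatrix <- function(x, criteria = rownames(x), set_id = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (ncol(x) != n) stop("pairwise-comparison matrix must be square", call. = FALSE)
  if (is.null(criteria)) criteria <- paste0("c", seq_len(n))
  if (length(criteria) != n) stop("criteria length must match matrix order", call. = FALSE)
  if (any(!is.finite(x) | x <= 0)) {
    stop("all entries must be positive finite ratios", call. = FALSE)
  }
  if (any(abs(diag(x) - 1) > 1e-9)) {
    stop("diagonal entries must equal 1", call. = FALSE)
  }
  if (any(abs(x * t(x) - 1) > 1e-9)) {
    stop("matrix is not reciprocal: a_ij * a_ji must equal 1", call. = FALSE)
  }
  dimnames(x) <- list(criteria, criteria)
  structure(x, set_id = set_id, class = c("pcmatrix", "matrix", "array"))
}

#' @export
print.pcmatrix <- function(x, digits = 3, ...) {
  set <- attr(x, "set_id")
  cat(sprintf("Pairwise comparison matrix (%d criteria%s)\n", nrow(x),
              if (is.null(set)) "" else paste0(", set: ", set)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Build a reciprocal matrix from one expert's pairwise judgments
#'
#' Takes exactly one judgment per unordered pair of criteria — the
#' questionnaire asks "how important is A compared to B" once per pair —
#' and fills the full reciprocal matrix with unit diagonal. A judgment
#' `(a, b, x)` sets `a over b = x` and `b over a = 1/x`; judgments may be
#' given in either orientation.
#'
#' @param judgments Data frame with columns `criterion_a`, `criterion_b`
#'   and either `intensity` (numeric or `"1/7"`-style character) or
#'   `linguistic_label`.
#' @param criteria Character vector of criterion ids defining matrix order,
#'   or a criterion-set data frame with an `id` column.
#' @param set_id Optional set id recorded on the result.
#' @return A [pcmatrix()].
#' @export
#' @examples
#' j <- data.frame(criterion_a = "A", criterion_b = "B", intensity = 3)
#' matrix_from_judgments(j, c("A", "B"))
matrix_from_judgments <- function(judgments, criteria, set_id = NULL) {
  if (is.data.frame(criteria)) criteria <- criteria$id
  criteria <- as.character(criteria)
  n <- length(criteria)
  if (n < 2) stop("need at least 2 criteria to compare", call. = FALSE)
  judgments <- as.data.frame(judgments, stringsAsFactors = FALSE)
  if (!all(c("criterion_a", "criterion_b") %in% names(judgments))) {
    stop("judgments need columns criterion_a and criterion_b", call. = FALSE)
  }
  if ("intensity" %in% names(judgments) && !all(is.na(judgments$intensity))) {
    intensity <- parse_intensity(judgments$intensity)
  } else if ("linguistic_label" %in% names(judgments)) {
    intensity <- linguistic_to_intensity(judgments$linguistic_label)
  } else {
    stop("judgments need an 'intensity' or 'linguistic_label' column",
         call. = FALSE)
  }

  ia <- match(judgments$criterion_a, criteria)
  ib <- match(judgments$criterion_b, criteria)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(judgments$criterion_a[is.na(ia)],
                    judgments$criterion_b[is.na(ib)]))
    stop("judgment references unknown criterion: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  if (any(ia == ib)) {
    stop("self-comparison judgment for criterion ",
         sQuote(criteria[ia[which(ia == ib)[1]]]), call. = FALSE)
  }

  pair_key <- paste(pmin(ia, ib), pmax(ia, ib))
  if (anyDuplicated(pair_key)) {
    d <- which(duplicated(pair_key))[1]
    stop("duplicate judgment for pair (", criteria[ia[d]], ", ",
         criteria[ib[d]], ")", call. = FALSE)
  }
  all_pairs <- utils::combn(n, 2)
  all_keys <- paste(all_pairs[1, ], all_pairs[2, ])
  missing <- setdiff(all_keys, pair_key)
  if (length(missing)) {
    idx <- as.integer(strsplit(missing[1], " ")[[1]])
    stop("missing judgment for pair (", criteria[idx[1]], ", ",
         criteria[idx[2]], ")", call. = FALSE)
  }

  a <- diag(n)
  for (k in seq_along(ia)) {
    a[ia[k], ib[k]] <- intensity[k]
    a[ib[k], ia[k]] <- 1 / intensity[k]
  }
  pcmatrix(a, criteria, set_id = set_id)
}

#' Combine individual matrices into a group matrix
#'
#' The workshop-level matrix is the element-wise geometric mean of the
#' participants' matrices; geometric averaging is the aggregation that
#' preserves reciprocity, so the group matrix is again a valid
#' pairwise-comparison matrix.
#'
#' @param matrices List of [pcmatrix()] objects with identical criterion
#'   order and set id.
#' @return A [pcmatrix()] of the same order.
#' @export
aggregate_group <- function(matrices) {
  if (!length(matrices)) stop("need at least one matrix to aggregate", call. = FALSE)
  stopifnot(all(vapply(matrices, inherits, logical(1), "pcmatrix")))
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!identical(dim(m), dim(ref)) ||
        !identical(rownames(m), rownames(ref))) {
      stop("matrices differ in order or criterion ordering", call. = FALSE)
    }
    if (!identical(attr(m, "set_id"), attr(ref, "set_id"))) {
      stop("matrices belong to different criterion sets", call. = FALSE)
    }
  }
  logsum <- Reduce(`+`, lapply(matrices, function(m) log(unclass(m))))
  g <- exp(logsum / length(matrices))
  # symmetrize log-reciprocity against floating-point drift
  g <- sqrt(g / t(g))
  pcmatrix(g, rownames(ref), set_id = attr(ref, "set_id"))
}

#' Read and write pairwise-comparison matrices as CSV
#'
#' Square CSV table with criterion ids as header row and first column.
#' Ratios may be decimals or `"1/7"`-style fractions; fractions are
#' preserved on write. Lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @param set_id Optional set id recorded on the result.
#' @return `read_matrix_csv` returns a [pcmatrix()]; `write_matrix_csv`
#'   returns `path` invisibly.
#' @export
read_matrix_csv <- function(path, set_id = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                         colClasses = "character")
  criteria <- names(raw)[-1]
  vals <- apply(as.matrix(raw[, -1, drop = FALSE]), c(1, 2), identity)
  m <- matrix(parse_intensity(as.vector(vals)), nrow = nrow(raw))
  pcmatrix(m, criteria, set_id = set_id)
}

#' @rdname read_matrix_csv
#' @param x A [pcmatrix()].
#' @param manifest Optional manifest file name recorded as a `#` comment.
#' @export
write_matrix_csv <- function(x, path, manifest = NULL) {
  stopifnot(inherits(x, "pcmatrix"))
  out <- data.frame(criterion = rownames(x),
                    matrix(format_intensity(as.vector(unclass(x))), nrow(x),
                           dimnames = list(NULL, colnames(x))),
                    check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest)) writeLines(paste("# manifest:", manifest), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read per-participant judgments from long-format CSV
#'
#' Expected header: `participant_id,set_id,criterion_a,criterion_b`, plus
#' `linguistic_label` and/or `intensity`.
#'
#' @param path CSV file path.
#' @return Data frame of judgments.
#' @export
read_judgments <- function(path) {
  j <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("participant_id", "set_id", "criterion_a", "criterion_b")
  missing <- setdiff(need, names(j))
  if (length(missing)) {
    stop("judgments file ", path, " missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!any(c("intensity", "linguistic_label") %in% names(j))) {
    stop("judgments file ", path,
         " needs an 'intensity' or 'linguistic_label' column", call. = FALSE)
  }
  j
}

#' Build all matrices from a long-format judgment table
#'
#' @param judgments Data frame as returned by [read_judgments()].
#' @param config A [workshop_config()] supplying criterion-set orderings.
#' @return Nested list: `result[[participant]][[set_id]]` is a [pcmatrix()].
#' @export
matrices_from_judgments <- function(judgments, config) {
  stopifnot(inherits(config, "workshop_config"))
  out <- list()
  for (pid in unique(judgments$participant_id)) {
    jp <- judgments[judgments$participant_id == pid, , drop = FALSE]
    out[[pid]] <- list()
    for (sid in unique(jp$set_id)) {
      if (!sid %in% names(config$criteria)) {
        stop("unknown criterion set '", sid, "' for participant ", pid,
             call. = FALSE)
      }
      out[[pid]][[sid]] <- matrix_from_judgments(
        jp[jp$set_id == sid, , drop = FALSE],
        config$criteria[[sid]], set_id = sid
      )
    }
  }
  out
}
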