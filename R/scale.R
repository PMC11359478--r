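#' The linguistic judgment scale
#'
#' Nine phrases used in the elicitation questionnaire, each paired with a
#' Saaty intensity-of-importance ratio. "Equally important" maps to 1; the
#' "more important" phrases map to the odd intensities 3, 5, 7, 9 and the
#' "less important" phrases to their reciprocals.
#'
#' @return A data frame with columns `label` and `intensity`.
#' @export
#' @examples
#' linguistic_scale()
linguistic_scale <- function() {
  data.frame(
    label = c(
      "Extremely less important",
      "Strongly less important",
      "Moderately less important",
      "Slightly less important",
      "Equally important",
      "Slightly more important",
      "Moderately more important",
      "Strongly more important",
      "Extremely more important"
    ),
    intensity = c(1 / 9, 1 / 7, 1 / 5, 1 / 3, 1, 3, 5, 7, 9),
    stringsAsFactors = FALSE
  )
}

# Odd Saaty intensities produced by the linguistic scale.
saaty_odd_scale <- function() c(1 / 9, 1 / 7, 1 / 5, 1 / 3, 1, 3, 5, 7, 9)

# Intensities accepted on input: odd scale plus intermediate evens and
# their reciprocals (interoperability with generic AHP data).
saaty_accepted_scale <- function() {
  v <- c(1:9, 1 / (2:9))
  sort(unique(v))
}

#' Convert a linguistic judgment to its numeric intensity
#'
#' @param label Character vector of scale phrases (case-insensitive;
#'   surrounding whitespace ignored).
#' @return Numeric vector of intensities in `{1/9, 1/7, 1/5, 1/3, 1, 3, 5, 7, 9}`.
#' @seealso [intensity_to_linguistic()] for the inverse mapping.
#' @export
#' @examples
#' linguistic_to_intensity("Extremely more important") # 9
#' linguistic_to_intensity("strongly less important")  # 1/7
linguistic_to_intensity <- function(label) {
  stopifnot(is.character(label))
  scale <- linguistic_scale()
  idx <- match(tolower(trimws(label)), tolower(scale$label))
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop("unknown linguistic label(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  scale$intensity[idx]
}

#' Convert a numeric intensity back to its linguistic phrase
#'
#' @param intensity Numeric vector of scale intensities.
#' @return Character vector of phrases.
#' @export
intensity_to_linguistic <- function(intensity) {
  stopifnot(is.numeric(intensity))
  scale <- linguistic_scale()
  idx <- vapply(intensity, function(x) {
    hit <- which(abs(scale$intensity - x) < 1e-9)
    if (length(hit) != 1L) NA_integer_ else hit
  }, integer(1))
  if (anyNA(idx)) {
    bad <- unique(intensity[is.na(idx)])
    stop("intensity not on the linguistic scale: ",
         paste(format(bad), collapse = ", "), call. = FALSE)
  }
  scale$label[idx]
}

#' Parse intensity values written as decimals or fractions
#'
#' Judgment and matrix files may write reciprocal intensities as `"1/7"`.
#' This parses both forms; [format_intensity()] writes them back, preserving
#' the fraction style for reciprocals of integers.
#'
#' @param x Character or numeric vector.
#' @return Numeric vector of positive ratios.
#' @export
#' @examples
#' parse_intensity(c("1/7", "3", "0.2"))
parse_intensity <- function(x) {
  if (is.numeric(x)) {
    out <- as.numeric(x)
  } else {
    x <- trimws(as.character(x))
    out <- suppressWarnings(as.numeric(x))
    frac <- grepl("^[0-9]+(\\.[0-9]+)?\\s*/\\s*[0-9]+(\\.[0-9]+)?$", x)
    if (any(frac)) {
      parts <- strsplit(x[frac], "/")
      out[frac] <- vapply(parts, function(p) {
        as.numeric(p[1]) / as.numeric(p[2])
      }, numeric(1))
    }
    if (anyNA(out)) {
      stop("cannot parse intensity value(s): ",
           paste(sQuote(unique(x[is.na(out)])), collapse = ", "),
           call. = FALSE)
    }
  }
  if (any(!is.finite(out) | out <= 0)) {
    stop("intensities must be positive finite ratios", call. = FALSE)
  }
  out
}

#' @rdname parse_intensity
#' @export
format_intensity <- function(x) {
  vapply(x, function(v) {
    inv <- 1 / v
    if (v < 1 && abs(inv - round(inv)) < 1e-9) {
      sprintf("1/%d", as.integer(round(inv)))
    } else {
      format(v, digits = 15)
    }
  }, character(1))
}
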