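#' Weight of a scoring question
#'
#' Each question combines one climate hazard, one transmission process and
#' one health outcome; its weight is the arithmetic mean of the three
#' (normalized defuzzified) criterion weights it references.
#'
#' @param hazard_w,transmission_w,outcome_w Non-negative criterion weights.
#' @return The question weight `w_q`.
#' @export
#' @examples
#' question_weight(0.65, 0.19, 0.27) # 0.37
question_weight <- function(hazard_w, transmission_w, outcome_w) {
  w <- c(hazard_w, transmission_w, outcome_w)
  if (any(!is.finite(w) | w < 0)) {
    stop("criterion weights must be non-negative", call. = FALSE)
  }
  (hazard_w + transmission_w + outcome_w) / 3
}

#' Question weights for a whole configuration
#'
#' @param config A [workshop_config()].
#' @param set_weights Named list of per-set criterion weight vectors
#'   (names `hazard`, `transmission`, `outcome`; each vector named by
#'   criterion id), e.g. the `normalized_defuzzified` columns of group
#'   [weight_report()]s.
#' @return Data frame with columns `question_id`, `w_q`, `max_value`.
#' @export
question_weights <- function(config, set_weights) {
  stopifnot(inherits(config, "workshop_config"))
  if (!length(config$questions)) stop("configuration has no questions", call. = FALSE)
  rows <- lapply(config$questions, function(q) {
    w3 <- mapply(function(kind, id) {
      wv <- set_weights[[kind]]
      if (is.null(wv) || is.na(wv[id])) {
        stop("no ", kind, " weight for criterion '", id, "' (question '",
             q$id, "')", call. = FALSE)
      }
      wv[[id]]
    }, criterion_set_kinds(), c(q$hazard, q$transmission, q$outcome))
    data.frame(question_id = q$id,
               w_q = question_weight(w3[1], w3[2], w3[3]),
               max_value = q$max_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Initial score of one answer
#'
#' `Z = w_q * V / M`: the question weight scaled by the fraction of the
#' maximum ordinal answer value attained.
#'
#' @param w_q Question weight.
#' @param V Answer value, integer in `[0, M]`.
#' @param M Maximum answer value (`>= 1`).
#' @return The initial score `Z`.
#' @export
#' @examples
#' question_score(0.37, 2, 3) # 0.2467
question_score <- function(w_q, V, M) {
  check_answer(V, M)
  w_q * V / M
}

#' Confidence bounds of one answer's score
#'
#' The confidence half-width `C` is subtracted from / added to the answer
#' value before scaling: `Z_low = w_q * (V - C)/M`, `Z_high =
#' w_q * (V + C)/M`, with `V -+ C` clamped into `[0, M]` so the bounds stay
#' within `[0, w_q]`.
#'
#' @inheritParams question_score
#' @param C Non-negative integer confidence value.
#' @return Numeric vector `c(z_low, z_high)` (or a two-column matrix for
#'   vector input).
#' @export
#' @examples
#' score_bounds(0.37, 2, 1, 3) # 0.1233 0.3700
score_bounds <- function(w_q, V, C, M) {
  check_answer(V, M)
  if (any(C < 0)) stop("confidence value C must be non-negative", call. = FALSE)
  z_low <- w_q * pmax(V - C, 0) / M
  z_high <- w_q * pmin(V + C, M) / M
  if (length(z_low) == 1L) c(z_low = z_low, z_high = z_high)
  else cbind(z_low = z_low, z_high = z_high)
}

check_answer <- function(V, M) {
  if (any(M < 1)) stop("maximum answer value M must be >= 1", call. = FALSE)
  if (any(V < 0 | V > M)) {
    stop("answer value V must lie in [0, M]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write long-format response tables
#'
#' Expected header: `participant_id,disease_id,question_id,answer_value,
#' confidence`; `confidence` holds the labels low/medium/high. Lines
#' starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @return Data frame of responses.
#' @export
read_responses <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("participant_id", "disease_id", "question_id", "answer_value",
            "confidence")
  missing <- setdiff(need, names(r))
  if (length(missing)) {
    stop("responses file ", path, " missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  r$answer_value <- as.integer(r$answer_value)
  r
}

#' @rdname read_responses
#' @param responses Response data frame.
#' @param manifest Optional manifest file name recorded as a `#` comment.
#' @export
write_responses <- function(responses, path, manifest = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest)) writeLines(paste("# manifest:", manifest), con)
  utils::write.csv(responses, con, row.names = FALSE)
  invisible(path)
}

#' Aggregate confidence-adjusted disease scores
#'
#' For every response, the initial score and confidence bounds are computed
#' with [question_score()] and [score_bounds()], then summed over all
#' participants and questions per disease. Normalized scores divide the
#' sums by `P * sum_q w_q` (participants times total question weight), the
#' score attained when every participant gives the maximum answer to every
#' question — so the normalized initial score has ceiling 1.
#'
#' @param responses Data frame with columns `participant_id`, `disease_id`,
#'   `question_id`, `answer_value`, `confidence` (labels or integer `C`
#'   values).
#' @param weights Question-weight table from [question_weights()] (columns
#'   `question_id`, `w_q`, `max_value`).
#' @param confidence Mapping from confidence label to integer `C`, see
#'   [default_confidence()].
#' @param missing How to treat absent (participant, disease, question)
#'   triples: `"error"` (workshops require complete answering) or `"zero"`
#'   (impute answer 0 with low confidence; imputations are reported in the
#'   `imputed` attribute).
#' @return Data frame of class `disease_scores`: one row per disease with
#'   raw sums `z`, `z_low`, `z_high`, their `*_norm` counterparts, and
#'   counts `n_participants`, `n_questions`.
#' @export
disease_scores <- function(responses, weights,
                           confidence = default_confidence(),
                           missing = c("error", "zero")) {
  missing <- match.arg(missing)
  confidence <- check_confidence_map(confidence)
  responses <- as.data.frame(responses, stringsAsFactors = FALSE)
  need <- c("participant_id", "disease_id", "question_id", "answer_value",
            "confidence")
  if (!all(need %in% names(responses))) {
    stop("responses need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  participants <- unique(as.character(responses$participant_id))
  diseases <- sort(unique(as.character(responses$disease_id)))
  if (!length(participants) || !nrow(responses)) {
    stop("no responses: at least one participant is required", call. = FALSE)
  }

  key <- paste(responses$participant_id, responses$disease_id,
               responses$question_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- responses[duplicated(key), ][1, ]
    stop("duplicate response for (", d$participant_id, ", ", d$disease_id,
         ", ", d$question_id, ")", call. = FALSE)
  }

  qi <- match(responses$question_id, weights$question_id)
  if (anyNA(qi)) {
    stop("response references unweighted question: ",
         paste(unique(responses$question_id[is.na(qi)]), collapse = ", "),
         call. = FALSE)
  }

  n_expected <- length(participants) * length(diseases) * nrow(weights)
  imputed <- NULL
  if (nrow(responses) < n_expected) {
    grid <- expand.grid(participant_id = participants, disease_id = diseases,
                        question_id = weights$question_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gkey <- paste(grid$participant_id, grid$disease_id, grid$question_id,
                  sep = "\r")
    absent <- grid[!gkey %in% key, , drop = FALSE]
    if (missing == "error") {
      a <- absent[1, ]
      stop(nrow(absent), " missing response(s), e.g. (", a$participant_id,
           ", ", a$disease_id, ", ", a$question_id,
           "); use missing = \"zero\" to impute", call. = FALSE)
    }
    absent$answer_value <- 0L
    absent$confidence <- "low"
    imputed <- absent
    responses <- rbind(responses[, need], absent[, need])
    qi <- match(responses$question_id, weights$question_id)
  }

  conf_chr <- as.character(responses$confidence)
  is_label <- conf_chr %in% names(confidence)
  C <- ifelse(is_label, confidence[conf_chr], suppressWarnings(as.numeric(conf_chr)))
  if (anyNA(C)) {
    stop("unknown confidence label(s): ",
         paste(unique(conf_chr[is.na(C)]), collapse = ", "), call. = FALSE)
  }

  w_q <- weights$w_q[qi]
  M <- weights$max_value[qi]
  V <- responses$answer_value
  check_answer(V, M)
  z <- w_q * V / M
  z_low <- w_q * pmax(V - C, 0) / M
  z_high <- w_q * pmin(V + C, M) / M

  did <- as.character(responses$disease_id)
  agg <- function(v) as.numeric(tapply(v, factor(did, levels = diseases), sum))
  denom <- length(participants) * sum(weights$w_q)
  out <- data.frame(
    disease_id = diseases,
    z = agg(z), z_low = agg(z_low), z_high = agg(z_high),
    stringsAsFactors = FALSE
  )
  out$z_norm <- out$z / denom
  out$z_low_norm <- out$z_low / denom
  out$z_high_norm <- out$z_high / denom
  out$n_participants <- length(participants)
  out$n_questions <- nrow(weights)
  attr(out, "normalization_constant") <- denom
  attr(out, "imputed") <- imputed
  class(out) <- c("disease_scores", "data.frame")
  out
}

#' Rank diseases into a priority list
#'
#' Orders diseases by normalized initial score descending; ties are broken
#' by the normalized lower bound descending, then by disease id
#' lexicographically, so the ranking is a deterministic function of the
#' score set. Ranks are 1-based and gap-free.
#'
#' @param scores Output of [disease_scores()].
#' @return The same table sorted, with a `rank` column prepended.
#' @export
rank_diseases <- function(scores) {
  stopifnot(is.data.frame(scores))
  ord <- order(-scores$z_norm, -scores$z_low_norm,
               as.character(scores$disease_id), method = "radix")
  out <- scores[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("priority_list", class(scores))
  out
}

#' @export
print.priority_list <- function(x, digits = 3, ...) {
  cat(sprintf("Priority list: %d diseases, %d participants, %d questions\n",
              nrow(x), x$n_participants[1], x$n_questions[1]))
  shown <- data.frame(rank = x$rank, disease = x$disease_id,
                      score = round(x$z_norm, digits),
                      low = round(x$z_low_norm, digits),
                      high = round(x$z_high_norm, digits))
  print.data.frame(head(shown, 25), row.names = FALSE)
  if (nrow(x) > 25) cat("...\n")
  invisible(x)
}

#' Long-format plot data for dot-and-range priority charts
#'
#' Reshapes a ranked priority list into one row per (disease, estimate)
#' with estimate in initial/lower/upper — the layout used to draw the
#' classic dot with a horizontal confidence bar per disease.
#'
#' @param ranked A ranked priority list from [rank_diseases()].
#' @return Long data frame with columns `disease_id`, `rank`, `estimate`,
#'   `value`.
#' @export
priority_plot_data <- function(ranked) {
  stopifnot(is.data.frame(ranked), "rank" %in% names(ranked))
  long <- rbind(
    data.frame(disease_id = ranked$disease_id, rank = ranked$rank,
               estimate = "initial", value = ranked$z_norm),
    data.frame(disease_id = ranked$disease_id, rank = ranked$rank,
               estimate = "lower", value = ranked$z_low_norm),
    data.frame(disease_id = ranked$disease_id, rank = ranked$rank,
               estimate = "upper", value = ranked$z_high_norm)
  )
  long[order(long$rank), , drop = FALSE]
}

#' Plot a priority list as dots with confidence ranges
#'
#' @param ranked A ranked priority list from [rank_diseases()].
#' @return A ggplot object.
#' @export
plot_priority <- function(ranked) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- ranked
  d$disease_id <- factor(d$disease_id, levels = rev(d$disease_id))
  ggplot2::ggplot(d, ggplot2::aes(y = disease_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = z_low_norm, xend = z_high_norm,
                                       yend = disease_id),
                          colour = "grey60", linewidth = 1.5) +
    ggplot2::geom_point(ggplot2::aes(x = z_norm), colour = "red3", size = 2) +
    ggplot2::labs(x = "Normalized score (confidence range)", y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}
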