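#' @noRd
criterion_set_kinds <- function() c("hazard", "transmission", "outcome")

#' Default confidence-level mapping
#'
#' Maps each confidence label to the non-negative integer half-width `C`
#' applied around an answer value: medium confidence widens the score range
#' by one ordinal step in each direction, low by two, high by none. The
#' mapping must be monotone (lower confidence never gives a smaller `C`)
#' and can be overridden wherever a `confidence` argument is accepted.
#'
#' @return Named integer vector with elements `high`, `medium`, `low`.
#' @export
#' @examples
#' default_confidence()
default_confidence <- function() c(high = 0L, medium = 1L, low = 2L)

check_confidence_map <- function(conf) {
  conf <- unlist(conf)
  if (!all(c("high", "medium", "low") %in% names(conf))) {
    stop("confidence mapping must name high, medium and low", call. = FALSE)
  }
  conf <- vapply(conf[c("high", "medium", "low")], as.integer, integer(1))
  if (any(conf < 0)) stop("confidence values must be non-negative", call. = FALSE)
  if (conf[["high"]] > conf[["medium"]] || conf[["medium"]] > conf[["low"]]) {
    stop("confidence mapping must be monotone: high <= medium <= low",
         call. = FALSE)
  }
  conf
}

#' Assemble and validate a workshop configuration
#'
#' A workshop configuration holds the three criterion sets (climate hazards,
#' processes of transmission, health outcomes), the scoring questions (each
#' referencing one criterion from each set and carrying ordered multinomial
#' answer options), the disease list, participant ids, and the confidence
#' mapping. All cross-references are checked here; every loader funnels
#' through this constructor.
#'
#' @param criteria Named list with elements `hazard`, `transmission`,
#'   `outcome`, each a data frame with columns `id` and `label` (two or more
#'   rows per set so pairwise weighting is possible).
#' @param questions List of question records; each has `id`, `text`,
#'   `hazard`, `transmission`, `outcome` (criterion ids) and `options`, a
#'   data frame with columns `text` and `value`. Option values must be
#'   consecutive integers starting at 0 or 1, with at least two options.
#' @param diseases Data frame with columns `id` and `label`, or a character
#'   vector of ids.
#' @param participants Character vector of participant ids (may be empty).
#' @param confidence Named confidence mapping, see [default_confidence()].
#' @return An object of class `workshop_config`.
#' @export
workshop_config <- function(criteria, questions = list(), diseases = NULL,
                            participants = character(),
                            confidence = default_confidence()) {
  kinds <- criterion_set_kinds()
  if (!is.list(criteria) || !all(kinds %in% names(criteria))) {
    stop("criteria must be a named list with sets: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  criteria <- lapply(criteria[kinds], function(set) {
    set <- as.data.frame(set, stringsAsFactors = FALSE)
    if (!"id" %in% names(set)) stop("criterion records need an 'id'", call. = FALSE)
    if (!"label" %in% names(set)) set$label <- set$id
    set$id <- as.character(set$id)
    set$label <- as.character(set$label)
    set[, c("id", "label")]
  })
  for (kind in kinds) {
    ids <- criteria[[kind]]$id
    if (anyDuplicated(ids)) {
      stop("duplicate criterion id in set '", kind, "': ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    }
  }

  questions <- lapply(questions, normalize_question, criteria = criteria)
  qids <- vapply(questions, `[[`, character(1), "id")
  if (anyDuplicated(qids)) {
    stop("duplicate question id: ",
         paste(unique(qids[duplicated(qids)]), collapse = ", "), call. = FALSE)
  }
  names(questions) <- qids

  if (is.null(diseases)) diseases <- character()
  if (is.character(diseases)) {
    diseases <- data.frame(id = diseases, label = diseases,
                           stringsAsFactors = FALSE)
  } else {
    diseases <- as.data.frame(diseases, stringsAsFactors = FALSE)
    if (!"id" %in% names(diseases)) stop("disease records need an 'id'", call. = FALSE)
    if (!"label" %in% names(diseases)) diseases$label <- diseases$id
    diseases <- diseases[, c("id", "label")]
    diseases$id <- as.character(diseases$id)
  }
  if (anyDuplicated(diseases$id)) {
    stop("duplicate disease id: ",
         paste(unique(diseases$id[duplicated(diseases$id)]), collapse = ", "),
         call. = FALSE)
  }
  participants <- as.character(participants)
  if (anyDuplicated(participants)) {
    stop("duplicate participant id", call. = FALSE)
  }

  structure(
    list(criteria = criteria, questions = questions, diseases = diseases,
         participants = participants,
         confidence = check_confidence_map(confidence)),
    class = "workshop_config"
  )
}

normalize_question <- function(q, criteria) {
  need <- c("id", "hazard", "transmission", "outcome", "options")
  missing <- setdiff(need, names(q))
  if (length(missing)) {
    stop("question record missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  q$id <- as.character(q$id)
  if (is.null(q$text)) q$text <- q$id
  for (kind in criterion_set_kinds()) {
    ref <- as.character(q[[kind]])
    if (length(ref) != 1L || !ref %in% criteria[[kind]]$id) {
      stop("question '", q$id, "': unknown ", kind, " criterion '", ref, "'",
           call. = FALSE)
    }
    q[[kind]] <- ref
  }
  opts <- q$options
  if (is.character(opts)) {
    # plain text options: ordinal values assigned 0, 1, 2, ... in order
    opts <- data.frame(text = opts, value = seq_along(opts) - 1L,
                       stringsAsFactors = FALSE)
  } else if (is.list(opts) && !is.data.frame(opts)) {
    opts <- do.call(rbind, lapply(opts, function(o) {
      data.frame(text = as.character(o$text), value = as.integer(o$value),
                 stringsAsFactors = FALSE)
    }))
  } else {
    opts <- as.data.frame(opts, stringsAsFactors = FALSE)
  }
  if (nrow(opts) < 2L) {
    stop("question '", q$id, "': needs at least 2 answer options", call. = FALSE)
  }
  opts$value <- as.integer(opts$value)
  v <- sort(opts$value)
  if (!v[1] %in% c(0L, 1L) || !identical(v, seq(v[1], length.out = length(v)))) {
    stop("question '", q$id, "': option values must be consecutive integers ",
         "starting at 0 or 1", call. = FALSE)
  }
  q$options <- opts[order(opts$value), , drop = FALSE]
  q$max_value <- max(opts$value)
  q[c("id", "text", "hazard", "transmission", "outcome", "options", "max_value")]
}

#' @export
print.workshop_config <- function(x, ...) {
  sizes <- vapply(x$criteria, nrow, integer(1))
  cat("Workshop configuration\n")
  cat(sprintf("  criteria: %s\n",
              paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", ")))
  cat(sprintf("  questions: %d   diseases: %d   participants: %d\n",
              length(x$questions), nrow(x$diseases), length(x$participants)))
  cat(sprintf("  confidence C: high=%d medium=%d low=%d\n",
              x$confidence[["high"]], x$confidence[["medium"]],
              x$confidence[["low"]]))
  invisible(x)
}

#' Read a workshop configuration from YAML or JSON
#'
#' The file has top-level sections `criteria` (with `hazard`,
#' `transmission`, `outcome` lists of `{id, label}` records), `questions`,
#' `diseases`, and optionally `participants` and `confidence`. A packaged
#' example is at `system.file("extdata", "example_workshop.yaml",
#' package = "zoonoprior")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [workshop_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- switch(tolower(tools::file_ext(path)),
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = FALSE),
    stop("unsupported config format: ", path, call. = FALSE)
  )
  if (!is.list(raw) || is.null(raw$criteria)) {
    stop("config ", path, ": missing 'criteria' section", call. = FALSE)
  }
  criteria <- lapply(raw$criteria, function(set) {
    do.call(rbind, lapply(set, function(cr) {
      data.frame(id = as.character(cr$id),
                 label = as.character(if (is.null(cr$label)) cr$id else cr$label),
                 stringsAsFactors = FALSE)
    }))
  })
  diseases <- if (is.null(raw$diseases)) NULL else {
    if (all(vapply(raw$diseases, is.character, logical(1)))) {
      unlist(raw$diseases)
    } else {
      do.call(rbind, lapply(raw$diseases, function(d) {
        data.frame(id = as.character(d$id),
                   label = as.character(if (is.null(d$label)) d$id else d$label),
                   stringsAsFactors = FALSE)
      }))
    }
  }
  tryCatch(
    workshop_config(
      criteria = criteria,
      questions = if (is.null(raw$questions)) list() else raw$questions,
      diseases = diseases,
      participants = if (is.null(raw$participants)) character()
                     else unlist(raw$participants),
      confidence = if (is.null(raw$confidence)) default_confidence()
                   else raw$confidence
    ),
    error = function(e) {
      stop("config ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
}

config_as_list <- function(config) {
  list(
    criteria = lapply(config$criteria, function(set) {
      lapply(seq_len(nrow(set)), function(i) {
        list(id = set$id[i], label = set$label[i])
      })
    }),
    questions = lapply(unname(config$questions), function(q) {
      list(
        id = q$id, text = q$text, hazard = q$hazard,
        transmission = q$transmission, outcome = q$outcome,
        options = lapply(seq_len(nrow(q$options)), function(i) {
          list(text = q$options$text[i], value = q$options$value[i])
        })
      )
    }),
    diseases = lapply(seq_len(nrow(config$diseases)), function(i) {
      list(id = config$diseases$id[i], label = config$diseases$label[i])
    }),
    participants = as.list(config$participants),
    confidence = as.list(config$confidence)
  )
}

#' Write a workshop configuration back to YAML or JSON
#'
#' Round-trip stable: `load_config(write_config(cfg, path))` is semantically
#' identical to `cfg`.
#'
#' @param config A [workshop_config()] object.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "workshop_config"))
  x <- config_as_list(config)
  switch(tolower(tools::file_ext(path)),
    "yaml" = , "yml" = yaml::write_yaml(x, path),
    "json" = jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE),
    stop("unsupported config format: ", path, call. = FALSE)
  )
  invisible(path)
}

#' Packaged default criterion vocabulary
#'
#' The default criterion sets distilled from literature on climate-driven
#' zoonotic transmission: eight climate hazards, four biological
#' transmission processes, and four health-outcome categories.
#'
#' @return A `workshop_config` with the three criterion sets populated and
#'   no questions or diseases.
#' @export
default_vocabulary <- function() {
  load_config(system.file("extdata", "default_criteria.yaml",
                          package = "zoonoprior"))
}
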