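#' Configuration for a synthetic elicitation workshop
#'
#' Describes the workshop to simulate. The defaults mirror the illustrative
#' scenario used throughout the tool's documentation: 10 experts answering
#' 10 questions for 25 diseases (expert panels typically range from 6 to 15
#' members and select around 10-20 questions).
#'
#' @param seed Integer seed; mandatory, every draw is derived from it.
#' @param n_participants Number of experts.
#' @param n_questions Number of scoring questions.
#' @param n_diseases Number of diseases to score.
#' @param set_sizes Named integer vector: criteria per set.
#' @param n_options Answer options per question (ordinal values `0` to
#'   `n_options - 1`).
#' @param judgment_noise Standard deviation of the multiplicative
#'   (log-scale) perturbation applied to each expert's consistent judgment
#'   ratios before snapping to the Saaty scale. 0 means ratios are snapped
#'   without perturbation.
#' @param answer_noise Standard deviation of the logit-scale noise added to
#'   a disease's latent sensitivity when drawing ordinal answers. 0 makes
#'   answers a deterministic function of the latent score.
#' @param confidence_probs Sampling probabilities of the three confidence
#'   labels.
#' @param max_retries Regeneration budget per matrix when enforcing the
#'   consistency gate.
#' @return A list of class `workshop_sim_config`.
#' @export
workshop_sim_config <- function(seed,
                                n_participants = 10L,
                                n_questions = 10L,
                                n_diseases = 25L,
                                set_sizes = c(hazard = 4L, transmission = 4L,
                                              outcome = 4L),
                                n_options = 4L,
                                judgment_noise = 0.15,
                                answer_noise = 1.0,
                                confidence_probs = c(high = 0.3, medium = 0.5,
                                                     low = 0.2),
                                max_retries = 200L) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is mandatory for reproducible simulation", call. = FALSE)
  }
  stopifnot(
    n_participants >= 1, n_questions >= 1, n_diseases >= 1, n_options >= 2,
    all(set_sizes >= 2), judgment_noise >= 0, answer_noise >= 0,
    max_retries >= 1
  )
  if (!all(criterion_set_kinds() %in% names(set_sizes))) {
    stop("set_sizes must name hazard, transmission and outcome", call. = FALSE)
  }
  confidence_probs <- confidence_probs / sum(confidence_probs)
  structure(
    list(seed = as.integer(seed), n_participants = as.integer(n_participants),
         n_questions = as.integer(n_questions),
         n_diseases = as.integer(n_diseases),
         set_sizes = set_sizes[criterion_set_kinds()],
         n_options = as.integer(n_options),
         judgment_noise = judgment_noise, answer_noise = answer_noise,
         confidence_probs = confidence_probs,
         max_retries = as.integer(max_retries)),
    class = "workshop_sim_config"
  )
}

# Nearest odd Saaty value in log space; ratios are multiplicative, so
# distance is measured on the log scale.
snap_to_scale <- function(x) {
  scale <- saaty_odd_scale()
  vapply(x, function(v) scale[which.min(abs(log(v) - log(scale)))], numeric(1))
}

# One near-consistent snapped matrix: consistent ratios from a Dirichlet
# weight draw, multiplicative noise, snap, mirror; retried until the
# consistency gate passes.
draw_matrix <- function(n, criteria, set_id, noise, max_retries) {
  for (try in seq_len(max_retries)) {
    w <- rgamma(n, shape = 2, rate = 1)
    w <- w / sum(w)
    a <- diag(n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        r <- (w[i] / w[j]) * exp(rnorm(1, 0, noise))
        r <- snap_to_scale(r)
        a[i, j] <- r
        a[j, i] <- 1 / r
      }
    }
    m <- pcmatrix(a, criteria, set_id = set_id)
    if (consistency(m)$acceptable) return(m)
  }
  stop("could not draw a CR < 0.10 matrix for set '", set_id, "' in ",
       max_retries, " attempts; reduce judgment_noise", call. = FALSE)
}

#' Simulate per-participant judgment matrices
#'
#' Each expert's matrix starts from a random true weight vector on the
#' simplex (normalized gamma draws), forms the consistent ratio matrix
#' `w_i/w_j`, perturbs each upper-triangle entry multiplicatively, snaps it
#' to the nearest odd Saaty value in log space, and mirrors reciprocals.
#' Matrices failing the `CR < 0.10` gate are redrawn (bounded retries), so
#' every returned matrix is workshop-admissible.
#'
#' @param config A [workshop_sim_config()].
#' @param criteria Named list of criterion-set data frames (defaults to
#'   sets generated to match `config$set_sizes`).
#' @return Nested list `result[[participant]][[set_id]]` of [pcmatrix()]
#'   objects.
#' @export
simulate_matrices <- function(config, criteria = sim_criteria(config)) {
  stopifnot(inherits(config, "workshop_sim_config"))
  set.seed(config$seed)
  participants <- sprintf("expert_%02d", seq_len(config$n_participants))
  out <- list()
  for (pid in participants) {
    out[[pid]] <- list()
    for (sid in names(criteria)) {
      out[[pid]][[sid]] <- draw_matrix(
        nrow(criteria[[sid]]), criteria[[sid]]$id, sid,
        config$judgment_noise, config$max_retries
      )
    }
  }
  out
}

# Criterion sets for simulation: the packaged vocabulary truncated to the
# requested sizes, padded with generic ids if a set is asked to be larger.
sim_criteria <- function(config) {
  vocab <- default_vocabulary()$criteria
  out <- list()
  for (sid in criterion_set_kinds()) {
    k <- config$set_sizes[[sid]]
    set <- vocab[[sid]]
    if (k > nrow(set)) {
      extra <- sprintf("%s_%02d", sid, seq(nrow(set) + 1, k))
      set <- rbind(set, data.frame(id = extra, label = extra))
    }
    out[[sid]] <- set[seq_len(k), , drop = FALSE]
  }
  out
}

#' Simulate ordinal answers driven by latent climate sensitivity
#'
#' Each disease receives a latent sensitivity `s_d ~ Uniform(0, 1)`. A
#' participant's answer to question `q` is a discretized logistic draw:
#' logit-scale noise is added to `logit(s_d)` and the resulting proportion
#' is scaled to the question's maximum value and rounded, giving an ordinal
#' distribution whose mean increases with `s_d`. Confidence labels are
#' sampled from `config$confidence_probs`.
#'
#' @param config A [workshop_sim_config()].
#' @param workshop_config A [workshop_config()] providing questions and
#'   diseases.
#' @return List with `responses` (long-format data frame) and `latent`
#'   (data frame of `disease_id`, `sensitivity`).
#' @export
simulate_responses <- function(config, workshop_config) {
  stopifnot(inherits(config, "workshop_sim_config"),
            inherits(workshop_config, "workshop_config"))
  set.seed(config$seed + 1L)
  participants <- workshop_config$participants
  diseases <- workshop_config$diseases$id
  questions <- workshop_config$questions

  s <- runif(length(diseases))
  names(s) <- diseases

  rows <- expand.grid(
    participant_id = participants, disease_id = diseases,
    question_id = vapply(questions, `[[`, character(1), "id"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  M <- vapply(questions, `[[`, numeric(1), "max_value")[rows$question_id]
  eta <- qlogis(pmin(pmax(s[rows$disease_id], 1e-12), 1 - 1e-12))
  if (config$answer_noise > 0) {
    eta <- eta + rnorm(nrow(rows), 0, config$answer_noise)
  }
  rows$answer_value <- as.integer(round(plogis(eta) * M))
  rows$confidence <- sample(names(config$confidence_probs), nrow(rows),
                            replace = TRUE, prob = config$confidence_probs)
  list(responses = rows,
       latent = data.frame(disease_id = diseases, sensitivity = unname(s),
                           stringsAsFactors = FALSE))
}

#' Simulate a complete workshop
#'
#' Generates criterion sets, questions (random criterion triples), a
#' disease list, per-participant near-consistent judgment matrices, and
#' latent-sensitivity-driven answers with confidence levels — everything
#' the weighting and scoring pipeline consumes.
#'
#' @param config A [workshop_sim_config()].
#' @return List of class `synthetic_workshop` with elements `config` (a
#'   [workshop_config()]), `matrices`, `judgments` (long data frame),
#'   `responses`, `latent`, and `sim_config`.
#' @export
#' @examples
#' ws <- simulate_workshop(workshop_sim_config(seed = 1, n_diseases = 5,
#'                                             n_questions = 3))
#' head(ws$responses)
simulate_workshop <- function(config) {
  stopifnot(inherits(config, "workshop_sim_config"))
  criteria <- sim_criteria(config)
  matrices <- simulate_matrices(config, criteria)

  set.seed(config$seed + 2L)
  questions <- lapply(seq_len(config$n_questions), function(i) {
    list(
      id = sprintf("q%02d", i),
      text = sprintf("Synthetic scoring question %d", i),
      hazard = sample(criteria$hazard$id, 1),
      transmission = sample(criteria$transmission$id, 1),
      outcome = sample(criteria$outcome$id, 1),
      options = data.frame(
        text = sprintf("option %d", seq_len(config$n_options)),
        value = seq_len(config$n_options) - 1L
      )
    )
  })
  wc <- workshop_config(
    criteria = criteria,
    questions = questions,
    diseases = sprintf("disease_%02d", seq_len(config$n_diseases)),
    participants = names(matrices)
  )

  judgments <- do.call(rbind, lapply(names(matrices), function(pid) {
    do.call(rbind, lapply(names(matrices[[pid]]), function(sid) {
      m <- matrices[[pid]][[sid]]
      idx <- which(upper.tri(m), arr.ind = TRUE)
      data.frame(
        participant_id = pid, set_id = sid,
        criterion_a = rownames(m)[idx[, 1]],
        criterion_b = colnames(m)[idx[, 2]],
        intensity = format_intensity(unclass(m)[idx]),
        linguistic_label = intensity_to_linguistic(unclass(m)[idx]),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(judgments) <- NULL

  resp <- simulate_responses(config, wc)
  structure(
    list(config = wc, matrices = matrices, judgments = judgments,
         responses = resp$responses, latent = resp$latent,
         sim_config = config),
    class = "synthetic_workshop"
  )
}

#' @export
print.synthetic_workshop <- function(x, ...) {
  cat("Synthetic workshop (seed ", x$sim_config$seed, ")\n", sep = "")
  print(x$config)
  invisible(x)
}

#' Write a synthetic workshop to a self-contained directory
#'
#' Emits `config.yaml`, `judgments.csv`, `responses.csv` and
#' `latent_sensitivity.csv` in the exact dialects the pipeline readers
#' consume.
#'
#' @param workshop A [simulate_workshop()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_workshop <- function(workshop, dir) {
  stopifnot(inherits(workshop, "synthetic_workshop"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(workshop$config, file.path(dir, "config.yaml"))
  utils::write.csv(workshop$judgments, file.path(dir, "judgments.csv"),
                   row.names = FALSE)
  write_responses(workshop$responses, file.path(dir, "responses.csv"))
  utils::write.csv(workshop$latent, file.path(dir, "latent_sensitivity.csv"),
                   row.names = FALSE)
  invisible(dir)
}
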