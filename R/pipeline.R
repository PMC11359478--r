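#' Build a run manifest
#'
#' Every batch step records what produced its outputs: input paths with
#' content digests, package version, seed and the options in effect. Output
#' files written by the pipeline reference the manifest file by name (JSON
#' outputs in a `manifest` field, CSV outputs in a leading `#` comment).
#'
#' @param inputs Character vector of input file paths (digested if they
#'   exist).
#' @param options Named list of options in effect.
#' @param seed Optional integer seed.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(inputs = character(), options = list(), seed = NULL) {
  digests <- lapply(inputs, function(p) {
    list(path = p,
         md5 = if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_)
  })
  structure(
    list(package = "zoonoprior",
         version = as.character(utils::packageVersion("zoonoprior")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed, options = options, inputs = digests,
         outputs = character()),
    class = "run_manifest"
  )
}

write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

as_config <- function(config) {
  if (inherits(config, "workshop_config")) config else load_config(config)
}

write_report_csv <- function(df, path, manifest_file) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# manifest:", manifest_file), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Pipeline step: validate inputs
#'
#' Loads and cross-validates a configuration file and, optionally,
#' judgment and response files against it, reporting what was checked.
#'
#' @param config Path to a configuration file (or a `workshop_config`).
#' @param judgments,responses Optional paths to the long-format CSV files.
#' @return The validated `workshop_config`, invisibly.
#' @export
run_validate <- function(config, judgments = NULL, responses = NULL) {
  cfg <- as_config(config)
  print(cfg)
  if (!is.null(judgments)) {
    j <- if (is.character(judgments)) read_judgments(judgments) else judgments
    matrices_from_judgments(j, cfg)
    cat(sprintf("judgments: %d rows, %d participant(s) - OK\n",
                nrow(j), length(unique(j$participant_id))))
  }
  if (!is.null(responses)) {
    r <- if (is.character(responses)) read_responses(responses) else responses
    qw <- data.frame(
      question_id = vapply(cfg$questions, `[[`, character(1), "id"),
      w_q = 1,
      max_value = vapply(cfg$questions, `[[`, numeric(1), "max_value")
    )
    disease_scores(r, qw, confidence = cfg$confidence, missing = "zero")
    cat(sprintf("responses: %d rows - OK\n", nrow(r)))
  }
  invisible(cfg)
}

#' Pipeline step: criteria weighting
#'
#' Builds every participant's pairwise-comparison matrices from a judgment
#' table, enforces the consistency gate, aggregates a group matrix per
#' criterion set by element-wise geometric means, and produces a
#' per-criterion weight report (crisp weight, fuzzy triple, defuzzified and
#' normalized defuzzified weight) for each participant and for the group.
#'
#' Matrices with `CR >= 0.10` are refused by default, mirroring the
#' elicitation interface which only lets a participant save an acceptably
#' consistent matrix; set `gate = FALSE` to keep them with a warning.
#'
#' @param judgments Path to a judgments CSV or a judgments data frame.
#' @param config Path to a configuration file or a `workshop_config`.
#' @param out_dir Optional output directory for the report files.
#' @param method Crisp weighting method, `"gm"` (default) or `"eigen"`.
#' @param gate Refuse inconsistent participant matrices?
#' @return List with `group` (per-set [weight_report()]s), `participants`
#'   (nested reports), `consistency` (long data frame), and `manifest`.
#' @export
run_weights <- function(judgments, config, out_dir = NULL,
                        method = c("gm", "eigen"), gate = TRUE) {
  method <- match.arg(method)
  cfg <- as_config(config)
  jpath <- if (is.character(judgments)) judgments else character()
  j <- if (is.character(judgments)) read_judgments(judgments) else judgments
  matrices <- matrices_from_judgments(j, cfg)

  cons_rows <- list()
  reports <- list()
  for (pid in names(matrices)) {
    reports[[pid]] <- list()
    for (sid in names(matrices[[pid]])) {
      m <- matrices[[pid]][[sid]]
      cs <- consistency(m)
      if (!cs$acceptable) {
        msg <- sprintf(
          "participant '%s', set '%s': consistency ratio %.4f >= 0.10; %s",
          pid, sid, cs$cr,
          "judgments must be revised before the matrix can be saved")
        if (gate) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      }
      reports[[pid]][[sid]] <- weight_report(m, method = method)
      cons_rows[[length(cons_rows) + 1L]] <- data.frame(
        participant_id = pid, set_id = sid, lambda_max = cs$lambda_max,
        ci = cs$ci, ri = cs$ri, cr = cs$cr, acceptable = cs$acceptable)
    }
  }

  set_ids <- unique(j$set_id)
  group <- list()
  for (sid in set_ids) {
    mats <- lapply(matrices, `[[`, sid)
    mats <- mats[!vapply(mats, is.null, logical(1))]
    gm <- aggregate_group(mats)
    group[[sid]] <- weight_report(gm, method = method,
                                  fuzzy_matrix = aggregate_group_fuzzy(mats))
    gc <- attr(group[[sid]], "consistency")
    cons_rows[[length(cons_rows) + 1L]] <- data.frame(
      participant_id = "GROUP", set_id = sid, lambda_max = gc$lambda_max,
      ci = gc$ci, ri = gc$ri, cr = gc$cr, acceptable = gc$acceptable)
  }
  cons <- do.call(rbind, cons_rows)

  manifest <- run_manifest(
    inputs = jpath,
    options = list(step = "weights", method = method, gate = gate)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    mf <- "run_manifest.json"
    for (sid in names(group)) {
      write_report_csv(as.data.frame(group[[sid]]),
                       file.path(out_dir, paste0("weights_", sid, ".csv")), mf)
    }
    pall <- do.call(rbind, lapply(names(reports), function(pid) {
      do.call(rbind, lapply(names(reports[[pid]]), function(sid) {
        cbind(participant_id = pid, set_id = sid,
              as.data.frame(reports[[pid]][[sid]]))
      }))
    }))
    write_report_csv(pall, file.path(out_dir, "weights_participants.csv"), mf)
    write_report_csv(cons, file.path(out_dir, "consistency.csv"), mf)
    jsonlite::write_json(
      list(manifest = mf,
           group = lapply(group, as.data.frame),
           consistency = cons),
      file.path(out_dir, "weights.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    manifest$outputs <- c(paste0("weights_", names(group), ".csv"),
                          "weights_participants.csv", "consistency.csv",
                          "weights.json")
    write_manifest(manifest, out_dir)
  }
  list(group = group, participants = reports, consistency = cons,
       manifest = manifest)
}

# Per-set named weight vectors (normalized defuzzified) from group reports.
set_weights_from_reports <- function(group) {
  lapply(group, function(rep) {
    setNames(rep$normalized_defuzzified, rep$criterion)
  })
}

#' Pipeline step: score and rank diseases
#'
#' Derives question weights by averaging the group normalized-defuzzified
#' weights of each question's three criteria, scores every response with
#' its confidence bounds, aggregates per disease, normalizes, and ranks.
#'
#' @param responses Path to a responses CSV or a responses data frame.
#' @param weights Result of [run_weights()], or its `group` element, or a
#'   path to a `weights.json` written by it.
#' @param config Path to a configuration file or a `workshop_config`.
#' @param out_dir Optional output directory.
#' @param missing Passed to [disease_scores()].
#' @return List with `ranked` (priority list), `question_weights`,
#'   `plot_data`, and `manifest`.
#' @export
run_rank <- function(responses, weights, config, out_dir = NULL,
                     missing = "error") {
  cfg <- as_config(config)
  rpath <- if (is.character(responses)) responses else character()
  resp <- if (is.character(responses)) read_responses(responses) else responses
  if (is.character(weights)) {
    wj <- jsonlite::read_json(weights, simplifyVector = TRUE)
    group <- wj$group
  } else if (!is.null(weights$group)) {
    group <- weights$group
  } else {
    group <- weights
  }
  sw <- set_weights_from_reports(group)
  qw <- question_weights(cfg, sw)
  scores <- disease_scores(resp, qw, confidence = cfg$confidence,
                           missing = missing)
  ranked <- rank_diseases(scores)
  plot_data <- priority_plot_data(ranked)

  manifest <- run_manifest(
    inputs = c(rpath, if (is.character(weights)) weights else character()),
    options = list(step = "rank", missing = missing,
                   normalization_constant = attr(scores,
                                                 "normalization_constant"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    mf <- "run_manifest.json"
    disp <- as.data.frame(ranked)
    for (col in c("z_norm", "z_low_norm", "z_high_norm")) {
      disp[[paste0(col, "_2dp")]] <- round_half_up(disp[[col]], 2)
    }
    write_report_csv(disp, file.path(out_dir, "priority_list.csv"), mf)
    write_report_csv(plot_data, file.path(out_dir, "plot_data.csv"), mf)
    jsonlite::write_json(
      list(manifest = mf, question_weights = qw,
           priority_list = as.data.frame(ranked)),
      file.path(out_dir, "priority_list.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    manifest$outputs <- c("priority_list.csv", "plot_data.csv",
                          "priority_list.json")
    write_manifest(manifest, out_dir)
  }
  list(ranked = ranked, question_weights = qw, plot_data = plot_data,
       manifest = manifest)
}

#' Pipeline step: simulate a workshop to disk
#'
#' @param seed Integer seed.
#' @param out_dir Output directory for the workshop files.
#' @param ... Further arguments to [workshop_sim_config()].
#' @return The `synthetic_workshop`, invisibly.
#' @export
run_simulate <- function(seed, out_dir, ...) {
  cfg <- workshop_sim_config(seed = seed, ...)
  ws <- simulate_workshop(cfg)
  write_workshop(ws, out_dir)
  manifest <- run_manifest(options = c(list(step = "simulate"),
                                       cfg[setdiff(names(cfg), "seed")]),
                           seed = cfg$seed)
  manifest$outputs <- c("config.yaml", "judgments.csv", "responses.csv",
                        "latent_sensitivity.csv")
  write_manifest(manifest, out_dir)
  invisible(ws)
}
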