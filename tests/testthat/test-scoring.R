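test_that("question weight is the mean of its three criterion weights", {
  expect_equal(question_weight(0.4, 0.3, 0.2), 0.3)
  expect_equal(question_weight(0.5, 0.5, 0.5), 0.5)
  expect_equal(question_weight(0.65, 0.19, 0.27), 0.37)
  expect_error(question_weight(-0.1, 0.2, 0.3), "non-negative")
})

test_that("the worked single-answer example scores 0.25 with range 0.12-0.37", {
  z <- question_score(0.37, 2, 3)
  expect_equal(z, 0.37 * 2 / 3, tolerance = 1e-12)
  expect_equal(round_half_up(z, 2), 0.25)
  b <- score_bounds(0.37, 2, 1, 3)
  expect_equal(unname(b), c(0.37 * 1 / 3, 0.37), tolerance = 1e-12)
  expect_equal(round_half_up(unname(b), 2), c(0.12, 0.37))
})

test_that("scores span [0, w_q] and bounds clamp to the answer range", {
  expect_equal(question_score(0.4, 0, 3), 0)
  expect_equal(question_score(0.4, 3, 3), 0.4)
  expect_equal(unname(score_bounds(0.4, 2, 0, 3)),
               rep(question_score(0.4, 2, 3), 2))
  # V + C beyond M clamps to w_q, V - C below 0 clamps to 0
  expect_equal(unname(score_bounds(0.4, 3, 1, 3)), c(0.4 * 2 / 3, 0.4))
  expect_equal(unname(score_bounds(0.4, 0, 2, 3)), c(0, 0.4 * 2 / 3))
  expect_error(question_score(0.4, 4, 3), "\\[0, M\\]")
  expect_error(question_score(0.4, 2, 0), "M must be")
  expect_error(score_bounds(0.4, 2, -1, 3), "non-negative")
})

test_that("disease scores sum question scores over participants and questions", {
  # 2 participants x 2 questions, every per-question score 0.25
  w <- data.frame(question_id = c("q1", "q2"), w_q = 0.5, max_value = 2L)
  resp <- expand.grid(participant_id = c("p1", "p2"), disease_id = "d1",
                      question_id = c("q1", "q2"), stringsAsFactors = FALSE)
  resp$answer_value <- 1L
  resp$confidence <- "high"
  s <- disease_scores(resp, w)
  expect_equal(s$z, 1.0)
  expect_equal(s$z_norm, 0.5) # half the attainable maximum
  expect_equal(s$z_low, s$z)  # high confidence: zero half-width
  expect_equal(s$z_high, s$z)
})

test_that("vectorized aggregation matches the brute-force double loop", {
  conf <- default_confidence()
  set.seed(99)
  for (rep in 1:5) {
    nq <- sample(2:5, 1)
    w <- data.frame(question_id = paste0("q", seq_len(nq)),
                    w_q = runif(nq, 0.05, 0.5),
                    max_value = sample(2:4, nq, replace = TRUE))
    resp <- expand.grid(participant_id = paste0("p", 1:3),
                        disease_id = paste0("d", 1:4),
                        question_id = w$question_id,
                        stringsAsFactors = FALSE)
    resp$answer_value <- vapply(w$max_value[match(resp$question_id,
                                                  w$question_id)],
                                function(m) sample(0:m, 1), integer(1))
    resp$confidence <- sample(names(conf), nrow(resp), replace = TRUE)
    got <- disease_scores(resp, w, confidence = conf)
    want <- oracle_disease_scores(resp, w, as.list(conf))
    for (col in c("z", "z_low", "z_high", "z_norm", "z_low_norm",
                  "z_high_norm")) {
      expect_equal(got[[col]], want[[col]], tolerance = 1e-12)
    }
    expect_true(all(got$z_low <= got$z + 1e-12 & got$z <= got$z_high + 1e-12))
    expect_true(all(got$z_norm >= 0 & got$z_norm <= 1))
  }
})

test_that("normalized scores hit 1 and 0 exactly at the answer extremes", {
  w <- data.frame(question_id = c("q1", "q2"), w_q = c(0.37, 0.21),
                  max_value = c(3L, 2L))
  resp <- expand.grid(participant_id = paste0("p", 1:3),
                      disease_id = c("dmax", "dmin"),
                      question_id = w$question_id, stringsAsFactors = FALSE)
  resp$answer_value <- ifelse(
    resp$disease_id == "dmax",
    w$max_value[match(resp$question_id, w$question_id)], 0L)
  resp$confidence <- "medium"
  s <- disease_scores(resp, w)
  expect_equal(s$z_norm[s$disease_id == "dmax"], 1, tolerance = 1e-12)
  expect_equal(s$z_norm[s$disease_id == "dmin"], 0)
})

test_that("raising any single answer never lowers a disease score", {
  w <- data.frame(question_id = paste0("q", 1:3), w_q = c(0.2, 0.3, 0.1),
                  max_value = 3L)
  resp <- expand.grid(participant_id = c("p1", "p2"), disease_id = "d1",
                      question_id = w$question_id, stringsAsFactors = FALSE)
  resp$answer_value <- 1L
  resp$confidence <- "medium"
  base <- disease_scores(resp, w)
  for (k in seq_len(nrow(resp))) {
    bumped <- resp
    bumped$answer_value[k] <- bumped$answer_value[k] + 1L
    s <- disease_scores(bumped, w)
    expect_gte(s$z, base$z)
    expect_gte(s$z_norm, base$z_norm)
  }
})

test_that("duplicate, empty and incomplete response sets follow the rules", {
  w <- data.frame(question_id = "q1", w_q = 0.5, max_value = 2L)
  resp <- data.frame(participant_id = "p1", disease_id = "d1",
                     question_id = "q1", answer_value = 1L,
                     confidence = "medium")
  expect_error(disease_scores(rbind(resp, resp), w), "duplicate response")
  expect_error(disease_scores(resp[0, ], w), "at least one participant")

  two <- rbind(resp, within(resp, disease_id <- "d2"))
  expect_error(disease_scores(two[1, , drop = FALSE],
                              rbind(w, data.frame(question_id = "q2",
                                                  w_q = 0.5, max_value = 2L))),
               "missing response")
  imputed <- disease_scores(
    two, rbind(w, data.frame(question_id = "q2", w_q = 0.5, max_value = 2L)),
    missing = "zero")
  expect_equal(nrow(attr(imputed, "imputed")), 2L)
  expect_error(disease_scores(two, w[0, ]), "unweighted question")
})

test_that("ranking is deterministic with documented tie-breaks", {
  s <- data.frame(
    disease_id = c("b_mid", "a_mid", "top"),
    z = c(0.5, 0.5, 0.8), z_low = c(0.4, 0.4, 0.7),
    z_high = c(0.6, 0.6, 0.9),
    z_norm = c(0.5, 0.5, 0.8), z_low_norm = c(0.4, 0.4, 0.7),
    z_high_norm = c(0.6, 0.6, 0.9),
    n_participants = 1L, n_questions = 1L
  )
  r <- rank_diseases(s)
  expect_equal(r$rank, 1:3)
  expect_equal(r$disease_id, c("top", "a_mid", "b_mid"))
  # permutation invariance
  r2 <- rank_diseases(s[c(3, 1, 2), ])
  expect_equal(r2$disease_id, r$disease_id)
  # lower bound breaks score ties before the lexicographic fallback
  s$z_low_norm[1] <- 0.45
  expect_equal(rank_diseases(s)$disease_id, c("top", "b_mid", "a_mid"))
  expect_equal(rank_diseases(s[2, ])$rank, 1L)
})

test_that("plot data is long format with one row per disease and estimate", {
  w <- data.frame(question_id = "q1", w_q = 0.4, max_value = 2L)
  resp <- data.frame(participant_id = "p1", disease_id = c("d1", "d2"),
                     question_id = "q1", answer_value = c(2L, 1L),
                     confidence = "medium")
  long <- priority_plot_data(rank_diseases(disease_scores(resp, w)))
  expect_equal(nrow(long), 6L)
  expect_setequal(unique(long$estimate), c("initial", "lower", "upper"))
  expect_equal(long$value[long$disease_id == "d1" &
                            long$estimate == "initial"], 1)
})
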