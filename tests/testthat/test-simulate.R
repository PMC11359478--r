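test_that("simulation is fully deterministic given the seed", {
  cfg <- workshop_sim_config(seed = 123, n_participants = 3, n_diseases = 6,
                             n_questions = 4)
  a <- simulate_workshop(cfg)
  b <- simulate_workshop(cfg)
  expect_identical(a$judgments, b$judgments)
  expect_identical(a$responses, b$responses)
  expect_identical(a$latent, b$latent)

  c2 <- simulate_workshop(workshop_sim_config(seed = 124, n_participants = 3,
                                              n_diseases = 6, n_questions = 4))
  expect_false(identical(a$judgments, c2$judgments))
  expect_error(workshop_sim_config(), "seed is mandatory")
})

test_that("written workshop directories are byte-stable under the seed", {
  cfg <- workshop_sim_config(seed = 55, n_participants = 3, n_diseases = 5,
                             n_questions = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_workshop(simulate_workshop(cfg), d1)
  write_workshop(simulate_workshop(cfg), d2)
  for (f in c("config.yaml", "judgments.csv", "responses.csv",
              "latent_sensitivity.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("generated matrices are on the odd scale and pass the gate", {
  mats <- simulate_matrices(workshop_sim_config(seed = 3, n_participants = 4,
                                                judgment_noise = 0))
  scale <- saaty_odd_scale()
  for (pm in mats) {
    for (m in pm) {
      expect_true(all(vapply(as.vector(unclass(m)), function(v) {
        any(abs(v - scale) < 1e-9)
      }, logical(1))))
      expect_true(consistency(m)$acceptable)
    }
  }
  # and under moderate noise the gate still holds by construction
  mats <- simulate_matrices(workshop_sim_config(seed = 4, n_participants = 4,
                                                judgment_noise = 0.3))
  crs <- unlist(lapply(mats, function(pm) {
    vapply(pm, function(m) consistency(m)$cr, numeric(1))
  }))
  expect_true(all(crs < 0.10))
})

test_that("snap-to-scale picks the log-nearest odd intensity", {
  snap <- zoonoprior:::snap_to_scale
  expect_equal(snap(c(1, 3, 9)), c(1, 3, 9))
  expect_equal(snap(2.9), 3)
  expect_equal(snap(1 / 2.9), 1 / 3)
  # log midpoint of 1 and 3 is sqrt(3); just below snaps down
  expect_equal(snap(sqrt(3) * 0.99), 1)
  expect_equal(snap(sqrt(3) * 1.01), 3)
})

test_that("the retry budget errors out under extreme judgment noise", {
  expect_error(
    simulate_matrices(workshop_sim_config(seed = 2, n_participants = 1,
                                          judgment_noise = 3,
                                          max_retries = 2)),
    "reduce judgment_noise"
  )
})

test_that("generated artifacts pass the loaders and validators", {
  ws <- simulate_workshop(workshop_sim_config(seed = 21, n_participants = 3,
                                              n_diseases = 5, n_questions = 4))
  dir <- withr::local_tempdir()
  write_workshop(ws, dir)
  cfg <- load_config(file.path(dir, "config.yaml"))
  j <- read_judgments(file.path(dir, "judgments.csv"))
  mats <- matrices_from_judgments(j, cfg)
  # round-tripped matrices equal the generator's matrices
  for (pid in names(mats)) {
    for (sid in names(mats[[pid]])) {
      expect_equal(unclass(mats[[pid]][[sid]]),
                   unclass(ws$matrices[[pid]][[sid]]), tolerance = 1e-12)
    }
  }
  r <- read_responses(file.path(dir, "responses.csv"))
  expect_true(all(r$confidence %in% c("low", "medium", "high")))
  qmax <- vapply(cfg$questions, `[[`, numeric(1), "max_value")
  expect_true(all(r$answer_value >= 0 & r$answer_value <=
                    qmax[r$question_id]))
})

test_that("answers are a monotone function of latent sensitivity at zero noise", {
  cfg <- workshop_sim_config(seed = 31, n_participants = 4, n_diseases = 12,
                             n_questions = 5, answer_noise = 0)
  ws <- simulate_workshop(cfg)
  qw <- data.frame(
    question_id = vapply(ws$config$questions, `[[`, character(1), "id"),
    w_q = 0.2,
    max_value = vapply(ws$config$questions, `[[`, numeric(1), "max_value")
  )
  s <- disease_scores(ws$responses, qw)
  z <- s$z_norm[match(ws$latent$disease_id, s$disease_id)]
  sens <- ws$latent$sensitivity
  # every more-sensitive disease scores at least as high (discretization ties)
  ord <- order(sens)
  expect_true(all(diff(z[ord]) >= -1e-12))
})

test_that("rank recovery: latent sensitivity and scores correlate strongly", {
  recovery_rho <- function(seed, ...) {
    ws <- simulate_workshop(workshop_sim_config(seed = seed, ...))
    r <- run_rank(ws$responses, run_weights(ws$judgments, ws$config),
                  ws$config)
    z <- r$ranked$z_norm[match(ws$latent$disease_id, r$ranked$disease_id)]
    cor(ws$latent$sensitivity, z, method = "spearman")
  }
  # default scenario: 10 experts, 10 questions, 25 diseases, moderate noise
  expect_gt(recovery_rho(41), 0.8)
  # recovery tightens toward 1 as the panel grows
  seeds <- 401:403
  small <- mean(vapply(seeds, recovery_rho, numeric(1), n_participants = 2))
  large <- mean(vapply(seeds, recovery_rho, numeric(1), n_participants = 15))
  expect_gt(small, 0.5)
  expect_gt(large, small)
})
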