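# Shared fixtures and independent oracles used across the test files.

# The packaged 4-hazard example matrix, built directly (independent of the
# CSV reader used by example_hazard_matrix()).
fixture_matrix <- function() {
  a <- diag(4)
  put <- function(i, j, v) {
    a[i, j] <<- v
    a[j, i] <<- 1 / v
  }
  put(2, 1, 7) # flooding vs warming
  put(3, 1, 3) # drought vs warming
  put(1, 4, 3) # warming vs sea level rise
  put(2, 3, 5) # flooding vs drought
  put(2, 4, 7) # flooding vs sea level rise
  put(3, 4, 3) # drought vs sea level rise
  pcmatrix(a, c("warming", "flooding", "drought", "sea_level_rise"),
           set_id = "hazard")
}

# Brute-force row-geometric-mean weights, written independently of
# geometric_mean_weights() (explicit products, no logs).
oracle_gm_weights <- function(a) {
  n <- nrow(a)
  gm <- apply(unclass(a), 1, function(r) prod(r)^(1 / n))
  gm / sum(gm)
}

# Brute-force double-loop aggregation applying the score equations one
# response at a time; the vectorized disease_scores() must match this.
oracle_disease_scores <- function(responses, weights, conf_map) {
  diseases <- sort(unique(responses$disease_id))
  out <- data.frame(disease_id = diseases, z = 0, z_low = 0, z_high = 0,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(responses))) {
    r <- responses[k, ]
    wrow <- weights[weights$question_id == r$question_id, ]
    C <- conf_map[[as.character(r$confidence)]]
    i <- match(r$disease_id, out$disease_id)
    out$z[i] <- out$z[i] + wrow$w_q * r$answer_value / wrow$max_value
    out$z_low[i] <- out$z_low[i] +
      wrow$w_q * max(r$answer_value - C, 0) / wrow$max_value
    out$z_high[i] <- out$z_high[i] +
      wrow$w_q * min(r$answer_value + C, wrow$max_value) / wrow$max_value
  }
  denom <- length(unique(responses$participant_id)) * sum(weights$w_q)
  out$z_norm <- out$z / denom
  out$z_low_norm <- out$z_low / denom
  out$z_high_norm <- out$z_high / denom
  out
}

# A consistent matrix a_ij = w_i / w_j from a positive weight vector.
consistent_matrix <- function(w, ids = paste0("c", seq_along(w))) {
  pcmatrix(outer(w, w, "/"), ids)
}

# Minimal single-question configuration whose question weight is exactly
# the mean of the three given criterion weights.
single_question_config <- function(n_options = 4) {
  workshop_config(
    criteria = list(
      hazard = data.frame(id = c("h1", "h2")),
      transmission = data.frame(id = c("t1", "t2")),
      outcome = data.frame(id = c("o1", "o2"))
    ),
    questions = list(list(
      id = "q1", hazard = "h1", transmission = "t1", outcome = "o1",
      options = data.frame(text = letters[seq_len(n_options)],
                           value = seq_len(n_options) - 1L)
    )),
    diseases = "d1",
    participants = "p1"
  )
}
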