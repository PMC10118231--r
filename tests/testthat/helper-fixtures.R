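# Small in-code fixtures shared across test files.

# a 2-exercise, 4-claim key
tiny_claim_key <- function() {
  data.frame(
    exercise_id = c("ex1", "ex1", "ex2", "ex2"),
    claim_id = c("a", "b", "c", "d"),
    truth = c(TRUE, FALSE, TRUE, FALSE)
  )
}

# three participants with known scoring outcomes against tiny_claim_key()
tiny_responses <- function() {
  data.frame(
    participant_id = rep(c("p1", "p2", "p3"), each = 4),
    exercise_id = rep(c("ex1", "ex1", "ex2", "ex2"), 3),
    claim_id = rep(c("a", "b", "c", "d"), 3),
    vas_value = c(
      100, -100, 100, -100,   # p1: all correct, maximal confidence
      -50, 50, -50, 50,       # p2: all incorrect at confidence 50
      80, -90, 0, NA          # p3: two correct, one unknown, one missing
    )
  )
}

# deterministic small scored table for metacognition tests
scored_fixture <- function() {
  score_responses(tiny_responses(), tiny_claim_key())
}

# small simulation config for fast tests
small_sim_config <- function(...) {
  simulation_config(
    n_per_profile = c(student = 30, resident = 10, physician = 10),
    ...
  )
}
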