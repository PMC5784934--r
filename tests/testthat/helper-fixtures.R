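# Shared fixtures built in code.

# Response table for one participant cell from an events x questions 0/1
# matrix with columns named "<cue>.<target>".
rt_from_qmat <- function(qmat, participant = "p001", condition = "neutral",
                         order = "simultaneous") {
  qs <- strsplit(colnames(qmat), ".", fixed = TRUE)
  rows <- lapply(seq_along(qs), function(k) {
    tibble::tibble(
      participant_id = participant,
      condition = condition,
      encoding_order = order,
      event_id = rownames(qmat) %||% sprintf("ev%03d", seq_len(nrow(qmat))),
      cue_category = qs[[k]][1],
      target_category = qs[[k]][2],
      correct = as.integer(qmat[, k])
    )
  })
  dplyr::bind_rows(rows)
}

all_question_names <- function() {
  cats <- c("location", "person", "object")
  g <- subset(
    expand.grid(cue = cats, target = cats, stringsAsFactors = FALSE),
    cue != target
  )
  paste(g$cue, g$target, sep = ".")
}

random_rt <- function(n_events = 12, p = 0.6, seed = 1,
                      participant = "p001") {
  set.seed(seed)
  q <- matrix(rbinom(n_events * 6, 1, p), nrow = n_events)
  colnames(q) <- all_question_names()
  rt_from_qmat(q, participant = participant)
}

# The full study-scale simulation (26 networks, 36 neutral + 36 negative
# events, default parameters) is shared by several acceptance checks; build
# it once, lazily, under a seed fixed in advance.
acceptance_sim_env <- new.env()
acceptance_sim <- function() {
  if (is.null(acceptance_sim_env$rt)) {
    params <- memcoh::model_params()
    es <- memcoh::make_events(36, 36)
    enc <- memcoh::make_encoding_schedule(
      es, "pairs", memcoh::assign_orders(es),
      seed = 1
    )
    ts <- memcoh::make_test_schedule(es, seed = 2)
    acceptance_sim_env$rt <- memcoh::run_simulation(
      es, enc, ts, params,
      seed = 1
    )
    acceptance_sim_env$report <- memcoh::dependency_report(
      acceptance_sim_env$rt,
      P_G = 0
    )
  }
  list(rt = acceptance_sim_env$rt, report = acceptance_sim_env$report)
}
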