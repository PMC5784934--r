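# Independent brute-force oracles used to cross-check the network code.

# Scalar-loop fixed-point iteration of the threshold-linear dynamics:
# r_i <- clip(I_i + sum_j w_ij r_j - theta_T, 0, r_max), synchronous updates.
# No matrix algebra, no shared code with the package implementation.
oracle_settle <- function(w, I_ext, theta_T = 5, r_max = 10,
                          max_steps = 1000) {
  n <- length(I_ext)
  r <- rep(0, n)
  for (step in seq_len(max_steps)) {
    r_new <- rep(0, n)
    for (i in seq_len(n)) {
      tot <- I_ext[i]
      for (j in seq_len(n)) {
        tot <- tot + w[i, j] * r[j]
      }
      x <- tot - theta_T
      if (x < 0) x <- 0
      if (x > r_max) x <- r_max
      r_new[i] <- x
    }
    if (max(abs(r_new - r)) < 1e-13) {
      return(r_new)
    }
    r <- r_new
  }
  r
}

# Whether a cue -> target question is answered correctly given the three
# within-event pair weights, by brute-force settling of the 3-neuron
# subnetwork (cue driven at 15 nA, target partially driven at 5 nA, third
# element undriven; foils have no weights and stay silent).
oracle_question_correct <- function(w3, cue, target, theta_ret = 5) {
  I <- c(location = 0, person = 0, object = 0)
  I[target] <- 5
  I[cue] <- 15
  r <- oracle_settle(w3, I)
  names(r) <- names(I)
  r[[target]] >= theta_ret
}

# Enumerate the eight link-presence configurations of an event and return the
# exact per-question accuracies plus the distribution of the event's mean
# accuracy. Link strengths follow from the protocol, derived by hand:
#   neutral: every encoded pair saturates at 1.0;
#   negative person_last (pairs L-O, P-L, O-P): the opening neutral pair
#     encodes at 1.0 (no negative element active yet), both person pairs at
#     0.6 (the negative person is on screen);
#   negative person_first (pairs O-P, P-L, L-O): both person pairs at 0.6; the
#     closing neutral pair encodes at 1.0 only when neither person pair was
#     encoded (otherwise the person is reactivated through a learned
#     association and modulates the trial to 0.6).
oracle_enumerated_accuracy <- function(condition, order, p_enc = 0.65) {
  cats <- c("location", "person", "object")
  pairs <- if (order == "person_last") {
    list(
      c("location", "object"), c("person", "location"),
      c("object", "person")
    )
  } else {
    list(
      c("object", "person"), c("person", "location"),
      c("location", "object")
    )
  }
  questions <- subset(
    expand.grid(
      cue = cats, target = cats,
      stringsAsFactors = FALSE
    ),
    cue != target
  )
  acc <- rep(0, nrow(questions))
  cfg_probs <- numeric(0)
  cfg_means <- numeric(0)
  for (e1 in 0:1) {
    for (e2 in 0:1) {
      for (e3 in 0:1) {
        enc <- c(e1, e2, e3)
        w3 <- matrix(0, 3, 3, dimnames = list(cats, cats))
        for (t in 1:3) {
          if (enc[t] == 0) next
          strength <- if (condition == "neutral") {
            1
          } else if ("person" %in% pairs[[t]]) {
            0.6
          } else if (order == "person_last") {
            1 # neutral pair first: person silent, unmodulated
          } else {
            if (e1 == 0 && e2 == 0) 1 else 0.6
          }
          w3[pairs[[t]][1], pairs[[t]][2]] <- strength
          w3[pairs[[t]][2], pairs[[t]][1]] <- strength
        }
        ok <- vapply(seq_len(nrow(questions)), function(qi) {
          oracle_question_correct(w3, questions$cue[qi], questions$target[qi])
        }, logical(1))
        pr <- prod(ifelse(enc == 1, p_enc, 1 - p_enc))
        acc <- acc + pr * ok
        cfg_probs <- c(cfg_probs, pr)
        cfg_means <- c(cfg_means, mean(ok))
      }
    }
  }
  mu <- sum(cfg_probs * cfg_means)
  list(
    questions = questions,
    question_accuracy = acc,
    mean_accuracy = mu,
    event_mean_var = sum(cfg_probs * cfg_means^2) - mu^2
  )
}
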