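#' Run one encoding trial
#'
#' Presented elements receive the drive current `I_drive`; the network settles
#' under the current weights; the modulation factor is read off the settled
#' rates (a negative element counts whether presented or incidentally
#' reactivated through already-learned associations); a single learning-rate
#' draw (`k_neut` with probability `p_enc`, else 0) is shared by both
#' directions of the pair; the Hebbian update is applied; rates reset to zero.
#'
#' Uses the ambient RNG stream for the encoding draw - seed control lives in
#' [run_simulation()].
#'
#' @param state A `network_state`.
#' @param presented_ids Element ids presented on this trial.
#' @param params A [model_params()] object.
#' @return The updated `network_state`.
#' @export
encode_trial <- function(state, presented_ids, params = model_params()) {
  idx <- match(presented_ids, state$neuron_ids)
  if (anyNA(idx)) {
    stop(
      "unknown element(s): ",
      paste(presented_ids[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  I_ext <- numeric(length(state$neuron_ids))
  I_ext[idx] <- params$I_drive
  r <- settle(state$weights, I_ext, params)
  m <- modulation_factor(r, state$negative_ids, params)
  k <- if (stats::runif(1) < params$p_enc) params$k_neut else 0
  state$weights <- hebbian_update(state$weights, r, k, m, params)
  state$rates[] <- 0
  state
}

#' Run one forced-choice retrieval trial
#'
#' The cue neuron receives `I_drive`, the six choice neurons receive
#' `I_choice`, all other neurons no external input; learning is off (weights
#' frozen). After settling, the trial is correct iff the correct target's rate
#' reaches `theta_ret` and is strictly the maximum among the six choices (the
#' strict-argmax clause never binds under default weights, where foils stay
#' silent, but guards degenerate parameterisations). Rates reset afterwards.
#'
#' @param state A `network_state`.
#' @param cue_id,target_id Element ids of cue and correct target.
#' @param choice_ids Element ids of the six options (must include the target).
#' @param params A [model_params()] object.
#' @return List with `correct` (logical) and `choice_rates` (named rates of
#'   the six options, Hz).
#' @export
retrieve_trial <- function(state, cue_id, target_id, choice_ids,
                           params = model_params()) {
  idx_cue <- match(cue_id, state$neuron_ids)
  idx_choices <- match(choice_ids, state$neuron_ids)
  if (is.na(idx_cue) || anyNA(idx_choices)) {
    stop("unknown element id in retrieval trial", call. = FALSE)
  }
  if (!target_id %in% choice_ids) {
    stop("`choice_ids` must contain the correct target", call. = FALSE)
  }
  I_ext <- numeric(length(state$neuron_ids))
  I_ext[idx_choices] <- params$I_choice
  I_ext[idx_cue] <- params$I_drive
  r <- settle(state$weights, I_ext, params)
  choice_rates <- stats::setNames(r[idx_choices], choice_ids)
  target_rate <- choice_rates[[target_id]]
  others <- choice_rates[names(choice_rates) != target_id]
  correct <- target_rate >= params$theta_ret && all(target_rate > others)
  list(correct = correct, choice_rates = choice_rates)
}

#' Simulate the full encoding/retrieval protocol
#'
#' One independent network per simulated participant (fresh zero weights, own
#' RNG stream derived from the master seed), executing every encoding trial in
#' schedule order and then every test trial. Mirrors the overlapping-pairs
#' protocol; simultaneous (triples) schedules are not supported by the model.
#'
#' @param events An `event_set`.
#' @param enc An `encoding_schedule` in pairs mode.
#' @param test A `test_schedule` over the same events.
#' @param params A [model_params()] object; `params$n_sims` networks are run.
#' @param seed Master integer seed.
#' @return A response table (tibble) with one row per simulated retrieval
#'   trial: `participant_id`, `condition`, `encoding_order`, `event_id`,
#'   `cue_category`, `target_category`, `correct` (0/1).
#' @export
#' @examples
#' es <- make_events(3, 3)
#' enc <- make_encoding_schedule(es, "pairs", assign_orders(es), seed = 1)
#' ts <- make_test_schedule(es, seed = 2)
#' rt <- run_simulation(es, enc, ts, model_params(n_sims = 2), seed = 3)
#' nrow(rt) # 2 sims x 6 events x 6 questions
run_simulation <- function(events, enc, test, params = model_params(),
                           seed = NULL) {
  stopifnot(is_event_set(events))
  if (any(enc$encoding_order == "simultaneous")) {
    stop(
      "the network protocol mirrors overlapping-pairs encoding; ",
      "simultaneous (triples) schedules are unsupported",
      call. = FALSE
    )
  }
  orders <- schedule_orders(enc)
  el <- events$elements
  el_key <- stats::setNames(el$element_id, paste(el$event_id, el$category))
  enc_ids <- lapply(seq_len(nrow(enc)), function(i) {
    cats <- strsplit(enc$presented_categories[i], "|", fixed = TRUE)[[1]]
    unname(el_key[paste(enc$event_id[i], cats)])
  })
  test_choices <- strsplit(test$choice_ids, "|", fixed = TRUE)
  sim_seeds <- derive_seeds(seed %||% sample.int(2^30, 1), params$n_sims)

  one_sim <- function(s) {
    net <- new_network(events)
    with_seed(sim_seeds[s], {
      for (i in seq_len(nrow(enc))) {
        net <- encode_trial(net, enc_ids[[i]], params)
      }
      correct <- vapply(seq_len(nrow(test)), function(i) {
        out <- retrieve_trial(
          net, test$cue_id[i], test$target_id[i], test_choices[[i]], params
        )
        as.integer(out$correct)
      }, integer(1))
      tibble::tibble(
        participant_id = sprintf("sim%02d", s),
        condition = test$condition,
        encoding_order = unname(orders[test$event_id]),
        event_id = test$event_id,
        cue_category = test$cue_category,
        target_category = test$target_category,
        correct = correct
      )
    })
  }
  out <- dplyr::bind_rows(lapply(seq_len(params$n_sims), one_sim))
  class(out) <- c("response_table", class(out))
  out
}

#' Predicted question accuracies by link-configuration enumeration
#'
#' Under default dynamics the only weights that can form are the three
#' within-event pair associations, each present independently with probability
#' `p_enc` and with strength set by the modulation state of its encoding
#' trial. Enumerating the eight presence/absence configurations per event and
#' settling the retrieval dynamics for each question yields the exact
#' per-question accuracy and the exact distribution of an event's mean
#' accuracy - the basis for calibration checks on the simulator.
#'
#' @param condition `"neutral"` or `"negative"`.
#' @param order `"person_last"` or `"person_first"`.
#' @param params A [model_params()] object.
#' @return A list with `question_accuracy` (tibble: cue/target categories and
#'   probability correct), `mean_accuracy`, and `event_mean_dist` (tibble of
#'   possible per-event mean accuracies and their probabilities).
#' @export
predicted_accuracy <- function(condition = c("neutral", "negative"),
                               order = c("person_last", "person_first"),
                               params = model_params()) {
  condition <- match.arg(condition)
  order <- match.arg(order)
  pair_seq <- PAIR_ORDERS[[order]]
  cats <- ELEMENT_CATEGORIES
  qp <- question_pairs()
  p <- params$p_enc
  configs <- expand.grid(e1 = 0:1, e2 = 0:1, e3 = 0:1)
  rows <- vector("list", nrow(configs))
  for (ci in seq_len(nrow(configs))) {
    enc_ok <- as.numeric(configs[ci, ])
    w <- matrix(0, 3, 3, dimnames = list(cats, cats))
    linked <- character(0) # categories already associated to the person
    for (t in 1:3) {
      pr <- pair_seq[[t]]
      if (condition == "negative") {
        if ("person" %in% pr) {
          m <- params$m_neg
        } else {
          # neutral pair of a negative event: modulated iff the person is
          # reactivated through an already-formed association
          m <- if (length(intersect(linked, pr)) > 0) params$m_neg else 1
        }
      } else {
        m <- 1
      }
      if (enc_ok[t] == 1) {
        w[pr[1], pr[2]] <- w[pr[2], pr[1]] <- m * params$w_max
        if ("person" %in% pr) {
          linked <- union(linked, setdiff(pr, "person"))
        }
      }
    }
    correct <- vapply(seq_len(nrow(qp)), function(qi) {
      cue <- qp$cue_category[qi]
      tgt <- qp$target_category[qi]
      I_ext <- stats::setNames(numeric(3), cats)
      I_ext[tgt] <- params$I_choice
      I_ext[cue] <- params$I_drive
      r <- settle(w, I_ext, params)
      as.integer(r[[tgt]] >= params$theta_ret)
    }, integer(1))
    prob <- prod(ifelse(enc_ok == 1, p, 1 - p))
    rows[[ci]] <- list(prob = prob, correct = correct)
  }
  probs <- vapply(rows, `[[`, numeric(1), "prob")
  cmat <- do.call(rbind, lapply(rows, `[[`, "correct"))
  qacc <- as.numeric(probs %*% cmat)
  event_means <- rowMeans(cmat)
  dist <- stats::aggregate(probs, by = list(mean_accuracy = event_means), sum)
  list(
    question_accuracy = tibble::tibble(
      cue_category = qp$cue_category,
      target_category = qp$target_category,
      accuracy = qacc
    ),
    mean_accuracy = sum(probs * event_means),
    event_mean_dist = tibble::tibble(
      mean_accuracy = dist$mean_accuracy,
      prob = dist$x
    )
  )
}
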