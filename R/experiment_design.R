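#' Build a set of three-element events
#'
#' Constructs abstract person-location-object events. Each event owns three
#' unique elements, one per category; for negative events the person element
#' carries negative valence while location and object stay neutral (the person
#' image is the only negative element in the design).
#'
#' Elements are opaque identifiers, not images: the downstream analysis and
#' the network model never consume stimulus content, only identity, category
#' and valence.
#'
#' @param n_neutral,n_negative Numbers of neutral and negative events.
#' @param seed Optional integer seed (construction is deterministic; the seed
#'   is honoured for interface symmetry with the schedule builders).
#' @return An object of class `event_set`: a list with tibbles `events`
#'   (`event_id`, `condition`) and `elements` (`element_id`, `event_id`,
#'   `category`, `valence`).
#' @export
#' @examples
#' es <- make_events(18, 18)
#' nrow(es$events) # 36
#' nrow(es$elements) # 108
make_events <- function(n_neutral, n_negative, seed = NULL) {
  n_neutral <- assert_count(n_neutral, "n_neutral")
  n_negative <- assert_count(n_negative, "n_negative")
  n <- n_neutral + n_negative
  if (n == 0) {
    es <- list(
      events = tibble::tibble(
        event_id = character(),
        condition = character()
      ),
      elements = tibble::tibble(
        element_id = character(), event_id = character(),
        category = character(), valence = character()
      )
    )
    return(structure(es, class = "event_set"))
  }
  condition <- c(rep("neutral", n_neutral), rep("negative", n_negative))
  event_id <- sprintf("ev%03d", seq_len(n))
  events <- tibble::tibble(event_id = event_id, condition = condition)
  elements <- tidyr::crossing(events, category = ELEMENT_CATEGORIES)
  elements <- dplyr::mutate(
    elements,
    valence = ifelse(.data$condition == "negative" &
      .data$category == "person", "negative", "neutral"),
    element_id = paste0(.data$event_id, "_", substr(.data$category, 1, 3))
  )
  elements <- dplyr::select(
    elements,
    "element_id", "event_id", "category", "valence"
  )
  structure(list(events = events, elements = elements), class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  tab <- table(x$events$condition)
  cat(sprintf(
    "Event set: %d events (%s), %d elements\n",
    nrow(x$events),
    paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", "),
    nrow(x$elements)
  ))
  invisible(x)
}

is_event_set <- function(x) inherits(x, "event_set")

#' Assign an encoding order to every event
#'
#' Convenience helper producing the order map consumed by
#' [make_encoding_schedule()]. `"half"` splits each condition evenly between
#' person-last and person-first (the two overlapping-pair orders).
#'
#' @param events An `event_set`.
#' @param orders `"half"`, a single order name recycled to all events, or a
#'   named character vector `event_id -> order`.
#' @return Named character vector mapping event ids to orders.
#' @export
assign_orders <- function(events, orders = "half") {
  stopifnot(is_event_set(events))
  ids <- events$events$event_id
  if (length(orders) == 1 && orders == "half") {
    out <- character(length(ids))
    names(out) <- ids
    for (cond in unique(events$events$condition)) {
      sel <- which(events$events$condition == cond)
      half <- ceiling(length(sel) / 2)
      out[sel] <- "person_first"
      out[sel[seq_len(half)]] <- "person_last"
    }
    return(out)
  }
  if (length(orders) == 1 && is.null(names(orders))) {
    out <- rep(orders, length(ids))
    names(out) <- ids
    return(out)
  }
  if (is.null(names(orders)) || !setequal(names(orders), ids)) {
    stop("`orders` must name every event exactly once", call. = FALSE)
  }
  orders[ids]
}

#' Build an encoding schedule
#'
#' In `triples` mode every event contributes a single trial presenting all
#' three elements simultaneously. In `pairs` mode each event is studied as
#' three overlapping paired associates across three blocks: person-last events
#' as location-object, person-location, object-person; person-first events as
#' object-person, person-location, location-object. The first pair of every
#' event falls in block 1, the second in block 2, the third in block 3, and
#' trials are randomised within each block.
#'
#' @param events An `event_set`.
#' @param mode `"triples"` or `"pairs"`.
#' @param order_assignment For `pairs`, a map from event id to
#'   `"person_last"`/`"person_first"` (see [assign_orders()]); for `triples`
#'   every event must be (and defaults to) `"simultaneous"`.
#' @param seed Integer seed controlling within-block randomisation.
#' @return A tibble of class `encoding_schedule` with columns `trial_index`,
#'   `phase`, `block`, `event_id`, `condition`, `encoding_order`,
#'   `presented_categories` (pipe-separated).
#' @export
#' @examples
#' es <- make_events(2, 2)
#' enc <- make_encoding_schedule(es, "pairs", assign_orders(es), seed = 1)
#' table(enc$block)
make_encoding_schedule <- function(events, mode = c("pairs", "triples"),
                                   order_assignment = NULL, seed = NULL) {
  stopifnot(is_event_set(events))
  mode <- match.arg(mode)
  ids <- events$events$event_id
  if (mode == "triples") {
    oa <- order_assignment %||% stats::setNames(
      rep("simultaneous", length(ids)), ids
    )
    if (length(oa) == 1 && is.null(names(oa))) {
      oa <- stats::setNames(rep(oa, length(ids)), ids)
    }
    if (!all(oa[ids] == "simultaneous")) {
      stop("triples mode requires every event assigned 'simultaneous'",
        call. = FALSE
      )
    }
    trials <- tibble::tibble(
      event_id = ids,
      condition = events$events$condition,
      encoding_order = "simultaneous",
      block = 1L,
      presented_categories = paste(ELEMENT_CATEGORIES, collapse = "|")
    )
    trials <- with_seed(seed, dplyr::slice_sample(trials, n = nrow(trials)))
    trials <- dplyr::mutate(trials,
      trial_index = dplyr::row_number(), phase = "encoding"
    )
  } else {
    if (is.null(order_assignment)) {
      stop("pairs mode requires an order assignment for every event",
        call. = FALSE
      )
    }
    oa <- order_assignment
    if (is.null(names(oa)) || !all(ids %in% names(oa))) {
      stop("`order_assignment` must name every event", call. = FALSE)
    }
    oa <- oa[ids]
    bad <- !oa %in% names(PAIR_ORDERS)
    if (any(bad)) {
      stop(
        "pairs mode requires 'person_last' or 'person_first' for every ",
        "event; offending: ", paste(ids[bad], collapse = ", "),
        call. = FALSE
      )
    }
    per_event <- lapply(seq_along(ids), function(i) {
      seqs <- PAIR_ORDERS[[oa[[i]]]]
      tibble::tibble(
        event_id = ids[i],
        condition = events$events$condition[i],
        encoding_order = oa[[i]],
        block = 1:3,
        presented_categories = vapply(seqs, paste,
          character(1),
          collapse = "|"
        )
      )
    })
    trials <- dplyr::bind_rows(per_event)
    trials <- with_seed(seed, {
      trials |>
        dplyr::group_by(.data$block) |>
        dplyr::slice_sample(prop = 1) |>
        dplyr::ungroup()
    })
    trials <- dplyr::arrange(trials, .data$block)
    trials <- dplyr::mutate(trials,
      trial_index = dplyr::row_number(), phase = "encoding"
    )
  }
  out <- dplyr::select(
    trials, "trial_index", "phase", "block", "event_id", "condition",
    "encoding_order", "presented_categories"
  )
  class(out) <- c("encoding_schedule", class(out))
  out
}

# Recover the event -> order map from an encoding schedule.
schedule_orders <- function(enc) {
  u <- dplyr::distinct(
    tibble::as_tibble(enc), .data$event_id, .data$encoding_order
  )
  stats::setNames(u$encoding_order, u$event_id)
}

#' Build a six-alternative forced-choice test schedule
#'
#' Every within-event association is tested in both directions: six directed
#' cue -> target trials per event. Each trial's six options hold the correct
#' target, two foils of the target's category drawn from other events of the
#' same emotional condition, and three foils of the target's category from
#' events of the opposite condition, so every choice list carries three
#' elements from neutral events and three from negative events. Trial order is
#' randomised with trials from the same event separated by at least one
#' intervening trial (bounded reshuffles, then a greedy repair; if a valid
#' arrangement cannot be found the constraint is relaxed).
#'
#' @param events An `event_set` with at least three events per condition (the
#'   foil pools must exist).
#' @param seed Integer seed for foil sampling and trial ordering.
#' @param includes_recognition Flag recording whether an old/new recognition
#'   judgement precedes each forced choice (representational only; recognition
#'   scoring is out of scope).
#' @return A tibble of class `test_schedule` with columns `trial_index`,
#'   `phase`, `event_id`, `condition`, `cue_category`, `target_category`,
#'   `cue_id`, `target_id`, `choice_ids` (pipe-separated, randomised order).
#' @export
#' @examples
#' es <- make_events(3, 3)
#' ts <- make_test_schedule(es, seed = 1)
#' nrow(ts) # 36
make_test_schedule <- function(events, seed = NULL,
                               includes_recognition = FALSE) {
  stopifnot(is_event_set(events))
  n_by_cond <- table(factor(events$events$condition,
    levels = c("neutral", "negative")
  ))
  if (any(n_by_cond < 3)) {
    stop(
      "need at least 3 events per condition to populate same- and ",
      "opposite-condition foil pools",
      call. = FALSE
    )
  }
  el <- events$elements
  ev <- events$events
  qp <- question_pairs()
  base <- tidyr::crossing(ev, qp)
  el_key <- stats::setNames(el$element_id, paste(el$event_id, el$category))
  cond_of <- stats::setNames(ev$condition, ev$event_id)

  out <- with_seed(seed, {
    base$cue_id <- unname(el_key[paste(base$event_id, base$cue_category)])
    base$target_id <- unname(el_key[paste(base$event_id, base$target_category)])
    base$choice_ids <- vapply(seq_len(nrow(base)), function(i) {
      tc <- base$target_category[i]
      own <- base$event_id[i]
      cond <- base$condition[i]
      pool <- el[el$category == tc & el$event_id != own, ]
      same <- pool$element_id[cond_of[pool$event_id] == cond]
      opp <- pool$element_id[cond_of[pool$event_id] != cond]
      choices <- c(
        base$target_id[i],
        sample(same, 2),
        sample(opp, 3)
      )
      paste(sample(choices), collapse = "|")
    }, character(1))
    base <- interleave_trials(base)
    base
  })
  out <- dplyr::mutate(out, trial_index = dplyr::row_number(), phase = "test")
  out <- dplyr::select(
    out, "trial_index", "phase", "event_id", "condition", "cue_category",
    "target_category", "cue_id", "target_id", "choice_ids"
  )
  attr(out, "includes_recognition") <- includes_recognition
  class(out) <- c("test_schedule", class(out))
  out
}

# Shuffle rows so no two consecutive trials share an event: bounded
# reshuffles, then a greedy swap repair, then relax.
interleave_trials <- function(df, max_shuffles = 50, max_repair = 1000) {
  n <- nrow(df)
  if (n < 2) {
    return(df)
  }
  for (try in seq_len(max_shuffles)) {
    perm <- sample.int(n)
    ev <- df$event_id[perm]
    if (!any(ev[-1] == ev[-n])) {
      return(df[perm, , drop = FALSE])
    }
  }
  perm <- sample.int(n)
  ev <- df$event_id[perm]
  for (rep_i in seq_len(max_repair)) {
    clash <- which(ev[-1] == ev[-n])
    if (length(clash) == 0) break
    i <- clash[1] + 1L
    ok <- which(ev != ev[i] &
      c(ev[-1], "") != ev[i] &
      c("", ev[-n]) != ev[i])
    ok <- setdiff(ok, c(i - 1L, i, if (i < n) i + 1L))
    if (length(ok) == 0) break
    j <- ok[sample.int(length(ok), 1)]
    tmp <- perm[i]
    perm[i] <- perm[j]
    perm[j] <- tmp
    ev <- df$event_id[perm]
  }
  df[perm, , drop = FALSE]
}
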