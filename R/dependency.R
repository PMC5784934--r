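# Dependency statistic D and the Independent / Dependent model predictions,
# computed from 2x2 contingency tables over events.

RT_COLUMNS <- c(
  "participant_id", "condition", "encoding_order", "event_id",
  "cue_category", "target_category", "correct"
)

#' Validate a response table
#'
#' A response table records one retrieval trial per row: participant,
#' condition (neutral/negative), encoding order (simultaneous, person_last,
#' person_first), event, cue and target element categories, and binary
#' correctness. Every (participant, event) must contribute exactly the six
#' directed questions, each once.
#'
#' @param rt A data frame.
#' @return The validated table as a tibble (invisibly classed
#'   `response_table`).
#' @export
validate_response_table <- function(rt) {
  rt <- tibble::as_tibble(rt)
  missing_cols <- setdiff(RT_COLUMNS, names(rt))
  if (length(missing_cols)) {
    stop("response table is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(rt$correct %in% c(0, 1))) {
    stop("`correct` must be coded 0/1", call. = FALSE)
  }
  bad_cat <- !(rt$cue_category %in% ELEMENT_CATEGORIES) |
    !(rt$target_category %in% ELEMENT_CATEGORIES) |
    rt$cue_category == rt$target_category
  if (any(bad_cat)) {
    stop("cue/target categories must be distinct members of {",
      paste(ELEMENT_CATEGORIES, collapse = ", "), "}",
      call. = FALSE
    )
  }
  key <- paste(rt$participant_id, rt$event_id)
  qkey <- paste(key, rt$cue_category, rt$target_category)
  if (anyDuplicated(qkey)) {
    dup <- qkey[duplicated(qkey)][1]
    stop("duplicate question row: ", dup, call. = FALSE)
  }
  counts <- table(key)
  if (any(counts != 6)) {
    bad <- names(counts)[counts != 6][1]
    stop(
      "event with ", counts[[bad]], " (not 6) questions: participant/event ",
      bad,
      call. = FALSE
    )
  }
  if (!inherits(rt, "response_table")) {
    class(rt) <- c("response_table", class(rt))
  }
  rt
}

# Wide events x questions 0/1 matrix for one participant cell. Question
# columns are named "<cue>.<target>".
question_matrix <- function(cell) {
  q <- paste(cell$cue_category, cell$target_category, sep = ".")
  wide <- tapply(cell$correct, list(cell$event_id, q), sum)
  qp <- question_pairs()
  wanted <- paste(qp$cue_category, qp$target_category, sep = ".")
  if (!all(wanted %in% colnames(wide)) || anyNA(wide)) {
    stop("cell is missing questions for some event", call. = FALSE)
  }
  wide[, wanted, drop = FALSE]
}

# The six contingency-table definitions: for each common element A, a
# cue-common table over (A->B, A->C) and a target-common table over
# (B->A, C->A). The episodic-factor reference set is the remaining four
# questions.
table_definitions <- function() {
  defs <- list()
  for (a in ELEMENT_CATEGORIES) {
    bc <- setdiff(ELEMENT_CATEGORIES, a)
    defs[[length(defs) + 1]] <- list(
      table_kind = "cue_common", common_category = a,
      q1 = paste(a, bc[1], sep = "."), q2 = paste(a, bc[2], sep = ".")
    )
    defs[[length(defs) + 1]] <- list(
      table_kind = "target_common", common_category = a,
      q1 = paste(bc[1], a, sep = "."), q2 = paste(bc[2], a, sep = ".")
    )
  }
  defs
}

subset_cell <- function(rt, participant, condition, order) {
  cell <- rt[rt$participant_id == participant & rt$condition == condition &
    rt$encoding_order == order, , drop = FALSE]
  if (nrow(cell) == 0) {
    stop(
      "empty cell: participant ", participant, ", condition ", condition,
      ", order ", order,
      call. = FALSE
    )
  }
  cell
}

#' Accuracy by pair type, collapsed over test direction
#'
#' Mean correctness per participant, condition, encoding order and unordered
#' element pair (e.g. both directions of location-object pooled).
#'
#' @param rt A response table.
#' @return A tibble with columns `participant_id`, `condition`,
#'   `encoding_order`, `pair_type`, `accuracy`, `n_trials`.
#' @export
accuracy_summary <- function(rt) {
  rt <- validate_response_table(rt)
  rt |>
    dplyr::mutate(pair_type = paste(
      pmin(.data$cue_category, .data$target_category),
      pmax(.data$cue_category, .data$target_category),
      sep = "-"
    )) |>
    dplyr::group_by(
      .data$participant_id, .data$condition, .data$encoding_order,
      .data$pair_type
    ) |>
    dplyr::summarise(
      accuracy = mean(.data$correct),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-question marginal accuracies
#'
#' The participant's mean correctness for each directed question within a
#' condition x encoding-order cell: the marginals P_AB that feed the
#' Independent model.
#'
#' @param rt A response table.
#' @return A tibble keyed by participant, condition, order, cue and target
#'   categories.
#' @export
question_means <- function(rt) {
  rt <- validate_response_table(rt)
  dplyr::summarise(
    dplyr::group_by(
      rt, .data$participant_id, .data$condition, .data$encoding_order,
      .data$cue_category, .data$target_category
    ),
    accuracy = mean(.data$correct), n_events = dplyr::n(), .groups = "drop"
  )
}

#' Build the six 2x2 contingency tables for one participant cell
#'
#' For each common element A: a cue-common table counting, over events, the
#' four combinations of correct/incorrect retrieval of B and C when cued by A;
#' and a target-common table for retrieving A when cued by B and by C.
#'
#' @param rt A response table.
#' @param participant,condition,order Cell selectors.
#' @return A tibble with one row per table: `table_kind`, `common_category`,
#'   counts `n11` (both correct), `n10` (first only), `n01` (second only),
#'   `n00` (both incorrect) and `n` (events).
#' @export
build_contingency_tables <- function(rt, participant, condition, order) {
  rt <- validate_response_table(rt)
  q <- question_matrix(subset_cell(rt, participant, condition, order))
  defs <- table_definitions()
  dplyr::bind_rows(lapply(defs, function(d) {
    x1 <- q[, d$q1]
    x2 <- q[, d$q2]
    tibble::tibble(
      table_kind = d$table_kind,
      common_category = d$common_category,
      n11 = sum(x1 == 1 & x2 == 1),
      n10 = sum(x1 == 1 & x2 == 0),
      n01 = sum(x1 == 0 & x2 == 1),
      n00 = sum(x1 == 0 & x2 == 0),
      n = length(x1)
    )
  }))
}

#' Observed dependency D
#'
#' Per table, the proportion of events in which both associations were either
#' correctly or incorrectly retrieved; D is the unweighted mean over the six
#' tables.
#'
#' @param tables Output of [build_contingency_tables()].
#' @return Scalar D in \[0, 1\].
#' @export
compute_D <- function(tables) {
  if (nrow(tables) == 0 || any(tables$n == 0)) {
    stop("contingency tables must be nonempty", call. = FALSE)
  }
  mean((tables$n11 + tables$n00) / tables$n)
}

#' Independent-model dependency Di
#'
#' Per table, `P_AB * P_AC + (1 - P_AB) * (1 - P_AC)` with the marginals taken
#' as the participant's question-type means over that cell's events; Di is the
#' mean over the six tables.
#'
#' @inheritParams build_contingency_tables
#' @return Scalar Di in \[0, 1\].
#' @export
compute_Di <- function(rt, participant, condition, order) {
  rt <- validate_response_table(rt)
  q <- question_matrix(subset_cell(rt, participant, condition, order))
  mean(vapply(table_definitions(), function(d) {
    p1 <- mean(q[, d$q1])
    p2 <- mean(q[, d$q2])
    p1 * p2 + (1 - p1) * (1 - p2)
  }, numeric(1)))
}

#' Episodic factors and adjusted probabilities for one table
#'
#' The episodic factor of event i reflects its performance relative to other
#' events, based on the four questions outside the table under test: `E_i` is
#' event i's guessing-corrected mean over those questions relative to their
#' grand mean over all events in the cell,
#' `E_i = (e_i - P_G/c) / (mean(e) - P_G/c)`. The adjusted probability
#' replaces the marginal with `P'_i = E_i * (P - P_G/c) + P_G/c`, clamped to
#' \[0, 1\], where `P_G` is the probability of guessing and `c` the number of
#' forced-choice options. The correction makes the Dependent model the
#' maximal-dependency benchmark: fully dependent responding yields `Dd >= D`
#' up to estimation noise, while `E_i = 1` for every event still collapses it
#' onto the Independent model exactly. Events performing below the guessing
#' floor get `E_i < 0`; the clamp on `P'` absorbs this.
#'
#' @inheritParams build_contingency_tables
#' @param table_kind `"cue_common"` or `"target_common"`.
#' @param common_category The table's common element.
#' @param P_G Guessing probability (default 1: guesses land on the target at
#'   the full chance rate 1/c).
#' @param n_choices Number of forced-choice options (6).
#' @return A tibble per event: `event_id`, `E`, `p_adj_1`, `p_adj_2` (adjusted
#'   probabilities for the table's two questions).
#' @export
episodic_factors <- function(rt, participant, condition, order,
                             table_kind = c("cue_common", "target_common"),
                             common_category = "person",
                             P_G = 1, n_choices = 6) {
  rt <- validate_response_table(rt)
  table_kind <- match.arg(table_kind)
  q <- question_matrix(subset_cell(rt, participant, condition, order))
  if (nrow(q) < 2) {
    stop("episodic factors need at least 2 events in the cell", call. = FALSE)
  }
  defs <- table_definitions()
  d <- defs[[which(vapply(defs, function(x) {
    x$table_kind == table_kind && x$common_category == common_category
  }, logical(1)))]]
  ep <- episodic_adjust(q, d, P_G, n_choices)
  tibble::tibble(
    event_id = rownames(q),
    E = ep$E, p_adj_1 = ep$pp1, p_adj_2 = ep$pp2
  )
}

# Core of the Dependent model for one table definition. The episodic factor
# is the event's guessing-corrected reference performance relative to the
# cell's: E_i = (e_i - P_G/c) / (gm - P_G/c), where e_i is event i's mean
# over the four questions outside the table and gm their grand mean. The
# correction keeps the Dependent model the maximal-dependency benchmark: on
# fully dependent (all-or-none) responses the adjusted probability reduces to
# the event's observed reference performance, so Dd tracks D from above
# instead of being dragged toward the marginal by the guessing floor. E can
# fall below zero for events performing under the floor; the clamping of the
# adjusted probabilities to [0, 1] absorbs this.
episodic_adjust <- function(q, d, P_G, n_choices, force_unit_E = FALSE) {
  ref <- setdiff(colnames(q), c(d$q1, d$q2))
  e_i <- unname(rowMeans(q[, ref, drop = FALSE]))
  gm <- mean(e_i)
  floor_g <- P_G / n_choices
  if (!force_unit_E && gm <= floor_g) {
    stop(
      "degenerate reference for table ", d$table_kind, "/",
      d$common_category, ": grand mean of the four reference questions (",
      signif(gm, 4), ") is at or below the guessing floor ",
      signif(floor_g, 4),
      call. = FALSE
    )
  }
  E <- if (force_unit_E) rep(1, nrow(q)) else (e_i - floor_g) / (gm - floor_g)
  p1 <- mean(q[, d$q1])
  p2 <- mean(q[, d$q2])
  pp1 <- pmin(pmax(E * (p1 - floor_g) + floor_g, 0), 1)
  pp2 <- pmin(pmax(E * (p2 - floor_g) + floor_g, 0), 1)
  list(E = E, pp1 = pp1, pp2 = pp2)
}

#' Dependent-model dependency Dd
#'
#' Per table, the mean over events of
#' `P'_AB * P'_AC + (1 - P'_AB) * (1 - P'_AC)` with the per-event adjusted
#' probabilities of [episodic_factors()]; Dd is the mean over the six tables.
#' With all episodic factors forced to 1 this reduces exactly to the
#' Independent model.
#'
#' @inheritParams episodic_factors
#' @param force_unit_E Force every episodic factor to 1 (identity check
#'   against Di).
#' @return Scalar Dd in \[0, 1\].
#' @export
compute_Dd <- function(rt, participant, condition, order, P_G = 1,
                       n_choices = 6, force_unit_E = FALSE) {
  rt <- validate_response_table(rt)
  q <- question_matrix(subset_cell(rt, participant, condition, order))
  if (nrow(q) < 2 && !force_unit_E) {
    stop("the Dependent model needs at least 2 events in the cell",
      call. = FALSE
    )
  }
  mean(vapply(table_definitions(), function(d) {
    ep <- episodic_adjust(q, d, P_G, n_choices, force_unit_E)
    mean(ep$pp1 * ep$pp2 + (1 - ep$pp1) * (1 - ep$pp2))
  }, numeric(1)))
}

#' Full dependency report
#'
#' One row per participant x condition x encoding-order cell with D, Di, Dd
#' and the contrasts D - Di and D - Dd, plus unweighted condition-level means
#' and standard errors across participants.
#'
#' @param rt A response table.
#' @param P_G Guessing probability for the Dependent model (see
#'   [episodic_factors()]).
#' @param n_choices Number of forced-choice options.
#' @return A list of class `dependency_report`: `by_participant` (tibble of
#'   per-cell results) and `summary` (tibble of means and standard errors per
#'   condition x order).
#' @export
#' @examples
#' spec <- behavior_spec(
#'   n_participants = 3, n_events = 12,
#'   regime = "all_or_none", q = 0.5, seed = 1
#' )
#' rep <- dependency_report(generate_responses(spec))
#' rep$summary
dependency_report <- function(rt, P_G = 1, n_choices = 6) {
  rt <- validate_response_table(rt)
  cells <- dplyr::distinct(
    rt, .data$participant_id, .data$condition, .data$encoding_order
  )
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    pid <- cells$participant_id[i]
    cond <- cells$condition[i]
    ord <- cells$encoding_order[i]
    tables <- build_contingency_tables(rt, pid, cond, ord)
    D <- compute_D(tables)
    Di <- compute_Di(rt, pid, cond, ord)
    Dd <- compute_Dd(rt, pid, cond, ord, P_G = P_G, n_choices = n_choices)
    tibble::tibble(
      participant_id = pid, condition = cond, encoding_order = ord,
      n_events = tables$n[1],
      D = D, Di = Di, Dd = Dd,
      D_minus_Di = D - Di, D_minus_Dd = D - Dd,
      P_G = P_G, n_choices = n_choices
    )
  })
  by_participant <- dplyr::bind_rows(rows)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- by_participant |>
    dplyr::group_by(.data$condition, .data$encoding_order) |>
    dplyr::summarise(
      n_participants = dplyr::n(),
      dplyr::across(
        c("D", "Di", "Dd", "D_minus_Di", "D_minus_Dd"),
        list(mean = mean, se = se)
      ),
      .groups = "drop"
    )
  structure(
    list(by_participant = by_participant, summary = summary),
    class = "dependency_report"
  )
}

#' @export
print.dependency_report <- function(x, ...) {
  cat("Dependency report:",
    nrow(x$by_participant), "participant cells\n\n"
  )
  print(x$summary, ...)
  invisible(x)
}
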