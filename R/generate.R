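#' Specify a synthetic behavioural responder
#'
#' Defines a population of simulated participants answering the six directed
#' questions per event under one of three regimes with known ground-truth
#' dependency structure:
#' * `independent`: every question an independent Bernoulli at its marginal
#'   accuracy - zero event-level dependency by construction.
#' * `all_or_none`: with probability `q` the whole event is known (all six
#'   questions correct); otherwise every question is an independent guess
#'   succeeding with probability `g` - the fully dependent limiting case.
#' * `graded`: each event draws an episodic strength `s ~ Beta(shape1,
#'   shape2)` and every question succeeds with probability `g + s * (1 - g)` -
#'   intermediate dependency.
#'
#' @param n_participants Number of simulated participants.
#' @param n_events Events per condition x order cell.
#' @param regime `"independent"`, `"all_or_none"` or `"graded"`.
#' @param marginal Marginal per-question accuracy for the independent regime.
#' @param q Event-knowledge probability (all_or_none).
#' @param shape1,shape2 Beta parameters of the graded strength distribution.
#' @param g Guess success probability (default 1/6, the six-alternative
#'   forced-choice chance rate).
#' @param cells Tibble of cells to populate (columns `condition`,
#'   `encoding_order`); defaults to a single neutral/simultaneous cell.
#' @param seed Integer seed.
#' @return A list of class `behavior_spec`.
#' @export
behavior_spec <- function(n_participants = 1,
                          n_events = 18,
                          regime = c("independent", "all_or_none", "graded"),
                          marginal = 0.8,
                          q = 0.5,
                          shape1 = 2, shape2 = 2,
                          g = 1 / 6,
                          cells = NULL,
                          seed = NULL) {
  regime <- match.arg(regime)
  n_participants <- assert_count(n_participants, "n_participants")
  n_events <- assert_count(n_events, "n_events")
  probs <- c(marginal = marginal, q = q, g = g)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("`marginal`, `q` and `g` must lie in [0, 1]", call. = FALSE)
  }
  if (regime == "independent" && marginal < g) {
    stop("`marginal` must be at least the guessing rate `g`", call. = FALSE)
  }
  if (shape1 <= 0 || shape2 <= 0) {
    stop("Beta shape parameters must be positive", call. = FALSE)
  }
  cells <- cells %||% tibble::tibble(
    condition = "neutral", encoding_order = "simultaneous"
  )
  structure(
    list(
      n_participants = n_participants, n_events = n_events, regime = regime,
      marginal = marginal, q = q, shape1 = shape1, shape2 = shape2, g = g,
      cells = tibble::as_tibble(cells), seed = seed
    ),
    class = "behavior_spec"
  )
}

#' Generate a synthetic response table
#'
#' @param spec A [behavior_spec()].
#' @return A validated response table (6 rows per participant x event).
#' @export
#' @examples
#' rt <- generate_responses(behavior_spec(
#'   n_participants = 2, n_events = 10,
#'   regime = "all_or_none", q = 1, seed = 1
#' ))
#' mean(rt$correct) # 1
generate_responses <- function(spec) {
  stopifnot(inherits(spec, "behavior_spec"))
  qp <- question_pairs()
  n_q <- nrow(qp)
  with_seed(spec$seed %||% sample.int(2^30, 1), {
    parts <- lapply(seq_len(spec$n_participants), function(p) {
      cell_rows <- lapply(seq_len(nrow(spec$cells)), function(ci) {
        cond <- spec$cells$condition[ci]
        ord <- spec$cells$encoding_order[ci]
        n_ev <- spec$n_events
        event_id <- sprintf("%s_%s_ev%05d", cond, ord, seq_len(n_ev))
        correct <- switch(spec$regime,
          independent = matrix(
            stats::rbinom(n_ev * n_q, 1, spec$marginal),
            nrow = n_ev
          ),
          all_or_none = {
            known <- stats::rbinom(n_ev, 1, spec$q)
            m <- matrix(stats::rbinom(n_ev * n_q, 1, spec$g), nrow = n_ev)
            m[known == 1, ] <- 1L
            m
          },
          graded = {
            s <- stats::rbeta(n_ev, spec$shape1, spec$shape2)
            pr <- spec$g + s * (1 - spec$g)
            matrix(stats::rbinom(n_ev * n_q, 1, rep(pr, n_q)), nrow = n_ev)
          }
        )
        tibble::tibble(
          participant_id = sprintf("p%03d", p),
          condition = cond,
          encoding_order = ord,
          event_id = rep(event_id, times = n_q),
          cue_category = rep(qp$cue_category, each = n_ev),
          target_category = rep(qp$target_category, each = n_ev),
          correct = as.integer(correct)
        )
      })
      dplyr::bind_rows(cell_rows)
    })
    validate_response_table(dplyr::bind_rows(parts))
  })
}

#' Ground-truth dependency for a generator specification
#'
#' Closed forms for the expected observed dependency and the Independent-model
#' prediction. Under the independent regime every contingency table pairs two
#' independent Bernoulli(p) outcomes, so `D = Di = p^2 + (1 - p)^2`. Under
#' all_or_none, `D = q + (1 - q) * (g^2 + (1 - g)^2)` and Di follows from the
#' overall marginal `p = q + (1 - q) * g`; the Dependent model has no simple
#' closed form (it tracks D asymptotically) and is reported as `NA`.
#'
#' @param spec A [behavior_spec()] with regime `independent` or `all_or_none`.
#' @return A list with `D`, `Di`, `Dd`.
#' @export
dependency_truth <- function(spec) {
  stopifnot(inherits(spec, "behavior_spec"))
  agree <- function(p) p^2 + (1 - p)^2
  switch(spec$regime,
    independent = {
      d <- agree(spec$marginal)
      list(D = d, Di = d, Dd = d)
    },
    all_or_none = {
      p <- spec$q + (1 - spec$q) * spec$g
      list(
        D = spec$q + (1 - spec$q) * agree(spec$g),
        Di = agree(p),
        Dd = NA_real_
      )
    },
    stop("no closed form for the graded regime; use Monte Carlo",
      call. = FALSE
    )
  )
}
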