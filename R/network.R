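#' Create a fresh attractor network over an event set
#'
#' One rate-coded neuron per element, fully recurrently connected except for
#' self-connections. All weights and rates start at zero.
#'
#' @param events An `event_set` (see [make_events()]).
#' @return An object of class `network_state`: list with `weights` (N x N,
#'   zero diagonal, dimnames = element ids), `rates` (length-N, Hz),
#'   `neuron_ids`, and `negative_ids` (indices of neurons coding negative
#'   elements).
#' @export
new_network <- function(events) {
  stopifnot(is_event_set(events))
  ids <- events$elements$element_id
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  structure(
    list(
      weights = w,
      rates = stats::setNames(numeric(n), ids),
      neuron_ids = ids,
      negative_ids = which(events$elements$valence == "negative")
    ),
    class = "network_state"
  )
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf(
    "Attractor network: %d neurons (%d negative), %d nonzero weights\n",
    length(x$neuron_ids), length(x$negative_ids), sum(x$weights > 0)
  ))
  invisible(x)
}

check_weights <- function(w, w_max) {
  if (!is.matrix(w) || nrow(w) != ncol(w) || !all(is.finite(w))) {
    stop("weights must be a finite square matrix", call. = FALSE)
  }
  if (any(diag(w) != 0) || any(w < 0) || any(w > w_max + 1e-12)) {
    stop("weights must satisfy 0 <= w <= w_max with zero diagonal",
      call. = FALSE
    )
  }
  invisible(w)
}

#' Settle network firing rates under fixed external currents
#'
#' Synchronous discrete-time iteration (1 step = 1 ms) of the threshold-linear
#' dynamics: each neuron's total input is its external current plus the
#' recurrent synaptic current `sum_j w_ij r_j`, converted to a rate by
#' `r = min(max(I_total - theta_T, 0), r_max)`. Iteration stops at `n_steps`
#' or earlier once an exact fixed point is reached (the update leaves every
#' rate unchanged to within 1e-12, which never truncates the marginal gain-one
#' loops that climb linearly to saturation).
#'
#' @param weights N x N non-negative weight matrix, zero diagonal.
#' @param external_currents Length-N vector of external currents (nA).
#' @param params A [model_params()] object.
#' @param rates Optional starting rates (default zero).
#' @return Length-N vector of settled firing rates (Hz).
#' @export
#' @examples
#' p <- model_params()
#' settle(matrix(0, 2, 2), c(15, 0), p) # 10 Hz and 0 Hz
settle <- function(weights, external_currents, params = model_params(),
                   rates = NULL) {
  check_weights(weights, params$w_max)
  n <- nrow(weights)
  if (length(external_currents) != n || !all(is.finite(external_currents))) {
    stop("`external_currents` must be a finite length-N vector", call. = FALSE)
  }
  r <- rates %||% numeric(n)
  if (length(r) != n || !all(is.finite(r))) {
    stop("`rates` must be a finite length-N vector", call. = FALSE)
  }
  for (step in seq_len(params$n_steps)) {
    active <- which(r > 0)
    I_syn <- if (length(active)) {
      as.numeric(weights[, active, drop = FALSE] %*% r[active])
    } else {
      numeric(n)
    }
    r_new <- pmin(pmax(external_currents + I_syn - params$theta_T, 0),
      params$r_max
    )
    if (max(abs(r_new - r)) < 1e-12) {
      r <- r_new
      break
    }
    r <- r_new
  }
  names(r) <- rownames(weights)
  r
}

#' Learning-rate modulation by negative-element activity
#'
#' Returns the modulated value `m_neg` when any neuron coding a negative
#' element fires at or above `theta_neg` (whether driven externally or
#' incidentally reactivated through recurrent excitation), and 1 otherwise.
#' The threshold comparison is inclusive: a negative element reactivated
#' through a single weak association settles at exactly `theta_neg`, and that
#' case must trigger modulation for reactivation to weaken later learning.
#'
#' @param rates Length-N rate vector (Hz).
#' @param negative_ids Indices of negative-element neurons.
#' @param params A [model_params()] object.
#' @return Scalar modulation factor (`m_neg` or 1).
#' @export
modulation_factor <- function(rates, negative_ids, params = model_params()) {
  if (length(negative_ids) && any(rates[negative_ids] >= params$theta_neg)) {
    params$m_neg
  } else {
    1
  }
}

#' Hebbian weight update with BCM-like potentiation threshold
#'
#' Potentiation is proportional to the product of the two rates, gated by the
#' postsynaptic threshold `theta_p`: the increment for `w_ij` over a trial is
#' `m * k * r_i * max(r_j - theta_p, 0)` per step, integrated over
#' `t_enc` steps. Potentiation requires both units to clear `theta_p`, so an
#' incidentally reactivated neuron settling below the threshold gains no
#' weights in either direction. Increments are capped per trial at
#' `max(w_old, m * w_max)` - a modulated trial drives its pair only to the
#' reduced ceiling `m * w_max`, but never decrements a weight already above it
#' - and globally at `w_max`. No decrements ever occur.
#'
#' @param weights N x N weight matrix.
#' @param rates Settled rates for the trial (Hz).
#' @param k Learning rate for the trial (0 or `k_neut`).
#' @param m Modulation factor for the trial (1 or `m_neg`).
#' @param params A [model_params()] object.
#' @return Updated weight matrix.
#' @export
hebbian_update <- function(weights, rates, k, m, params = model_params()) {
  if (k == 0) {
    return(weights)
  }
  post <- pmax(rates - params$theta_p, 0)
  eligible <- which(post > 0)
  if (length(eligible) < 2) {
    return(weights)
  }
  # both-suprathreshold gate: restrict to neurons clearing theta_p
  r_e <- rates[eligible]
  post_e <- post[eligible]
  inc <- (m * k * params$t_enc) * outer(r_e, post_e)
  diag(inc) <- 0
  w_old <- weights[eligible, eligible, drop = FALSE]
  ceiling_trial <- pmax(w_old, m * params$w_max)
  w_new <- pmin(w_old + inc, ceiling_trial, params$w_max)
  weights[eligible, eligible] <- w_new
  weights
}
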