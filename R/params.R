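#' Attractor-model parameters
#'
#' Bundle of every constant governing the rate-coded network: activation
#' threshold and peak rate of the threshold-linear units, the BCM-like
#' potentiation threshold, the weight ceiling, the neutral learning rate and
#' per-trial encoding probability, the emotional modulation factor and the
#' negative-reactivation threshold, the external currents used at encoding and
#' retrieval, the retrieval rate threshold, and trial durations.
#'
#' Units: currents in nA, rates and rate thresholds in Hz, durations in ms
#' (one synchronous update step per ms). `w_max` is dimensionless.
#'
#' @param theta_T Activation threshold of the threshold-linear unit (nA).
#' @param r_max Peak firing rate (Hz).
#' @param theta_p Postsynaptic potentiation threshold (Hz); no weight change
#'   below it.
#' @param w_max Hard ceiling on synaptic weights.
#' @param k_neut Learning rate for purely neutral trials (per ms).
#' @param p_enc Probability that a given encoding trial draws a positive
#'   learning rate.
#' @param m_neg Multiplicative modulation of the learning rate when a
#'   negative-element neuron is active or incidentally reactivated.
#' @param theta_neg Firing-rate threshold (Hz) above which a negative-element
#'   neuron triggers modulation. Comparisons are inclusive (>=).
#' @param I_drive External current to presented/cued elements (nA).
#' @param I_choice External current to the six forced-choice options (nA).
#' @param theta_ret Firing-rate threshold (Hz) for counting an element as
#'   retrieved.
#' @param t_enc,t_ret Encoding/retrieval trial duration (ms).
#' @param n_steps Synchronous settle iterations per trial (1 step = 1 ms).
#' @param n_sims Number of independent simulated participants.
#'
#' @return A list of class `memcoh_params`.
#' @export
#' @examples
#' p <- model_params()
#' p$p_enc
model_params <- function(theta_T = 5,
                         r_max = 10,
                         theta_p = 7.5,
                         w_max = 1,
                         k_neut = 1.6e-4,
                         p_enc = 0.65,
                         m_neg = 0.6,
                         theta_neg = 1,
                         I_drive = 15,
                         I_choice = 5,
                         theta_ret = 5,
                         t_enc = 1000,
                         t_ret = 1000,
                         n_steps = 1000,
                         n_sims = 26) {
  p <- list(
    theta_T = theta_T, r_max = r_max, theta_p = theta_p, w_max = w_max,
    k_neut = k_neut, p_enc = p_enc, m_neg = m_neg, theta_neg = theta_neg,
    I_drive = I_drive, I_choice = I_choice, theta_ret = theta_ret,
    t_enc = t_enc, t_ret = t_ret, n_steps = n_steps, n_sims = n_sims
  )
  validate_params(p)
  structure(p, class = "memcoh_params")
}

validate_params <- function(p) {
  nonneg <- c(
    "theta_T", "r_max", "theta_p", "w_max", "k_neut", "theta_neg",
    "I_drive", "I_choice", "theta_ret", "t_enc", "t_ret"
  )
  for (f in nonneg) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] < 0) {
      stop("`", f, "` must be a single non-negative finite number",
        call. = FALSE
      )
    }
  }
  if (p$p_enc < 0 || p$p_enc > 1) {
    stop("`p_enc` must lie in [0, 1]", call. = FALSE)
  }
  if (p$m_neg <= 0 || p$m_neg > 1) {
    stop("`m_neg` must lie in (0, 1]", call. = FALSE)
  }
  if (p$n_steps < 1 || p$n_sims < 1) {
    stop("`n_steps` and `n_sims` must be positive", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.memcoh_params <- function(x, ...) {
  cat("Attractor-model parameters\n")
  cat(sprintf(
    "  units: theta_T = %g nA, r_max = %g Hz, theta_p = %g Hz\n",
    x$theta_T, x$r_max, x$theta_p
  ))
  cat(sprintf(
    "  learning: k_neut = %g, p_enc = %g, m_neg = %g, theta_neg = %g Hz, w_max = %g\n",
    x$k_neut, x$p_enc, x$m_neg, x$theta_neg, x$w_max
  ))
  cat(sprintf(
    "  protocol: I_drive = %g nA, I_choice = %g nA, theta_ret = %g Hz, %d steps/trial, %d sims\n",
    x$I_drive, x$I_choice, x$theta_ret, x$n_steps, x$n_sims
  ))
  invisible(x)
}
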