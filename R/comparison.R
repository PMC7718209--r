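#' Parameters for the fixed-learning-rate comparison models
#'
#' Two alternatives to the dynamic Bayesian learner: a single fixed
#' learning rate, and valenced fixed rates that apply \code{alpha_neg}
#' after harmful observations and \code{alpha_pos} after helpful ones.
#' Both track a point estimate of the agent's harm aversion rather than a
#' full belief distribution.
#'
#' @param kappa_hat0 initial kappa estimate in [0, 1].
#' @param alpha_fixed single fixed learning rate in [0, 1].
#' @param alpha_neg,alpha_pos valenced rates in [0, 1] (negative = after a
#'   harmful choice, positive = after a helpful one). Default to
#'   \code{alpha_fixed}, so the valenced model with equal rates reproduces
#'   the single-rate model exactly.
#' @param beta assumed agent choice consistency, >= 0.
#' @return an object of class \code{"fixed_lr_params"}.
#' @export
fixed_lr_params <- function(kappa_hat0 = 0.5, alpha_fixed = 0.1,
                            alpha_neg = alpha_fixed,
                            alpha_pos = alpha_fixed, beta = 6) {
  for (nm in c("kappa_hat0", "alpha_fixed", "alpha_neg", "alpha_pos")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be in [0, 1]", nm))
  }
  if (!is.finite(beta) || beta < 0) stop("'beta' must be >= 0")
  structure(list(kappa_hat0 = kappa_hat0, alpha_fixed = alpha_fixed,
                 alpha_neg = alpha_neg, alpha_pos = alpha_pos, beta = beta),
            class = "fixed_lr_params")
}

#' Run a fixed-learning-rate learner over a choice sequence
#'
#' Per trial: predict \code{p_pred = choice_prob(kappa_hat, beta, trial)},
#' observe the agent's choice, compute \code{delta = observed - p_pred},
#' then update \code{kappa_hat <- clip01(kappa_hat - alpha * delta)} where
#' \code{alpha} is the single fixed rate or, in the valenced model,
#' \code{alpha_neg} when the observation was harmful and \code{alpha_pos}
#' when helpful. Harmful evidence (positive delta) lowers the estimated
#' harm aversion.
#'
#' @param params a \code{\link{fixed_lr_params}}.
#' @param trials a trial set.
#' @param choices logical vector of agent choices, aligned with trials.
#' @param valenced logical; use separate rates by observation valence?
#' @return a trace data.frame in the same schema as
#'   \code{\link{run_learner}}: \code{mu_pre}/\code{mu_post} carry the
#'   kappa estimate before/after each update, the sigma columns are
#'   \code{NA} (a point estimate has no spread), and \code{alpha} is the
#'   fixed rate applied on that trial.
#' @export
run_fixed_lr <- function(params, trials, choices, valenced = FALSE) {
  stopifnot(inherits(params, "fixed_lr_params"))
  .check_trials(trials)
  choices <- as.logical(choices)
  if (length(choices) != nrow(trials))
    stop("length(choices) must equal nrow(trials)")
  n <- nrow(trials)
  k <- params$kappa_hat0
  tr <- data.frame(
    trial_index = trials$trial_index,
    p_pred = numeric(n), observed = choices, delta = numeric(n),
    mu_pre = numeric(n), sigma_pre = NA_real_,
    mu_post = numeric(n), sigma_post = NA_real_, alpha = numeric(n)
  )
  for (t in seq_len(n)) {
    p_pred <- choice_prob(k, params$beta, trials[t, , drop = FALSE])
    delta <- as.numeric(choices[t]) - p_pred
    a <- if (!valenced) params$alpha_fixed
         else if (choices[t]) params$alpha_neg else params$alpha_pos
    k_new <- min(1, max(0, k - a * delta))
    tr$p_pred[t] <- p_pred
    tr$delta[t] <- delta
    tr$mu_pre[t] <- k
    tr$mu_post[t] <- k_new
    tr$alpha[t] <- a
    k <- k_new
  }
  tr
}
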