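#' Learner parameters for the dynamic Bayesian model
#'
#' The learner maintains a discretized probability distribution over the
#' agent's harm-aversion exchange rate kappa. \code{mu0} and \code{sigma0}
#' parameterize the truncated-Gaussian prior belief (the participant's
#' pre-task expectation about moral character and their confidence in it);
#' \code{beta} is the choice consistency the learner assumes the agent has;
#' \code{lam} is a leak (forgetting) weight that mixes a uniform
#' distribution into the belief after every update, keeping uncertainty
#' bounded away from zero over long runs.
#'
#' @param mu0 prior mean over kappa, in [0, 1].
#' @param sigma0 prior spread, > 0.
#' @param beta assumed agent choice consistency, >= 0.
#' @param lam leak weight in [0, 1].
#' @return an object of class \code{"learner_params"}.
#' @export
learner_params <- function(mu0 = 0.5, sigma0 = 0.25, beta = 6, lam = 0.1) {
  if (!is.finite(mu0) || mu0 < 0 || mu0 > 1) stop("'mu0' must be in [0, 1]")
  if (!is.finite(sigma0) || sigma0 <= 0) stop("'sigma0' must be > 0")
  if (!is.finite(beta) || beta < 0) stop("'beta' must be >= 0")
  if (!is.finite(lam) || lam < 0 || lam > 1) stop("'lam' must be in [0, 1]")
  structure(list(mu0 = mu0, sigma0 = sigma0, beta = beta, lam = lam),
            class = "learner_params")
}

.new_belief <- function(grid, mass) {
  s <- sum(mass)
  if (!is.finite(s) || s <= 0) stop("belief mass is degenerate")
  structure(list(grid = grid, mass = mass / s), class = "belief_state")
}

#' Initialize a belief distribution over kappa
#'
#' The prior mass is a truncated Gaussian N(mu0, sigma0^2) evaluated on a
#' regular grid over [0, 1] and renormalized. Densities are computed in log
#' space so very tight priors far from a grid point do not underflow.
#'
#' @param params a \code{\link{learner_params}} object.
#' @param grid_size number of grid points G >= 3.
#' @return an object of class \code{"belief_state"} with fields
#'   \code{grid} (G ordered kappa values) and \code{mass} (G probabilities
#'   summing to 1).
#' @export
init_belief <- function(params, grid_size = 101) {
  stopifnot(inherits(params, "learner_params"))
  if (grid_size < 3) stop("'grid_size' must be >= 3")
  grid <- seq(0, 1, length.out = as.integer(grid_size))
  logd <- stats::dnorm(grid, params$mu0, params$sigma0, log = TRUE)
  .new_belief(grid, exp(logd - max(logd)))
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("<belief_state> G=%d mean=%.4f sd=%.4f\n",
              length(x$grid), belief_mean(x), belief_sd(x)))
  invisible(x)
}

#' Belief mean and spread
#'
#' Mean and standard deviation of kappa under the current belief mass.
#'
#' @param belief a \code{"belief_state"}.
#' @return a numeric scalar.
#' @export
belief_mean <- function(belief) sum(belief$grid * belief$mass)

#' @rdname belief_mean
#' @export
belief_sd <- function(belief) {
  m <- belief_mean(belief)
  sqrt(max(0, sum(belief$mass * (belief$grid - m)^2)))
}

#' Predicted probability that the agent picks the harmful option
#'
#' Marginalizes the choice probability over the current belief:
#' \code{sum_g mass(g) * choice_prob(kappa_g, beta, trial)}.
#'
#' @param belief a \code{"belief_state"}.
#' @param trial a single-row trial set (or multi-row; vectorized).
#' @param beta assumed agent choice consistency.
#' @return predicted probability (vector, one per trial row).
#' @export
predict_choice <- function(belief, trial, beta) {
  stopifnot(inherits(belief, "belief_state"))
  p <- choice_prob(belief$grid, beta, trial)  # G x T
  drop(crossprod(belief$mass, p))
}

#' Bayesian belief update after observing the agent's choice
#'
#' Applies Bayes' rule with the logistic choice likelihood, then mixes in a
#' uniform leak: \code{mass'' = (1 - lam) * mass' + lam / G}.
#'
#' @param belief a \code{"belief_state"}.
#' @param trial a single-row trial set.
#' @param observed logical; did the agent choose the harmful option?
#' @param beta assumed agent choice consistency.
#' @param lam leak weight in [0, 1].
#' @return the posterior \code{"belief_state"}.
#' @export
update_belief <- function(belief, trial, observed, beta, lam = 0) {
  stopifnot(inherits(belief, "belief_state"), is.logical(observed),
            length(observed) == 1L)
  like <- drop(as.matrix(choice_prob(belief$grid, beta, trial)))
  if (!observed) like <- 1 - like
  post <- belief$mass * like
  s <- sum(post)
  if (!is.finite(s) || s <= 0)
    stop("likelihood vanished over the whole grid")
  post <- post / s
  mass <- (1 - lam) * post + lam / length(belief$grid)
  .new_belief(belief$grid, mass)
}

#' Run the dynamic-learning-rate Bayesian learner over a choice sequence
#'
#' On every trial the learner predicts the agent's choice from its current
#' belief, observes the actual choice, and performs a Bayes + leak update.
#' The trialwise effective learning rate is
#' \code{alpha_t = |mu_post - mu_pre| / |delta_t|} with
#' \code{delta_t = observed_t - p_pred_t} the prediction error in
#' probability space: the weight placed on new information over the prior
#' belief. Because Bayesian updates scale with belief precision, alpha is
#' larger when the prior belief is less precise.
#'
#' @param params a \code{\link{learner_params}}.
#' @param trials a trial set.
#' @param choices logical vector of agent choices (chose harmful),
#'   \code{length(choices) == nrow(trials)}.
#' @param grid_size grid resolution (default 101).
#' @return a list with components \code{trace} (data.frame with columns
#'   \code{trial_index, p_pred, observed, delta, mu_pre, sigma_pre,
#'   mu_post, sigma_post, alpha}) and \code{final} (the final
#'   \code{"belief_state"}).
#' @export
run_learner <- function(params, trials, choices, grid_size = 101) {
  stopifnot(inherits(params, "learner_params"))
  .check_trials(trials)
  choices <- as.logical(choices)
  if (length(choices) != nrow(trials))
    stop("length(choices) must equal nrow(trials)")
  belief <- init_belief(params, grid_size)
  n <- nrow(trials)
  tr <- data.frame(
    trial_index = trials$trial_index,
    p_pred = numeric(n), observed = choices, delta = numeric(n),
    mu_pre = numeric(n), sigma_pre = numeric(n),
    mu_post = numeric(n), sigma_post = numeric(n), alpha = numeric(n)
  )
  if (n == 0L) return(list(trace = tr, final = belief))
  pmat <- choice_prob(belief$grid, params$beta, trials)  # G x n
  g <- length(belief$grid)
  mass <- belief$mass
  grid <- belief$grid
  for (t in seq_len(n)) {
    lk <- pmat[, t]
    p_pred <- sum(mass * lk)
    mu_pre <- sum(grid * mass)
    sd_pre <- sqrt(max(0, sum(mass * (grid - mu_pre)^2)))
    if (!choices[t]) lk <- 1 - lk
    post <- mass * lk
    post <- post / sum(post)
    mass <- (1 - params$lam) * post + params$lam / g
    mass <- mass / sum(mass)
    mu_post <- sum(grid * mass)
    sd_post <- sqrt(max(0, sum(mass * (grid - mu_post)^2)))
    delta <- as.numeric(choices[t]) - p_pred
    tr$p_pred[t] <- p_pred
    tr$delta[t] <- delta
    tr$mu_pre[t] <- mu_pre
    tr$sigma_pre[t] <- sd_pre
    tr$mu_post[t] <- mu_post
    tr$sigma_post[t] <- sd_post
    tr$alpha[t] <- learning_rate(mu_pre, mu_post, delta)
  }
  list(trace = tr, final = .new_belief(grid, mass))
}

#' Dynamic learning rate from a belief update
#'
#' \code{alpha = |mu_post - mu_pre| / |delta|}; defined as 0 when the
#' prediction error is (numerically) zero, i.e. the observation carried no
#' information.
#'
#' @param mu_pre,mu_post belief mean before and after the update.
#' @param delta prediction error in probability space.
#' @return the effective learning rate, >= 0.
#' @export
learning_rate <- function(mu_pre, mu_post, delta) {
  ifelse(abs(delta) < 1e-12, 0, abs(mu_post - mu_pre) / abs(delta))
}
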