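#' Define an agent's moral preference
#'
#' An agent in the moral inference task is characterized by a harm-aversion
#' exchange rate \code{kappa} in [0, 1] (how much money the agent requires
#' per shock inflicted; higher values mean the agent is more averse to
#' harming others for profit) and a choice consistency \code{beta >= 0}
#' (softmax inverse temperature).
#'
#' @param label agent label, \code{"good"} or \code{"bad"}.
#' @param kappa harm aversion in [0, 1].
#' @param beta choice consistency (inverse temperature), >= 0.
#' @return an object of class \code{"agent_spec"}.
#' @examples
#' good <- agent_spec("good", kappa = 0.7)
#' bad  <- agent_spec("bad",  kappa = 0.3)
#' @export
agent_spec <- function(label = c("good", "bad"), kappa, beta = 6) {
  label <- match.arg(label)
  if (!is.finite(kappa) || kappa < 0 || kappa > 1)
    stop("'kappa' must be a finite value in [0, 1]")
  if (!is.finite(beta) || beta < 0)
    stop("'beta' must be finite and >= 0")
  structure(list(label = label, kappa = kappa, beta = beta),
            class = "agent_spec")
}

#' @export
print.agent_spec <- function(x, ...) {
  cat(sprintf("<agent_spec> label=%s kappa=%.3f beta=%.2f\n",
              x$label, x$kappa, x$beta))
  invisible(x)
}

#' Generate a trial set for the moral inference task
#'
#' Each trial offers a choice between a harmful option (more money, more
#' shocks inflicted on a third party) and a helpful option (less money,
#' fewer shocks). Money and shock differences are rescaled by their
#' task-wide maxima so that the harm-aversion parameter kappa is a unitless
#' exchange rate comparable across trial sets; the rescaled differences are
#' stored in columns \code{dm} and \code{ds}.
#'
#' @param n_trials number of trials (>= 1).
#' @param variant_seed integer seed identifying the task variant; the same
#'   seed always yields the same trial sequence (matched participants share
#'   a variant).
#' @param money_max maximal money difference between options, in currency
#'   units (> 0).
#' @param shock_max maximal shock-count difference between options (>= 1).
#' @return a data.frame of class \code{"moral_trials"} with columns
#'   \code{trial_index}, \code{harmful_money}, \code{harmful_shocks},
#'   \code{helpful_money}, \code{helpful_shocks}, \code{dm}, \code{ds}.
#' @examples
#' tr <- generate_trial_set(10, variant_seed = 1)
#' stopifnot(all(tr$harmful_money > tr$helpful_money))
#' @export
generate_trial_set <- function(n_trials = 50, variant_seed = 1,
                               money_max = 10, shock_max = 20) {
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("'n_trials' must be >= 1")
  if (!is.finite(money_max) || money_max <= 0)
    stop("'money_max' must be > 0")
  if (!is.numeric(shock_max) || shock_max < 1)
    stop("'shock_max' must be >= 1")
  n_trials <- as.integer(n_trials)
  shock_max <- as.integer(shock_max)
  old <- .hold_seed()
  on.exit(.restore_seed(old))
  set.seed(as.integer(variant_seed))
  # differences span their ranges so both agents face easy and hard trials
  d_money <- stats::runif(n_trials, min = 0.05 * money_max, max = money_max)
  d_shock <- sample.int(shock_max, n_trials, replace = TRUE)
  helpful_money <- stats::runif(n_trials, 0, money_max / 2)
  helpful_shocks <- sample(0:3, n_trials, replace = TRUE)
  out <- data.frame(
    trial_index    = seq_len(n_trials),
    harmful_money  = helpful_money + d_money,
    harmful_shocks = helpful_shocks + d_shock,
    helpful_money  = helpful_money,
    helpful_shocks = helpful_shocks
  )
  out$dm <- d_money / max(d_money)
  out$ds <- d_shock / max(d_shock)
  class(out) <- c("moral_trials", "data.frame")
  out
}

# preserve/restore the caller's RNG state so variant generation does not
# perturb an enclosing simulation stream
.hold_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
}

.check_trials <- function(trials) {
  if (!is.data.frame(trials) ||
      !all(c("dm", "ds", "trial_index") %in% names(trials)))
    stop("'trials' must be a trial set from generate_trial_set() ",
         "(or a data.frame with dm/ds columns)")
  if (any(!is.finite(trials$dm)) || any(!is.finite(trials$ds)))
    stop("non-finite trial attributes")
  invisible(trials)
}

#' Probability that an agent picks the harmful option
#'
#' The agent values the harmful option relative to the helpful one as
#' \code{dV = (1 - kappa) * dm - kappa * ds}, where \code{dm} and \code{ds}
#' are the money and shock differences rescaled by their task-wide maxima,
#' and chooses the harmful option with probability
#' \code{plogis(beta * dV)}. For \code{kappa = 0.5} the agent is indifferent
#' exactly when \code{dm == ds}.
#'
#' @param kappa harm aversion in [0, 1] (scalar or vector).
#' @param beta choice consistency >= 0.
#' @param trials a trial set from \code{\link{generate_trial_set}}, or any
#'   data.frame with rescaled \code{dm}, \code{ds} columns.
#' @return if \code{kappa} is scalar, a vector of probabilities (one per
#'   trial); otherwise a \code{length(kappa) x nrow(trials)} matrix.
#' @examples
#' tr <- generate_trial_set(5, variant_seed = 1)
#' choice_prob(0.3, 6, tr) > choice_prob(0.7, 6, tr)  # bad agent harms more
#' @export
choice_prob <- function(kappa, beta, trials) {
  .check_trials(trials)
  if (any(!is.finite(kappa)) || any(kappa < 0) || any(kappa > 1))
    stop("'kappa' must be finite in [0, 1]")
  if (!is.finite(beta) || beta < 0)
    stop("'beta' must be finite and >= 0")
  dv <- outer(1 - kappa, trials$dm) - outer(kappa, trials$ds)
  p <- stats::plogis(beta * dv)
  if (length(kappa) == 1L) drop(p) else p
}

#' Simulate an agent's choices over a trial set
#'
#' Draws each choice independently as Bernoulli with probability
#' \code{choice_prob(agent$kappa, agent$beta, trials)}.
#'
#' @param agent an \code{\link{agent_spec}}.
#' @param trials a trial set.
#' @param seed integer seed; the choice sequence is reproducible given the
#'   seed.
#' @return logical vector \code{chose_harmful}, one element per trial.
#' @export
simulate_agent <- function(agent, trials, seed = 1) {
  stopifnot(inherits(agent, "agent_spec"))
  .check_trials(trials)
  p <- choice_prob(agent$kappa, agent$beta, trials)
  old <- .hold_seed()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  stats::runif(nrow(trials)) < p
}
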