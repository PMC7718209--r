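#' Assemble one participant's data for model fitting
#'
#' @param participant_id identifier.
#' @param group group label: \code{"BPD"}, \code{"non-BPD"} or \code{"DTC"}.
#' @param agents named list (names are agent labels, typically \code{bad}
#'   and \code{good}); each element a list with \code{trials} (trial set),
#'   \code{choices} (logical agent choices) and \code{predictions} (the
#'   participant's binary predictions, aligned with trials).
#' @param ratings optional data.frame of impression/certainty ratings.
#' @param covariates optional list (e.g. \code{severity}, \code{medication}).
#' @param variant_seed task-variant seed this participant saw.
#' @return an object of class \code{"participant_data"}.
#' @export
participant_data <- function(participant_id, group, agents, ratings = NULL,
                             covariates = list(), variant_seed = NA_integer_) {
  group <- as.character(group)
  if (!group %in% c("BPD", "non-BPD", "DTC"))
    stop("unknown group label: ", group)
  if (!is.list(agents) || is.null(names(agents)) || length(agents) < 1)
    stop("'agents' must be a named list")
  for (nm in names(agents)) {
    a <- agents[[nm]]
    .check_trials(a$trials)
    if (length(a$choices) != nrow(a$trials) ||
        length(a$predictions) != nrow(a$trials))
      stop("choices/predictions misaligned with trials for agent ", nm)
  }
  structure(list(participant_id = participant_id, group = group,
                 agents = agents, ratings = ratings,
                 covariates = covariates, variant_seed = variant_seed),
            class = "participant_data")
}

# predicted-harmful sequence of the dynamic learner, lean inner loop.
# pmat is the G x T matrix of grid choice probabilities.
.ppred_dynamic <- function(mu0, sigma0, lam, grid, pmat) {
  .dyn_traj(mu0, sigma0, lam, grid, pmat)$p_pred
}

# belief trajectory of the dynamic learner: predicted probabilities plus
# posterior mean/sd after each trial (index 0 = the prior itself)
.dyn_traj <- function(mu0, sigma0, lam, grid, pmat) {
  logd <- stats::dnorm(grid, mu0, sigma0, log = TRUE)
  mass <- exp(logd - max(logd))
  mass <- mass / sum(mass)
  g <- length(grid)
  nt <- ncol(pmat)
  p_pred <- numeric(nt)
  mu <- numeric(nt + 1)
  sd_ <- numeric(nt + 1)
  mu[1] <- sum(grid * mass)
  sd_[1] <- sqrt(max(0, sum(mass * (grid - mu[1])^2)))
  for (t in seq_len(nt)) {
    lk <- pmat[, t]
    p_pred[t] <- sum(mass * lk)
    if (!attr(pmat, "choices")[t]) lk <- 1 - lk
    post <- mass * lk
    post <- post / sum(post)
    mass <- (1 - lam) * post + lam / g
    mu[t + 1] <- sum(grid * mass)
    sd_[t + 1] <- sqrt(max(0, sum(mass * (grid - mu[t + 1])^2)))
  }
  list(p_pred = p_pred, mu = mu, sd = sd_)
}

# Gaussian log-likelihood terms tying the belief trajectory to the
# impression (0-100, scaled by 100) and certainty (1 - sd / 0.5) rating
# streams; `ratings` has columns trial_index, impression, certainty
.rating_nll <- function(traj, ratings, rating_noise) {
  idx <- ratings$trial_index + 1L   # trajectory is 0-based
  mu_hat <- traj$mu[idx]
  cer_hat <- 1 - traj$sd[idx] / 0.5
  sum(((ratings$impression / 100 - mu_hat)^2 +
         (ratings$certainty - cer_hat)^2) / (2 * rating_noise^2))
}

.ppred_fixed <- function(kappa0, a_neg, a_pos, beta, dm, ds, choices) {
  k <- kappa0
  nt <- length(dm)
  p_pred <- numeric(nt)
  for (t in seq_len(nt)) {
    p <- stats::plogis(beta * ((1 - k) * dm[t] - k * ds[t]))
    p_pred[t] <- p
    a <- if (choices[t]) a_neg else a_pos
    k <- min(1, max(0, k - a * (as.numeric(choices[t]) - p)))
  }
  p_pred
}

.bernoulli_nll <- function(p_pred, predictions, lapse) {
  q <- (1 - 2 * lapse) * p_pred + lapse
  -sum(ifelse(predictions, log(q), log1p(-q)))
}

#' Negative log-likelihood of a participant's trialwise predictions
#'
#' The participant is modelled as predicting the harmful option with
#' probability \code{q_t = (1 - 2 * lapse) * p_pred_t + lapse}, where
#' \code{p_pred_t} is the candidate model's predicted probability on trial
#' t; \code{lapse} is the asymptote of the response function (at
#' \code{lapse = 0.5} responding is pure chance). It keeps the likelihood
#' finite when the model is certain and the participant disagrees. The nll is
#' summed over all agents' trial sequences.
#'
#' @param model_id \code{"dynamic"}, \code{"fixed"} or \code{"valenced"}.
#' @param params named list of model parameters. Dynamic: \code{mu0},
#'   \code{sigma0} (scalars, or vectors named by agent label), \code{beta},
#'   \code{lam}. Fixed/valenced: \code{kappa_hat0}, \code{alpha_fixed} or
#'   \code{alpha_neg}/\code{alpha_pos}, \code{beta}.
#' @param data a \code{\link{participant_data}} object.
#' @param lapse lapse probability in [0, 0.5].
#' @param grid_size grid resolution for the dynamic model.
#' @return the negative log-likelihood (scalar, >= 0).
#' @export
prediction_nll <- function(model_id = c("dynamic", "fixed", "valenced"),
                           params, data, lapse = 0.02, grid_size = 101) {
  model_id <- match.arg(model_id)
  stopifnot(inherits(data, "participant_data"))
  if (!is.finite(lapse) || lapse < 0 || lapse > 0.5)
    stop("'lapse' must be in [0, 0.5]")
  nll <- 0
  grid <- seq(0, 1, length.out = grid_size)
  for (nm in names(data$agents)) {
    a <- data$agents[[nm]]
    ch <- as.logical(a$choices)
    if (model_id == "dynamic") {
      mu0 <- if (length(params$mu0) > 1) params$mu0[[nm]] else params$mu0
      s0 <- if (length(params$sigma0) > 1) params$sigma0[[nm]] else params$sigma0
      lam <- if (is.null(params$lam)) 0.1 else params$lam
      pmat <- choice_prob(grid, params$beta, a$trials)
      attr(pmat, "choices") <- ch
      p_pred <- .ppred_dynamic(mu0, s0, lam, grid, pmat)
    } else {
      a_neg <- if (model_id == "valenced") params$alpha_neg else params$alpha_fixed
      a_pos <- if (model_id == "valenced") params$alpha_pos else params$alpha_fixed
      p_pred <- .ppred_fixed(params$kappa_hat0, a_neg, a_pos, params$beta,
                             a$trials$dm, a$trials$ds, ch)
    }
    nll <- nll + .bernoulli_nll(p_pred, as.logical(a$predictions), lapse)
  }
  nll
}

# parameter vector layout for the optimizer, by model and config.
# prior_scheme: "shared" (one mu0/sigma0), "per_agent" (both per agent),
# "shared_mean" (one mu0, per-agent sigma0 — pins the prior location with
# both agents' evidence, which identifies the per-agent spreads)
.par_layout <- function(model_id, agent_names, fit_beta, prior_scheme) {
  if (model_id == "dynamic") {
    multi <- length(agent_names) > 1
    if (prior_scheme == "per_agent" && multi) {
      nm <- c(paste0("mu0_", agent_names), paste0("sigma0_", agent_names))
      lo <- c(rep(0.01, length(agent_names)), rep(0.01, length(agent_names)))
      hi <- c(rep(0.99, length(agent_names)), rep(1, length(agent_names)))
      st <- c(rep(0.5, length(agent_names)), rep(0.25, length(agent_names)))
    } else if (prior_scheme == "shared_mean" && multi) {
      nm <- c("mu0", paste0("sigma0_", agent_names))
      lo <- c(0.01, rep(0.01, length(agent_names)))
      hi <- c(0.99, rep(1, length(agent_names)))
      st <- c(0.5, rep(0.25, length(agent_names)))
    } else {
      nm <- c("mu0", "sigma0"); lo <- c(0.01, 0.01); hi <- c(0.99, 1)
      st <- c(0.5, 0.25)
    }
  } else if (model_id == "fixed") {
    nm <- c("kappa_hat0", "alpha_fixed"); lo <- c(0.01, 0); hi <- c(0.99, 1)
    st <- c(0.5, 0.2)
  } else {
    nm <- c("kappa_hat0", "alpha_neg", "alpha_pos")
    lo <- c(0.01, 0, 0); hi <- c(0.99, 1, 1); st <- c(0.5, 0.2, 0.2)
  }
  if (fit_beta) {
    nm <- c(nm, "beta"); lo <- c(lo, 0.1); hi <- c(hi, 20); st <- c(st, 5)
  }
  list(names = nm, lower = lo, upper = hi, start = st)
}

.par_to_list <- function(par, model_id, agent_names, fit_beta, beta,
                         prior_scheme, lam) {
  p <- as.list(par)
  out <- list(beta = if (fit_beta) p$beta else beta)
  if (model_id == "dynamic") {
    out$lam <- lam
    multi <- length(agent_names) > 1
    if (prior_scheme == "per_agent" && multi) {
      out$mu0 <- stats::setNames(unlist(p[paste0("mu0_", agent_names)]),
                                 agent_names)
      out$sigma0 <- stats::setNames(unlist(p[paste0("sigma0_", agent_names)]),
                                    agent_names)
    } else if (prior_scheme == "shared_mean" && multi) {
      out$mu0 <- p$mu0
      out$sigma0 <- stats::setNames(unlist(p[paste0("sigma0_", agent_names)]),
                                    agent_names)
    } else {
      out$mu0 <- p$mu0; out$sigma0 <- p$sigma0
    }
  } else if (model_id == "fixed") {
    out$kappa_hat0 <- p$kappa_hat0; out$alpha_fixed <- p$alpha_fixed
  } else {
    out$kappa_hat0 <- p$kappa_hat0
    out$alpha_neg <- p$alpha_neg; out$alpha_pos <- p$alpha_pos
  }
  out
}

#' Fit one model to one participant by maximum likelihood
#'
#' Bounded multi-start local optimization (\code{nlminb}) of
#' \code{\link{prediction_nll}}. Restart starting points are drawn
#' uniformly within the bounds from \code{seed}, so refitting with the
#' same seed reproduces the result exactly. Model evidence is approximated
#' as \code{-BIC / 2}.
#'
#' When \code{fit_beta = FALSE} and the model is dynamic, the grid
#' likelihood matrix is precomputed once per agent, which makes the fit
#' substantially cheaper; \code{beta} is then fixed at the supplied value
#' (the task's agents have a known design consistency).
#'
#' @param model_id \code{"dynamic"}, \code{"fixed"} or \code{"valenced"}.
#' @param data a \code{\link{participant_data}}.
#' @param n_restarts number of optimizer starts (default 10).
#' @param seed integer seed controlling the restart draws.
#' @param fit_beta fit the consistency parameter (default TRUE)?
#' @param beta value used when \code{fit_beta = FALSE}.
#' @param prior_scheme dynamic model only: \code{"shared_mean"} (default
#'   for multi-agent data; one prior mean, per-agent prior spread),
#'   \code{"per_agent"} (mean and spread per agent) or \code{"shared"}
#'   (one mean, one spread). The shared mean lets both agents' evidence
#'   streams pin down the prior location, which identifies the per-agent
#'   spreads.
#' @param grid_size,lam,lapse learner settings (see
#'   \code{\link{learner_params}} and \code{\link{prediction_nll}}).
#' @param use_ratings dynamic model only: augment the prediction
#'   likelihood with Gaussian likelihood terms for the impression and
#'   certainty rating streams (including the pre-task probe), which tie
#'   the belief mean and spread trajectories to their direct empirical
#'   readouts. The prior spread is weakly identified by binary
#'   predictions alone at task length; the certainty stream is its
#'   designed measurement.
#' @param rating_noise rating noise SD (unit scale) assumed by the rating
#'   likelihood.
#' @return an object of class \code{"fit_result"}: fitted \code{params},
#'   \code{nll}, \code{n_params}, \code{n_obs}, \code{AIC}, \code{BIC},
#'   \code{log_evidence}, convergence diagnostics.
#' @export
fit_participant <- function(model_id = c("dynamic", "fixed", "valenced"),
                            data, n_restarts = 10, seed = 1,
                            fit_beta = TRUE, beta = 6,
                            prior_scheme = c("shared_mean", "per_agent",
                                             "shared"),
                            grid_size = 101, lam = 0.1, lapse = 0.02,
                            use_ratings = FALSE, rating_noise = 0.05) {
  model_id <- match.arg(model_id)
  prior_scheme <- match.arg(prior_scheme)
  stopifnot(inherits(data, "participant_data"))
  agent_names <- names(data$agents)
  lay <- .par_layout(model_id, agent_names, fit_beta, prior_scheme)
  grid <- seq(0, 1, length.out = grid_size)

  # cache per-agent likelihood matrices when beta is fixed
  pmats <- NULL
  if (model_id == "dynamic" && !fit_beta) {
    pmats <- lapply(data$agents, function(a) {
      m <- choice_prob(grid, beta, a$trials)
      attr(m, "choices") <- as.logical(a$choices)
      m
    })
  }

  ratings_by_agent <- NULL
  if (use_ratings) {
    if (model_id != "dynamic")
      stop("'use_ratings' applies to the dynamic model only ",
           "(point-estimate models carry no belief spread)")
    if (is.null(data$ratings) || !nrow(data$ratings))
      stop("'use_ratings = TRUE' but the participant has no ratings")
    ratings_by_agent <- split(data$ratings, data$ratings$agent_label)
  }

  obj <- function(par) {
    names(par) <- lay$names
    pl <- .par_to_list(par, model_id, agent_names, fit_beta, beta,
                       prior_scheme, lam)
    if (model_id == "dynamic" && (use_ratings || !is.null(pmats))) {
      nll <- 0
      for (nm in agent_names) {
        mu0 <- if (length(pl$mu0) > 1) pl$mu0[[nm]] else pl$mu0
        s0 <- if (length(pl$sigma0) > 1) pl$sigma0[[nm]] else pl$sigma0
        pm <- if (!is.null(pmats)) pmats[[nm]] else {
          m <- choice_prob(grid, pl$beta, data$agents[[nm]]$trials)
          attr(m, "choices") <- as.logical(data$agents[[nm]]$choices)
          m
        }
        traj <- .dyn_traj(mu0, s0, lam, grid, pm)
        nll <- nll + .bernoulli_nll(
          traj$p_pred, as.logical(data$agents[[nm]]$predictions), lapse)
        if (use_ratings && !is.null(ratings_by_agent[[nm]]))
          nll <- nll + .rating_nll(traj, ratings_by_agent[[nm]],
                                   rating_noise)
      }
      nll
    } else {
      prediction_nll(model_id, pl, data, lapse = lapse,
                     grid_size = grid_size)
    }
  }

  old <- .hold_seed()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  k <- length(lay$names)
  starts <- rbind(lay$start,
                  matrix(stats::runif((n_restarts - 1) * k,
                                      rep(lay$lower, each = n_restarts - 1),
                                      rep(lay$upper, each = n_restarts - 1)),
                         ncol = k))
  best <- NULL
  n_conv <- 0L
  for (r in seq_len(nrow(starts))) {
    ans <- tryCatch(
      stats::nlminb(starts[r, ], obj, lower = lay$lower, upper = lay$upper,
                    control = list(iter.max = 300, eval.max = 500)),
      error = function(e) NULL)
    if (is.null(ans) || !is.finite(ans$objective)) next
    if (ans$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || ans$objective < best$objective) best <- ans
  }
  if (is.null(best))
    stop("all ", n_restarts, " restarts failed for model ", model_id,
         ", participant ", data$participant_id)
  par <- best$par
  names(par) <- lay$names
  n_obs <- sum(vapply(data$agents, function(a) nrow(a$trials), 0))
  nll <- best$objective
  structure(list(
    model_id = model_id,
    participant_id = data$participant_id,
    params = .par_to_list(par, model_id, agent_names, fit_beta, beta,
                          prior_scheme, lam),
    par = par,
    nll = nll,
    n_params = k,
    n_obs = n_obs,
    AIC = 2 * nll + 2 * k,
    BIC = 2 * nll + k * log(n_obs),
    log_evidence = -(2 * nll + k * log(n_obs)) / 2,
    converged = best$convergence == 0,
    n_restarts_converged = n_conv,
    n_restarts = n_restarts,
    fit_beta = fit_beta,
    settings = list(grid_size = grid_size, lam = lam, lapse = lapse,
                    prior_scheme = prior_scheme, beta_fixed = beta,
                    use_ratings = use_ratings)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s participant=%s nll=%.2f BIC=%.2f\n",
              x$model_id, as.character(x$participant_id), x$nll, x$BIC))
  invisible(x)
}

#' Log-evidence matrix across participants and models
#'
#' @param fits a list of \code{"fit_result"} objects covering every
#'   participant x model cell exactly once.
#' @param model_ids column order (default dynamic, fixed, valenced).
#' @return an N x K numeric matrix of log evidences, rownames participant
#'   ids, colnames model ids; participant order follows first appearance.
#' @export
evidence_matrix <- function(fits,
                            model_ids = c("dynamic", "fixed", "valenced")) {
  pid <- vapply(fits, function(f) as.character(f$participant_id), "")
  mid <- vapply(fits, function(f) f$model_id, "")
  ids <- unique(pid)
  out <- matrix(NA_real_, length(ids), length(model_ids),
                dimnames = list(ids, model_ids))
  for (i in seq_along(fits))
    out[pid[i], mid[i]] <- fits[[i]]$log_evidence
  if (any(is.na(out))) {
    miss <- which(is.na(out), arr.ind = TRUE)
    stop("missing fits for ", nrow(miss), " participant/model cell(s), e.g. ",
         ids[miss[1, 1]], " / ", model_ids[miss[1, 2]])
  }
  out
}
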