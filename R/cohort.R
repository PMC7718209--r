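#' Group-level generative profile for the synthetic cohort
#'
#' A profile describes the distribution of learner parameters and
#' covariates within one participant group. Per-agent prior means
#' (\code{mu0}) encode general expectations about moral character
#' (pessimism = lower values); per-agent prior spreads (\code{sigma0})
#' encode how uncertain — and therefore how updatable — beliefs about each
#' agent are.
#'
#' @param name group label: \code{"BPD"}, \code{"non-BPD"} or \code{"DTC"}.
#' @param n number of participants, >= 1.
#' @param mu0,sigma0 named numeric vectors (\code{bad}, \code{good}): group
#'   means of the prior-belief parameters.
#' @param mu0_sd,sigma0_sd between-participant SDs of the parameter draws.
#' @param beta,lam learner consistency and leak (shared within group).
#' @param rating_noise rating noise scale: certainty ratings get Gaussian
#'   noise with this SD, impression ratings with 100 times it.
#' @param severity mean/SD of the symptom-severity score, or NULL for
#'   groups that are not assessed.
#' @param medication_prob probability a participant is on psychotropic
#'   medication.
#' @return an object of class \code{"group_profile"}.
#' @export
group_profile <- function(name, n, mu0, sigma0,
                          mu0_sd = 0.05, sigma0_sd = 0.05,
                          beta = 6, lam = 0.02, rating_noise = 0.05,
                          severity = NULL, medication_prob = 0) {
  if (!name %in% c("BPD", "non-BPD", "DTC")) stop("unknown group: ", name)
  if (n < 1) stop("'n' must be >= 1")
  stopifnot(all(c("bad", "good") %in% names(mu0)),
            all(c("bad", "good") %in% names(sigma0)),
            all(mu0 >= 0 & mu0 <= 1), all(sigma0 > 0),
            mu0_sd >= 0, sigma0_sd >= 0, rating_noise >= 0,
            medication_prob >= 0, medication_prob <= 1)
  structure(list(name = name, n = as.integer(n), mu0 = mu0, sigma0 = sigma0,
                 mu0_sd = mu0_sd, sigma0_sd = sigma0_sd, beta = beta,
                 lam = lam, rating_noise = rating_noise,
                 severity = severity, medication_prob = medication_prob),
            class = "group_profile")
}

#' Default group profiles
#'
#' Encodes the qualitative phenotype generatively: controls and treated
#' patients hold more uncertain (hence more updatable) beliefs about the
#' bad agent than about the good agent; untreated patients show the
#' reverse asymmetry (certain, rigid beliefs about the bad agent, less
#' certain beliefs about the good agent) together with pessimistic prior
#' expectations; treated patients match the untreated profile except that
#' uncertainty about the bad agent is restored.
#'
#' @return a named list of three \code{\link{group_profile}} objects
#'   (BPD n = 20, non-BPD n = 106, DTC n = 23).
#' @export
default_profiles <- function() {
  list(
    "BPD" = group_profile("BPD", 20,
      mu0 = c(bad = 0.40, good = 0.40),
      sigma0 = c(bad = 0.18, good = 0.22),
      severity = c(mean = 41.4, sd = 8.8),
      medication_prob = 9 / 20),
    "non-BPD" = group_profile("non-BPD", 106,
      mu0 = c(bad = 0.50, good = 0.50),
      sigma0 = c(bad = 0.30, good = 0.15)),
    "DTC" = group_profile("DTC", 23,
      mu0 = c(bad = 0.40, good = 0.40),
      sigma0 = c(bad = 0.28, good = 0.18),
      severity = c(mean = 26.9, sd = 9.4),
      medication_prob = 11 / 23)
  )
}

#' Read out noisy impression and certainty ratings from a belief
#'
#' Impression maps the belief mean onto the 0 (nasty) to 100 (nice) scale;
#' certainty maps the belief SD onto 0 (very uncertain) to 1 (very
#' certain) via \code{1 - sigma / 0.5}, 0.5 being the maximal SD of a
#' distribution on [0, 1]. Gaussian noise (SD \code{noise_sd} on the
#' certainty scale, \code{100 * noise_sd} on the impression scale) is
#' added before clipping to the scale bounds.
#'
#' @param belief a \code{"belief_state"}.
#' @param noise_sd rating noise SD on the unit scale, >= 0.
#' @param seed optional integer seed; if NULL the current RNG stream is
#'   used.
#' @return a list with \code{impression} in [0, 100] and \code{certainty}
#'   in [0, 1].
#' @export
rate_beliefs <- function(belief, noise_sd = 0.05, seed = NULL) {
  stopifnot(inherits(belief, "belief_state"))
  if (!is.finite(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.null(seed)) {
    old <- .hold_seed()
    on.exit(.restore_seed(old))
    set.seed(as.integer(seed))
  }
  imp <- 100 * belief_mean(belief) + stats::rnorm(1, 0, 100 * noise_sd)
  cer <- 1 - belief_sd(belief) / 0.5 + stats::rnorm(1, 0, noise_sd)
  list(impression = min(100, max(0, imp)),
       certainty = min(1, max(0, cer)))
}

# default task agents: the good agent requires more money per shock
.default_agents <- function(beta = 6) {
  list(bad = agent_spec("bad", kappa = 0.3, beta = beta),
       good = agent_spec("good", kappa = 0.7, beta = beta))
}

#' Simulate one participant's full session
#'
#' Draws the participant's learner parameters from the group profile, then
#' plays the task: for each agent, the participant predicts each choice by
#' sampling from the dynamic learner's (lapse-mixed) predicted
#' probability, observes the agent's actual choice, and updates the
#' belief. A pre-task rating (trial index 0) probes the prior belief;
#' impression and certainty ratings follow every \code{rating_every}-th
#' trial. Trials and agent choices are keyed to \code{variant_seed} (they
#' are part of the task variant, so matched participants see identical
#' sequences); all participant-level randomness is keyed to
#' \code{participant_seed}.
#'
#' @param profile a \code{\link{group_profile}}.
#' @param variant_seed task-variant seed.
#' @param participant_seed participant-level seed.
#' @param participant_id identifier stored in the result.
#' @param n_trials trials per agent (default 50).
#' @param agents named list of \code{\link{agent_spec}}s (default: bad
#'   kappa 0.3, good kappa 0.7, beta 6).
#' @param grid_size belief grid resolution.
#' @param rating_every rating cadence in trials (default 3).
#' @param lapse participant lapse probability used when sampling
#'   predictions.
#' @return a \code{\link{participant_data}} object; \code{$ratings} holds
#'   rows (agent_label, trial_index, impression, certainty) with
#'   trial_index 0 the pre-task probe, and \code{$generative} records the
#'   drawn parameters.
#' @export
simulate_participant <- function(profile, variant_seed, participant_seed,
                                 participant_id = "p1", n_trials = 50,
                                 agents = .default_agents(),
                                 grid_size = 101, rating_every = 3,
                                 lapse = 0.02) {
  stopifnot(inherits(profile, "group_profile"))
  old <- .hold_seed()
  on.exit(.restore_seed(old))

  agent_names <- names(agents)
  blocks <- list()
  ratings <- list()
  gen <- list(beta = profile$beta, lam = profile$lam)

  # task variant: trials and agent choices are shared by matched
  # participants, so both derive from variant_seed only
  task <- lapply(seq_along(agents), function(i) {
    tr <- generate_trial_set(n_trials,
                             variant_seed = as.integer(variant_seed) + i - 1L)
    ch <- simulate_agent(agents[[i]], tr,
                         seed = as.integer(variant_seed) + 7919L * i)
    list(trials = tr, choices = ch)
  })
  names(task) <- agent_names

  set.seed(as.integer(participant_seed))
  for (nm in agent_names) {
    tr <- task[[nm]]$trials
    ch <- task[[nm]]$choices
    mu0 <- min(0.98, max(0.02,
      stats::rnorm(1, profile$mu0[[nm]], profile$mu0_sd)))
    s0 <- min(1, max(0.02,
      stats::rnorm(1, profile$sigma0[[nm]], profile$sigma0_sd)))
    gen[[paste0("mu0_", nm)]] <- mu0
    gen[[paste0("sigma0_", nm)]] <- s0
    params <- learner_params(mu0, s0, profile$beta, profile$lam)
    belief <- init_belief(params, grid_size)
    r0 <- rate_beliefs(belief, profile$rating_noise)
    ratings[[length(ratings) + 1L]] <- data.frame(
      agent_label = nm, trial_index = 0L,
      impression = r0$impression, certainty = r0$certainty)
    pmat <- choice_prob(belief$grid, profile$beta, tr)
    mass <- belief$mass
    grid <- belief$grid
    g <- length(grid)
    preds <- logical(nrow(tr))
    for (t in seq_len(nrow(tr))) {
      lk <- pmat[, t]
      q <- (1 - 2 * lapse) * sum(mass * lk) + lapse
      preds[t] <- stats::runif(1) < q
      if (!ch[t]) lk <- 1 - lk
      post <- mass * lk
      post <- post / sum(post)
      mass <- (1 - profile$lam) * post + profile$lam / g
      mass <- mass / sum(mass)
      if (t %% rating_every == 0L) {
        r <- rate_beliefs(.new_belief(grid, mass), profile$rating_noise)
        ratings[[length(ratings) + 1L]] <- data.frame(
          agent_label = nm, trial_index = t,
          impression = r$impression, certainty = r$certainty)
      }
    }
    blocks[[nm]] <- list(trials = tr, choices = ch, predictions = preds)
  }

  severity <- if (is.null(profile$severity)) NA_real_ else
    min(72, max(12, stats::rnorm(1, profile$severity[["mean"]],
                                 profile$severity[["sd"]])))
  medication <- stats::runif(1) < profile$medication_prob

  pd <- participant_data(
    participant_id = participant_id, group = profile$name,
    agents = blocks, ratings = do.call(rbind, ratings),
    covariates = list(severity = severity, medication = medication),
    variant_seed = as.integer(variant_seed))
  pd$generative <- gen
  pd
}

# MSI screening scores for the generated (post-screen) control sample:
# binomial(10, .2) truncated at the exclusion threshold of 6
.draw_msi <- function(n) {
  p <- stats::dbinom(0:6, 10, 0.2)
  sample(0:6, n, replace = TRUE, prob = p / sum(p))
}

#' Simulate a full synthetic cohort
#'
#' Generates the three groups from their profiles. Each untreated patient
#' is assigned a task variant shared with 5 matched controls (the control
#' group beyond 5x the patient count, and all treated patients, receive
#' fresh variants). Control participants carry McLean-screen scores drawn
#' below the exclusion threshold (the generator emulates the final,
#' post-screen sample).
#'
#' @param profiles list of \code{\link{group_profile}}s (default
#'   \code{\link{default_profiles}}).
#' @param seed master seed; everything downstream derives from it.
#' @param n_trials trials per agent.
#' @param match_controls share each BPD patient's variant with 5 controls
#'   (default TRUE)?
#' @param ... further arguments to \code{\link{simulate_participant}}.
#' @return an object of class \code{"cohort_dataset"}: \code{participants}
#'   (one row per participant: id, group, variant_seed, msi, severity,
#'   medication), \code{behavior} (long trial table with ratings), and
#'   \code{data} (list of \code{\link{participant_data}} objects keyed by
#'   id).
#' @export
simulate_cohort <- function(profiles = default_profiles(), seed = 1,
                            n_trials = 50, match_controls = TRUE, ...) {
  old <- .hold_seed()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  n_tot <- sum(vapply(profiles, function(p) p$n, 0L))
  pseeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  vpool <- sample.int(10^6, n_tot + 10L)

  n_bpd <- if ("BPD" %in% names(profiles)) profiles[["BPD"]]$n else 0L
  bpd_variants <- vpool[seq_len(n_bpd)]
  vnext <- n_bpd

  rows <- list(); dat <- list(); idx <- 0L
  for (pf in profiles) {
    for (i in seq_len(pf$n)) {
      idx <- idx + 1L
      vs <- if (pf$name == "BPD") {
        bpd_variants[i]
      } else if (pf$name == "non-BPD" && match_controls &&
                 i <= 5L * n_bpd) {
        bpd_variants[(i - 1L) %/% 5L + 1L]
      } else {
        vnext <- vnext + 1L
        vpool[vnext]
      }
      id <- sprintf("%s_%03d", sub("-", "", pf$name), i)
      pd <- simulate_participant(pf, variant_seed = vs,
                                 participant_seed = pseeds[idx],
                                 participant_id = id,
                                 n_trials = n_trials, ...)
      msi <- if (pf$name == "non-BPD") .draw_msi(1) else NA_integer_
      rows[[idx]] <- data.frame(
        participant_id = id, group = pf$name, variant_seed = vs,
        msi = msi, severity = pd$covariates$severity,
        medication = pd$covariates$medication)
      pd$covariates$msi <- msi
      dat[[id]] <- pd
    }
  }
  participants <- do.call(rbind, rows)
  structure(list(participants = participants,
                 behavior = .behavior_table(dat),
                 data = dat),
            class = "cohort_dataset")
}

# long-format behavioral table (CSV schema) from participant_data objects
.behavior_table <- function(dat) {
  out <- lapply(dat, function(pd) {
    ag <- lapply(names(pd$agents), function(nm) {
      a <- pd$agents[[nm]]
      cbind(data.frame(participant_id = pd$participant_id,
                       agent_label = nm),
            a$trials,
            data.frame(agent_choice = a$choices,
                       prediction = a$predictions))
    })
    ag <- do.call(rbind, ag)
    if (!is.null(pd$ratings)) {
      r <- pd$ratings
      key <- paste(r$agent_label, r$trial_index)
      m <- match(paste(ag$agent_label, ag$trial_index), key)
      ag$impression <- r$impression[m]
      ag$certainty <- r$certainty[m]
      pre <- r[r$trial_index == 0L, , drop = FALSE]
      if (nrow(pre)) {
        pre_rows <- data.frame(
          participant_id = pd$participant_id,
          agent_label = pre$agent_label, trial_index = 0L,
          harmful_money = NA_real_, harmful_shocks = NA_real_,
          helpful_money = NA_real_, helpful_shocks = NA_real_,
          dm = NA_real_, ds = NA_real_,
          agent_choice = NA, prediction = NA,
          impression = pre$impression, certainty = pre$certainty)
        ag <- rbind(pre_rows, ag)
      }
    } else {
      ag$impression <- NA_real_
      ag$certainty <- NA_real_
    }
    ag
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Print method for cohort datasets
#' @param x a \code{"cohort_dataset"}.
#' @param ... ignored.
#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d participants (%s), %d behavior rows\n",
              nrow(x$participants),
              paste(sprintf("%s=%d", names(table(x$participants$group)),
                            table(x$participants$group)), collapse = ", "),
              nrow(x$behavior)))
  invisible(x)
}

#' Apply the McLean screening exclusion to a cohort
#'
#' Removes control (non-BPD) participants whose screening score exceeds 6
#' (clinically relevant symptom level); patient groups are never screened
#' out. The number of removed participants is reported via a message and
#' stored in the \code{"n_removed"} attribute.
#'
#' @param cohort a \code{"cohort_dataset"}; every non-BPD participant must
#'   have a non-missing \code{msi} score.
#' @return the filtered \code{"cohort_dataset"}.
#' @export
msi_screen <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  pt <- cohort$participants
  ctrl <- pt$group == "non-BPD"
  if (any(ctrl & is.na(pt$msi)))
    stop("missing McLean screening score for ",
         sum(ctrl & is.na(pt$msi)), " control participant(s)")
  drop <- ctrl & pt$msi > 6
  n_removed <- sum(drop)
  if (n_removed > 0) {
    keep_ids <- pt$participant_id[!drop]
    cohort$participants <- pt[!drop, , drop = FALSE]
    cohort$behavior <-
      cohort$behavior[cohort$behavior$participant_id %in% keep_ids, ,
                      drop = FALSE]
    cohort$data <- cohort$data[keep_ids]
  }
  message(n_removed, " control participant(s) removed by McLean screen")
  attr(cohort, "n_removed") <- n_removed
  cohort
}

#' Simulate a prediction-only panel for parameter and model recovery
#'
#' Generates participants from the dynamic learner under conditions chosen
#' for identifiability of the prior parameters: both agents are observed
#' with a single shared (mu0, sigma0) prior, and the learner runs without
#' leak, so the two agents' opposing evidence streams jointly pin down the
#' prior location and spread. True parameters are drawn uniformly from the
#' stated ranges.
#'
#' @param n_participants number of simulated participants.
#' @param seed master seed.
#' @param n_trials trials per agent (default 50, i.e. 100 predictions).
#' @param mu0_range,sigma0_range uniform ranges of the true parameters.
#' @param beta,lam,lapse learner settings used for generation (defaults:
#'   consistency 6, no leak, 2 percent lapse).
#' @param agents task agents (default bad kappa 0.3 / good kappa 0.7).
#' @param rating_every emit impression/certainty ratings every this many
#'   trials (plus the pre-task probe); 0 disables ratings.
#' @param rating_noise rating noise SD on the unit scale.
#' @return a list with \code{data} (list of
#'   \code{\link{participant_data}}) and \code{truth} (data.frame of true
#'   mu0, sigma0 per participant).
#' @export
simulate_learner_panel <- function(n_participants, seed = 1, n_trials = 50,
                                   mu0_range = c(0.25, 0.75),
                                   sigma0_range = c(0.05, 0.35),
                                   beta = 6, lam = 0, lapse = 0.02,
                                   agents = .default_agents(beta),
                                   rating_every = 3, rating_noise = 0.05) {
  old <- .hold_seed()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  trials <- lapply(seq_along(agents), function(i)
    generate_trial_set(n_trials, variant_seed = seed + 13L * i))
  names(trials) <- names(agents)
  choices <- lapply(names(agents), function(nm)
    simulate_agent(agents[[nm]], trials[[nm]],
                   seed = seed + 7919L * match(nm, names(agents))))
  names(choices) <- names(agents)
  dat <- list(); truth <- NULL
  for (i in seq_len(n_participants)) {
    mu0 <- stats::runif(1, mu0_range[1], mu0_range[2])
    s0 <- stats::runif(1, sigma0_range[1], sigma0_range[2])
    lp <- learner_params(mu0, s0, beta, lam)
    blocks <- list()
    ratings <- list()
    for (nm in names(agents)) {
      run <- run_learner(lp, trials[[nm]], choices[[nm]])
      q <- (1 - 2 * lapse) * run$trace$p_pred + lapse
      blocks[[nm]] <- list(trials = trials[[nm]], choices = choices[[nm]],
                           predictions = stats::runif(n_trials) < q)
      if (rating_every > 0) {
        idx <- c(0L, seq(rating_every, n_trials, by = rating_every))
        mu_t <- c(run$trace$mu_pre[1], run$trace$mu_post)
        sd_t <- c(run$trace$sigma_pre[1], run$trace$sigma_post)
        imp <- 100 * mu_t[idx + 1L] +
          stats::rnorm(length(idx), 0, 100 * rating_noise)
        cer <- 1 - sd_t[idx + 1L] / 0.5 +
          stats::rnorm(length(idx), 0, rating_noise)
        ratings[[nm]] <- data.frame(
          agent_label = nm, trial_index = idx,
          impression = pmin(100, pmax(0, imp)),
          certainty = pmin(1, pmax(0, cer)))
      }
    }
    id <- sprintf("sim_%03d", i)
    dat[[id]] <- participant_data(
      id, "non-BPD", blocks,
      ratings = if (length(ratings)) do.call(rbind, ratings))
    truth <- rbind(truth, data.frame(participant_id = id,
                                     mu0 = mu0, sigma0 = s0))
  }
  list(data = dat, truth = truth)
}
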