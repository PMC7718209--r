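#' Standardize a numeric vector to z-scores
#'
#' Centers to mean 0 and scales to sample SD 1 over the analysis sample.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @return the z-scored vector.
#' @export
standardize <- function(x) {
  if (length(unique(x[is.finite(x)])) < 2)
    stop("cannot standardize a constant input")
  (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
}

#' Reverse-score certainty ratings to uncertainty
#'
#' @param certainty values in [0, 1] (0 = very uncertain, 1 = very
#'   certain).
#' @return \code{1 - certainty}: higher values indicate greater
#'   uncertainty.
#' @export
reverse_uncertainty <- function(certainty) {
  ok <- is.na(certainty) | (certainty >= 0 & certainty <= 1)
  if (!all(ok)) stop("certainty ratings must lie in [0, 1]")
  1 - certainty
}

#' Build the long analysis table from a fitted cohort
#'
#' Produces the measure table entering the group-level regressions: per
#' participant x agent x trial, the fitted dynamic model's learning rate
#' and belief spread (model uncertainty), and per rating trial the
#' impression and the reverse-scored certainty (subjective uncertainty).
#' Learning rates are standardized across the full analysis sample.
#'
#' @param cohort a \code{"cohort_dataset"}.
#' @param fits list of dynamic-model \code{"fit_result"}s (one per
#'   participant, named or carrying participant ids).
#' @return a data.frame with columns participant_id, group, agent,
#'   trial_index, measure (\code{learning_rate},
#'   \code{model_uncertainty}, \code{impression}, \code{uncertainty}),
#'   value, severity, medication.
#' @export
analysis_table <- function(cohort, fits) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  fid <- vapply(fits, function(f) as.character(f$participant_id), "")
  rows <- list()
  for (f in fits) {
    pd <- cohort$data[[as.character(f$participant_id)]]
    if (is.null(pd)) stop("fit for unknown participant ", f$participant_id)
    sev <- pd$covariates$severity
    med <- pd$covariates$medication
    for (nm in names(pd$agents)) {
      a <- pd$agents[[nm]]
      mu0 <- if (length(f$params$mu0) > 1) f$params$mu0[[nm]] else f$params$mu0
      s0 <- if (length(f$params$sigma0) > 1) f$params$sigma0[[nm]] else
        f$params$sigma0
      lp <- learner_params(mu0, s0, f$params$beta, f$params$lam)
      run <- run_learner(lp, a$trials, a$choices,
                         grid_size = f$settings$grid_size)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pd$participant_id, group = pd$group, agent = nm,
        trial_index = run$trace$trial_index,
        measure = "learning_rate", value = run$trace$alpha,
        severity = sev, medication = med)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pd$participant_id, group = pd$group, agent = nm,
        trial_index = run$trace$trial_index,
        measure = "model_uncertainty", value = run$trace$sigma_post,
        severity = sev, medication = med)
    }
    if (!is.null(pd$ratings)) {
      r <- pd$ratings[pd$ratings$trial_index > 0, , drop = FALSE]
      if (nrow(r)) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pd$participant_id, group = pd$group,
          agent = r$agent_label, trial_index = r$trial_index,
          measure = "impression", value = r$impression,
          severity = sev, medication = med)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pd$participant_id, group = pd$group,
          agent = r$agent_label, trial_index = r$trial_index,
          measure = "uncertainty",
          value = reverse_uncertainty(r$certainty),
          severity = sev, medication = med)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  lr <- out$measure == "learning_rate"
  out$value[lr] <- standardize(out$value[lr])
  out
}

#' Robust bisquare regression of a measure on agent, group and trial
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685, scale from the median absolute deviation; the
#' standard 95-percent-efficiency choice), via \code{MASS::rlm}. The model
#' is \code{value ~ agent * group + trial_index} with treatment (dummy)
#' coding: agent has \code{good} as baseline so the \code{agentbad}
#' coefficient is the bad-minus-good effect, and the group reference is
#' configurable. If the initial least-squares fit leaves (numerically)
#' zero residual scale the OLS solution is returned with unit weights.
#'
#' @param table an analysis table (see \code{\link{analysis_table}}).
#' @param measure which measure to analyze.
#' @param reference_group baseline group for the dummy coding.
#' @param include_trial control for trial number (default TRUE).
#' @param covariates optional character vector of additional main-effect
#'   terms present in the table (e.g. \code{"medication"}).
#' @param moderators optional character vector; each m adds
#'   \code{m + agent:m} terms (e.g. severity moderation).
#' @param aggregate average values per participant x agent before fitting
#'   (drops the trial term).
#' @param subset_groups optional subset of groups to include.
#' @return a \code{"coef_table"} data.frame: term, estimate, se, t, p,
#'   n_obs; attributes carry the converged flag and weights.
#' @export
robust_fit <- function(table, measure, reference_group = "BPD",
                       include_trial = TRUE, covariates = NULL,
                       moderators = NULL, aggregate = FALSE,
                       subset_groups = NULL) {
  d <- table[table$measure == measure, , drop = FALSE]
  if (!nrow(d)) stop("no rows for measure '", measure, "'")
  if (!is.null(subset_groups)) d <- d[d$group %in% subset_groups, , drop = FALSE]
  d <- d[is.finite(d$value), , drop = FALSE]
  if (!reference_group %in% d$group)
    stop("reference group '", reference_group, "' not present")
  d$agent <- factor(d$agent, levels = c("good", "bad"))
  d$group <- stats::relevel(factor(d$group), ref = reference_group)
  if (aggregate) {
    agg <- stats::aggregate(
      d["value"],
      by = d[c("participant_id", "group", "agent", covariates, moderators)],
      FUN = mean)
    d <- agg
    include_trial <- FALSE
  }
  terms <- c("agent", "group", "agent:group",
             if (include_trial) "trial_index",
             covariates,
             unlist(lapply(moderators, function(m) c(m, paste0("agent:", m)))))
  fml <- stats::reformulate(terms, response = "value")
  drop_single <- nlevels(droplevels(d$group)) < 2
  if (drop_single)  # single-group table: agent (+ moderators) only
    fml <- stats::reformulate(setdiff(terms, c("group", "agent:group")),
                              response = "value")
  mm <- stats::model.matrix(fml, d)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  ols <- stats::lm(fml, data = d)
  if (stats::mad(stats::residuals(ols)) < 1e-10) {
    est <- stats::coef(ols)
    sm <- suppressWarnings(summary(ols))$coefficients
    fit_df <- nrow(d) - length(est)
    out <- data.frame(term = names(est), estimate = est,
                      se = sm[, 2], t = sm[, 3],
                      p = 2 * stats::pt(-abs(sm[, 3]), fit_df),
                      n_obs = nrow(d))
  } else {
    rf <- MASS::rlm(fml, data = d, psi = MASS::psi.bisquare,
                    scale.est = "MAD", maxit = 100)
    if (!rf$converged)
      warning("robust IRLS did not converge in 100 iterations; ",
              "returning last iterate")
    sm <- summary(rf)$coefficients
    fit_df <- nrow(d) - nrow(sm)
    out <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      se = sm[, 2], t = sm[, 3],
                      p = 2 * stats::pt(-abs(sm[, 3]), fit_df),
                      n_obs = nrow(d))
    attr(out, "converged") <- rf$converged
  }
  rownames(out) <- NULL
  attr(out, "measure") <- measure
  attr(out, "reference_group") <- reference_group
  class(out) <- c("coef_table", "data.frame")
  out
}

#' Look up one coefficient from a coefficient table
#'
#' @param ct a \code{"coef_table"}.
#' @param term exact term name as it appears in the table.
#' @return a one-row data.frame (estimate, se, t, p).
#' @export
coef_term <- function(ct, term) {
  i <- match(term, ct$term)
  if (is.na(i)) stop("term '", term, "' not in table; have: ",
                     paste(ct$term, collapse = ", "))
  ct[i, , drop = FALSE]
}

#' Wilcoxon rank-sum test with z statistic
#'
#' Two-sided rank-sum test using midranks for ties. The p-value is exact
#' (from the null rank-sum distribution) when both samples are small and
#' tie-free, otherwise from the normal approximation with tie and
#' continuity corrections. The z statistic (always reported, normal
#' approximation) is positive when sample a tends to exceed sample b.
#'
#' @param a,b numeric samples (nonempty).
#' @param exact_max use the exact distribution when \code{length(a) +
#'   length(b)} is at most this and there are no ties (default 50).
#' @return a list: \code{z}, \code{p.value}, \code{W} (rank sum of a),
#'   \code{U}, \code{method}.
#' @export
ranksum_test <- function(a, b, exact_max = 50) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])          # rank sum of sample a
  u <- w - na * (na + 1) / 2        # Mann-Whitney U of a over b
  ties <- table(r)
  has_ties <- any(ties > 1)
  tie_term <- sum(ties^3 - ties)
  v <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  mu_u <- na * nb / 2
  if (v <= 0) return(list(z = 0, p.value = 1, W = w, U = u,
                          method = "degenerate (all values tied)"))
  z <- (u - mu_u - sign(u - mu_u) * 0.5) / sqrt(v)
  if (abs(u - mu_u) <= 0.5) z <- 0
  if (!has_ties && n <= exact_max) {
    p <- if (u > mu_u) 2 * (1 - stats::pwilcox(u - 1, na, nb))
         else 2 * stats::pwilcox(u, na, nb)
    p <- min(1, p)
    method <- "exact rank-sum distribution"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie + continuity correction"
  }
  list(z = z, p.value = p, W = w, U = u, method = method)
}

#' Group-level phenotype report
#'
#' For each requested measure, fits the agent x group robust regression
#' twice — once with the untreated-patient reference (BPD), once with the
#' control reference (non-BPD) — plus per-agent simple-effect contrasts
#' (group differences within each agent's trials), and summarizes the
#' direction and significance of (i) the agent main effect in controls
#' (bad minus good), (ii) the BPD x agent interaction relative to
#' controls, and (iii) the DTC x agent interaction relative to untreated
#' patients.
#'
#' @param table an analysis table.
#' @param measures measures to report (default learning_rate,
#'   model_uncertainty, uncertainty, impression).
#' @param alpha significance level for the flags (default 0.05).
#' @param ... passed to \code{\link{robust_fit}} (e.g. \code{aggregate},
#'   \code{covariates}).
#' @return an object of class \code{"phenotype_report"}: per measure the
#'   two coefficient tables, simple effects, and a \code{signs} summary;
#'   serializable with \code{\link{report_to_json}}.
#' @export
phenotype_report <- function(table,
                             measures = c("learning_rate",
                                          "model_uncertainty",
                                          "uncertainty", "impression"),
                             alpha = 0.05, ...) {
  out <- list()
  for (m in measures) {
    if (!m %in% table$measure) {
      out[[m]] <- list(absent = TRUE)
      next
    }
    ref_bpd <- robust_fit(table, m, reference_group = "BPD", ...)
    ref_ctl <- robust_fit(table, m, reference_group = "non-BPD", ...)
    simple <- lapply(c(bad = "bad", good = "good"), function(ag) {
      d <- table[table$measure == m & table$agent == ag, , drop = FALSE]
      robust_fit_group_only(d, reference_group = "BPD", ...)
    })
    agent_ctl <- coef_term(ref_ctl, "agentbad")
    int_bpd <- coef_term(ref_ctl, "agentbad:groupBPD")
    int_dtc <- coef_term(ref_bpd, "agentbad:groupDTC")
    signs <- data.frame(
      effect = c("agent_bad_minus_good_controls",
                 "bpd_x_agent_vs_controls",
                 "dtc_x_agent_vs_bpd"),
      estimate = c(agent_ctl$estimate, int_bpd$estimate, int_dtc$estimate),
      p = c(agent_ctl$p, int_bpd$p, int_dtc$p))
    signs$sign <- sign(signs$estimate)
    signs$significant <- signs$p < alpha
    out[[m]] <- list(ref_bpd = ref_bpd, ref_non_bpd = ref_ctl,
                     simple_effects = simple, signs = signs)
  }
  structure(out, class = "phenotype_report", alpha = alpha)
}

# group contrast within one agent's rows: value ~ group (+ trial)
robust_fit_group_only <- function(table, reference_group = "BPD",
                                  include_trial = TRUE, aggregate = FALSE,
                                  ...) {
  d2 <- table[is.finite(table$value), , drop = FALSE]
  d2$group <- stats::relevel(factor(d2$group), ref = reference_group)
  if (aggregate) {
    d2 <- stats::aggregate(d2["value"],
                           by = d2[c("participant_id", "group")], FUN = mean)
    include_trial <- FALSE
  }
  fml <- if (include_trial) value ~ group + trial_index else value ~ group
  ols <- stats::lm(fml, data = d2)
  if (stats::mad(stats::residuals(ols)) < 1e-10) {
    sm <- summary(ols)$coefficients
  } else {
    rf <- MASS::rlm(fml, data = d2, psi = MASS::psi.bisquare,
                    scale.est = "MAD", maxit = 100)
    sm <- summary(rf)$coefficients
    if (ncol(sm) == 3) sm <- cbind(sm, NA)
  }
  fit_df <- nrow(d2) - nrow(sm)
  out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    t = sm[, 3], p = 2 * stats::pt(-abs(sm[, 3]), fit_df),
                    n_obs = nrow(d2))
  rownames(out) <- NULL
  class(out) <- c("coef_table", "data.frame")
  out
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat("<phenotype_report>\n")
  for (m in names(x)) {
    if (isTRUE(x[[m]]$absent)) {
      cat(sprintf("  %s: absent\n", m))
      next
    }
    cat(sprintf("  %s:\n", m))
    s <- x[[m]]$signs
    for (i in seq_len(nrow(s)))
      cat(sprintf("    %-32s beta=% .3f p=%.4g%s\n", s$effect[i],
                  s$estimate[i], s$p[i],
                  if (s$significant[i]) " *" else ""))
  }
  invisible(x)
}

#' Serialize / restore a phenotype report as JSON
#'
#' @param report a \code{"phenotype_report"}.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  stripped <- lapply(report, function(m) {
    if (isTRUE(m$absent)) return(list(absent = TRUE))
    list(ref_bpd = as.data.frame(m$ref_bpd),
         ref_non_bpd = as.data.frame(m$ref_non_bpd),
         simple_effects = lapply(m$simple_effects, as.data.frame),
         signs = m$signs)
  })
  js <- jsonlite::toJSON(stripped, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
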