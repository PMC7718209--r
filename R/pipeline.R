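#' Default pipeline configuration
#'
#' A nested list mirroring the YAML config schema: task (n_trials, agent
#' kappas/beta), learner (grid_size, lam, lapse), fit (models, restarts,
#' fit_beta, seed), bms (alpha0, n_samples), stats (reference group,
#' aggregate flag), cohort profile overrides, and master seed.
#'
#' @return a named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    task = list(n_trials = 50L, kappa_good = 0.7, kappa_bad = 0.3,
                beta = 6),
    learner = list(grid_size = 101L, lam = 0.02, lapse = 0.02),
    fit = list(models = c("dynamic", "fixed", "valenced"),
               n_restarts = 5L, fit_beta = FALSE,
               prior_scheme = "per_agent", use_ratings = TRUE,
               rating_noise = 0.05),
    bms = list(alpha0 = 1, n_samples = 1e6),
    stats = list(reference_group = "BPD", aggregate = FALSE,
                 include_trial = TRUE),
    profiles = NULL
  )
}

.config_schema <- list(
  seed = "numeric", task = "list", learner = "list", fit = "list",
  bms = "list", stats = "list", profiles = "list"
)

# profile overrides from a config: a named list (group -> fields of
# group_profile) merged over the defaults. The group size is spelled
# n_participants in YAML (a bare `n` key is a YAML 1.1 boolean).
.profiles_from_config <- function(config) {
  pf <- default_profiles()
  if (is.null(config$profiles)) return(pf)
  for (g in names(config$profiles)) {
    if (!g %in% names(pf))
      stop("unknown profile group in config: '", g, "'")
    ov <- config$profiles[[g]]
    names(ov)[names(ov) == "n_participants"] <- "n"
    base <- pf[[g]]
    allowed <- setdiff(names(base), "name")
    bad <- setdiff(names(ov), allowed)
    if (length(bad))
      stop("unknown profile field: '", g, ".", bad[1], "'")
    for (f in names(ov)) {
      v <- ov[[f]]
      if (f %in% c("mu0", "sigma0")) v <- unlist(v)[c("bad", "good")]
      if (f == "severity") v <- unlist(v)[c("mean", "sd")]
      base[[f]] <- v
    }
    pf[[g]] <- group_profile(g, base$n, base$mu0, base$sigma0,
                             base$mu0_sd, base$sigma0_sd, base$beta,
                             base$lam, base$rating_noise, base$severity,
                             base$medication_prob)
  }
  pf
}

#' Read and validate a pipeline config
#'
#' Reads a YAML file, merges it over \code{\link{default_config}}, and
#' validates field names and types; unknown or ill-typed fields raise an
#' error naming the field.
#'
#' @param path YAML file path, or NULL for the defaults.
#' @return the validated config list, with a \code{config_hash} attribute
#'   (md5 of the canonical YAML serialization).
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    for (nm in names(user)) {
      if (!nm %in% names(.config_schema))
        stop("unknown config field: '", nm, "'")
      if (!inherits(user[[nm]], .config_schema[[nm]]) &&
          !(is.numeric(user[[nm]]) && .config_schema[[nm]] == "numeric"))
        stop("config field '", nm, "' must be ", .config_schema[[nm]])
      if (is.list(user[[nm]]) && !is.null(cfg[[nm]])) {
        bad <- setdiff(names(user[[nm]]), names(cfg[[nm]]))
        if (length(bad))
          stop("unknown config field: '", nm, ".", bad[1], "'")
        cfg[[nm]][names(user[[nm]])] <- user[[nm]]
      } else {
        cfg[[nm]] <- user[[nm]]
      }
    }
  }
  attr(cfg, "config_hash") <- .config_hash(cfg)
  cfg
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(out_dir, cfg, stage, extra = list()) {
  man <- c(list(stage = stage, seed = cfg$seed,
                config_hash = attr(cfg, "config_hash") %||% .config_hash(cfg),
                package_version = as.character(utils::packageVersion("moralinfer")),
                timestamp = format(Sys.time(), tz = "UTC")),
           extra)
  jsonlite::write_json(man, file.path(out_dir, paste0("manifest_", stage,
                                                      ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort and write it to CSV
#'
#' Writes \code{participants.csv}, \code{behavior.csv} and a stage
#' manifest (seed, config hash, package version) to \code{out_dir}.
#'
#' @param config a config list (see \code{\link{read_pipeline_config}}).
#' @param out_dir output directory (created if missing).
#' @return the \code{"cohort_dataset"}, invisibly.
#' @export
pipeline_simulate <- function(config = default_config(), out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  agents <- list(
    bad = agent_spec("bad", config$task$kappa_bad, config$task$beta),
    good = agent_spec("good", config$task$kappa_good, config$task$beta))
  cohort <- simulate_cohort(profiles = .profiles_from_config(config),
                            seed = config$seed,
                            n_trials = config$task$n_trials,
                            agents = agents,
                            grid_size = config$learner$grid_size,
                            lapse = config$learner$lapse)
  utils::write.csv(cohort$participants,
                   file.path(out_dir, "participants.csv"), row.names = FALSE)
  utils::write.csv(cohort$behavior,
                   file.path(out_dir, "behavior.csv"), row.names = FALSE)
  .write_manifest(out_dir, config, "simulate",
                  list(n_participants = nrow(cohort$participants)))
  invisible(cohort)
}

#' Read a cohort back from its CSV files
#'
#' Reconstructs the \code{"cohort_dataset"} (including the per-participant
#' fitting structures) from \code{participants.csv} and
#' \code{behavior.csv} as written by \code{\link{pipeline_simulate}}.
#'
#' @param dir directory containing the two CSV files.
#' @return a \code{"cohort_dataset"}.
#' @export
read_cohort_csv <- function(dir) {
  pf <- file.path(dir, "participants.csv")
  bf <- file.path(dir, "behavior.csv")
  if (!file.exists(pf) || !file.exists(bf))
    stop("missing cohort files in ", dir,
         " (need participants.csv and behavior.csv)")
  participants <- utils::read.csv(pf)
  behavior <- utils::read.csv(bf)
  dat <- list()
  for (i in seq_len(nrow(participants))) {
    id <- participants$participant_id[i]
    rows <- behavior[behavior$participant_id == id, , drop = FALSE]
    agents <- list()
    for (nm in unique(rows$agent_label)) {
      ar <- rows[rows$agent_label == nm & rows$trial_index > 0, ,
                 drop = FALSE]
      ar <- ar[order(ar$trial_index), , drop = FALSE]
      tr <- ar[c("trial_index", "harmful_money", "harmful_shocks",
                 "helpful_money", "helpful_shocks", "dm", "ds")]
      class(tr) <- c("moral_trials", "data.frame")
      agents[[nm]] <- list(trials = tr,
                           choices = as.logical(ar$agent_choice),
                           predictions = as.logical(ar$prediction))
    }
    rr <- rows[!is.na(rows$impression),
               c("agent_label", "trial_index", "impression", "certainty")]
    rr <- rr[order(rr$agent_label, rr$trial_index), , drop = FALSE]
    rownames(rr) <- NULL
    dat[[as.character(id)]] <- participant_data(
      participant_id = id, group = participants$group[i], agents = agents,
      ratings = rr,
      covariates = list(severity = participants$severity[i],
                        medication = participants$medication[i],
                        msi = participants$msi[i]),
      variant_seed = participants$variant_seed[i])
  }
  structure(list(participants = participants, behavior = behavior,
                 data = dat),
            class = "cohort_dataset")
}

#' Fit candidate models to every participant in a cohort
#'
#' Loops \code{\link{fit_participant}} over participants and models, with
#' optional per-participant resumability: finished fits are cached under
#' \code{cache_dir} and reloaded on a rerun, so an interrupted run picks
#' up where it stopped and yields the same results as a continuous one
#' (fits are seeded per participant).
#'
#' @param cohort a \code{"cohort_dataset"}.
#' @param models character vector of model ids.
#' @param config a config list.
#' @param cache_dir optional cache directory for resumability.
#' @param progress print a line every 25 participants.
#' @return a list of \code{"fit_result"} objects (participant-major
#'   order).
#' @export
fit_cohort <- function(cohort, models = c("dynamic", "fixed", "valenced"),
                       config = default_config(), cache_dir = NULL,
                       progress = FALSE) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (!is.null(cache_dir))
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$data)
  fits <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    pd <- cohort$data[[id]]
    for (m in models) {
      cache <- if (!is.null(cache_dir))
        file.path(cache_dir, paste0(id, "_", m, ".rds"))
      if (!is.null(cache) && file.exists(cache)) {
        fits[[paste0(id, ".", m)]] <- readRDS(cache)
        next
      }
      use_r <- m == "dynamic" && isTRUE(config$fit$use_ratings) &&
        !is.null(pd$ratings) && nrow(pd$ratings) > 0
      f <- tryCatch(
        fit_participant(m, pd,
                        n_restarts = config$fit$n_restarts,
                        seed = config$seed + i,
                        fit_beta = isTRUE(config$fit$fit_beta),
                        beta = config$task$beta,
                        prior_scheme = config$fit$prior_scheme %||%
                          "shared_mean",
                        grid_size = config$learner$grid_size,
                        lam = config$learner$lam,
                        lapse = config$learner$lapse,
                        use_ratings = use_r,
                        rating_noise = config$fit$rating_noise %||% 0.05),
        error = function(e) {
          warning("skipping participant ", id, " model ", m, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(f)) next
      if (!is.null(cache)) saveRDS(f, cache)
      fits[[paste0(id, ".", m)]] <- f
    }
    if (progress && i %% 25 == 0)
      message("fitted ", i, "/", length(ids), " participants")
  }
  fits
}

#' Run the full group-level analysis
#'
#' Runs random-effects model selection over the fitted evidences, the
#' best-model-by-group chi-square, the robust agent x group regressions
#' for every measure, the rank-sum comparisons of pre-task prior
#' expectations between groups, and assembles the phenotype report.
#' Writes BMS JSON, coefficient CSVs and the report (JSON + text) when
#' \code{out_dir} is given.
#'
#' @param cohort a \code{"cohort_dataset"}.
#' @param fits list of \code{"fit_result"}s covering all participants for
#'   at least the dynamic model; model selection uses whichever models are
#'   complete across participants.
#' @param config a config list.
#' @param out_dir optional output directory.
#' @return a list: \code{bms}, \code{best_counts}, \code{chi_square},
#'   \code{report}, \code{analysis_table}, \code{prior_expectation}.
#' @export
pipeline_analyze <- function(cohort, fits, config = default_config(),
                             out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  mids <- unique(vapply(fits, function(f) f$model_id, ""))
  dyn_fits <- Filter(function(f) f$model_id == "dynamic", fits)
  if (!length(dyn_fits)) stop("no dynamic-model fits supplied")
  fit_ids <- vapply(dyn_fits, function(f) as.character(f$participant_id), "")
  missing <- setdiff(names(cohort$data), fit_ids)
  if (length(missing))
    stop("participants without dynamic fits: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")

  bms <- NULL; counts <- NULL; chi <- NULL
  if (length(mids) >= 2) {
    ev <- evidence_matrix(fits, model_ids = mids)
    bms <- rfx_bms(ev, alpha0 = config$bms$alpha0,
                   n_samples = config$bms$n_samples, seed = config$seed)
    groups <- cohort$participants$group[
      match(rownames(ev), cohort$participants$participant_id)]
    counts <- best_model_counts(bms, groups)
    # the proportion comparison is undefined when one model class is empty
    chi <- tryCatch(chi_square_independence(counts),
                    error = function(e) NULL)
  }

  tab <- analysis_table(cohort, dyn_fits)
  report <- phenotype_report(
    tab, alpha = 0.05,
    aggregate = isTRUE(config$stats$aggregate),
    include_trial = isTRUE(config$stats$include_trial))

  # pre-task prior-expectation probes, compared pairwise across groups
  pre <- cohort$behavior[cohort$behavior$trial_index == 0 &
                           !is.na(cohort$behavior$impression), , drop = FALSE]
  pre <- stats::aggregate(pre[c("impression", "certainty")],
                          by = pre["participant_id"], FUN = mean)
  pre$group <- cohort$participants$group[
    match(pre$participant_id, cohort$participants$participant_id)]
  prior_tests <- list()
  pairs <- list(c("BPD", "non-BPD"), c("BPD", "DTC"))
  for (pr in pairs) {
    if (all(pr %in% pre$group)) {
      key <- paste0(pr[1], "_vs_", pr[2])
      prior_tests[[key]] <- list(
        impression = ranksum_test(pre$impression[pre$group == pr[1]],
                                  pre$impression[pre$group == pr[2]]),
        certainty = ranksum_test(pre$certainty[pre$group == pr[1]],
                                 pre$certainty[pre$group == pr[2]]))
    }
  }

  out <- list(bms = bms, best_counts = counts, chi_square = chi,
              report = report, analysis_table = tab,
              prior_expectation = prior_tests)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(bms)) {
      jsonlite::write_json(
        list(alpha = bms$alpha, expected_freq = bms$expected_freq,
             exceedance = bms$exceedance, converged = bms$converged),
        file.path(out_dir, "bms.json"), auto_unbox = TRUE, digits = NA)
      post <- data.frame(participant_id = rownames(bms$posterior),
                         bms$posterior, best = bms$best,
                         check.names = FALSE)
      utils::write.csv(post, file.path(out_dir, "bms_posteriors.csv"),
                       row.names = FALSE)
    }
    for (m in names(report)) {
      if (isTRUE(report[[m]]$absent)) next
      utils::write.csv(as.data.frame(report[[m]]$ref_bpd),
                       file.path(out_dir, paste0("coef_", m, ".csv")),
                       row.names = FALSE)
    }
    report_to_json(report, file.path(out_dir, "phenotype_report.json"))
    txt <- utils::capture.output(print(report))
    writeLines(txt, file.path(out_dir, "phenotype_report.txt"))
    .write_manifest(out_dir, config, "analyze")
  }
  out
}
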