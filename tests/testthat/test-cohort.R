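test_that("default profiles encode the group phenotypes", {
  pf <- default_profiles()
  ns <- vapply(pf, function(p) p$n, 0L)
  expect_equal(unname(ns[c("BPD", "non-BPD", "DTC")]), c(20L, 106L, 23L))
  # controls: beliefs about the bad agent are the more uncertain ones
  expect_gt(pf[["non-BPD"]]$sigma0[["bad"]], pf[["non-BPD"]]$sigma0[["good"]])
  expect_gt(pf[["DTC"]]$sigma0[["bad"]], pf[["DTC"]]$sigma0[["good"]])
  # untreated patients: reversed asymmetry relative to controls
  expect_lt(pf[["BPD"]]$sigma0[["bad"]], pf[["non-BPD"]]$sigma0[["bad"]])
  expect_gt(pf[["BPD"]]$sigma0[["good"]], pf[["non-BPD"]]$sigma0[["good"]])
  expect_lt(pf[["BPD"]]$sigma0[["bad"]], pf[["BPD"]]$sigma0[["good"]])
  # treatment restores bad-agent uncertainty, matches otherwise
  expect_gt(pf[["DTC"]]$sigma0[["bad"]], pf[["BPD"]]$sigma0[["bad"]])
  # pessimistic prior expectations in both patient groups
  expect_lt(pf[["BPD"]]$mu0[["bad"]], pf[["non-BPD"]]$mu0[["bad"]])
  expect_lt(pf[["BPD"]]$mu0[["good"]], pf[["non-BPD"]]$mu0[["good"]])
})

test_that("simulated participants are reproducible with correct cadence", {
  pf <- default_profiles()
  p1 <- simulate_participant(pf[["BPD"]], 5, 77, n_trials = 12)
  p2 <- simulate_participant(pf[["BPD"]], 5, 77, n_trials = 12)
  expect_identical(p1$agents, p2$agents)
  expect_identical(p1$ratings, p2$ratings)
  # ratings at 0 (pre-task) and every third trial
  r_bad <- p1$ratings[p1$ratings$agent_label == "bad", ]
  expect_equal(sort(r_bad$trial_index), c(0, 3, 6, 9, 12))
  expect_true(all(r_bad$impression >= 0 & r_bad$impression <= 100))
  expect_true(all(r_bad$certainty >= 0 & r_bad$certainty <= 1))
})

test_that("zero-variance profiles yield identical ratings across people", {
  pf <- group_profile("non-BPD", 2, mu0 = c(bad = 0.5, good = 0.5),
                      sigma0 = c(bad = 0.25, good = 0.15),
                      mu0_sd = 0, sigma0_sd = 0, rating_noise = 0)
  a <- simulate_participant(pf, 9, 1, n_trials = 9)
  b <- simulate_participant(pf, 9, 2, n_trials = 9)
  expect_equal(a$ratings, b$ratings)
})

test_that("rate_beliefs maps belief summaries onto the rating scales", {
  # point mass at kappa = 1: nicest possible, fully certain
  pt <- structure(list(grid = c(0.5, 1), mass = c(0, 1)),
                  class = "belief_state")
  r <- rate_beliefs(pt, noise_sd = 0)
  expect_equal(r$impression, 100)
  expect_equal(r$certainty, 1)
  # uniform belief: midpoint impression, certainty 1 - (1/sqrt(12))/0.5
  ub <- init_belief(learner_params(0.5, 1e3), grid_size = 401)
  r2 <- rate_beliefs(ub, noise_sd = 0)
  expect_equal(r2$impression, 50, tolerance = 0.01)
  expect_equal(r2$certainty, 1 - (1 / sqrt(12)) / 0.5, tolerance = 0.01)
  # deterministic without noise, reproducible with a seed
  expect_identical(rate_beliefs(pt, 0), rate_beliefs(pt, 0))
  expect_identical(rate_beliefs(ub, 0.1, seed = 4),
                   rate_beliefs(ub, 0.1, seed = 4))
  expect_error(rate_beliefs(pt, noise_sd = -1), "noise_sd")
})

test_that("cohort generation matches variants and sizes", {
  pf <- default_profiles()
  pf[["BPD"]]$n <- 4L; pf[["non-BPD"]]$n <- 22L; pf[["DTC"]]$n <- 5L
  co <- simulate_cohort(pf, seed = 3, n_trials = 6)
  expect_s3_class(co, "cohort_dataset")
  expect_equal(nrow(co$participants), 31)
  # each patient's variant seed appears for exactly 5 matched controls
  bpd_vs <- co$participants$variant_seed[co$participants$group == "BPD"]
  ctrl_vs <- co$participants$variant_seed[co$participants$group == "non-BPD"]
  for (v in bpd_vs) expect_equal(sum(ctrl_vs == v), 5)
  # the extra controls and the DTC group have their own variants
  expect_equal(sum(!ctrl_vs %in% bpd_vs), 22 - 20)
  dtc_vs <- co$participants$variant_seed[co$participants$group == "DTC"]
  expect_false(any(dtc_vs %in% bpd_vs))
  # matched participants saw identical trials and agent choices
  pid_b <- co$participants$participant_id[co$participants$group == "BPD"][1]
  pid_c <- co$participants$participant_id[
    co$participants$group == "non-BPD" &
      co$participants$variant_seed == bpd_vs[1]][1]
  expect_identical(co$data[[pid_b]]$agents$bad$trials,
                   co$data[[pid_c]]$agents$bad$trials)
  expect_identical(co$data[[pid_b]]$agents$bad$choices,
                   co$data[[pid_c]]$agents$bad$choices)
  # generated control screening scores sit below the exclusion threshold
  msi <- co$participants$msi[co$participants$group == "non-BPD"]
  expect_true(all(msi <= 6))
  # severity only assessed in patient groups
  expect_true(all(is.na(
    co$participants$severity[co$participants$group == "non-BPD"])))
  expect_true(all(!is.na(
    co$participants$severity[co$participants$group != "non-BPD"])))
})

test_that("the McLean screen removes controls above the threshold only", {
  pf <- default_profiles()
  pf[["BPD"]]$n <- 2L; pf[["non-BPD"]]$n <- 11L; pf[["DTC"]]$n <- 2L
  co <- simulate_cohort(pf, seed = 5, n_trials = 4)
  # construct raw scores straddling the threshold: 6 retained, 7 excluded
  ctrl <- co$participants$group == "non-BPD"
  co$participants$msi[ctrl] <- c(7, 6, 3, 0, 8, 5, 6, 7, 2, 1, 10)
  expect_message(sc <- msi_screen(co), "4 control")
  expect_equal(attr(sc, "n_removed"), 4)
  expect_equal(sum(sc$participants$group == "non-BPD"), 7)
  expect_equal(sum(sc$participants$group != "non-BPD"), 4)
  expect_true(all(sc$participants$msi[sc$participants$group == "non-BPD"] <= 6))
  expect_false(any(
    sc$behavior$participant_id %in%
      setdiff(co$participants$participant_id, sc$participants$participant_id)))
  # all below threshold: unchanged
  co$participants$msi[ctrl] <- 4
  expect_message(sc2 <- msi_screen(co), "0 control")
  expect_equal(nrow(sc2$participants), nrow(co$participants))
  # missing control score is an error
  co$participants$msi[which(ctrl)[1]] <- NA
  expect_error(msi_screen(co), "missing McLean")
})

test_that("learner panels are reproducible with stated truth ranges", {
  p1 <- simulate_learner_panel(3, seed = 8, n_trials = 10)
  p2 <- simulate_learner_panel(3, seed = 8, n_trials = 10)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$data, p2$data)
  expect_true(all(p1$truth$mu0 >= 0.25 & p1$truth$mu0 <= 0.75))
  expect_true(all(p1$truth$sigma0 >= 0.05 & p1$truth$sigma0 <= 0.35))
  expect_equal(length(p1$data[[1]]$agents), 2)
})
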