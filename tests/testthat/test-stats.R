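# build a small analysis-style table from explicit cell means
cell_table <- function(means, n_per = 4, noise = 0, seed = 1,
                       measure = "learning_rate") {
  set.seed(seed)
  rows <- list()
  for (g in names(means)) for (ag in c("bad", "good")) {
    for (i in seq_len(n_per)) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = paste0(g, "_", i), group = g, agent = ag,
        trial_index = 1L, measure = measure,
        value = means[[g]][[ag]] + rnorm(1, 0, noise),
        severity = NA_real_, medication = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("standardize produces exact z-scores and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(100, 5, 3)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(3, 10)), "constant")
})

test_that("reverse_uncertainty flips the certainty scale", {
  expect_equal(reverse_uncertainty(1), 0)
  expect_equal(reverse_uncertainty(0), 1)
  expect_equal(reverse_uncertainty(0.25), 0.75)
  x <- c(0.1, 0.9, 0.4)
  expect_equal(order(reverse_uncertainty(x)), rev(order(x)))
  expect_error(reverse_uncertainty(1.2), "\\[0, 1\\]")
})

test_that("robust_fit equals OLS on clean data and resists an outlier", {
  set.seed(7)
  n <- 60
  d <- data.frame(participant_id = paste0("p", 1:n),
                  group = rep(c("BPD", "non-BPD"), each = n / 2),
                  agent = rep(c("bad", "good"), n / 2),
                  trial_index = rep(1:5, length.out = n),
                  measure = "learning_rate",
                  severity = NA_real_, medication = FALSE)
  X <- model.matrix(~ factor(agent, c("good", "bad")) *
                      relevel(factor(group), "BPD") + trial_index, d)
  beta_true <- c(0.2, 0.5, 0.1, -0.3, 0.01)
  d$value <- drop(X %*% beta_true)   # exactly linear: residuals vanish
  ct <- robust_fit(d, "learning_rate", reference_group = "BPD")
  ols <- lm(value ~ factor(agent, c("good", "bad")) *
              relevel(factor(group), "BPD") + trial_index, d)
  expect_equal(unname(ct$estimate), unname(coef(ols)), tolerance = 1e-6)
  # with noise the bisquare fit stays close to OLS absent outliers
  d$value <- drop(X %*% beta_true) + rnorm(n, 0, 0.05)
  ct2 <- robust_fit(d, "learning_rate", reference_group = "BPD")
  ols2 <- lm(value ~ factor(agent, c("good", "bad")) *
               relevel(factor(group), "BPD") + trial_index, d)
  expect_equal(unname(ct2$estimate), unname(coef(ols2)), tolerance = 0.05)
  # one gross outlier: robust slope closer to the generating coefficients
  d$value[1] <- d$value[1] + 50
  ct3 <- robust_fit(d, "learning_rate", reference_group = "BPD")
  ols3 <- lm(value ~ factor(agent, c("good", "bad")) *
               relevel(factor(group), "BPD") + trial_index, d)
  err_rob <- sum((ct3$estimate - beta_true)^2)
  err_ols <- sum((coef(ols3) - beta_true)^2)
  expect_lt(err_rob, err_ols)
  # t = estimate / se throughout
  expect_equal(ct3$t, ct3$estimate / ct3$se, tolerance = 1e-8)
})

test_that("interaction coefficients recover noiseless cell-mean contrasts", {
  means <- list("BPD" = list(bad = 0.30, good = 0.25),
                "non-BPD" = list(bad = 0.60, good = 0.20),
                "DTC" = list(bad = 0.55, good = 0.22))
  tab <- cell_table(means)
  ct <- robust_fit(tab, "learning_rate", reference_group = "BPD",
                   include_trial = FALSE)
  # agentbad = bad - good in the reference (BPD) group
  expect_equal(coef_term(ct, "agentbad")$estimate, 0.05, tolerance = 1e-9)
  # interactions = difference-in-differences against BPD
  dd_ctl <- (0.60 - 0.20) - (0.30 - 0.25)
  dd_dtc <- (0.55 - 0.22) - (0.30 - 0.25)
  expect_equal(coef_term(ct, "agentbad:groupnon-BPD")$estimate, dd_ctl,
               tolerance = 1e-9)
  expect_equal(coef_term(ct, "agentbad:groupDTC")$estimate, dd_dtc,
               tolerance = 1e-9)
  # reference switch re-anchors the contrasts
  ct2 <- robust_fit(tab, "learning_rate", reference_group = "non-BPD",
                    include_trial = FALSE)
  expect_equal(coef_term(ct2, "agentbad:groupBPD")$estimate, -dd_ctl,
               tolerance = 1e-9)
  expect_error(robust_fit(tab, "nope"), "no rows")
})

test_that("robust_fit flags collinear designs by term name", {
  means <- list("BPD" = list(bad = 0.3, good = 0.2),
                "non-BPD" = list(bad = 0.5, good = 0.2))
  tab <- cell_table(means, noise = 0.01)
  tab$medication <- tab$group == "BPD"   # aliased with the group dummy
  expect_error(robust_fit(tab, "learning_rate", reference_group = "BPD",
                          include_trial = FALSE, covariates = "medication"),
               "collinear")
})

test_that("rank-sum test matches exact enumeration for small samples", {
  cases <- list(
    list(a = c(1, 2, 3), b = c(4, 5, 6)),
    list(a = c(1.5, 2.2, 9.1), b = c(0.3, 4.4, 5.5, 6.1)),
    list(a = c(10, 12), b = c(11, 13, 14, 9, 8, 15)),
    list(a = c(0.2, 0.9, 1.4, 2.2, 3.1), b = c(0.5, 1.1, 2.9, 3.3, 4.2))
  )
  for (cs in cases) {
    res <- ranksum_test(cs$a, cs$b)
    expect_equal(res$p.value, oracle_ranksum_exact(cs$a, cs$b),
                 tolerance = 1e-12)
  }
  # antisymmetry: order swap flips z, keeps p
  r1 <- ranksum_test(c(1, 5, 7), c(2, 3, 9, 11))
  r2 <- ranksum_test(c(2, 3, 9, 11), c(1, 5, 7))
  expect_equal(r1$z, -r2$z)
  expect_equal(r1$p.value, r2$p.value)
  # degenerate: fully tied samples
  r3 <- ranksum_test(rep(2, 4), rep(2, 5))
  expect_equal(r3$z, 0)
  expect_equal(r3$p.value, 1)
  # ties: normal approximation with tie correction agrees with wilcox.test
  a <- c(1, 2, 2, 3, 5); b <- c(2, 3, 3, 6, 7, 7)
  r4 <- ranksum_test(a, b)
  w <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(r4$p.value, w$p.value, tolerance = 1e-9)
  expect_error(ranksum_test(numeric(0), 1:3), "nonempty")
})

test_that("phenotype report summarizes directions and round-trips JSON", {
  means <- list("BPD" = list(bad = 0.28, good = 0.28),
                "non-BPD" = list(bad = 0.60, good = 0.20),
                "DTC" = list(bad = 0.55, good = 0.25))
  tab <- cell_table(means, n_per = 6, noise = 0.03)
  tab2 <- cell_table(lapply(means, lapply, function(x) 1 - x), n_per = 6,
                     noise = 0.03, seed = 2, measure = "uncertainty")
  rep_ <- phenotype_report(rbind(tab, tab2),
                           measures = c("learning_rate", "uncertainty",
                                        "impression"),
                           include_trial = FALSE)
  expect_true(isTRUE(rep_$impression$absent))
  s <- rep_$learning_rate$signs
  expect_equal(s$sign[s$effect == "agent_bad_minus_good_controls"], 1)
  expect_equal(s$sign[s$effect == "bpd_x_agent_vs_controls"], -1)
  expect_equal(s$sign[s$effect == "dtc_x_agent_vs_bpd"], 1)
  js <- report_to_json(rep_)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$learning_rate$signs$estimate, s$estimate,
               tolerance = 1e-9)
  tmp <- tempfile(fileext = ".json")
  report_to_json(rep_, tmp)
  expect_true(file.exists(tmp))
  expect_equal(jsonlite::fromJSON(tmp)$uncertainty$signs$sign,
               rep_$uncertainty$signs$sign)
})
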