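test_that("init_belief matches the truncated-Gaussian prior", {
  # flat-prior limit
  flat <- init_belief(learner_params(0.5, 100), grid_size = 51)
  expect_true(all(abs(flat$mass - 1 / 51) < 1e-4))
  expect_equal(belief_mean(flat), 0.5, tolerance = 1e-6)
  # symmetry about the prior mean
  sym <- init_belief(learner_params(0.5, 0.2), grid_size = 41)
  expect_equal(sym$mass, rev(sym$mass))
  # G = 3 hand computation: densities at 0, .5, 1 with mu0 = .5, s0 = .25
  b3 <- init_belief(learner_params(0.5, 0.25), grid_size = 3)
  d <- dnorm(c(0, 0.5, 1), 0.5, 0.25)
  expect_equal(b3$mass, d / sum(d), tolerance = 1e-12)
  # mean tracks mu0 for moderate priors
  for (m in c(0.2, 0.5, 0.8)) {
    b <- init_belief(learner_params(m, 0.15))
    expect_lt(abs(belief_mean(b) - m), 0.05)
  }
  expect_error(learner_params(0.5, 0), "sigma0")
  expect_error(init_belief(learner_params(0.5, 0.2), grid_size = 2),
               "grid_size")
})

test_that("predict_choice is the belief-weighted mixture of choice probs", {
  tr <- generate_trial_set(5, variant_seed = 4)
  # point mass: equals the member probability
  pt <- structure(list(grid = c(0.3, 0.7), mass = c(1, 0)),
                  class = "belief_state")
  expect_equal(predict_choice(pt, tr, 6), choice_prob(0.3, 6, tr))
  # beta 0: chance regardless of belief
  b <- init_belief(learner_params(0.3, 0.1))
  expect_equal(predict_choice(b, tr, 0), rep(0.5, 5))
  # two-point uniform: arithmetic mean of the two probabilities
  two <- structure(list(grid = c(0.3, 0.7), mass = c(0.5, 0.5)),
                   class = "belief_state")
  expect_equal(predict_choice(two, tr, 6),
               (choice_prob(0.3, 6, tr) + choice_prob(0.7, 6, tr)) / 2)
})

test_that("update_belief implements Bayes plus uniform leak", {
  tr1 <- generate_trial_set(1, variant_seed = 5)
  b <- init_belief(learner_params(0.4, 0.2), grid_size = 21)
  # flat likelihood (beta = 0), no leak: posterior = prior
  post <- update_belief(b, tr1, TRUE, beta = 0, lam = 0)
  expect_equal(post$mass, b$mass, tolerance = 1e-12)
  # full forgetting: uniform regardless of the data
  post1 <- update_belief(b, tr1, TRUE, beta = 6, lam = 1)
  expect_equal(post1$mass, rep(1 / 21, 21), tolerance = 1e-12)
  # two-point Bayes by hand
  two <- structure(list(grid = c(0.3, 0.7), mass = c(0.5, 0.5)),
                   class = "belief_state")
  lk <- drop(choice_prob(c(0.3, 0.7), 6, tr1))
  post2 <- update_belief(two, tr1, TRUE, beta = 6, lam = 0)
  expect_equal(post2$mass, lk * 0.5 / sum(lk * 0.5), tolerance = 1e-12)
  # harmful evidence never raises the belief mean (lam = 0)
  post3 <- update_belief(b, tr1, TRUE, beta = 6, lam = 0)
  expect_lte(belief_mean(post3), belief_mean(b))
  post4 <- update_belief(b, tr1, FALSE, beta = 6, lam = 0)
  expect_gte(belief_mean(post4), belief_mean(b))
})

test_that("mass stays normalized through init and update", {
  set.seed(42)
  tr <- generate_trial_set(200, variant_seed = 7)
  b <- init_belief(learner_params(0.45, 0.2), grid_size = 31)
  for (i in 1:200) {
    b <- update_belief(b, tr[i, ], runif(1) < 0.5, beta = runif(1, 0, 12),
                       lam = runif(1, 0, 0.3))
    expect_lt(abs(sum(b$mass) - 1), 1e-10)
  }
})

test_that("learning rate is zero for null updates and gated by uncertainty", {
  expect_equal(learning_rate(0.4, 0.4, 0.3), 0)
  expect_equal(learning_rate(0.4, 0.4, 0), 0)
  expect_equal(learning_rate(0.4, 0.5, -0.25), 0.4)
  # alpha strictly increases with prior spread, all else fixed (lam = 0)
  tr1 <- generate_trial_set(1, variant_seed = 13)
  alphas <- sapply(seq(0.05, 0.4, by = 0.05), function(s0) {
    r <- run_learner(learner_params(0.5, s0, 6, 0), tr1, TRUE)
    r$trace$alpha[1]
  })
  expect_true(all(diff(alphas) > 0))
})

test_that("run_learner matches the brute-force Bayes oracle", {
  set.seed(11)
  for (rep in 1:4) {
    g <- sample(3:5, 1)
    tt <- sample(5:10, 1)
    tr <- generate_trial_set(tt, variant_seed = 100 + rep)
    ch <- runif(tt) < 0.5
    mu0 <- runif(1, 0.2, 0.8); s0 <- runif(1, 0.1, 0.4)
    beta <- runif(1, 1, 10); lam <- sample(c(0, 0.1, 0.25), 1)
    run <- run_learner(learner_params(mu0, s0, beta, lam), tr, ch,
                       grid_size = g)
    orc <- oracle_bayes_loop(mu0, s0, beta, lam, tr$dm, tr$ds, ch, g)
    for (col in colnames(orc))
      expect_equal(run$trace[[col]], unname(orc[, col]), tolerance = 1e-12)
  }
})

test_that("run_learner handles edge sequences correctly", {
  tr <- generate_trial_set(10, variant_seed = 17)
  lp <- learner_params(0.5, 0.2, 6, 0)
  # empty sequence: empty trace, belief untouched
  r0 <- run_learner(lp, tr[0, ], logical(0))
  expect_equal(nrow(r0$trace), 0)
  expect_equal(r0$final$mass, init_belief(lp)$mass)
  # consistently harmful evidence: mean non-increasing
  r1 <- run_learner(lp, tr, rep(TRUE, 10))
  expect_true(all(diff(c(0.5, r1$trace$mu_post)) <= 1e-12))
  expect_error(run_learner(lp, tr, rep(TRUE, 9)), "length")
})

test_that("leak keeps uncertainty bounded away from zero in long runs", {
  tr <- generate_trial_set(300, variant_seed = 19)
  ch <- simulate_agent(agent_spec("bad", 0.3), tr, seed = 3)
  no_leak <- run_learner(learner_params(0.5, 0.25, 6, 0), tr, ch)
  leak <- run_learner(learner_params(0.5, 0.25, 6, 0.1), tr, ch)
  expect_lt(tail(no_leak$trace$sigma_post, 1), 0.05)
  expect_gt(tail(leak$trace$sigma_post, 1),
            2 * tail(no_leak$trace$sigma_post, 1))
  # informative observations typically shrink uncertainty without leak
  expect_true(mean(no_leak$trace$sigma_post <= no_leak$trace$sigma_pre) > 0.7)
})
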