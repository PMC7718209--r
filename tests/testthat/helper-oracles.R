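# Independent oracles used across tests. These deliberately avoid the
# package's internal code paths: scalar loops, no shared helpers.

# Brute-force grid Bayes loop: scalar arithmetic throughout.
oracle_bayes_loop <- function(mu0, sigma0, beta, lam, dm, ds, choices,
                              grid_size) {
  grid <- seq(0, 1, length.out = grid_size)
  mass <- numeric(grid_size)
  for (g in seq_len(grid_size))
    mass[g] <- exp(-(grid[g] - mu0)^2 / (2 * sigma0^2))
  mass <- mass / sum(mass)
  res <- list()
  for (t in seq_along(dm)) {
    p_pred <- 0
    for (g in seq_len(grid_size)) {
      pg <- 1 / (1 + exp(-beta * ((1 - grid[g]) * dm[t] - grid[g] * ds[t])))
      p_pred <- p_pred + mass[g] * pg
    }
    mu_pre <- sum(grid * mass)
    sd_pre <- sqrt(sum(mass * (grid - mu_pre)^2))
    new_mass <- numeric(grid_size)
    for (g in seq_len(grid_size)) {
      pg <- 1 / (1 + exp(-beta * ((1 - grid[g]) * dm[t] - grid[g] * ds[t])))
      lk <- if (choices[t]) pg else 1 - pg
      new_mass[g] <- mass[g] * lk
    }
    new_mass <- new_mass / sum(new_mass)
    for (g in seq_len(grid_size))
      new_mass[g] <- (1 - lam) * new_mass[g] + lam / grid_size
    new_mass <- new_mass / sum(new_mass)
    mu_post <- sum(grid * new_mass)
    sd_post <- sqrt(sum(new_mass * (grid - mu_post)^2))
    delta <- as.numeric(choices[t]) - p_pred
    res[[t]] <- c(p_pred = p_pred, delta = delta, mu_pre = mu_pre,
                  sigma_pre = sd_pre, mu_post = mu_post,
                  sigma_post = sd_post,
                  alpha = if (abs(delta) < 1e-12) 0 else
                    abs(mu_post - mu_pre) / abs(delta))
    mass <- new_mass
  }
  do.call(rbind, res)
}

# Exact two-sided rank-sum p by full enumeration of group assignments.
oracle_ranksum_exact <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  idx <- utils::combn(length(r), na)
  ws <- apply(idx, 2, function(i) sum(r[i]))
  mu <- mean(ws)
  min(1, sum(abs(ws - mu) >= abs(w_obs - mu) - 1e-9) / length(ws))
}

# Pearson chi-square statistic computed from the textbook formula.
oracle_pearson_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# single-block participant_data from raw pieces (test convenience)
make_participant <- function(id = "p1", trials, choices, predictions,
                             group = "non-BPD") {
  participant_data(id, group,
                   list(bad = list(trials = trials, choices = choices,
                                   predictions = predictions)))
}
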