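#' Random-effects Bayesian model selection
#'
#' Variational estimation of population model frequencies from a matrix of
#' per-participant log model evidences. The generating model is treated as
#' a random effect across participants with a Dirichlet population prior;
#' the fixed-point iteration alternates per-participant responsibilities
#' \code{g_nk} proportional to \code{exp(log evidence + digamma(alpha_k) -
#' digamma(sum alpha))} with the Dirichlet update \code{alpha = alpha0 +
#' colSums(g)}.
#'
#' @param ev N x K matrix of log evidences (rows = participants, columns =
#'   models); finite entries, K >= 2.
#' @param alpha0 Dirichlet prior count per model (scalar or length-K).
#' @param tol convergence tolerance on the alpha update (default 1e-6).
#' @param max_iter iteration cap (default 10000); non-convergence warns
#'   and returns the last iterate flagged.
#' @param n_samples Monte Carlo draws for exceedance probabilities.
#' @param seed seed for the exceedance draws.
#' @return an object of class \code{"bms_result"}: \code{alpha}
#'   (posterior Dirichlet counts), \code{expected_freq} (alpha normalized),
#'   \code{exceedance} (probability each model is the most frequent),
#'   \code{posterior} (N x K responsibilities), \code{best} (per-participant
#'   best model; ties broken toward \code{"dynamic"} then lexicographic),
#'   \code{converged}, \code{n_iter}.
#' @export
rfx_bms <- function(ev, alpha0 = 1, tol = 1e-6, max_iter = 10000,
                    n_samples = 1e6, seed = 1) {
  ev <- as.matrix(ev)
  if (ncol(ev) < 2) stop("need at least 2 models")
  if (nrow(ev) < 1) stop("need at least 1 participant")
  if (any(!is.finite(ev))) stop("log evidences must be finite")
  n <- nrow(ev); k <- ncol(ev)
  if (length(alpha0) == 1) alpha0 <- rep(alpha0, k)
  stopifnot(length(alpha0) == k, all(alpha0 > 0))
  alpha <- alpha0
  converged <- FALSE
  it <- 0L
  g <- matrix(1 / k, n, k)
  while (it < max_iter) {
    it <- it + 1L
    lw <- sweep(ev, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    g <- exp(lw)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  if (!converged)
    warning("rfx_bms did not converge in ", max_iter, " iterations")
  model_ids <- colnames(ev)
  if (is.null(model_ids)) model_ids <- paste0("model", seq_len(k))
  names(alpha) <- model_ids
  colnames(g) <- model_ids
  rownames(g) <- rownames(ev)
  best <- apply(g, 1, function(r) {
    top <- which(r >= max(r) - 1e-12)
    if (length(top) > 1 && "dynamic" %in% model_ids[top]) return("dynamic")
    model_ids[min(top)]
  })
  structure(list(
    alpha = alpha,
    expected_freq = alpha / sum(alpha),
    exceedance = exceedance_prob(alpha, n_samples = n_samples, seed = seed),
    posterior = g,
    best = best,
    model_ids = model_ids,
    converged = converged,
    n_iter = it
  ), class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>\n")
  print(round(rbind(expected_freq = x$expected_freq,
                    exceedance = x$exceedance), 4))
  invisible(x)
}

#' Exceedance probabilities of a Dirichlet frequency posterior
#'
#' Monte Carlo estimate of the probability that each model's population
#' frequency exceeds all others, from draws of the Dirichlet posterior.
#'
#' @param alpha Dirichlet parameters, all > 0.
#' @param n_samples number of draws (warns below 1000).
#' @param seed integer seed; the estimate is reproducible given the seed.
#' @return a probability vector summing to 1.
#' @export
exceedance_prob <- function(alpha, n_samples = 1e6, seed = 1) {
  stopifnot(all(alpha > 0))
  if (n_samples < 1000)
    warning("fewer than 1000 Monte Carlo samples; estimate will be noisy")
  k <- length(alpha)
  old <- .hold_seed()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  draws <- matrix(stats::rgamma(n_samples * k, shape = rep(alpha,
                                                           each = n_samples)),
                  nrow = n_samples)
  win <- max.col(draws, ties.method = "first")
  xp <- tabulate(win, nbins = k) / n_samples
  names(xp) <- names(alpha)
  xp
}

#' Contingency table of best-model assignment by group
#'
#' Tallies, per group, how many participants are best explained by the
#' dynamic-learning-rate model versus any other model.
#'
#' @param bms a \code{"bms_result"}.
#' @param groups group label per participant (same order as the evidence
#'   matrix rows); labels must be BPD, non-BPD or DTC.
#' @return a 3 x 2 integer matrix (rows = groups, columns =
#'   \code{dynamic}, \code{other}); row sums equal group sizes.
#' @export
best_model_counts <- function(bms, groups) {
  stopifnot(inherits(bms, "bms_result"))
  groups <- as.character(groups)
  if (length(groups) != length(bms$best))
    stop("one group label per participant required")
  levels <- c("BPD", "non-BPD", "DTC")
  if (!all(groups %in% levels))
    stop("unknown group label(s): ",
         paste(setdiff(groups, levels), collapse = ", "))
  gf <- factor(groups, levels = levels)
  dyn <- bms$best == "dynamic"
  out <- cbind(dynamic = tapply(dyn, gf, sum, default = 0L),
               other = tapply(!dyn, gf, sum, default = 0L))
  storage.mode(out) <- "integer"
  out
}

#' Pearson chi-square test of independence
#'
#' @param table an R x C matrix of nonnegative counts with positive
#'   margins.
#' @return a list with \code{statistic} (Pearson X^2, no continuity
#'   correction), \code{df} = (R-1)(C-1), and \code{p.value} from the
#'   chi-square upper tail.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(!is.finite(table)))
    stop("counts must be finite and nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all row and column margins must be positive")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value))
}
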