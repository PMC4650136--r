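#' Power-posterior temperature ladder
#'
#' Temperatures \code{beta_j = ((j-1)/(n_beta-1))^exponent},
#' \code{j = 1..n_beta}, running from exactly 0 (the prior) to exactly 1
#' (the posterior).  The default 30-rung, exponent-5 ladder concentrates
#' rungs near the prior, where the integrand of the thermodynamic
#' identity changes fastest.
#'
#' @param n_beta number of temperatures (>= 2).
#' @param exponent positive ladder exponent; 1 gives uniform spacing.
#' @return increasing numeric vector of temperatures.
#' @export
make_ladder <- function(n_beta = 30, exponent = 5) {
  if (n_beta < 2) stop("n_beta must be at least 2", call. = FALSE)
  if (exponent <= 0) stop("exponent must be positive", call. = FALSE)
  ((seq_len(n_beta) - 1) / (n_beta - 1))^exponent
}

#' Unnormalized log density of a power posterior
#'
#' \code{beta * loglik(theta) + logprior(theta)}: the bridging density
#' between prior (beta = 0) and posterior (beta = 1).
#'
#' @param theta parameter point.
#' @param beta inverse temperature in [0, 1].
#' @param loglik,logprior functions of \code{theta}.
#' @return scalar log density (unnormalized).
#' @export
power_logdensity <- function(theta, beta, loglik, logprior) {
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]", call. = FALSE)
  lp <- logprior(theta)
  if (!is.finite(lp)) return(-Inf)
  ll <- loglik(theta)
  if (beta == 0) lp else beta * ll + lp
}

#' Log acceptance probability of an exchange (swap) move
#'
#' Swapping the states of the chains at inverse temperatures
#' \code{beta_i} and \code{beta_j} preserves the product of power
#' posteriors when accepted with probability
#' \code{min(1, exp((beta_j - beta_i) * (ll_i - ll_j)))}, where the
#' \code{ll} are the cached log-likelihoods of the two states.
#'
#' @param beta_i,beta_j the two inverse temperatures.
#' @param ll_i,ll_j cached log-likelihoods of the states currently at
#'   those temperatures.
#' @return log acceptance probability (<= 0 after capping at 0).
#' @export
exchange_logaccept <- function(beta_i, beta_j, ll_i, ll_j) {
  min(0, (beta_j - beta_i) * (ll_i - ll_j))
}

#' Proposal covariances adapted from sampling history
#'
#' Per temperature, the proposal covariance is the empirical covariance
#' of the supplied history scaled by \code{2.38^2 / d} (the classical
#' random-walk optimum), plus a small diagonal jitter that keeps the
#' proposal full rank when the history is degenerate.  Used once, at the
#' burn-in boundary; the tuned covariances are then frozen for the
#' collection phase.
#'
#' @param history list (one element per temperature) of matrices of
#'   draws, rows = iterations, columns = parameters.
#' @param jitter diagonal jitter added to each covariance.
#' @return list of covariance matrices.
#' @export
adapt_proposals <- function(history, jitter = 1e-8) {
  lapply(history, function(h) {
    h <- as.matrix(h)
    d <- ncol(h)
    cv <- if (nrow(h) > d) stats::cov(h) else diag(0, d)
    if (any(!is.finite(cv))) cv <- diag(0, d)
    (2.38^2 / d) * cv + diag(jitter, d)
  })
}

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Between/within-variance convergence diagnostic computed per
#' coordinate from two or more chains of equal length.
#'
#' @param chains list of >= 2 matrices (iterations x parameters) of equal
#'   dimensions, one per independent chain.
#' @return numeric vector of PSRF values, one per parameter.
#' @export
psrf <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("psrf needs at least two chains", call. = FALSE)
  chains <- lapply(chains, as.matrix)
  dims <- vapply(chains, dim, integer(2))
  if (any(dims != dims[, 1])) stop("chains must have equal dimensions",
                                   call. = FALSE)
  n <- dims[1, 1]
  means <- vapply(chains, colMeans, numeric(dims[2, 1]))
  vars <- vapply(chains, function(x) apply(x, 2, var),
                 numeric(dims[2, 1]))
  means <- matrix(means, nrow = dims[2, 1])
  vars <- matrix(vars, nrow = dims[2, 1])
  w <- rowMeans(vars)
  b_over_n <- apply(means, 1, var)
  var_plus <- (n - 1) / n * w + b_over_n
  sqrt(var_plus / w)
}

#' Population MCMC over a ladder of power posteriors
#'
#' Runs one chain per temperature on the product target
#' \code{prod_i p_{beta_i}}, where each factor is
#' \code{exp(beta_i * loglik) * prior} with an independent standard
#' normal prior on the (log-scale) parameter vector.  Each iteration
#' performs one symmetric multivariate-normal Metropolis update per
#' temperature followed by one exchange attempt between a uniformly
#' chosen adjacent pair.  Proposals are isotropic during burn-in (with
#' the step size tuned toward a 30 % acceptance rate), then replaced at
#' the burn-in boundary by covariances adapted from the burn-in history
#' (\code{\link{adapt_proposals}}) and frozen for the collection phase.
#' Proposals where \code{loglik} is non-finite (e.g. a failed ODE
#' integration) are always rejected.
#'
#' @param loglik function(eta) -> scalar log-likelihood; eta lives in the
#'   unconstrained (log-parameter) space.
#' @param d dimension of eta.
#' @param ladder temperatures from \code{\link{make_ladder}}.
#' @param n_iter total iterations (burn-in included).
#' @param burn_frac fraction of iterations treated as burn-in.
#' @param thin retain every thin-th post-burn-in iteration.
#' @param prop_sd initial isotropic proposal standard deviation.
#' @param init optional d x n_beta matrix of starting points.  The
#'   default (\code{init_strategy = "best_of_prior"}) scores a batch of
#'   prior draws by log-likelihood and starts every chain at the best
#'   one: the high-temperature chains then begin inside the typical set
#'   of their targets instead of in the prior tails (where a cold start
#'   leaves them stuck for a long transient), while the low-temperature
#'   chains quickly diffuse back toward the prior.
#'   \code{init_strategy = "prior"} starts each chain at an independent
#'   prior draw with finite log-likelihood.
#' @param init_strategy see \code{init}.
#' @param n_init_candidates prior draws scored by the warm start.
#' @param n_exchange exchange attempts per iteration (each picks an
#'   adjacent pair uniformly at random); defaults to one sweep-worth,
#'   which costs nothing (no likelihood evaluations) and speeds up
#'   information flow along the ladder.
#' @param seed optional integer seed fixing the whole run.
#' @param log_every if positive, emit a progress line (iteration, mean
#'   local acceptance rate, exchange acceptance rate) via
#'   \code{message()} every \code{log_every} iterations.
#' @return object of class \code{th17_chains}: \code{draws} (array
#'   n_keep x d x n_beta), \code{loglik} (matrix n_keep x n_beta),
#'   \code{ladder}, per-temperature local acceptance rates, the exchange
#'   acceptance rate, and the frozen proposal covariances.
#' @export
power_mcmc <- function(loglik, d, ladder = make_ladder(),
                       n_iter = 5000, burn_frac = 0.5, thin = 10,
                       prop_sd = 0.3, init = NULL,
                       init_strategy = c("best_of_prior", "prior"),
                       n_init_candidates = 64, n_exchange = NULL,
                       seed = NULL, max_init_tries = 200,
                       log_every = 0) {
  if (!is.null(seed)) set.seed(seed)
  init_strategy <- match.arg(init_strategy)
  n_beta <- length(ladder)
  if (is.null(n_exchange)) n_exchange <- n_beta - 1L
  stopifnot(n_beta >= 2, d >= 1, n_iter >= 10)
  n_burn <- floor(n_iter * burn_frac)
  keep_iters <- seq(n_burn + thin, n_iter, by = thin)
  n_keep <- length(keep_iters)
  if (n_keep < 1) stop("no iterations retained; lower thin or burn_frac",
                       call. = FALSE)

  # state per temperature: eta, cached loglik and logprior
  eta <- matrix(NA_real_, d, n_beta)
  ll <- lp <- rep(-Inf, n_beta)
  if (!is.null(init)) {
    for (i in seq_len(n_beta)) {
      eta[, i] <- init[, i]
      ll[i] <- loglik(eta[, i]); lp[i] <- log_prior_eta(eta[, i])
      if (!is.finite(ll[i]))
        stop("supplied initial point has non-finite log-likelihood",
             call. = FALSE)
    }
  } else if (init_strategy == "best_of_prior") {
    best <- NULL; best_ll <- -Inf
    for (try in seq_len(n_init_candidates)) {
      cand <- rnorm(d)
      llc <- loglik(cand)
      if (llc > best_ll) { best <- cand; best_ll <- llc }
    }
    if (!is.finite(best_ll))
      stop("could not find a prior draw with finite log-likelihood",
           call. = FALSE)
    eta[] <- best
    ll[] <- best_ll
    lp[] <- log_prior_eta(best)
  } else {
    for (i in seq_len(n_beta)) {
      for (try in seq_len(max_init_tries)) {
        cand <- rnorm(d)
        llc <- loglik(cand)
        if (is.finite(llc)) {
          eta[, i] <- cand; ll[i] <- llc; lp[i] <- log_prior_eta(cand)
          break
        }
      }
      if (!is.finite(ll[i]))
        stop("could not find a prior draw with finite log-likelihood",
             call. = FALSE)
    }
  }

  draws <- array(NA_real_, c(n_keep, d, n_beta))
  ll_out <- matrix(NA_real_, n_keep, n_beta)
  burn_hist <- array(NA_real_, c(n_burn, d, n_beta))
  step_sd <- rep(prop_sd, n_beta)
  prop_chol <- vector("list", n_beta)   # NULL = isotropic phase
  acc_local <- att_local <- numeric(n_beta)
  batch_acc <- batch_att <- numeric(n_beta)
  acc_exch <- att_exch <- 0
  keep_ptr <- 1L
  batch <- 0L

  for (iter in seq_len(n_iter)) {
    for (i in seq_len(n_beta)) {
      z <- rnorm(d)
      prop <- if (is.null(prop_chol[[i]])) {
        eta[, i] + step_sd[i] * z
      } else {
        eta[, i] + drop(prop_chol[[i]] %*% z)
      }
      lp_p <- log_prior_eta(prop)
      ll_p <- loglik(prop)
      att_local[i] <- att_local[i] + 1
      batch_att[i] <- batch_att[i] + 1
      if (is.finite(ll_p) &&
          log(runif(1)) < ladder[i] * (ll_p - ll[i]) + lp_p - lp[i]) {
        eta[, i] <- prop; ll[i] <- ll_p; lp[i] <- lp_p
        acc_local[i] <- acc_local[i] + 1
        batch_acc[i] <- batch_acc[i] + 1
      }
    }
    # exchange attempts between uniformly chosen adjacent pairs
    for (ex in seq_len(n_exchange)) {
      i <- if (n_beta == 2L) 1L else sample.int(n_beta - 1L, 1L)
      att_exch <- att_exch + 1
      if (log(runif(1)) < exchange_logaccept(ladder[i], ladder[i + 1],
                                             ll[i], ll[i + 1])) {
        eta[, c(i, i + 1)] <- eta[, c(i + 1, i)]
        ll[c(i, i + 1)] <- ll[c(i + 1, i)]
        lp[c(i, i + 1)] <- lp[c(i + 1, i)]
        acc_exch <- acc_exch + 1
      }
    }

    if (log_every > 0 && iter %% log_every == 0L) {
      message(sprintf(
        "iter %d/%d | local acc %.2f | exchange acc %.2f", iter, n_iter,
        mean(acc_local / pmax(att_local, 1)),
        acc_exch / max(att_exch, 1)))
    }
    if (iter <= n_burn) {
      burn_hist[iter, , ] <- eta
      # step-size tuning in batches of 50, burn-in only
      if (iter %% 50L == 0L) {
        batch <- batch + 1L
        rate <- ifelse(batch_att > 0, batch_acc / batch_att, 0)
        step_sd <- step_sd * exp((rate - 0.3) / sqrt(batch))
        batch_acc[] <- 0; batch_att[] <- 0
      }
      if (iter == n_burn) {
        # covariance adaptation at the burn-in boundary, then frozen
        lo <- max(1L, floor(n_burn / 2))
        hist_list <- lapply(seq_len(n_beta), function(j)
          burn_hist[lo:n_burn, , j, drop = FALSE][, , 1, drop = TRUE])
        covs <- adapt_proposals(lapply(hist_list, function(h)
          matrix(h, ncol = d)))
        prop_chol <- lapply(seq_len(n_beta), function(j) {
          ch <- tryCatch(t(chol(covs[[j]])), error = function(e) NULL)
          if (is.null(ch)) diag(step_sd[j], d) else ch
        })
        acc_local[] <- 0; att_local[] <- 0
      }
    } else if (keep_ptr <= n_keep && iter == keep_iters[keep_ptr]) {
      draws[keep_ptr, , ] <- eta
      ll_out[keep_ptr, ] <- ll
      keep_ptr <- keep_ptr + 1L
    }
  }

  structure(list(
    draws = draws, loglik = ll_out, ladder = ladder,
    accept_local = acc_local / pmax(att_local, 1),
    accept_exchange = acc_exch / max(att_exch, 1),
    proposal_chol = prop_chol,
    settings = list(n_iter = n_iter, burn_frac = burn_frac, thin = thin,
                    n_keep = n_keep, d = d)),
    class = "th17_chains")
}

#' Posterior (beta = 1) draws of a sampler run
#'
#' @param chains a \code{th17_chains}.
#' @return matrix n_keep x d of draws in log-parameter space.
#' @export
posterior_draws <- function(chains) {
  stopifnot(inherits(chains, "th17_chains"))
  n_beta <- length(chains$ladder)
  matrix(chains$draws[, , n_beta],
         nrow = dim(chains$draws)[1], ncol = dim(chains$draws)[2])
}
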