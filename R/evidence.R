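#' Sampler settings
#'
#' Defaults follow the full-scale analysis protocol: a 30-temperature
#' exponent-5 ladder, five independent samplers, half the iterations as
#' burn-in.  The full-scale protocol thins heavily (every 1000th
#' iteration); the package default thins every 10th so that exploratory
#' runs remain cheap -- scale \code{n_iter} and \code{thin} together to
#' reproduce full-scale sample sizes.
#'
#' @param n_beta,exponent temperature ladder (see \code{\link{make_ladder}}).
#' @param n_iter iterations per sampler (burn-in included).
#' @param burn_frac burn-in fraction.
#' @param thin retain every thin-th post-burn-in iteration.
#' @param n_samplers number of independent samplers.
#' @param prop_sd initial isotropic proposal SD in log-parameter space.
#' @param log_every progress-logging interval in iterations (0 = silent);
#'   see \code{\link{power_mcmc}}.
#' @return list of settings.
#' @export
sampler_settings <- function(n_beta = 30, exponent = 5, n_iter = 20000,
                             burn_frac = 0.5, thin = 10, n_samplers = 5,
                             prop_sd = 0.3, log_every = 0) {
  list(n_beta = n_beta, exponent = exponent, n_iter = n_iter,
       burn_frac = burn_frac, thin = thin, n_samplers = n_samplers,
       prop_sd = prop_sd, log_every = log_every)
}

#' Thermodynamic-integration evidence estimate
#'
#' For each sampler, the expected log-likelihood \code{I_beta} under each
#' power posterior is estimated by the mean over retained draws, and the
#' log marginal likelihood by the trapezoidal rule over the ladder:
#' \code{sum (beta_i - beta_{i-1}) (I_i + I_{i-1}) / 2}.  The point
#' estimate is the mean over independent samplers and its standard error
#' the between-sampler standard deviation divided by sqrt(S).
#'
#' @param chains a \code{th17_chains} or a list of them (independent
#'   samplers run on the same ladder).
#' @return object of class \code{th17_evidence}: \code{log_evidence},
#'   \code{se}, per-sampler estimates, and the matrix of \code{I_beta}
#'   values (samplers x temperatures).
#' @export
thermodynamic_integral <- function(chains) {
  if (inherits(chains, "th17_chains")) chains <- list(chains)
  stopifnot(length(chains) >= 1,
            all(vapply(chains, inherits, logical(1), "th17_chains")))
  ladder <- chains[[1]]$ladder
  for (ch in chains) {
    if (!identical(ch$ladder, ladder))
      stop("all samplers must share the same temperature ladder",
           call. = FALSE)
  }
  i_beta <- t(vapply(chains, function(ch) colMeans(ch$loglik),
                     numeric(length(ladder))))
  per_sampler <- apply(i_beta, 1, function(I)
    sum(diff(ladder) * (I[-1] + I[-length(I)]) / 2))
  se <- if (length(per_sampler) > 1) {
    sd(per_sampler) / sqrt(length(per_sampler))
  } else {
    NA_real_
  }
  structure(list(log_evidence = mean(per_sampler), se = se,
                 per_sampler = per_sampler, i_beta = i_beta,
                 ladder = ladder),
            class = "th17_evidence")
}

#' @export
print.th17_evidence <- function(x, ...) {
  cat(sprintf("log evidence: %.3f (SE %.3f, %d sampler%s)\n",
              x$log_evidence, x$se, length(x$per_sampler),
              if (length(x$per_sampler) > 1) "s" else ""))
  invisible(x)
}

#' Fit a Th17 model variant to time-course count data
#'
#' Runs independent population-MCMC samplers on the power-posterior
#' ladder for one network variant, computes the thermodynamic-integration
#' evidence and cross-sampler convergence diagnostics.  When protein
#' dose-response data are supplied the likelihood is extended by the
#' normal dose-response term and the protein scale factor s becomes an
#' additional free parameter with the same standard log-normal prior as
#' the kinetic rates.
#'
#' @param counts a \code{th17_counts}.
#' @param variant a \code{th17_variant} or an integer id 1..12.
#' @param protein optional \code{th17_protein}.
#' @param settings from \code{\link{sampler_settings}}.
#' @param seed master seed; per-sampler seeds are derived from it.
#' @param input training-condition cytokine doses.
#' @param init initial condition; by default derived from the data
#'   (replicate-mean abundance at 0 h, proteins at their conventions).
#' @param gene_map optional gene -> state map.
#' @return object of class \code{th17_fit}: sampler chains, evidence,
#'   per-parameter PSRF over the posterior chains, parameter names, and
#'   the ingredients needed for prediction.
#' @export
fit_th17 <- function(counts, variant, protein = NULL,
                     settings = sampler_settings(), seed = 1,
                     input = cytokine_input(), init = NULL,
                     gene_map = NULL) {
  stopifnot(inherits(counts, "th17_counts"))
  if (!inherits(variant, "th17_variant")) variant <- build_variant(variant)
  if (is.null(init)) init <- th17_init(counts = counts)
  gene_map <- resolve_gene_map(counts$genes, gene_map)
  d0 <- n_free_parameters(variant)
  has_protein <- !is.null(protein)
  d <- d0 + has_protein
  par_names <- c(paste0("theta", variant$active),
                 if (has_protein) "log_s")
  ladder <- make_ladder(settings$n_beta, settings$exponent)
  obs_times <- counts$times
  t_assay <- 72
  loglik <- make_joint_loglik(counts, variant, protein, input, init,
                              gene_map, t_assay = t_assay)

  chains <- lapply(seq_len(settings$n_samplers), function(sidx) {
    power_mcmc(loglik, d = d, ladder = ladder,
               n_iter = settings$n_iter, burn_frac = settings$burn_frac,
               thin = settings$thin, prop_sd = settings$prop_sd,
               seed = derive_seed(seed, sidx),
               log_every = settings$log_every %||% 0)
  })
  evidence <- thermodynamic_integral(chains)
  conv <- if (settings$n_samplers > 1) {
    psrf(lapply(chains, posterior_draws))
  } else {
    rep(NA_real_, d)
  }
  names(conv) <- par_names

  structure(list(variant = variant, chains = chains, evidence = evidence,
                 psrf = conv, par_names = par_names,
                 counts = counts, protein = protein, input = input,
                 init = init, gene_map = gene_map, seed = seed,
                 settings = settings, has_protein = has_protein),
            class = "th17_fit")
}

# Build the log-likelihood closure over eta = log(active rates [, s])
# that the sampler evaluates.  This is the hot path of the whole
# package, so the data are pre-indexed once and the ODE is driven
# through deSolve::lsode directly (BDF, mf = 22), skipping the generic
# dispatch and trajectory packaging of simulate_th17.  Semantics match
# count_loglik/protein_loglik exactly (cross-checked in the tests); the
# protein part uses the dose-superposition identity, reusing the
# training trajectory for the reference-dose leg when the training
# input is the reference condition.
make_joint_loglik <- function(counts, variant, protein = NULL,
                              input = cytokine_input(),
                              init = th17_init(counts = counts),
                              gene_map = NULL, t_assay = 72,
                              rtol = 1e-8, atol = 1e-10) {
  gene_map <- resolve_gene_map(counts$genes, gene_map)
  d0 <- n_free_parameters(variant)
  active <- variant$active
  obs_times <- counts$times
  y0 <- unname(init[STATE_NAMES6])
  df <- counts$df[!is.na(counts$df$count), , drop = FALSE]
  lookup <- cbind(match(df$time_h, obs_times),
                  1L + match(gene_map[df$gene], STATE_NAMES6))
  cnt <- df$count; phi <- df$dispersion
  lib <- counts$count_scale * df$library_size
  has_protein <- !is.null(protein)
  if (has_protein) {
    doses <- protein$df$dose_ng_ml
    pmean <- protein$df$mean_percent
    psd <- protein$df$sd_percent
    reuse_ref <- t_assay %in% obs_times && input$il6_added == 20 &&
      input$tgfb_added == input$tgfb_input
    t_assay_row <- match(t_assay, obs_times)
  }

  solve_ode <- function(parms, times) {
    out <- tryCatch(
      suppressWarnings(deSolve::lsode(
        y = y0, times = times, func = "th17_derivs6", parms = parms,
        dllname = "th17ti", initfunc = "th17_initmod", mf = 22,
        rtol = rtol, atol = atol)),
      error = function(e) NULL)
    if (is.null(out) || nrow(out) < length(times) || anyNA(out) ||
        any(!is.finite(out))) return(NULL)
    out
  }

  function(eta) {
    theta_full <- numeric(18L)
    theta_full[active] <- exp(eta[seq_len(d0)])
    parms <- c(theta_full, input$il6_ratio, input$tgfb_ratio)
    out <- solve_ode(parms, obs_times)
    if (is.null(out)) return(-Inf)
    x <- pmax(out[lookup], 0)
    ll <- sum(nb_logdens(cnt, lib * x, phi))
    if (!is.finite(ll) || !has_protein) return(ll)
    s <- exp(eta[d0 + 1L])
    f1 <- if (reuse_ref) {
      out[t_assay_row, 7L]
    } else {
      out1 <- solve_ode(c(theta_full, 1, 1), c(0, t_assay))
      if (is.null(out1)) return(-Inf)
      out1[2L, 7L]
    }
    out0 <- solve_ode(c(theta_full, 1, 0), c(0, t_assay))
    if (is.null(out0)) return(-Inf)
    f0 <- out0[2L, 7L]
    fstar <- f0 + doses * (f1 - f0)
    ll + sum(dnorm(pmean, mean = s * fstar, sd = psd, log = TRUE))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-sampler seed derivation from a master seed.
derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 131 + idx * 7919) %% 2147483647)
}

#' @export
print.th17_fit <- function(x, ...) {
  cat(sprintf("Th17 fit of M%d (%d samplers, %d temperatures)\n",
              x$variant$id, length(x$chains), length(x$chains[[1]]$ladder)))
  print(x$evidence)
  cat(sprintf("max PSRF: %.3f\n", max(x$psrf)))
  invisible(x)
}

#' Pooled posterior draws of a fit
#'
#' @param fit a \code{th17_fit}.
#' @return matrix (draws x parameters) of beta = 1 draws in log space,
#'   pooled over samplers, with parameter names.
#' @export
fit_posterior <- function(fit) {
  stopifnot(inherits(fit, "th17_fit"))
  out <- do.call(rbind, lapply(fit$chains, posterior_draws))
  colnames(out) <- fit$par_names
  out
}

#' Rank model variants by evidence
#'
#' Orders fitted variants by decreasing log marginal likelihood (no prior
#' preference between models), carrying the standard errors along.  Exact
#' ties are broken deterministically by variant id.
#'
#' @param fits list of \code{th17_fit} objects (>= 2) or of
#'   \code{th17_evidence} objects paired with \code{variants}.
#' @param variants integer ids, required when \code{fits} are bare
#'   evidence objects.
#' @return data.frame with columns variant, log_evidence, se, rank.
#' @export
rank_models <- function(fits, variants = NULL) {
  stopifnot(length(fits) >= 2)
  if (all(vapply(fits, inherits, logical(1), "th17_fit"))) {
    variants <- vapply(fits, function(f) f$variant$id, integer(1))
    ev <- lapply(fits, function(f) f$evidence)
  } else {
    stopifnot(!is.null(variants), length(variants) == length(fits))
    ev <- fits
  }
  out <- data.frame(
    variant = as.integer(variants),
    log_evidence = vapply(ev, function(e) e$log_evidence, numeric(1)),
    se = vapply(ev, function(e) e$se, numeric(1)))
  ord <- order(-out$log_evidence, out$variant)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
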