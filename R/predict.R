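#' Posterior predictive band over continuous time
#'
#' Monte-Carlo approximation of the posterior predictive distribution of
#' the observable relative abundances: for each posterior draw the model
#' is simulated over the grid and one predictive observation per grid
#' point is drawn from the interpolated NB observation density (mean
#' library size, interpolated dispersion); the band reports pooled
#' empirical percentiles.  Band and data live on the common
#' relative-abundance scale (counts divided by library size).
#'
#' @param fit a \code{th17_fit}.
#' @param grid times within the observed range (default: 49 points).
#' @param probs percentiles to report.
#' @param max_draws cap on the number of posterior draws used.
#' @param seed seed for the observation noise.
#' @param phi_multiplier multiplies the interpolated dispersions
#'   (1 = as estimated); exposed for sensitivity checks.
#' @return data.frame (gene, time_h, then one column per percentile,
#'   e.g. q05/q50/q95) with attribute \code{n_failed} counting dropped
#'   failed simulations.
#' @export
posterior_predictive <- function(fit, grid = NULL,
                                 probs = c(0.05, 0.5, 0.95),
                                 max_draws = 400, seed = NULL,
                                 phi_multiplier = 1) {
  stopifnot(inherits(fit, "th17_fit"))
  draws <- fit_posterior(fit)
  predictive_band(draws, fit$variant, fit$counts, fit$init, fit$input,
                  gene_map = fit$gene_map, grid = grid, probs = probs,
                  max_draws = max_draws, seed = seed,
                  phi_multiplier = phi_multiplier)
}

#' Predictive band from an explicit draw matrix
#'
#' Lower-level engine behind \code{\link{posterior_predictive}}; useful
#' for predictive checks at a known (e.g. data-generating) parameter
#' point, supplied as a one-row matrix.
#'
#' @param draws matrix of draws in log-parameter space; the first
#'   \code{n_free_parameters(variant)} columns are the kinetic rates.
#' @param variant,counts,init,input model context (as in
#'   \code{\link{fit_th17}}).
#' @param gene_map optional gene -> state map.
#' @inheritParams posterior_predictive
#' @export
predictive_band <- function(draws, variant, counts, init = th17_init(),
                            input = cytokine_input(), gene_map = NULL,
                            grid = NULL, probs = c(0.05, 0.5, 0.95),
                            max_draws = 400, seed = NULL,
                            phi_multiplier = 1) {
  stopifnot(inherits(counts, "th17_counts"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid))
    grid <- seq(min(counts$times), max(counts$times), length.out = 49)
  scale <- prediction_scale(counts)
  if (min(grid) < scale$t_range[1] || max(grid) > scale$t_range[2])
    stop("prediction grid outside the observed time range", call. = FALSE)
  gene_map <- resolve_gene_map(counts$genes, gene_map)
  if (nrow(draws) == 0L) stop("empty posterior sample", call. = FALSE)
  if (nrow(draws) > max_draws) {
    draws <- draws[round(seq(1, nrow(draws), length.out = max_draws)), ,
                   drop = FALSE]
  }
  d0 <- n_free_parameters(variant)
  sim_times <- sort(unique(c(0, grid)))
  genes <- counts$genes
  phis <- lapply(genes, function(g)
    phi_multiplier * scale$phi_fun[[g]](grid))
  names(phis) <- genes

  ystar <- array(NA_real_, c(nrow(draws), length(grid), length(genes)),
                 dimnames = list(NULL, NULL, genes))
  n_failed <- 0L
  for (r in seq_len(nrow(draws))) {
    theta <- exp(draws[r, seq_len(d0)])
    tr <- simulate_th17(variant, theta, init, input, times = sim_times)
    if (!tr$ok) { n_failed <- n_failed + 1L; next }
    for (g in genes) {
      x <- pmax(traj_at(tr, grid, gene_map[[g]])[, 1], 0)
      ystar[r, , g] <- rnbinom(length(grid), size = 1 / phis[[g]],
                               mu = scale$lbar * x) / scale$lbar
    }
  }
  if (n_failed == nrow(draws))
    stop("all simulations failed during prediction", call. = FALSE)

  qs <- do.call(rbind, lapply(genes, function(g) {
    qm <- t(apply(ystar[, , g, drop = FALSE], 2, quantile, probs = probs,
                  na.rm = TRUE, type = 7))
    df <- data.frame(gene = g, time_h = grid)
    qdf <- as.data.frame(qm)
    names(qdf) <- sprintf("q%02d", round(100 * probs))
    cbind(df, qdf)
  }))
  rownames(qs) <- NULL
  attr(qs, "n_failed") <- n_failed
  qs
}

#' Posterior predictive TGFb dose-response of FOXP3 protein
#'
#' For every posterior draw and every dose, the model is simulated in the
#' protein-assay condition (IL6 20 ng/ml, TGFb at the dose) and the
#' scaled latent FOXP3 protein level at the assay time is recorded; the
#' table reports the posterior mean and percentiles per dose.  The scale
#' factor is the fitted \code{s} when the fit includes protein data,
#' otherwise the supplied \code{s}.
#'
#' @param fit a \code{th17_fit}.
#' @param doses positive TGFb doses in ng/ml.
#' @param t_assay assay time (hours).
#' @param probs percentiles to report.
#' @param max_draws cap on posterior draws used.
#' @param s protein scale used when the fit has no protein part
#'   (default 1: the raw latent level).
#' @return data.frame (dose_ng_ml, mean, percentile columns) with
#'   attribute \code{n_failed}.
#' @export
predict_dose_response <- function(fit, doses = c(1/16, 1/8, 1/4, 1/2, 1),
                                  t_assay = 72,
                                  probs = c(0.05, 0.5, 0.95),
                                  max_draws = 200, s = 1) {
  stopifnot(inherits(fit, "th17_fit"), all(doses > 0))
  draws <- fit_posterior(fit)
  if (nrow(draws) > max_draws) {
    draws <- draws[round(seq(1, nrow(draws), length.out = max_draws)), ,
                   drop = FALSE]
  }
  d0 <- n_free_parameters(fit$variant)
  lev <- matrix(NA_real_, nrow(draws), length(doses))
  n_failed <- 0L
  for (r in seq_len(nrow(draws))) {
    theta <- exp(draws[r, seq_len(d0)])
    s_r <- if (fit$has_protein) exp(draws[r, d0 + 1L]) else s
    f <- fstar_at_doses(fit$variant, theta, fit$init, doses,
                        il6_added = 20, t_assay = t_assay,
                        method = "per_dose")
    if (anyNA(f)) { n_failed <- n_failed + 1L; next }
    lev[r, ] <- s_r * f
  }
  if (n_failed == nrow(draws))
    stop("all simulations failed during prediction", call. = FALSE)
  qm <- t(apply(lev, 2, quantile, probs = probs, na.rm = TRUE, type = 7))
  out <- data.frame(dose_ng_ml = doses,
                    mean = colMeans(lev, na.rm = TRUE))
  qdf <- as.data.frame(qm)
  names(qdf) <- sprintf("q%02d", round(100 * probs))
  out <- cbind(out, qdf)
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}
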