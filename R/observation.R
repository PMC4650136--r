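#' Negative-binomial log pmf in the mean/dispersion parameterization
#'
#' \code{g(y; mu, phi)} with mean \code{mu} and dispersion \code{phi}, so
#' that the variance is \code{mu + phi * mu^2} -- the parameterization used
#' for RNA-seq read counts, where \code{mu = L * p} couples the library
#' size \code{L} to the relative mRNA abundance \code{p}.  Computed through
#' log-gamma/log-beta functions, so it stays finite for very large counts
#' and remains accurate in the Poisson limit \code{phi -> 0}.
#'
#' @param y nonnegative integer counts (vectorized).
#' @param mu nonnegative means; values below 1e-12 are floored there so a
#'   structural zero never produces log(0) against a positive count.
#' @param phi positive dispersions.
#' @return log probability mass, same length as the recycled arguments.
#' @examples
#' nb_logpmf(7, mu = 5, phi = 0.3)
#' # variance identity: mu + phi mu^2
#' v <- sum(exp(nb_logpmf(0:3000, 10, 0.5)) * (0:3000 - 10)^2)
#' all.equal(v, 10 + 0.5 * 100)
#' @export
nb_logpmf <- function(y, mu, phi) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y)))
    stop("y must be nonnegative integers", call. = FALSE)
  nb_logdens(y, mu, phi)
}

# Continuous-argument version of the NB density kernel: the gamma
# functions accept any real y >= 0, which is what the interpolated
# continuous-time likelihood evaluates.
nb_logdens <- function(y, mu, phi) {
  if (any(!is.finite(mu)) || any(mu < 0))
    stop("mu must be finite and nonnegative", call. = FALSE)
  if (any(!is.finite(phi)) || any(phi <= 0))
    stop("phi must be finite and strictly positive", call. = FALSE)
  n <- max(length(y), length(mu), length(phi))
  y <- rep_len(y, n); mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  mu <- pmax(mu, 1e-12)
  size <- 1 / phi
  # lgamma(y + size) - lgamma(size) - lgamma(y + 1) via lbeta: stable for
  # very large size (small phi) where direct lgamma differences cancel.
  comb <- ifelse(y == 0, 0, -log(y) - lbeta(y, size))
  comb - size * log1p(mu * phi) + y * (log(mu) - log(mu + size))
}

#' Log prior density over model rates
#'
#' All rates are strictly positive and carry independent standard normal
#' priors on their natural logarithms; this is also the space the sampler
#' moves in, so the density is reported with respect to log-rates.
#'
#' @param theta positive rate vector (active parameters only).
#' @return scalar log density; \code{-Inf} if any rate is nonpositive.
#' @export
log_prior <- function(theta) {
  if (any(!is.finite(theta)) || any(theta <= 0)) return(-Inf)
  sum(dnorm(log(theta), 0, 1, log = TRUE))
}

# Same prior evaluated directly at eta = log(theta).
log_prior_eta <- function(eta) sum(dnorm(eta, 0, 1, log = TRUE))

#' Time-course count data container
#'
#' @param df data.frame with columns \code{gene}, \code{time_h},
#'   \code{replicate}, \code{count}, \code{library_size},
#'   \code{dispersion}.  Missing replicates are rows with \code{NA} count
#'   (they are skipped in the likelihood); library sizes are per
#'   (time, replicate) sample and dispersions per (gene, time).
#' @param count_scale the model scaling constant linking the dimensionless
#'   model states to sequencing depth: a count has NB mean
#'   \code{count_scale * library_size * x}.  Model states are O(1)
#'   relative abundances (protein levels start at 1 by convention and the
#'   rate prior is centred at 1/h), whereas a transcript's share of a
#'   bulk library is ~1e-4 and below; this constant carries that unit
#'   conversion so that neither the states nor the rates have to leave
#'   the scale the prior supports.
#' @return object of class \code{th17_counts}: the validated data.frame
#'   plus \code{genes}, \code{times} and \code{count_scale}.
#' @export
th17_counts <- function(df, count_scale = 1) {
  need <- c("gene", "time_h", "replicate", "count", "library_size",
            "dispersion")
  if (!all(need %in% names(df)))
    stop("count data needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$gene, df$time_h, df$replicate), need]
  ok <- is.na(df$count) |
    (df$count >= 0 & df$count == floor(df$count))
  if (!all(ok)) stop("counts must be nonnegative integers or NA",
                     call. = FALSE)
  if (any(df$library_size <= 0)) stop("library sizes must be positive",
                                      call. = FALSE)
  if (any(df$dispersion <= 0)) stop("dispersions must be positive",
                                    call. = FALSE)
  if (!is.finite(count_scale) || count_scale <= 0)
    stop("count_scale must be positive", call. = FALSE)
  times <- sort(unique(df$time_h))
  structure(list(df = df, genes = sort(unique(df$gene)), times = times,
                 count_scale = count_scale),
            class = "th17_counts")
}

#' @export
print.th17_counts <- function(x, ...) {
  cat(sprintf("Th17 count data: %d genes x %d time points x %d replicates\n",
              length(x$genes), length(x$times),
              length(unique(x$df$replicate))))
  invisible(x)
}

#' Read / write count data as TSV
#'
#' The on-disk dialect is a plain TSV with columns gene, time_h,
#' replicate, count, library_size, dispersion; lines starting with
#' \code{#} are comments.  The model scaling constant is carried in a
#' \code{# count_scale:} comment line.
#'
#' @param path file path.
#' @return \code{read_counts}: a \code{th17_counts}.
#' @export
read_counts <- function(path) {
  head_lines <- grep("^#", readLines(path, n = 50), value = TRUE)
  cs_line <- grep("count_scale:", head_lines, value = TRUE)
  count_scale <- if (length(cs_line)) {
    as.numeric(sub(".*count_scale:\\s*", "", cs_line[1]))
  } else {
    1
  }
  th17_counts(read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE),
              count_scale = count_scale)
}

#' @rdname read_counts
#' @param x a \code{th17_counts}.
#' @param header optional character vector of comment lines (written with
#'   a leading \code{# }).
#' @export
write_counts <- function(x, path, header = NULL) {
  stopifnot(inherits(x, "th17_counts"))
  write_tsv_commented(x$df, path,
                      c(header, sprintf("count_scale: %.17g",
                                        x$count_scale)))
  invisible(path)
}

write_tsv_commented <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' FOXP3 protein dose-response data container
#'
#' Percentage of FOXP3+ cells at 72 h under a fixed IL6 dose (20 ng/ml)
#' and a dilution series of added TGFb, as mean and standard deviation
#' over replicate cultures.
#'
#' @param df data.frame with columns \code{dose_ng_ml},
#'   \code{mean_percent}, \code{sd_percent}.
#' @return object of class \code{th17_protein}.
#' @export
th17_protein <- function(df) {
  need <- c("dose_ng_ml", "mean_percent", "sd_percent")
  if (!all(need %in% names(df)))
    stop("protein data needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$dose_ng_ml), need]
  if (any(df$dose_ng_ml <= 0) || anyDuplicated(df$dose_ng_ml))
    stop("doses must be positive and distinct", call. = FALSE)
  if (any(!is.finite(df$sd_percent)) || any(df$sd_percent <= 0))
    stop("sd_percent must be positive", call. = FALSE)
  structure(list(df = df), class = "th17_protein")
}

#' @rdname th17_protein
#' @param path file path of the TSV (columns dose_ng_ml, mean_percent,
#'   sd_percent).
#' @export
read_protein <- function(path) {
  th17_protein(read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE))
}

#' @rdname th17_protein
#' @param x a \code{th17_protein}.
#' @param header optional comment lines.
#' @export
write_protein <- function(x, path, header = NULL) {
  stopifnot(inherits(x, "th17_protein"))
  write_tsv_commented(x$df, path, header)
  invisible(path)
}

#' Count-data log-likelihood of a trajectory
#'
#' Independent NB terms over genes, time points and replicates: each count
#' D has mean count_scale * library_size * x_gene(t) with the gene/time
#' dispersion.  A failed trajectory yields \code{-Inf}.
#'
#' @param counts a \code{th17_counts}.
#' @param traj a \code{th17_traj} covering all observed times.
#' @param gene_map named character vector gene -> state; by default genes
#'   named STAT3 / RORGT (or RORC) / FOXP3 map onto their mRNA states.
#' @return scalar log-likelihood.
#' @export
count_loglik <- function(counts, traj, gene_map = NULL) {
  stopifnot(inherits(counts, "th17_counts"), inherits(traj, "th17_traj"))
  if (!traj$ok) return(-Inf)
  gene_map <- resolve_gene_map(counts$genes, gene_map)
  d <- counts$df[!is.na(counts$df$count), , drop = FALSE]
  x <- numeric(nrow(d))
  for (g in counts$genes) {
    sel <- d$gene == g
    x[sel] <- traj_at(traj, d$time_h[sel], gene_map[[g]])
  }
  sum(nb_logpmf(d$count, counts$count_scale * d$library_size * pmax(x, 0),
                d$dispersion))
}

resolve_gene_map <- function(genes, gene_map = NULL) {
  if (is.null(gene_map)) {
    gene_map <- vapply(genes, gene_to_state, character(1))
  } else {
    gene_map <- gene_map[genes]
  }
  if (anyNA(gene_map))
    stop("no state mapping for gene(s): ",
         paste(genes[is.na(gene_map)], collapse = ", "), call. = FALSE)
  bad <- !gene_map %in% STATE_NAMES10
  if (any(bad))
    stop("unknown state(s) in gene_map: ",
         paste(gene_map[bad], collapse = ", "), call. = FALSE)
  gene_map
}

#' Prediction scale: interpolated dispersions and mean library size
#'
#' The continuous-time (interpolated) likelihood replaces the per-sample
#' library sizes by their overall mean and the per-gene, per-time
#' dispersions by a linear-in-time interpolant that is exact at the
#' observed time points.
#'
#' @param counts a \code{th17_counts}.
#' @param s optional protein scale factor linking the dimensionless FOXP3
#'   protein level to the measured percentage of FOXP3+ cells.
#' @return object of class \code{th17_scale}: \code{lbar}, per-gene
#'   dispersion interpolants \code{phi_fun}, the observed time range, and
#'   \code{s}.
#' @export
prediction_scale <- function(counts, s = NA_real_) {
  stopifnot(inherits(counts, "th17_counts"))
  d <- counts$df
  samples <- !duplicated(d[, c("time_h", "replicate")])
  # effective (model-scale) mean library size
  lbar <- counts$count_scale * mean(d$library_size[samples])
  phi_fun <- lapply(setNames(counts$genes, counts$genes), function(g) {
    dg <- d[d$gene == g, ]
    dg <- dg[!duplicated(dg$time_h), ]
    if (nrow(dg) == 1L) {
      local({ val <- dg$dispersion; function(t) rep_len(val, length(t)) })
    } else {
      approxfun(dg$time_h, dg$dispersion, rule = 1)
    }
  })
  structure(list(lbar = lbar, phi_fun = phi_fun, genes = counts$genes,
                 t_range = range(counts$times), s = s),
            class = "th17_scale")
}

#' Interpolated continuous-time log-likelihood
#'
#' Evaluates the NB observation density at an arbitrary time t between the
#' first and last observation, treating the (scaled) predicted level as a
#' continuous argument of the NB kernel: for each gene,
#' \code{g(lbar * y_star; lbar * x(t), phi(t))} with the interpolated
#' dispersion.  This is the density from which continuous-time posterior
#' predictive distributions are drawn.
#'
#' @param y_star named vector of predicted relative abundances per gene.
#' @param traj a \code{th17_traj}.
#' @param scale a \code{th17_scale}.
#' @param t single time in hours within the observed range.
#' @param gene_map optional gene -> state map (see
#'   \code{\link{count_loglik}}).
#' @return scalar log density.
#' @export
interpolated_loglik <- function(y_star, traj, scale, t, gene_map = NULL) {
  stopifnot(inherits(traj, "th17_traj"), inherits(scale, "th17_scale"))
  if (length(t) != 1L || t < scale$t_range[1] || t > scale$t_range[2])
    stop("t must be a single time within the observed range",
         call. = FALSE)
  gene_map <- resolve_gene_map(scale$genes, gene_map)
  sum(vapply(scale$genes, function(g) {
    x <- traj_at(traj, t, gene_map[[g]])[1, 1]
    nb_logdens(scale$lbar * y_star[[g]], scale$lbar * max(x, 0),
               scale$phi_fun[[g]](t))
  }, numeric(1)))
}

#' FOXP3 protein dose-response log-likelihood
#'
#' For each TGFb dose the model is run to 72 h in the protein-assay
#' condition (IL6 fixed at 20 ng/ml, TGFb at the dose) and the observed
#' mean percentage is given a normal likelihood centred on the scaled
#' latent FOXP3 protein level, with the replicate SD as its standard
#' deviation.
#'
#' Because nothing feeds back into the FOXP3 equations except
#' phospho-STAT3 (which does not depend on the TGFb dose), the latent
#' FOXP3 level at a given time is affine in the dose; the default
#' \code{method = "superposition"} exploits this and obtains all doses
#' from two integrations (dose 0 and the reference dose).
#' \code{method = "per_dose"} integrates each dose separately.
#'
#' @param protein a \code{th17_protein}.
#' @param variant a \code{th17_variant}.
#' @param theta active-parameter vector.
#' @param init initial condition (see \code{\link{th17_init}}).
#' @param s positive protein scale factor.
#' @param il6_added IL6 dose of the assay condition (ng/ml).
#' @param t_assay assay time (hours).
#' @param method \code{"superposition"} or \code{"per_dose"}.
#' @return scalar log-likelihood; \code{-Inf} on integration failure.
#' @export
protein_loglik <- function(protein, variant, theta, init = th17_init(),
                           s, il6_added = 20, t_assay = 72,
                           method = c("superposition", "per_dose")) {
  stopifnot(inherits(protein, "th17_protein"))
  method <- match.arg(method)
  if (!is.finite(s) || s <= 0) return(-Inf)
  doses <- protein$df$dose_ng_ml
  fstar <- fstar_at_doses(variant, theta, init, doses, il6_added, t_assay,
                          method)
  if (anyNA(fstar)) return(-Inf)
  sum(dnorm(protein$df$mean_percent, mean = s * fstar,
            sd = protein$df$sd_percent, log = TRUE))
}

#' Latent FOXP3 protein level at the assay time for each TGFb dose
#'
#' Runs the model in the protein-assay condition and returns the
#' dimensionless FOXP3 protein level at \code{t_assay} per dose; the
#' quantity the protein likelihood and the dose-response predictions are
#' built on.
#'
#' @inheritParams protein_loglik
#' @param doses positive TGFb doses (ng/ml).
#' @return numeric vector, one level per dose (NA where the integration
#'   failed).
#' @export
fstar_at_doses <- function(variant, theta, init, doses, il6_added = 20,
                           t_assay = 72,
                           method = c("superposition", "per_dose")) {
  method <- match.arg(method)
  times <- c(0, t_assay)
  sim_dose <- function(dose) {
    tr <- simulate_th17(variant, theta, init,
                        cytokine_input(il6_added = il6_added,
                                       tgfb_added = dose),
                        times = times)
    if (!tr$ok) return(NA_real_)
    tr$states[length(times), "foxp3_prot_star"]
  }
  if (method == "per_dose") {
    vapply(doses, sim_dose, numeric(1))
  } else {
    ref <- cytokine_input()$tgfb_input
    f0 <- sim_dose(0)
    f1 <- sim_dose(ref)
    f0 + (doses / ref) * (f1 - f0)
  }
}

#' Joint log-likelihood of count and protein data
#'
#' Product (sum of logs) of the NB count likelihood and, when protein
#' data are supplied, the normal dose-response likelihood.  A \code{-Inf}
#' count part is absorbing.
#'
#' @param counts a \code{th17_counts}.
#' @param traj trajectory in the training condition, covering the
#'   observed times.
#' @param protein optional \code{th17_protein}.
#' @param s protein scale factor (required with protein data).
#' @param gene_map optional gene -> state map.
#' @return scalar log-likelihood.
#' @export
joint_loglik <- function(counts, traj, protein = NULL, s = NA_real_,
                         gene_map = NULL) {
  ll <- count_loglik(counts, traj, gene_map)
  if (is.null(protein) || !is.finite(ll)) return(ll)
  ll + protein_loglik(protein, traj$variant,
                      restrict_theta(traj$theta_full, traj$variant),
                      traj$init, s = s)
}
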