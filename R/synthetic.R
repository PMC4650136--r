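#' Reference kinetic parameterization of the synthetic-data generator
#'
#' A fixed, documented rate vector used as the data-generating truth.
#' The values sit well inside the bulk of the standard log-normal prior
#' (all between 0.2 and 0.6 per hour) and produce dynamics with the
#' qualitative features of Th17 polarization: a stable basally expressed
#' STAT3 module, RORgt induction that follows the TGFb/phospho-STAT3
#' ramp, and FOXP3 kinetics shaped by whichever induction/inhibition
#' mechanisms the chosen variant activates.
#'
#' @return named numeric vector theta1..theta18.
#' @export
reference_theta <- function() {
  c(theta1 = 0.25,  # IL6 conversion
    theta2 = 0.5,   # STAT3 basal transcription
    theta3 = 0.2,   # STAT3 autoregulation
    theta4 = 0.5,   # STAT3 mRNA degradation
    theta5 = 0.4,   # STAT3 translation
    theta6 = 0.3,   # STAT3 phosphorylation
    theta7 = 0.3,   # STAT3 protein degradation
    theta8 = 0.4,   # STAT3 phosphoprotein degradation
    theta9 = 0.3,   # TGFb conversion
    theta10 = 0.6,  # RORgt activation by TGFb + phospho-STAT3
    theta11 = 0.5,  # RORgt inhibition by FOXP3
    theta12 = 0.25, # RORgt degradation
    theta13 = 0.2,  # FOXP3 basal induction
    theta14 = 0.5,  # FOXP3 induction by TGFb
    theta15 = 0.3,  # FOXP3 inhibition by phospho-STAT3
    theta16 = 0.3,  # FOXP3 mRNA degradation
    theta17 = 0.3,  # FOXP3 translation/phosphorylation
    theta18 = 0.25) # FOXP3 protein degradation
}

#' Configuration of the synthetic-data generator
#'
#' Describes a synthetic time-course RNA-seq experiment with the
#' statistical structure the analysis assumes: three genes (STAT3, RORGT,
#' FOXP3) in triplicate over 0--72 h sampled densely early, NB counts
#' with per-sample library sizes and gene/time-specific dispersions, and
#' optionally a five-dose TGFb dilution series of FOXP3 protein
#' measurements at 72 h.
#'
#' @param variant variant id (default 8: TGFb-driven FOXP3 with both
#'   inhibitory mechanisms).
#' @param theta data-generating rates for the active parameters; default
#'   is \code{\link{reference_theta}} restricted to the variant.  The
#'   string \code{"prior"} draws the truth from the prior instead.
#' @param times observation grid in hours.
#' @param n_rep replicates per time point.
#' @param lib_range library sizes are drawn log-uniformly in this range.
#' @param count_scale model scaling constant of the observation bridge
#'   (see \code{\link{th17_counts}}): NB means are
#'   \code{count_scale * library_size * x}, so the default pairs bulk
#'   library sizes of 5e6--2e7 reads with O(1) model states to give
#'   typical per-gene counts of tens to thousands.
#' @param phi_range dispersions are drawn log-uniformly in this range,
#'   independently per gene and time point.
#' @param protein generate the protein dose-response table too?
#' @param doses TGFb dilution series (ng/ml).
#' @param protein_sd replicate SD of the protein measurement
#'   (percentage points; recycled over doses).
#' @param protein_scale true scale factor linking the dimensionless
#'   latent FOXP3 protein level to the percentage of FOXP3+ cells.
#' @param init initial condition of the truth (relative mRNA abundances;
#'   proteins follow the model conventions).
#' @param seed master seed; every random element of the data set derives
#'   from it.
#' @return list of class \code{th17_synth_config}.
#' @export
synth_config <- function(variant = 8, theta = NULL,
                         times = c(0, 1, 3, 6, 12, 24, 48, 72),
                         n_rep = 3, lib_range = c(5e6, 2e7),
                         count_scale = 1e-4,
                         phi_range = c(0.01, 0.5), protein = TRUE,
                         doses = c(1/16, 1/8, 1/4, 1/2, 1),
                         protein_sd = 2, protein_scale = 25,
                         init = th17_init(stat3_mrna = 1.25,
                                          rorgt_mrna = 0.01,
                                          foxp3_mrna = 0.05),
                         seed = 1) {
  v <- if (inherits(variant, "th17_variant")) variant else
    build_variant(variant)
  structure(list(variant = v, theta = theta, times = times, n_rep = n_rep,
                 lib_range = lib_range, count_scale = count_scale,
                 phi_range = phi_range,
                 protein = protein, doses = doses,
                 protein_sd = protein_sd, protein_scale = protein_scale,
                 init = init, seed = seed),
            class = "th17_synth_config")
}

resolve_truth_theta <- function(config) {
  v <- config$variant
  if (is.null(config$theta)) {
    restrict_theta(reference_theta(), v)
  } else if (identical(config$theta, "prior")) {
    setNames(exp(rnorm(n_free_parameters(v))),
             paste0("theta", v$active))
  } else {
    theta <- config$theta
    if (length(theta) == 18L) theta <- restrict_theta(theta, v)
    stopifnot(length(theta) == n_free_parameters(v), all(theta > 0))
    setNames(as.numeric(theta), paste0("theta", v$active))
  }
}

#' Generate a synthetic count data set
#'
#' Simulates the chosen variant at the data-generating rates and draws
#' each count from \code{NB(L * x, phi)} with log-uniform library sizes
#' and dispersions.  The hidden truth (rates, trajectory, initial
#' condition) is returned alongside for recovery tests.
#'
#' @param config a \code{\link{synth_config}}.
#' @return list with \code{counts} (a \code{th17_counts}) and
#'   \code{truth} (theta, variant id, trajectory, init, protein scale,
#'   seed).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "th17_synth_config"))
  set.seed(derive_seed(config$seed, 1L))
  v <- config$variant
  theta <- resolve_truth_theta(config)
  tr <- simulate_th17(v, theta, config$init, cytokine_input(),
                      times = config$times)
  if (!tr$ok || max(tr$states) > 1e6)
    stop("data-generating parameters are not integrable over the grid",
         call. = FALSE)
  genes <- c("STAT3", "RORGT", "FOXP3")
  states <- c("stat3_mrna", "rorgt_mrna", "foxp3_mrna")
  m <- length(config$times); l <- config$n_rep
  libs <- matrix(exp(runif(m * l, log(config$lib_range[1]),
                           log(config$lib_range[2]))), m, l)
  phis <- matrix(exp(runif(3 * m, log(config$phi_range[1]),
                           log(config$phi_range[2]))), 3, m)
  rows <- expand.grid(replicate = seq_len(l), time_idx = seq_len(m),
                      gene_idx = 1:3)
  x <- tr$states[cbind(rows$time_idx, match(states[rows$gene_idx],
                                            colnames(tr$states)))]
  mu <- config$count_scale * libs[cbind(rows$time_idx, rows$replicate)] *
    pmax(x, 0)
  phi <- phis[cbind(rows$gene_idx, rows$time_idx)]
  df <- data.frame(
    gene = genes[rows$gene_idx],
    time_h = config$times[rows$time_idx],
    replicate = rows$replicate,
    count = rnbinom(nrow(rows), size = 1 / phi, mu = mu),
    library_size = libs[cbind(rows$time_idx, rows$replicate)],
    dispersion = phi)
  list(counts = th17_counts(df, count_scale = config$count_scale),
       truth = list(theta = theta, variant = v$id,
                    init = config$init, trajectory = tr,
                    protein_scale = config$protein_scale,
                    seed = config$seed))
}

#' Generate a synthetic protein dose-response table
#'
#' Per dose: the truth is simulated in the assay condition (IL6 20
#' ng/ml, TGFb at the dose), the latent FOXP3 protein level at 72 h is
#' scaled by the true scale factor, and normal measurement noise with
#' the configured replicate SD is added.
#'
#' @param config a \code{\link{synth_config}}.
#' @param truth the truth record from \code{\link{generate_counts}}.
#' @return a \code{th17_protein}.
#' @export
generate_protein <- function(config, truth) {
  stopifnot(inherits(config, "th17_synth_config"))
  set.seed(derive_seed(config$seed, 2L))
  v <- config$variant
  sds <- rep_len(config$protein_sd, length(config$doses))
  fstar <- fstar_at_doses(v, truth$theta, truth$init, config$doses,
                          method = "per_dose")
  if (anyNA(fstar))
    stop("truth simulation failed in the protein-assay condition",
         call. = FALSE)
  means <- config$protein_scale * fstar +
    if (all(sds == 0)) 0 else rnorm(length(config$doses), 0, sds)
  th17_protein(data.frame(dose_ng_ml = config$doses,
                          mean_percent = means,
                          sd_percent = ifelse(sds > 0, sds, 1e-6)))
}

#' Generate a complete synthetic data set
#'
#' @param config a \code{\link{synth_config}}.
#' @return list with \code{counts}, \code{protein} (or NULL), and
#'   \code{truth}.
#' @export
generate_dataset <- function(config) {
  gc <- generate_counts(config)
  protein <- if (isTRUE(config$protein)) generate_protein(config, gc$truth)
  list(counts = gc$counts, protein = protein, truth = gc$truth)
}

#' Write the hidden truth of a synthetic data set as JSON
#'
#' @param truth truth record from \code{\link{generate_counts}}.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(variant = truth$variant,
         theta = as.list(truth$theta),
         init = as.list(truth$init),
         protein_scale = truth$protein_scale,
         seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
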