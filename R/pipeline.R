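#' Default run configuration
#'
#' The pipeline is driven by a single configuration list (typically read
#' from YAML) covering the whole simulate -> fit -> evidence -> rank ->
#' predict chain.  Unknown keys are rejected up front so that typos fail
#' before any computation starts.
#'
#' @return nested list of defaults; see the fields in the source for the
#'   full schema.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "th17ti_out",
    counts = "counts.tsv",
    protein = "protein.tsv",
    use_protein = TRUE,
    variants = c(4L, 8L, 12L),
    il6_added = 20,
    tgfb_added = 1,
    psrf_threshold = 1.1,
    generator = list(variant = 8L, protein = TRUE, seed = NULL),
    sampler = list(n_beta = 30L, exponent = 5, n_iter = 20000L,
                   burn_frac = 0.5, thin = 10L, n_samplers = 5L,
                   prop_sd = 0.3),
    prediction = list(grid_n = 49L, doses = c(1/16, 1/8, 1/4, 1/2, 1),
                      t_assay = 72)
  )
}

#' Read and validate a run configuration
#'
#' @param path YAML file; keys override the defaults of
#'   \code{\link{default_run_config}}.  Unknown keys (top level or within
#'   the sampler / prediction / generator blocks) are an error.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config configuration list (possibly partial).
#' @export
validate_run_config <- function(config) {
  def <- default_run_config()
  check_keys <- function(given, allowed, where) {
    unknown <- setdiff(names(given), allowed)
    if (length(unknown))
      stop(sprintf("unknown config key%s in %s: %s",
                   if (length(unknown) > 1) "s" else "", where,
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }
  check_keys(config, names(def), "top level")
  for (blk in c("generator", "sampler", "prediction")) {
    if (!is.null(config[[blk]]))
      check_keys(config[[blk]], union(names(def[[blk]]),
                                      names(formals(synth_config))), blk)
  }
  out <- modifyList(def, config)
  if (!all(out$variants %in% 1:12))
    stop("variants must be ids in 1..12", call. = FALSE)
  if (out$sampler$n_beta < 2) stop("sampler$n_beta must be >= 2",
                                   call. = FALSE)
  out
}

# Short content hash of the configuration (simple polynomial rolling
# hash over its deparsed form), stamped into every output file header
# for provenance.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

output_header <- function(config, what) {
  c(sprintf("%s generated by th17ti", what),
    sprintf("seed: %d", config$seed),
    sprintf("config_hash: %s", config_hash(config)))
}

#' Generate synthetic data files
#'
#' Writes the synthetic count table, optionally the protein dose-response
#' table, and the hidden-truth JSON sidecar into the output directory.
#'
#' @param config run configuration (see \code{\link{read_run_config}}).
#' @return invisibly, the paths written.
#' @export
cmd_generate <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gen_args <- config$generator
  if (is.null(gen_args$seed)) gen_args$seed <- config$seed
  scfg <- do.call(synth_config, gen_args)
  ds <- generate_dataset(scfg)
  hdr <- output_header(config, "synthetic data")
  paths <- file.path(config$out_dir,
                     c("counts.tsv", "protein.tsv", "truth.json"))
  write_counts(ds$counts, paths[1], header = hdr)
  if (!is.null(ds$protein)) {
    write_protein(ds$protein, paths[2], header = hdr)
  } else {
    paths <- paths[-2]
  }
  write_truth(ds$truth, paths[length(paths)])
  invisible(paths)
}

#' Fit variants and rank them by evidence
#'
#' Reads the count (and optionally protein) tables, runs the
#' population-MCMC sampler for every requested variant, and writes the
#' evidence ranking, the PSRF report and a sample archive (RDS).
#'
#' @param config run configuration.
#' @return invisibly, the list of fits.
#' @export
cmd_fit <- function(config) {
  config <- validate_run_config(config)
  counts_path <- file.path(config$out_dir, config$counts)
  if (!file.exists(counts_path))
    stop("counts file not found: ", counts_path, call. = FALSE)
  counts <- read_counts(counts_path)
  protein <- NULL
  if (isTRUE(config$use_protein)) {
    protein_path <- file.path(config$out_dir, config$protein)
    if (!file.exists(protein_path))
      stop("protein likelihood enabled but protein file not found: ",
           protein_path, call. = FALSE)
    protein <- read_protein(protein_path)
  }
  settings <- do.call(sampler_settings,
                      config$sampler[names(config$sampler) %in%
                                     names(formals(sampler_settings))])
  input <- cytokine_input(il6_added = config$il6_added,
                          tgfb_added = config$tgfb_added)
  fits <- lapply(config$variants, function(vid) {
    message(sprintf("fitting M%d ...", vid))
    fit_th17(counts, vid, protein = protein, settings = settings,
             seed = derive_seed(config$seed, 100L + vid), input = input)
  })
  names(fits) <- paste0("M", config$variants)

  ranking <- if (length(fits) > 1) {
    rank_models(fits)
  } else {
    data.frame(variant = fits[[1]]$variant$id,
               log_evidence = fits[[1]]$evidence$log_evidence,
               se = fits[[1]]$evidence$se, rank = 1L)
  }
  hdr <- output_header(config, "evidence ranking")
  write_tsv_commented(ranking,
                      file.path(config$out_dir, "evidence.tsv"), hdr)
  psrf_df <- do.call(rbind, lapply(fits, function(f)
    data.frame(variant = f$variant$id, parameter = names(f$psrf),
               psrf = unname(f$psrf))))
  rownames(psrf_df) <- NULL
  write_tsv_commented(psrf_df, file.path(config$out_dir, "psrf.tsv"),
                      output_header(config, "PSRF report"))
  bad <- psrf_df$psrf > config$psrf_threshold
  if (any(bad, na.rm = TRUE))
    warning(sprintf("%d parameter(s) exceed PSRF threshold %.2f",
                    sum(bad, na.rm = TRUE), config$psrf_threshold),
            call. = FALSE)
  saveRDS(fits, file.path(config$out_dir, "fits.rds"))
  invisible(fits)
}

#' Posterior predictions from a fitted archive
#'
#' Writes the per-gene predictive bands and the FOXP3 dose-response table
#' for the top-ranked (or requested) variant.
#'
#' @param config run configuration.
#' @param archive path to the fits archive; defaults to the one
#'   \code{\link{cmd_fit}} writes.
#' @param variant variant id to predict from; default: highest evidence.
#' @return invisibly, the paths written.
#' @export
cmd_predict <- function(config, archive = NULL, variant = NULL) {
  config <- validate_run_config(config)
  if (is.null(archive)) archive <- file.path(config$out_dir, "fits.rds")
  if (!file.exists(archive)) stop("fit archive not found: ", archive,
                                  call. = FALSE)
  fits <- readRDS(archive)
  if (is.null(variant)) {
    variant <- if (length(fits) > 1) {
      rank_models(fits)$variant[1]
    } else {
      fits[[1]]$variant$id
    }
  }
  fit <- fits[[paste0("M", variant)]]
  if (is.null(fit)) stop("no fit for variant M", variant, call. = FALSE)
  grid <- seq(min(fit$counts$times), max(fit$counts$times),
              length.out = config$prediction$grid_n)
  band <- posterior_predictive(fit, grid = grid,
                               seed = derive_seed(config$seed, 301L))
  dose <- predict_dose_response(fit, doses = config$prediction$doses,
                                t_assay = config$prediction$t_assay)
  hdr <- c(output_header(config, "posterior predictions"),
           sprintf("variant: M%d", variant))
  paths <- file.path(config$out_dir,
                     c("predictive_bands.tsv", "dose_response.tsv"))
  write_tsv_commented(band, paths[1], hdr)
  write_tsv_commented(dose, paths[2], hdr)
  invisible(paths)
}
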