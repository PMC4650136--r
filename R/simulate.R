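#' @useDynLib th17ti
#' @importFrom stats approx approxfun dnorm quantile rnbinom rnorm
#'   runif sd setNames var
#' @importFrom utils modifyList read.delim write.table
NULL

STATE_NAMES6 <- c("stat3_mrna", "stat3_prot", "stat3_prot_star",
                  "rorgt_mrna", "foxp3_mrna", "foxp3_prot_star")
STATE_NAMES10 <- c("il6_ext", "il6_int", "tgfb_ext", "tgfb_int", STATE_NAMES6)

#' Cytokine input doses
#'
#' Doses of IL6 and TGFb added at time zero, together with the reference
#' input levels of the Th17 polarizing condition (IL6 20 ng/ml, TGFb
#' 1 ng/ml).  Inside the model, extracellular cytokine levels are the
#' dimensionless dose ratios added/reference.
#'
#' @param il6_added,tgfb_added added doses in ng/ml (>= 0).
#' @param il6_input,tgfb_input reference inputs in ng/ml (> 0).
#' @return object of class \code{th17_input}.
#' @export
cytokine_input <- function(il6_added = 20, tgfb_added = 1,
                           il6_input = 20, tgfb_input = 1) {
  if (il6_added < 0 || tgfb_added < 0)
    stop("added doses must be nonnegative", call. = FALSE)
  if (il6_input <= 0 || tgfb_input <= 0)
    stop("reference inputs must be strictly positive", call. = FALSE)
  structure(list(il6_added = il6_added, tgfb_added = tgfb_added,
                 il6_input = il6_input, tgfb_input = tgfb_input,
                 il6_ratio = il6_added / il6_input,
                 tgfb_ratio = tgfb_added / tgfb_input),
            class = "th17_input")
}

#' Closed-form intracellular cytokine level
#'
#' Extracellular cytokine decays at a first-order conversion rate into the
#' intracellular pool, so the intracellular level follows
#' \code{(added/input_ref) * (1 - exp(-rate * t))}: zero at t = 0,
#' saturating at the dose ratio.
#'
#' @param t time in hours (vectorized, >= 0).
#' @param rate positive conversion rate (1/h).
#' @param added added dose (ng/ml).
#' @param input_ref reference input (ng/ml, > 0).
#' @return intracellular level (dimensionless dose-ratio units).
#' @export
cytokine_analytic <- function(t, rate, added, input_ref) {
  if (input_ref <= 0)
    stop("input_ref must be strictly positive", call. = FALSE)
  if (rate <= 0) stop("rate must be strictly positive", call. = FALSE)
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  (added / input_ref) * (1 - exp(-rate * t))
}

#' Initial condition of the core network
#'
#' Conventions: STAT3 protein and FOXP3 protein are measured in unitless
#' relative abundances and start at 1; phospho-STAT3 starts at 0;
#' intracellular cytokines start at 0 and extracellular cytokines at the
#' added/reference dose ratio.  mRNA initial levels come from data (the
#' replicate-mean relative abundance at 0 h) when a count data set is
#' supplied; RORgt mRNA may alternatively be started at 0 since its basal
#' expression is negligible.
#'
#' @param stat3_mrna,rorgt_mrna,foxp3_mrna initial mRNA relative
#'   abundances (ignored for genes present in \code{counts}).
#' @param counts optional \code{th17_counts} object; if given, initial
#'   mRNA levels are the replicate means of count/library_size at the
#'   first time point.
#' @param rorgt_from_data if \code{FALSE}, RORgt mRNA starts at 0
#'   regardless of the data.
#' @return named numeric vector over the six core states.
#' @export
th17_init <- function(stat3_mrna = 1, rorgt_mrna = 0, foxp3_mrna = 0,
                      counts = NULL, rorgt_from_data = TRUE) {
  init <- c(stat3_mrna = stat3_mrna, stat3_prot = 1, stat3_prot_star = 0,
            rorgt_mrna = rorgt_mrna, foxp3_mrna = foxp3_mrna,
            foxp3_prot_star = 1)
  if (!is.null(counts)) {
    stopifnot(inherits(counts, "th17_counts"))
    ab0 <- initial_abundance(counts)
    for (g in names(ab0)) {
      state <- gene_to_state(g)
      if (identical(state, "rorgt_mrna") && !rorgt_from_data) next
      if (!is.na(state)) init[state] <- ab0[[g]]
    }
  }
  if (any(init < 0)) stop("initial states must be nonnegative", call. = FALSE)
  init
}

# Replicate-mean model-scale abundance (count / (count_scale * library
# size)) at the first observed time point, per gene.
initial_abundance <- function(counts) {
  d <- counts$df
  t0 <- min(d$time_h)
  d0 <- d[d$time_h == t0 & !is.na(d$count), , drop = FALSE]
  vapply(split(d0, d0$gene),
         function(x) mean(x$count / (counts$count_scale *
                                     x$library_size)),
         numeric(1))
}

# Map a measured gene name onto the mRNA state it reports on.
gene_to_state <- function(gene) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", gene))
  switch(key,
         STAT3 = "stat3_mrna",
         RORGT = , RORC = , RORGAMMAT = "rorgt_mrna",
         FOXP3 = "foxp3_mrna",
         NA_character_)
}

#' Reference R implementation of the core-network right-hand side
#'
#' Pure-R derivative of the six core states, with intracellular cytokine
#' levels supplied through their closed forms.  The compiled equivalent is
#' what \code{\link{simulate_th17}} integrates; this function is the
#' readable single source of the model equations and is used to
#' cross-check the compiled code.
#'
#' @param t time (hours).
#' @param state named state vector (six core states).
#' @param theta_full full 18-rate vector (inactive mechanisms 0), e.g.
#'   from \code{\link{expand_theta}}.
#' @param input a \code{th17_input}.
#' @return named vector of derivatives d(state)/dt.
#' @export
th17_rhs <- function(t, state, theta_full, input) {
  th <- unname(theta_full)
  il6 <- input$il6_ratio * (1 - exp(-th[1] * t))
  tgfb <- input$tgfb_ratio * (1 - exp(-th[9] * t))
  s_m <- state[["stat3_mrna"]]; s_p <- state[["stat3_prot"]]
  s_s <- state[["stat3_prot_star"]]; r_m <- state[["rorgt_mrna"]]
  f_m <- state[["foxp3_mrna"]]; f_s <- state[["foxp3_prot_star"]]
  c(stat3_mrna = th[2] + th[3] * s_s - th[4] * s_m,
    stat3_prot = th[5] * s_m - th[6] * il6 * s_p - th[7] * s_p,
    stat3_prot_star = th[6] * il6 * s_p - th[8] * s_s,
    rorgt_mrna = th[10] * tgfb * s_s - th[11] * f_s * r_m - th[12] * r_m,
    foxp3_mrna = th[13] + th[14] * tgfb - th[15] * s_s * f_m - th[16] * f_m,
    foxp3_prot_star = th[17] * f_m - th[18] * f_s)
}

#' Simulate the Th17 core network
#'
#' Integrates the model with a stiff (BDF) solver.  By default the
#' intracellular cytokine levels enter through their closed-form solutions
#' and only the six transcription-factor states are integrated; with
#' \code{cytokines = "ode"} the extracellular/intracellular conversion is
#' integrated explicitly as a 10-state system (useful to validate the
#' closed forms and cytokine mass balance).
#'
#' @param variant a \code{th17_variant}.
#' @param theta active-parameter vector for \code{variant} (positive), or
#'   a full length-18 vector.
#' @param init initial condition from \code{\link{th17_init}}.
#' @param input a \code{th17_input}.
#' @param times increasing vector of output times in hours, starting at 0.
#' @param cytokines \code{"analytic"} (default) or \code{"ode"}.
#' @param rtol,atol solver tolerances.
#' @return object of class \code{th17_traj}: list with \code{times},
#'   \code{states} (matrix time x species, cytokine columns included in
#'   both modes), \code{ok} (FALSE if the integration failed; states are
#'   then NA), plus the inputs used.  Never signals on solver failure --
#'   the likelihood layer maps \code{ok = FALSE} to log-likelihood -Inf.
#' @export
simulate_th17 <- function(variant, theta, init = th17_init(),
                          input = cytokine_input(),
                          times = seq(0, 72, by = 1),
                          cytokines = c("analytic", "ode"),
                          rtol = 1e-8, atol = 1e-10) {
  cytokines <- match.arg(cytokines)
  stopifnot(inherits(variant, "th17_variant"), inherits(input, "th17_input"))
  if (times[1] != 0) stop("times must start at 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  theta_full <- if (length(theta) == 18L) {
    check_full_theta(theta, variant)
  } else {
    expand_theta(theta, variant)
  }
  parms <- c(unname(theta_full), input$il6_ratio, input$tgfb_ratio)
  y0 <- init[STATE_NAMES6]
  if (anyNA(y0)) stop("incomplete initial condition", call. = FALSE)

  if (cytokines == "analytic") {
    y <- unname(y0)
    func <- "th17_derivs6"
  } else {
    y <- c(input$il6_ratio, 0, input$tgfb_ratio, 0, unname(y0))
    func <- "th17_derivs10"
  }
  out <- tryCatch(
    suppressWarnings(deSolve::ode(
      y = y, times = times, func = func, parms = parms,
      dllname = "th17ti", initfunc = "th17_initmod",
      method = "bdf", rtol = rtol, atol = atol)),
    error = function(e) NULL)

  ok <- !is.null(out) && nrow(out) == length(times) && !anyNA(out) &&
    all(is.finite(out))
  if (ok) {
    if (cytokines == "analytic") {
      states <- cbind(
        il6_ext = input$il6_ratio * exp(-theta_full[1] * times),
        il6_int = cytokine_analytic(times, theta_full[1],
                                    input$il6_added, input$il6_input),
        tgfb_ext = input$tgfb_ratio * exp(-theta_full[9] * times),
        tgfb_int = cytokine_analytic(times, theta_full[9],
                                     input$tgfb_added, input$tgfb_input),
        out[, -1, drop = FALSE])
    } else {
      states <- out[, -1, drop = FALSE]
    }
    colnames(states) <- STATE_NAMES10
  } else {
    states <- matrix(NA_real_, length(times), 10L,
                     dimnames = list(NULL, STATE_NAMES10))
  }
  structure(list(times = times, states = states, ok = ok,
                 variant = variant, theta_full = theta_full,
                 input = input, init = y0, cytokines = cytokines),
            class = "th17_traj")
}

check_full_theta <- function(theta, variant) {
  theta <- unname(theta)
  if (any(!is.finite(theta)) || any(theta[variant$active] <= 0))
    stop("active rates must be finite and strictly positive", call. = FALSE)
  inactive <- setdiff(1:18, variant$active)
  if (any(theta[inactive] != 0))
    stop("rates of inactive mechanisms must be 0 in a full vector",
         call. = FALSE)
  names(theta) <- paste0("theta", 1:18)
  theta
}

#' Query a trajectory at arbitrary times
#'
#' Linear interpolation on the stored time grid (exact at grid points).
#'
#' @param traj a \code{th17_traj}.
#' @param t times within the integration span.
#' @param species state names (default: all).
#' @return matrix length(t) x length(species).
#' @export
traj_at <- function(traj, t, species = colnames(traj$states)) {
  stopifnot(inherits(traj, "th17_traj"))
  if (!traj$ok) stop("trajectory is a failed integration", call. = FALSE)
  if (any(t < min(traj$times)) || any(t > max(traj$times)))
    stop("query time outside the integration span", call. = FALSE)
  species <- match.arg(species, colnames(traj$states), several.ok = TRUE)
  out <- vapply(species, function(s) {
    approx(traj$times, traj$states[, s], xout = t)$y
  }, numeric(length(t)))
  matrix(out, nrow = length(t), dimnames = list(NULL, species))
}

#' @export
print.th17_traj <- function(x, ...) {
  cat(sprintf("Th17 trajectory (M%d, %s cytokines): %d time points over [%g, %g] h%s\n",
              x$variant$id, x$cytokines, length(x$times), min(x$times),
              max(x$times), if (x$ok) "" else " [FAILED]"))
  invisible(x)
}

#' Tidy export of a trajectory
#'
#' @param x a \code{th17_traj}.
#' @param row.names,optional,... ignored (base generic signature).
#' @return data.frame with columns time_h, species, value.
#' @export
as.data.frame.th17_traj <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(
    time_h = rep(x$times, ncol(x$states)),
    species = rep(colnames(x$states), each = length(x$times)),
    value = as.vector(x$states))
}
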