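#' Model variants of the Th17 core network
#'
#' The core network couples the cytokine inputs IL6 and TGFb to the
#' transcription factors STAT3, RORgt and FOXP3.  On top of the backbone
#' (cytokine conversion, the STAT3 module, TGFb/STAT3-driven RORgt
#' activation, first-order degradation and translation), four regulatory
#' mechanisms are treated as hypotheses that may be switched on or off:
#'
#' \itemize{
#'   \item basal FOXP3 induction (rate \code{theta13}),
#'   \item FOXP3 induction by intracellular TGFb (rate \code{theta14}),
#'   \item RORgt inhibition by FOXP3 protein (rate \code{theta11}),
#'   \item FOXP3 inhibition by phospho-STAT3 (rate \code{theta15}).
#' }
#'
#' Every model must produce FOXP3 somehow, so at least one of the two
#' induction mechanisms is always active.  The twelve admissible
#' combinations are numbered 1--12: variants 1--4 have basal induction
#' only, 5--8 TGFb induction only, and 9--12 both; within each block of
#' four the two inhibition flags follow the pattern (off,off), (off,on),
#' (on,off), (on,on) for (FOXP3 inhibits RORgt, STAT3 inhibits FOXP3).
#'
#' @param id integer in 1..12 selecting the variant.
#' @return An object of class \code{th17_variant}: a list with the variant
#'   \code{id}, the four logical mechanism flags (\code{basal_foxp3},
#'   \code{tgfb_induces_foxp3}, \code{foxp3_inhibits_rorgt},
#'   \code{stat3_inhibits_foxp3}), and \code{active}, the integer indices
#'   (into \code{theta1..theta18}) of the rate parameters that are free in
#'   this variant.
#' @examples
#' build_variant(8)
#' sapply(1:12, function(i) length(build_variant(i)$active))
#' @export
build_variant <- function(id) {
  if (length(id) != 1L || !is.finite(id) || id != as.integer(id) ||
      id < 1L || id > 12L) {
    stop("variant id must be a single integer in 1..12", call. = FALSE)
  }
  id <- as.integer(id)
  block <- (id - 1L) %/% 4L   # 0: basal only, 1: TGFb only, 2: both
  within <- (id - 1L) %% 4L   # inhibition pattern within the block
  v <- structure(
    list(
      id = id,
      basal_foxp3 = block != 1L,
      tgfb_induces_foxp3 = block != 0L,
      foxp3_inhibits_rorgt = within >= 2L,
      stat3_inhibits_foxp3 = within %% 2L == 1L
    ),
    class = "th17_variant"
  )
  v$active <- active_indices(v)
  v
}

# Backbone rates present in every variant; the four hypothesis rates
# (11, 13, 14, 15) join when the corresponding mechanism is active.
BACKBONE_IDX <- c(1:10, 12L, 16:18)

active_indices <- function(v) {
  idx <- BACKBONE_IDX
  if (v$foxp3_inhibits_rorgt) idx <- c(idx, 11L)
  if (v$basal_foxp3) idx <- c(idx, 13L)
  if (v$tgfb_induces_foxp3) idx <- c(idx, 14L)
  if (v$stat3_inhibits_foxp3) idx <- c(idx, 15L)
  sort(idx)
}

#' @export
print.th17_variant <- function(x, ...) {
  onoff <- function(b) if (b) "on" else "off"
  cat(sprintf(
    paste0("Th17 core-network model variant M%d\n",
           "  basal FOXP3 induction:    %s\n",
           "  TGFb induces FOXP3:       %s\n",
           "  FOXP3 inhibits RORgt:     %s\n",
           "  STAT3 inhibits FOXP3:     %s\n",
           "  free parameters:          %d\n"),
    x$id, onoff(x$basal_foxp3), onoff(x$tgfb_induces_foxp3),
    onoff(x$foxp3_inhibits_rorgt), onoff(x$stat3_inhibits_foxp3),
    length(x$active)))
  invisible(x)
}

#' Number of free rate parameters of a variant
#'
#' Rates attached to inactive mechanisms are removed from the sampled
#' parameter vector entirely (rather than pinned at zero), so the model
#' dimension seen by the prior -- and hence by the evidence -- matches the
#' mechanisms actually present.
#'
#' @param variant a \code{th17_variant}.
#' @return integer dimension (14 backbone rates + active mechanisms).
#' @export
n_free_parameters <- function(variant) {
  stopifnot(inherits(variant, "th17_variant"))
  length(variant$active)
}

#' Expand an active-parameter vector to the full 18-rate vector
#'
#' @param theta positive rates for the active parameters of
#'   \code{variant}, in the order of \code{variant$active}.
#' @param variant a \code{th17_variant}.
#' @return named numeric vector \code{theta1..theta18}; rates of inactive
#'   mechanisms are 0 so that their terms vanish from the dynamics.
#' @export
expand_theta <- function(theta, variant) {
  stopifnot(inherits(variant, "th17_variant"))
  if (length(theta) != length(variant$active)) {
    stop(sprintf("expected %d active parameters for M%d, got %d",
                 length(variant$active), variant$id, length(theta)),
         call. = FALSE)
  }
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    stop("all rate parameters must be finite and strictly positive",
         call. = FALSE)
  }
  full <- numeric(18L)
  full[variant$active] <- theta
  names(full) <- paste0("theta", 1:18)
  full
}

#' Restrict a full 18-rate vector to the active parameters of a variant
#'
#' @param theta_full numeric vector of length 18 (\code{theta1..theta18}).
#' @param variant a \code{th17_variant}.
#' @return named vector of the active rates, in index order.
#' @export
restrict_theta <- function(theta_full, variant) {
  stopifnot(inherits(variant, "th17_variant"), length(theta_full) == 18L)
  out <- theta_full[variant$active]
  names(out) <- paste0("theta", variant$active)
  out
}
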