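#' Offspring carriage probabilities for the four mating classes
#'
#' Under random mating there are four mating classes between hosts carrying
#' the augmented symbiont community (S) and hosts carrying the resident
#' community (s). Writing the mother first, the probability that the
#' offspring carries S is 0 for s x s, `alpha` for S x s, `beta` for s x S
#' and `alpha + beta - alpha*beta` for S x S (the father's and mother's
#' transmission events are independent).
#'
#' @param tp A [transmission_params()] object (or preset name).
#' @return A data frame with one row per mating class and columns `mating`,
#'   `freq` (mating frequency as a function of the carrier frequency `p`,
#'   given symbolically), `p_S` and `p_s`; `p_S + p_s = 1` in every row.
#' @examples
#' offspring_carriage_probs("biparental")
#' @export
offspring_carriage_probs <- function(tp) {
  tp <- .as_tp(tp)
  a <- tp$alpha
  b <- tp$beta
  p_S <- c(0, a, b, a + b - a * b)
  data.frame(
    mating = c("s x s", "S x s", "s x S", "S x S"),
    freq = c("q^2", "p*q", "p*q", "p^2"),
    p_S = p_S,
    p_s = 1 - p_S,
    stringsAsFactors = FALSE
  )
}

# phi = alpha + beta - alpha*beta*p, the effective transmission factor.
.phi <- function(p, tp) tp$alpha + tp$beta - tp$alpha * tp$beta * p

#' Mean fitness of the host population
#'
#' The normalising constant of the frequency recursion:
#' \eqn{\bar{w} = 1 - p (1 - w)(\alpha + \beta - \alpha\beta p)}. It is the
#' fitness-weighted mass of offspring over the mating classes, so the
#' post-selection offspring frequencies sum to one after dividing by it.
#'
#' @param p Frequency (or vector of frequencies) in \[0, 1\] of hosts
#'   carrying the augmented community S.
#' @param w Relative fitness of carrier hosts (positive).
#' @param tp A [transmission_params()] object (or preset name).
#' @return Mean fitness, strictly positive for valid inputs.
#' @examples
#' mean_fitness(0.5, 0.6, "biparental") # 0.7
#' @export
mean_fitness <- function(p, w, tp) {
  tp <- .as_tp(tp)
  .check_freq(p)
  .check_w(w)
  1 - p * (1 - w) * .phi(p, tp)
}

#' Carrier frequency in the next host generation
#'
#' One application of the discrete-generation map
#' \eqn{p' = (p w / \bar{w}) (\alpha + \beta - \alpha\beta p)} for the
#' frequency of hosts carrying the augmented symbiont community under random
#' mating, selection on hosts (relative fitness `w`) and vertical
#' transmission with probabilities `alpha` (mother) and `beta` (father).
#'
#' @inheritParams mean_fitness
#' @return The next-generation frequency, in \[0, 1\]. Values are clipped to
#'   the unit interval only to absorb floating-point rounding (tolerance
#'   1e-12); any larger excursion is an error.
#' @examples
#' next_frequency(0.5, 0.6, "maternal") # 0.375
#' @export
next_frequency <- function(p, w, tp) {
  tp <- .as_tp(tp)
  .check_freq(p)
  .check_w(w)
  pp <- p * w / mean_fitness(p, w, tp) * .phi(p, tp)
  out_of_range <- pp < -1e-12 | pp > 1 + 1e-12
  if (any(out_of_range))
    stop("next_frequency left [0, 1] by more than rounding tolerance; ",
         "this indicates invalid parameters")
  pmin(pmax(pp, 0), 1)
}

#' Per-generation change in carrier frequency
#'
#' \eqn{\Delta p = (p/\bar{w})(\phi (p + w q) - 1)} with
#' \eqn{\phi = \alpha + \beta - \alpha\beta p} and \eqn{q = 1 - p}.
#' Identical to `next_frequency(p, w, tp) - p` up to rounding. The carrier
#' community spreads when \eqn{(p + wq) > 1/\phi}; at rarity
#' (\eqn{p \to 0}) this is \eqn{w > 1/(\alpha+\beta)}.
#'
#' @inheritParams mean_fitness
#' @return Signed change in frequency.
#' @examples
#' delta_p(0.5, 0.6, "maternal") # -0.125
#' @export
delta_p <- function(p, w, tp) {
  tp <- .as_tp(tp)
  .check_freq(p)
  .check_w(w)
  phi <- .phi(p, tp)
  p / mean_fitness(p, w, tp) * (phi * (p + w * (1 - p)) - 1)
}

#' Invasion threshold of a rare symbiont
#'
#' The relative host fitness above which a rare augmented community invades:
#' \eqn{w_0 = 1/(\alpha + \beta)}, the value of `w` at which [delta_p()]
#' changes sign as \eqn{p \to 0^+}. Equals 1/2 under biparental and 1 under
#' maternal transmission.
#'
#' @param tp A [transmission_params()] object (or preset name).
#' @return The threshold fitness, a positive number.
#' @examples
#' invasion_threshold("biparental") # 0.5
#' invasion_threshold("maternal")   # 1
#' @export
invasion_threshold <- function(tp) {
  tp <- .as_tp(tp)
  if (tp$alpha + tp$beta == 0)
    stop("no vertical transmission route: alpha + beta must be positive")
  1 / (tp$alpha + tp$beta)
}

#' Iterate the frequency recursion over generations
#'
#' @inheritParams mean_fitness
#' @param p0 Initial carrier frequency in \[0, 1\].
#' @param n_gen Number of generations to iterate (positive integer).
#' @return Numeric vector of length `n_gen + 1` starting at `p0`; entry
#'   `i + 1` is [next_frequency()] applied to entry `i`.
#' @examples
#' iterate_generations(0.01, 0.6, "biparental", 50)
#' @export
iterate_generations <- function(p0, w, tp, n_gen) {
  tp <- .as_tp(tp)
  .check_freq(p0)
  .check_w(w)
  if (!is.numeric(n_gen) || length(n_gen) != 1L || n_gen < 1 || n_gen != round(n_gen))
    stop("`n_gen` must be a positive integer")
  out <- numeric(n_gen + 1L)
  out[1L] <- p0
  for (i in seq_len(n_gen)) out[i + 1L] <- next_frequency(out[i], w, tp)
  out
}

#' Long-run fate of the recursion from a given starting frequency
#'
#' Iterates [next_frequency()] until the frequency is within `tol` of 0 or 1
#' or the generation cap is reached.
#'
#' @inheritParams iterate_generations
#' @param tol Convergence tolerance on the distance to an absorbing state.
#' @param max_gen Generation cap (default 1e4).
#' @return A list with `outcome` (`"loss"`, `"fixation"` or `"undecided"`),
#'   the final frequency `p` and the number of generations used.
#' @export
recursion_fate <- function(p0, w, tp, tol = 1e-6, max_gen = 1e4) {
  tp <- .as_tp(tp)
  p <- p0
  for (g in seq_len(max_gen)) {
    p <- next_frequency(p, w, tp)
    if (p < tol) return(list(outcome = "loss", p = p, generations = g))
    if (p > 1 - tol) return(list(outcome = "fixation", p = p, generations = g))
  }
  list(outcome = "undecided", p = p, generations = max_gen)
}
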