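#' Vertical-transmission parameters
#'
#' Bundles the probability `alpha` that a mother passes the augmented
#' symbiont community on to an offspring with the probability `beta` that a
#' father does. The three named presets are the modes studied throughout:
#' biparental `(1, 1)`, maternal `(1, 0)` and paternal `(0, 1)`.
#'
#' @param alpha Probability in \[0, 1\] that the mother transmits, or one of
#'   the preset names `"biparental"`, `"maternal"`, `"paternal"`.
#' @param beta Probability in \[0, 1\] that the father transmits. Ignored
#'   when `alpha` is a preset name.
#' @return An object of class `transmission_params` with fields `alpha` and
#'   `beta`.
#' @examples
#' transmission_params("maternal")
#' transmission_params(0.5, 0.5)
#' @export
transmission_params <- function(alpha = 1, beta = 1) {
  if (is.character(alpha)) {
    mode <- match.arg(alpha, c("biparental", "maternal", "paternal"))
    ab <- switch(mode,
      biparental = c(1, 1),
      maternal   = c(1, 0),
      paternal   = c(0, 1)
    )
    alpha <- ab[[1L]]
    beta <- ab[[2L]]
  }
  .check_prob(alpha, "alpha")
  .check_prob(beta, "beta")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "transmission_params")
}

#' @export
print.transmission_params <- function(x, ...) {
  cat(sprintf("transmission_params: alpha = %g (mother), beta = %g (father)\n",
              x$alpha, x$beta))
  invisible(x)
}

.as_tp <- function(tp) {
  if (inherits(tp, "transmission_params")) return(tp)
  if (is.character(tp) && length(tp) == 1L) return(transmission_params(tp))
  if (is.numeric(tp) && length(tp) == 2L) return(transmission_params(tp[1L], tp[2L]))
  stop("`tp` must be a transmission_params object, a preset name, or c(alpha, beta)")
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

.check_freq <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop("`p` must be a frequency (or frequencies) in [0, 1]", call. = FALSE)
  invisible(p)
}

.check_w <- function(w) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w <= 0)
    stop("`w` must be a single positive number", call. = FALSE)
  invisible(w)
}

#' Demographic parameters of the stochastic birth-death host population
#'
#' @param b0 Per-female birth rate (events per unit time); density
#'   independent. Default 4.
#' @param d0 Intrinsic per-capita death rate. Default 1.
#' @param dprime Density-dependence coefficient of death: each host adds
#'   `dprime` to every individual's death rate. Default 0.001, giving a
#'   symbiont-free equilibrium of `(b0/2 - d0)/dprime = 1000` hosts.
#' @param e0 Per-capita horizontal uptake rate of the focal symbiont from the
#'   environment. Default 0 (strict vertical transmission).
#' @return An object of class `demography_params`.
#' @details A positive symbiont-free equilibrium requires `b0/2 > d0`
#'   (daughters are born at rate `b0/2` per female under the 1:1 birth sex
#'   ratio).
#' @export
demography_params <- function(b0 = 4, d0 = 1, dprime = 0.001, e0 = 0) {
  for (nm in c("b0", "d0", "dprime", "e0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("`%s` must be a single non-negative number", nm), call. = FALSE)
  }
  structure(list(b0 = b0, d0 = d0, dprime = dprime, e0 = e0),
            class = "demography_params")
}

#' @export
print.demography_params <- function(x, ...) {
  cat(sprintf("demography_params: b0 = %g, d0 = %g, dprime = %g, e0 = %g\n",
              x$b0, x$d0, x$dprime, x$e0))
  if (x$b0 / 2 > x$d0)
    cat(sprintf("  symbiont-free equilibrium: %g hosts\n",
                (x$b0 / 2 - x$d0) / x$dprime))
  invisible(x)
}

#' Parameters of the deterministic (mean-field) differential equations
#'
#' Rate constants for the two-type and six-type ODE systems. Densities `x`
#' relate to host counts `n` through the scaling parameter `nu`
#' (`x = n / nu`); with the default `nu = 1` densities are host counts and
#' the two-type density term `2 dprime nu (x+ + x-)` equals
#' `dprime * (total hosts)`, matching the stochastic model.
#'
#' @inheritParams demography_params
#' @param nu Density scaling (hosts per density unit), positive. Default 1.
#' @param alpha,beta Vertical-transmission probabilities (mother, father).
#' @param w Relative fitness of carrier hosts; the carrier death rate is
#'   divided by `w`.
#' @return An object of class `ode_params`.
#' @export
ode_params <- function(b0 = 4, d0 = 1, dprime = 0.001, nu = 1, e0 = 0,
                       alpha = 1, beta = 1, w = 1) {
  for (nm in c("b0", "d0", "dprime", "e0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("`%s` must be a single non-negative number", nm), call. = FALSE)
  }
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0)
    stop("`nu` must be a single positive number", call. = FALSE)
  .check_prob(alpha, "alpha")
  .check_prob(beta, "beta")
  .check_w(w)
  structure(list(b0 = b0, d0 = d0, dprime = dprime, nu = nu, e0 = e0,
                 alpha = alpha, beta = beta, w = w),
            class = "ode_params")
}

#' @export
print.ode_params <- function(x, ...) {
  cat(sprintf(
    "ode_params: b0 = %g, d0 = %g, dprime = %g, nu = %g, e0 = %g, alpha = %g, beta = %g, w = %g\n",
    x$b0, x$d0, x$dprime, x$nu, x$e0, x$alpha, x$beta, x$w))
  invisible(x)
}

# Apply a transmission mode name to ode_params, returning updated params.
.ode_with_mode <- function(params, mode) {
  if (is.null(mode)) return(params)
  tp <- .as_tp(mode)
  params$alpha <- tp$alpha
  params$beta <- tp$beta
  params
}
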