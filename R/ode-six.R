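# Six-type mean-field system: females with/without the symbiont (x+, x-),
# M- males with/without it (y+, y-), M+ males with/without it (z+, z-).
# M- fathers transmit nothing (maternal-rule matings), M+ fathers transmit
# their carriage (biparental-rule matings); mothers always transmit.
# Density-dependent death d0 + dprime*nu*N with N the total over all six
# types, divided by w for carriers; horizontal uptake e0 on every
# non-carrier type. Written with the female birth terms normalised by the
# male total and the male birth terms by the female total, which coincide
# under the 1:1 sex ratio the reduction assumes.

.SIX_NAMES <- c("x_plus", "x_minus", "y_plus", "y_minus", "z_plus", "z_minus")

#' Right-hand side of the six-type modifier system
#'
#' @param state Numeric vector `c(x_plus, x_minus, y_plus, y_minus,
#'   z_plus, z_minus)` of non-negative densities: females with/without the
#'   augmented community, M- males with/without, M+ males with/without.
#' @param params An [ode_params()] object (`alpha`/`beta` are not used:
#'   the mating-level transmission mode is determined by the father's
#'   modifier class).
#' @return The six time derivatives.
#' @export
rhs_six_type <- function(state, params) {
  stopifnot(inherits(params, "ode_params"), length(state) == 6L)
  xp <- state[[1L]]; xm <- state[[2L]]
  yp <- state[[3L]]; ym <- state[[4L]]
  zp <- state[[5L]]; zm <- state[[6L]]
  X <- xp + xm
  M <- yp + ym + zp + zm
  if (X <= 0 || M <= 0)
    stop("structural extinction: a sex is absent, mating fractions undefined")
  .rhs_six(xp, xm, yp, ym, zp, zm, X, M, params)
}

.rhs_six <- function(xp, xm, yp, ym, zp, zm, X, M, params) {
  N <- X + M
  b2 <- params$b0 / 2
  dd <- params$d0 + params$dprime * params$nu * N
  ddw <- dd / params$w
  e0 <- params$e0
  c(
    b2 * (xp * M + xm * zp) / M        - xp * ddw + e0 * xm,
    b2 * (xm * ym + xm * yp + xm * zm) / M - xm * dd - e0 * xm,
    b2 * (xp * yp + xp * ym) / X       - yp * ddw + e0 * ym,
    b2 * (xm * ym + xm * yp) / X       - ym * dd - e0 * ym,
    b2 * (xp * zp + xp * zm + xm * zp) / X - zp * ddw + e0 * zm,
    b2 * (xm * zm) / X                 - zm * dd - e0 * zm
  )
}

# guarded version for the integrator: births vanish when a sex is absent
.rhs_six_safe <- function(state, params) {
  xp <- state[[1L]]; xm <- state[[2L]]
  yp <- state[[3L]]; ym <- state[[4L]]
  zp <- state[[5L]]; zm <- state[[6L]]
  X <- xp + xm
  M <- yp + ym + zp + zm
  if (X <= 0 || M <= 0) {
    N <- X + M
    dd <- params$d0 + params$dprime * params$nu * N
    ddw <- dd / params$w
    e0 <- params$e0
    return(c(-xp * ddw + e0 * xm, -xm * dd - e0 * xm,
             -yp * ddw + e0 * ym, -ym * dd - e0 * ym,
             -zp * ddw + e0 * zm, -zm * dd - e0 * zm))
  }
  .rhs_six(xp, xm, yp, ym, zp, zm, X, M, params)
}

#' Default invasion initial condition for the six-type system
#'
#' The symbiont-free two-sex equilibrium (total density solving
#' `d0 + dprime * nu * N = b0 / 2`) split 1:1 between the sexes, with
#' carriers added at `init_frac` of the females and the
#' transmission-suppressing allele M- at `mminus_frac` of the males (all
#' initial carriers female, all initial males non-carriers).
#'
#' @param params An [ode_params()] object.
#' @param init_frac Initial carrier fraction among females.
#' @param mminus_frac Initial M- fraction among males.
#' @return Named six-component state vector.
#' @export
six_type_init <- function(params, init_frac = 0.01, mminus_frac = 0.1) {
  Nstar <- (params$b0 / 2 - params$d0) / (params$dprime * params$nu)
  if (Nstar <= 0) stop("host population not viable: b0/2 < d0")
  X0 <- Nstar / 2
  M0 <- Nstar / 2
  setNames(c(init_frac * X0, (1 - init_frac) * X0,
             0, mminus_frac * M0,
             0, (1 - mminus_frac) * M0),
           .SIX_NAMES)
}

#' Deterministic trajectory of the six-type modifier system
#'
#' Integrates [rhs_six_type()] and reports, alongside the six densities,
#' the derived series used to overlay stochastic ensembles: the carrier
#' frequency, the M- frequency among males, and the coefficient of
#' disequilibrium `D = p1 p4 - p2 p3` over the four male classes.
#'
#' @param params An [ode_params()] object.
#' @param init Initial state (default [six_type_init()]).
#' @param t_span `c(t0, t1)`.
#' @param t_eval Output times (default 101 equally spaced points).
#' @param rtol,atol Integrator tolerances.
#' @inheritParams six_type_init
#' @return Data frame with `t`, the six densities, `N`, `carrier_freq`,
#'   `mminus_freq` and `D`.
#' @export
modifier_trajectory <- function(params, init = NULL, t_span = c(0, 50),
                                t_eval = NULL, init_frac = 0.01,
                                mminus_frac = 0.1,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "ode_params"))
  if (is.null(init)) init <- six_type_init(params, init_frac, mminus_frac)
  if (length(init) != 6L) stop("`init` must have six components")
  init <- setNames(as.numeric(init), .SIX_NAMES)
  if (is.null(t_eval)) t_eval <- seq(t_span[1L], t_span[2L], length.out = 101L)
  sol <- ode_integrate(.rhs_six_safe, init, t_span, params,
                       t_eval = t_eval, rtol = rtol, atol = atol, hmax = 5)
  y <- sol$y
  N <- rowSums(y)
  Mtot <- y[, "y_plus"] + y[, "y_minus"] + y[, "z_plus"] + y[, "z_minus"]
  p1 <- y[, "y_minus"] / Mtot
  p2 <- y[, "y_plus"] / Mtot
  p3 <- y[, "z_minus"] / Mtot
  p4 <- y[, "z_plus"] / Mtot
  out <- data.frame(t = sol$t, y, check.names = FALSE)
  out$N <- N
  out$carrier_freq <- (y[, "x_plus"] + y[, "y_plus"] + y[, "z_plus"]) / N
  out$mminus_freq <- (y[, "y_plus"] + y[, "y_minus"]) / Mtot
  out$D <- p1 * p4 - p2 * p3
  out
}
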