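#' Right-hand side of the two-type mean-field system
#'
#' Time derivatives of the densities of female hosts carrying the augmented
#' symbiont community (`x_plus`) and not carrying it (`x_minus`), assuming a
#' 1:1 sex ratio:
#' \deqn{\dot{x}^+ = \frac{b_0}{2}\frac{(x^+)^2(\alpha+\beta-\alpha\beta) +
#'   (\alpha+\beta) x^- x^+}{x^+ + x^-}
#'   - x^+ \frac{d_0 + 2 d' \nu (x^+ + x^-)}{w} + e_0 x^-}
#' \deqn{\dot{x}^- = \frac{b_0}{2}\frac{(x^-)^2 + (2-\alpha-\beta) x^- x^+ +
#'   (1-\alpha)(1-\beta)(x^+)^2}{x^+ + x^-}
#'   - x^- (d_0 + 2 d' \nu (x^+ + x^-)) - e_0 x^-}
#'
#' @param state Numeric vector `c(x_plus, x_minus)` of non-negative
#'   densities.
#' @param params An [ode_params()] object.
#' @return Numeric vector of the two time derivatives. Both are 0 for an
#'   extinct population (zero total density).
#' @export
rhs_two_type <- function(state, params) {
  stopifnot(inherits(params, "ode_params"), length(state) == 2L)
  xp <- state[[1L]]
  xm <- state[[2L]]
  X <- xp + xm
  if (X <= 0) return(c(0, 0))
  a <- params$alpha
  b <- params$beta
  dd <- params$d0 + 2 * params$dprime * params$nu * X
  birth_p <- params$b0 / 2 * (xp^2 * (a + b - a * b) + (a + b) * xm * xp) / X
  birth_m <- params$b0 / 2 *
    (xm^2 + (2 - a - b) * xm * xp + (1 - a) * (1 - b) * xp^2) / X
  c(birth_p - xp * dd / params$w + params$e0 * xm,
    birth_m - xm * dd - params$e0 * xm)
}

#' Boundary equilibrium I: symbiont absent
#'
#' The symbiont-free equilibrium of the two-type system (requires
#' `e0 = 0`): \eqn{\hat{x}^- = (b_0/2 - d_0)/(2 d' \nu)}, \eqn{\hat{x}^+ = 0}.
#' With the default parameters this is 500 females, i.e. 1000 hosts in
#' total under the 1:1 sex ratio.
#'
#' @param params An [ode_params()] object.
#' @return Named vector `c(x_plus = 0, x_minus = ...)`. The corresponding
#'   total host count is attached as attribute `total_hosts`
#'   (`2 * nu * x_minus`).
#' @export
equilibrium_I <- function(params) {
  stopifnot(inherits(params, "ode_params"))
  xm <- (params$b0 / 2 - params$d0) / (2 * params$dprime * params$nu)
  if (xm < 0) stop("host population not viable: b0/2 < d0")
  structure(c(x_plus = 0, x_minus = xm),
            total_hosts = 2 * params$nu * xm)
}

#' Boundary equilibrium II: symbiont carried by every host
#'
#' \eqn{\hat{x}^+ = (w b_0/2 - d_0)/(2 d' \nu)}, \eqn{\hat{x}^- = 0},
#' independent of the transmission mode. The carrier density reaches zero —
#' host extinction caused by the symbiont — at \eqn{w_1 = 2 d_0 / b_0}.
#'
#' @inheritParams equilibrium_I
#' @return Named vector `c(x_plus = ..., x_minus = 0)` with attribute
#'   `total_hosts`.
#' @export
equilibrium_II <- function(params) {
  stopifnot(inherits(params, "ode_params"))
  xp <- (params$w * params$b0 / 2 - params$d0) / (2 * params$dprime * params$nu)
  if (xp < 0) stop("host population not viable at equilibrium II: w b0/2 < d0")
  structure(c(x_plus = xp, x_minus = 0),
            total_hosts = 2 * params$nu * xp)
}

#' Initial per-capita growth rate of carriers at equilibrium I
#'
#' The per-capita rate of increase of carrier hosts when the symbiont is
#' rare at the symbiont-free equilibrium:
#' \eqn{(b_0/2)\,[(\alpha + \beta) - 1/w]}, which specialises to
#' \eqn{b_0 (1 - 1/(2w))} for biparental and \eqn{(b_0/2)(1 - 1/w)} for
#' maternal transmission. Its sign change defines the invasion threshold
#' \eqn{w_0 = 1/(\alpha + \beta)}.
#'
#' @inheritParams equilibrium_I
#' @param mode Optional transmission mode (preset name or
#'   [transmission_params()]) overriding `alpha`, `beta` in `params`.
#' @return Signed per-capita rate.
#' @examples
#' invasion_rate_at_I(ode_params(w = 0.5), "biparental") # 0
#' invasion_rate_at_I(ode_params(w = 1), "maternal")     # 0
#' @export
invasion_rate_at_I <- function(params, mode = NULL) {
  stopifnot(inherits(params, "ode_params"))
  params <- .ode_with_mode(params, mode)
  if (params$w <= 0) stop("`w` must be positive")
  params$b0 / 2 * ((params$alpha + params$beta) - 1 / params$w)
}

#' Invasion and extinction thresholds of the two-type system
#'
#' @inheritParams equilibrium_I
#' @return Named vector with `w0_biparental = 1/2` (invasion threshold under
#'   biparental transmission), `w0_maternal = 1`, and the host-extinction
#'   threshold `w1 = 2 d0 / b0` at which the all-carrier equilibrium density
#'   reaches zero. `w1` does not involve `dprime` or `nu`.
#' @examples
#' ode_thresholds(ode_params()) # 0.5, 1, 0.5
#' @export
ode_thresholds <- function(params) {
  stopifnot(inherits(params, "ode_params"))
  if (params$b0 == 0) stop("`b0` must be positive for the extinction threshold")
  c(w0_biparental = 0.5, w0_maternal = 1, w1 = 2 * params$d0 / params$b0)
}

# --- Dormand-Prince 5(4) adaptive integrator -------------------------------
#
# deSolve is not available in this environment, so the package carries its
# own embedded Runge-Kutta pair. Non-stiff use only; the systems here have
# O(1) rates except for strongly deleterious carriers (1/w large), which the
# step controller handles by shrinking h.

.DP_A <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
.DP_B5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.DP_B4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)

#' Integrate an ODE system with adaptive error control
#'
#' Dormand-Prince 5(4) embedded Runge-Kutta integration with proportional
#' step-size control. Densities that undershoot zero by less than `10 *
#' atol` are clamped to zero (solver rounding); larger excursions raise a
#' warning before clamping.
#'
#' @param f Right-hand side, called as `f(state, params)`.
#' @param y0 Initial state (named vectors keep their names in the output).
#' @param t_span `c(t0, t1)`.
#' @param params Passed through to `f`.
#' @param t_eval Optional times at which the solution is reported (steps
#'   land exactly on them); by default every accepted step is reported.
#' @param rtol,atol Relative and absolute local error tolerances.
#' @param h0 Initial step (default `diff(t_span)/1e4`).
#' @param hmax Maximum step.
#' @param max_steps Step cap; exceeding it is an error with diagnostics.
#' @param converge_tol If non-NULL, stop early once the state is stationary
#'   to this tolerance, `max(abs(f(y)) / (1 + abs(y)))  < converge_tol`
#'   (density-scaled, since the absolute derivative cannot drop below the
#'   integrator's own discretisation floor at large densities); used for
#'   long-run outcome classification.
#' @return List with `t`, `y` (matrix, one row per reported time) and
#'   `converged` (TRUE if `converge_tol` was met).
#' @export
ode_integrate <- function(f, y0, t_span, params = NULL, t_eval = NULL,
                          rtol = 1e-8, atol = 1e-10, h0 = NULL, hmax = Inf,
                          max_steps = 5e5, converge_tol = NULL) {
  stopifnot(length(t_span) == 2L, t_span[2L] >= t_span[1L])
  if (any(y0 < 0)) stop("initial state must be non-negative")
  t <- t_span[1L]
  tend <- t_span[2L]
  y <- as.numeric(y0)
  d <- length(y)
  h <- if (is.null(h0)) max((tend - t) / 1e4, 1e-8) else h0
  use_eval <- !is.null(t_eval)
  if (use_eval) {
    t_eval <- sort(t_eval)
    ts <- numeric(length(t_eval))
    ys <- matrix(NA_real_, length(t_eval), d)
    ie <- 1L
    while (ie <= length(t_eval) && t_eval[ie] <= t + 1e-14) {
      ts[ie] <- t_eval[ie]
      ys[ie, ] <- y
      ie <- ie + 1L
    }
  } else {
    ts <- t
    ys <- matrix(y, 1L, d)
  }
  converged <- FALSE
  warned <- FALSE
  k <- matrix(0, 7L, d)
  steps <- 0L
  while (t < tend - 1e-14) {
    if (steps >= max_steps)
      stop(sprintf("ode_integrate: step cap reached at t = %g (h = %g)", t, h))
    h <- min(h, hmax, tend - t)
    if (use_eval && ie <= length(t_eval)) h <- min(h, t_eval[ie] - t)
    k[1L, ] <- f(y, params)
    for (s in 1:6) {
      ynew <- y + h * drop(.DP_A[[s]] %*% k[seq_len(s), , drop = FALSE])
      k[s + 1L, ] <- f(ynew, params)
    }
    y5 <- y + h * drop(.DP_B5 %*% k)
    y4 <- y + h * drop(.DP_B4 %*% k)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    steps <- steps + 1L
    if (err <= 1 || h <= 1e-12) {
      t <- t + h
      y <- y5
      neg <- y < 0
      if (any(neg)) {
        if (any(y < -10 * atol) && !warned) {
          warning(sprintf("state clamped at 0 (min %.3g) during integration",
                          min(y)))
          warned <- TRUE
        }
        y[neg] <- 0
      }
      if (use_eval) {
        while (ie <= length(t_eval) && t_eval[ie] <= t + 1e-12) {
          ts[ie] <- t_eval[ie]
          ys[ie, ] <- y
          ie <- ie + 1L
        }
      } else {
        ts <- c(ts, t)
        ys <- rbind(ys, y)
      }
      if (!is.null(converge_tol) &&
          max(abs(f(y, params)) / (1 + abs(y))) < converge_tol) {
        converged <- TRUE
        break
      }
    }
    fac <- if (err > 0) 0.9 * err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
  }
  if (use_eval && converged && ie <= length(t_eval)) {
    # early convergence: remaining requested times hold the converged state
    for (j in ie:length(t_eval)) {
      ts[j] <- t_eval[j]
      ys[j, ] <- y
    }
  }
  colnames(ys) <- names(y0)
  list(t = ts, y = ys, converged = converged)
}

#' Integrate the two-type system
#'
#' Convenience wrapper around [ode_integrate()] for [rhs_two_type()].
#'
#' @inheritParams ode_integrate
#' @param state0 Initial `c(x_plus, x_minus)`.
#' @param params An [ode_params()] object.
#' @param mode Optional transmission mode overriding `alpha`, `beta`.
#' @return Data frame with `t`, `x_plus`, `x_minus`.
#' @export
integrate_two_type <- function(state0, params, t_span, mode = NULL,
                               t_eval = NULL, rtol = 1e-8, atol = 1e-10) {
  params <- .ode_with_mode(params, mode)
  sol <- ode_integrate(rhs_two_type, setNames(state0, c("x_plus", "x_minus")),
                       t_span, params, t_eval = t_eval,
                       rtol = rtol, atol = atol)
  data.frame(t = sol$t, x_plus = sol$y[, 1L], x_minus = sol$y[, 2L])
}
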