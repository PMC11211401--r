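.REGION_LABELS <- c("loss", "fixation", "bimorphic", "host_extinction",
                    "unresolved")

#' Long-run outcome of a symbiont invasion in the two-type system
#'
#' Integrates the two-type mean-field system from the invasion initial
#' condition — the symbiont-free equilibrium with a small carrier density
#' added (`x_plus = init_frac * x_minus_hat`) — until the state is
#' stationary to tolerance or `t_cap` is reached, and labels the outcome:
#' \describe{
#'   \item{`"loss"`}{carriers vanish (`x_plus < eps`); only possible at
#'     `e0 = 0`, where the symbiont-free state is invariant (the degenerate
#'     limit `w = 0`, in which carriers never persist, is also labelled
#'     loss when the hosts survive).}
#'   \item{`"fixation"`}{non-carriers vanish.}
#'   \item{`"bimorphic"`}{an interior state with both types present,
#'     sustained by horizontal uptake.}
#'   \item{`"host_extinction"`}{total density below `eps`, or a converged
#'     state carrying less than `extinct_density` (one host at `nu = 1`) —
#'     marginal dynamics can stall at sub-individual densities whose
#'     biological meaning is extinction.}
#'   \item{`"unresolved"`}{`t_cap` reached without convergence.}
#' }
#'
#' @param params An [ode_params()] object (its `w`, `e0`, `alpha`, `beta`
#'   are used).
#' @param mode Optional transmission mode overriding `alpha`, `beta`.
#' @param init_frac Carrier perturbation as a fraction of the equilibrium
#'   non-carrier density.
#' @param eps Density treated as zero for type labels.
#' @param conv_tol Stationarity tolerance: converged when
#'   `|d/dt| < conv_tol * (1 + density)` componentwise (density-scaled
#'   because the absolute derivative at an attractor cannot drop below the
#'   integrator's discretisation floor at densities of order 100-1000).
#' @param t_cap Integration horizon.
#' @param extinct_density Converged total densities below this count as
#'   host extinction (see Details above).
#' @param engine `"C"` (compiled, default) or `"R"` (via
#'   [ode_integrate()]); both apply identical rules.
#' @param rtol,atol Integrator tolerances.
#' @return The label, a character scalar, with the terminal state and time
#'   attached as attributes `state` and `t`.
#' @examples
#' classify_outcome(ode_params(w = 0.37, e0 = 0.1), "biparental") # bimorphic
#' @export
classify_outcome <- function(params, mode = NULL, init_frac = 0.01,
                             eps = 1e-6, conv_tol = 1e-8, t_cap = 1e4,
                             extinct_density = 1, engine = c("C", "R"),
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "ode_params"))
  engine <- match.arg(engine)
  params <- .ode_with_mode(params, mode)
  if (engine == "C") {
    res <- classify_two_cpp(params$b0, params$d0, params$dprime, params$nu,
                            params$e0, params$alpha, params$beta, params$w,
                            init_frac, eps, conv_tol, t_cap, extinct_density,
                            rtol, atol)
    return(structure(.REGION_LABELS[res$label],
                     state = setNames(res$state, c("x_plus", "x_minus")),
                     t = res$t))
  }
  xI <- unname(equilibrium_I(.ode_with_mode(params, NULL))["x_minus"])
  if (xI <= 0) return(structure("host_extinction", state = c(x_plus = 0, x_minus = 0), t = 0))
  y0 <- c(x_plus = init_frac * xI, x_minus = xI)
  sol <- ode_integrate(rhs_two_type, y0, c(0, t_cap), params,
                       rtol = rtol, atol = atol, hmax = 50,
                       converge_tol = conv_tol)
  y <- sol$y[nrow(sol$y), ]
  X <- sum(y)
  lab <- if (X < eps) {
    "host_extinction"
  } else if (sol$converged) {
    if (X < extinct_density) "host_extinction"
    else if (y[["x_minus"]] < eps) "fixation"
    else if (y[["x_plus"]] < eps) "loss"
    else "bimorphic"
  } else {
    if (X < extinct_density) "host_extinction"
    else if (y[["x_minus"]] < eps) "fixation"
    else if (y[["x_plus"]] < eps) "loss"
    else "unresolved"
  }
  structure(lab, state = y, t = sol$t[length(sol$t)])
}

#' Phase diagram of invasion outcomes over a (w, e0) grid
#'
#' Runs [classify_outcome()] at every node of a rectangular grid in the
#' carrier fitness effect `w` and the horizontal uptake rate `e0`.
#'
#' @param w_grid,e0_grid Strictly increasing coordinate vectors.
#' @param mode Transmission mode (`"biparental"` or `"maternal"`, or a
#'   [transmission_params()] object).
#' @param params Baseline [ode_params()]; its `w` and `e0` are overridden
#'   by the grid, `alpha`/`beta` by `mode`.
#' @param refine Number of bisection refinements of each region boundary
#'   along `w` (0 disables refinement).
#' @inheritParams classify_outcome
#' @return An object of class `phase_diagram`: list with `w`, `e0`, the
#'   label matrix `labels` (`length(w_grid)` by `length(e0_grid)`,
#'   character), `mode`, and — when refinement is requested — a
#'   `boundaries` data frame of refined boundary points
#'   (`e0`, `w_lo`, `w_hi`, `from`, `to`) forming polylines between
#'   regions.
#' @export
phase_scan <- function(w_grid, e0_grid, mode = "biparental",
                       params = ode_params(), refine = 0,
                       init_frac = 0.01, eps = 1e-6, conv_tol = 1e-8,
                       t_cap = 1e4, extinct_density = 1) {
  stopifnot(all(diff(w_grid) > 0), all(diff(e0_grid) >= 0))
  p <- .ode_with_mode(params, mode)
  labs <- classify_grid_cpp(w_grid, e0_grid, p$b0, p$d0, p$dprime, p$nu,
                            p$alpha, p$beta, init_frac, eps, conv_tol,
                            t_cap, extinct_density, 1e-8, 1e-10)
  labels <- matrix(.REGION_LABELS[labs], nrow = length(w_grid))
  out <- list(w = w_grid, e0 = e0_grid, labels = labels,
              mode = if (is.character(mode)) mode else "custom")
  if (refine > 0) {
    cls1 <- function(w, e0) {
      pp <- p
      pp$w <- w
      pp$e0 <- e0
      as.character(classify_outcome(pp, NULL, init_frac, eps, conv_tol,
                                    t_cap, extinct_density))
    }
    rows <- list()
    for (j in seq_along(e0_grid)) {
      for (i in seq_len(length(w_grid) - 1L)) {
        l1 <- labels[i, j]
        l2 <- labels[i + 1L, j]
        if (l1 == l2) next
        lo <- w_grid[i]
        hi <- w_grid[i + 1L]
        for (r in seq_len(refine)) {
          mid <- (lo + hi) / 2
          if (cls1(mid, e0_grid[j]) == l1) lo <- mid else hi <- mid
        }
        rows[[length(rows) + 1L]] <-
          data.frame(e0 = e0_grid[j], w_lo = lo, w_hi = hi,
                     from = l1, to = l2, stringsAsFactors = FALSE)
      }
    }
    out$boundaries <- if (length(rows)) do.call(rbind, rows) else
      data.frame(e0 = numeric(0), w_lo = numeric(0), w_hi = numeric(0),
                 from = character(0), to = character(0))
  }
  structure(out, class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("phase_diagram (%s): %d x %d grid, w in [%g, %g], e0 in [%g, %g]\n",
              x$mode, length(x$w), length(x$e0),
              min(x$w), max(x$w), min(x$e0), max(x$e0)))
  print(table(x$labels))
  invisible(x)
}

#' @export
as.data.frame.phase_diagram <- function(x, ...) {
  data.frame(w = rep(x$w, times = length(x$e0)),
             e0 = rep(x$e0, each = length(x$w)),
             mode = x$mode,
             label = as.vector(x$labels),
             stringsAsFactors = FALSE)
}
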