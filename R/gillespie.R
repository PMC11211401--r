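#' Instantaneous event rates of a population state
#'
#' The total event rate decomposes into birth (rate `b0` per female while at
#' least one male is present, otherwise zero), one death channel per
#' occupied class (`count * (d0 + dprime * n) / w_eff`), and horizontal
#' uptake of the focal taxon (`e0` per current non-carrier).
#'
#' @param state A `sym_population`.
#' @param dp A [demography_params()] object.
#' @return A list with `birth`, `death` (vector, one per class-table row),
#'   `uptake` and `total`.
#' @examples
#' st <- population_state(rep(c("F", "M"), each = 500), integer(1000))
#' event_rates(st, demography_params())$total # 4*500 + 2*1000 = 4000
#' @export
event_rates <- function(state, dp) {
  stopifnot(inherits(state, "sym_population"), inherits(dp, "demography_params"))
  cl <- state$classes
  n <- sum(cl$count)
  nF <- sum(cl$count[cl$sex == 0L])
  nM <- n - nF
  weff <- vapply(cl$mask, .mask_weff, numeric(1), w_list = state$w_list)
  death <- cl$count * (dp$d0 + dp$dprime * n) / weff
  birth <- if (nM > 0) dp$b0 * nF else 0
  uptake <- dp$e0 * sum(cl$count[bitwAnd(cl$mask, 1L) == 0L])
  list(birth = birth, death = death, uptake = uptake,
       total = birth + sum(death) + uptake)
}

#' Advance a population state by one Gillespie event
#'
#' Samples an exponential waiting time from the total rate, then applies a
#' single event chosen with probability proportional to its rate: a birth
#' (random mother among females, random father among males, newborn sex 1:1,
#' carriage by the vertical-transmission rule, sons inheriting the father's
#' Y-linked allele), a death, or a horizontal-uptake conversion of one
#' non-carrier. Uses the current R RNG stream.
#'
#' @inheritParams event_rates
#' @return A list with the updated `state`, the `event` label (`"birth"`,
#'   `"death"`, `"uptake"` or `"extinct"`), and the waiting time `dt`. For a
#'   death the affected class row is reported as `class`.
#' @export
gillespie_step <- function(state, dp) {
  stopifnot(inherits(state, "sym_population"), inherits(dp, "demography_params"))
  cl <- state$classes
  if (sum(cl$count) == 0L)
    return(list(state = state, event = "extinct", dt = 0, class = NA_integer_))
  rates <- event_rates(state, dp)
  dt <- -log(runif(1)) / rates$total
  r <- runif(1) * rates$total
  event <- NULL
  class_hit <- NA_integer_
  if (r < rates$birth) {
    event <- "birth"
    nF <- sum(cl$count[cl$sex == 0L])
    nM <- sum(cl$count[cl$sex == 1L])
    mi <- .pick_class(cl, cl$sex == 0L, runif(1) * nF)
    fi <- .pick_class(cl, cl$sex == 1L, runif(1) * nM)
    csex <- if (runif(1) < 0.5) 0L else 1L
    cmask <- bitwOr(cl$mask[mi],
                    if (cl$allele[fi] == .ALLELE_MPLUS) cl$mask[fi] else 0L)
    callele <- if (csex == 1L) cl$allele[fi] else .ALLELE_NONE
    cl <- .bump_class(cl, csex, callele, cmask, +1L)
  } else {
    r <- r - rates$birth
    di <- NA_integer_
    for (i in seq_len(nrow(cl))) {
      if (r < rates$death[i]) { di <- i; break }
      r <- r - rates$death[i]
    }
    if (!is.na(di)) {
      event <- "death"
      class_hit <- di
      cl$count[di] <- cl$count[di] - 1L
    } else {
      event <- "uptake"
      noncar <- bitwAnd(cl$mask, 1L) == 0L
      ui <- .pick_class(cl, noncar, runif(1) * sum(cl$count[noncar]))
      class_hit <- ui
      cl$count[ui] <- cl$count[ui] - 1L
      cl <- .bump_class(cl, cl$sex[ui], cl$allele[ui], bitwOr(cl$mask[ui], 1L), +1L)
    }
  }
  state$classes <- cl
  state$t <- state$t + dt
  list(state = state, event = event, dt = dt, class = class_hit)
}

# pick a class row among rows satisfying `sel`, proportional to count
.pick_class <- function(cl, sel, r) {
  idx <- which(sel & cl$count > 0L)
  for (i in idx) {
    if (r < cl$count[i]) return(i)
    r <- r - cl$count[i]
  }
  idx[length(idx)]
}

.bump_class <- function(cl, s, a, m, by) {
  hit <- which(cl$sex == s & cl$allele == a & cl$mask == m)
  if (length(hit)) {
    cl$count[hit[1L]] <- cl$count[hit[1L]] + by
  } else {
    cl <- rbind(cl, data.frame(sex = s, allele = a, mask = m, count = by))
  }
  cl
}

.OUTCOMES <- c("loss", "fixation", "host_extinction", "timeout")

#' Run one realisation of the stochastic birth-death process
#'
#' Repeats Gillespie steps until the focal symbiont is lost (only at
#' `e0 = 0`, where absence is absorbing) or fixed, the host population goes
#' extinct, or `t_max` is reached. In multi-taxon mode (more than one taxon
#' in the pool) the run instead terminates when the population becomes
#' monomorphic in carriage sets. The trajectory is sampled on a regular time
#' grid plus a final row at the termination time.
#'
#' @param state Initial `sym_population` (see [init_single()],
#'   [init_modifier()], [init_multitaxon()], [population_state()]).
#' @param dp A [demography_params()] object.
#' @param t_max Time horizon.
#' @param record_dt Trajectory sampling interval.
#' @param seed Optional integer seed applied before simulating; with a seed
#'   the realisation is fully reproducible.
#' @param engine `"C"` (compiled, default) or `"R"` (pure-R reference).
#'   Both consume the identical RNG stream and give identical trajectories.
#' @param record_taxa Also record per-taxon carrier counts at each sample
#'   time.
#' @param termination `"auto"` (multi-taxon rule when the pool has more than
#'   one taxon), `"single"`, `"multitaxon"`, or `"none"` (run to `t_max`
#'   regardless of carriage, e.g. for pure demography).
#' @param max_events Safety cap on the number of events.
#' @return An object of class `realisation_result`: a list with `outcome`
#'   (one of `"loss"`, `"fixation"`, `"host_extinction"`, `"timeout"`),
#'   `t_end`, `trajectory` (data frame with columns `t`, `n`, `n_female`,
#'   `n_plus`, male class counts `m_mm`, `m_mp`, `m_pm`, `m_pp`
#'   (allele M-/M+ crossed with non-carrier/carrier), derived `p_carrier`,
#'   `mminus_freq` and disequilibrium `D`, and per-taxon counts when
#'   requested), `final` (the class table, whose rows record every carriage
#'   combination ever observed), `seed` and `events`.
#' @export
run_realisation <- function(state, dp, t_max = 200, record_dt = 0.5,
                            seed = NULL, engine = c("C", "R"),
                            record_taxa = FALSE,
                            termination = c("auto", "single", "multitaxon", "none"),
                            max_events = 1e8) {
  stopifnot(inherits(state, "sym_population"), inherits(dp, "demography_params"))
  engine <- match.arg(engine)
  termination <- match.arg(termination)
  term_mode <- switch(termination,
    auto = if (state$n_taxa > 1L) 1L else 0L,
    single = 0L,
    multitaxon = 1L,
    none = 2L
  )
  if (!is.null(seed)) set.seed(seed)
  cl <- state$classes
  fn <- if (engine == "C") sim_gillespie_cpp else .sim_gillespie_r
  raw <- fn(cl$sex, cl$allele, cl$mask, cl$count, state$w_list,
            dp$b0, dp$d0, dp$dprime, dp$e0, t_max, record_dt,
            term_mode, record_taxa, max_events)
  traj <- as.data.frame(raw$trajectory)
  nm <- c("t", "n", "n_female", "n_plus", "m_mm", "m_mp", "m_pm", "m_pp")
  if (record_taxa) nm <- c(nm, paste0("taxon_", seq_len(state$n_taxa)))
  names(traj) <- nm
  n_male <- traj$m_mm + traj$m_mp + traj$m_pm + traj$m_pp
  traj$p_carrier <- ifelse(traj$n > 0, traj$n_plus / traj$n, NA_real_)
  traj$mminus_freq <- ifelse(n_male > 0, (traj$m_mm + traj$m_mp) / n_male, NA_real_)
  traj$D <- ifelse(n_male > 0,
                   (traj$m_mm * traj$m_pp - traj$m_mp * traj$m_pm) / n_male^2,
                   NA_real_)
  final <- data.frame(sex = raw$sex, allele = raw$allele,
                      mask = raw$mask, count = raw$count)
  structure(list(outcome = .OUTCOMES[raw$outcome],
                 t_end = raw$t_end, trajectory = traj, final = final,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 events = raw$events, n_taxa = state$n_taxa,
                 w_list = state$w_list),
            class = "realisation_result")
}

#' @export
print.realisation_result <- function(x, ...) {
  fin <- x$final[x$final$count > 0L, ]
  cat(sprintf("realisation_result: %s at t = %.3f (%d hosts, %s events)\n",
              x$outcome, x$t_end, sum(fin$count),
              format(x$events, big.mark = ",")))
  invisible(x)
}

#' Coefficient of disequilibrium between modifier allele and carriage
#'
#' Over the four male classes with frequencies `p1` (M-, non-carrier),
#' `p2` (M-, carrier), `p3` (M+, non-carrier) and `p4` (M+, carrier),
#' `D = p1 p4 - p2 p3` measures the association between the
#' transmission-modifier allele and symbiont status: positive when the
#' symbiont is under-represented in M- males, negative when
#' over-represented. `D` is bounded by \[-0.25, 0.25\].
#'
#' @param allele Character vector (`"Mminus"`/`"Mplus"`) or integer codes
#'   (1/2), one per male; alternatively a length-4 numeric vector of class
#'   counts `(n1, n2, n3, n4)` if `carrier` is missing.
#' @param carrier Logical vector, `TRUE` for carriers.
#' @return `D`, with the class frequencies attached as attribute `p`.
#' @examples
#' disequilibrium_D(c(0.4, 0.1, 0.2, 0.3)) # 0.4*0.3 - 0.1*0.2 = 0.1
#' @export
disequilibrium_D <- function(allele, carrier) {
  if (missing(carrier)) {
    counts <- as.numeric(allele)
    if (length(counts) != 4L || any(counts < 0))
      stop("expected a length-4 vector of non-negative male class counts")
  } else {
    if (length(allele) == 0L) stop("D is undefined for an empty male set")
    if (is.character(allele)) allele <- ifelse(allele == "Mminus", 1L, 2L)
    counts <- c(sum(allele == 1L & !carrier), sum(allele == 1L & carrier),
                sum(allele == 2L & !carrier), sum(allele == 2L & carrier))
  }
  tot <- sum(counts)
  if (tot == 0) stop("D is undefined for an empty male set")
  p <- counts / tot
  structure(p[1L] * p[4L] - p[2L] * p[3L],
            p = setNames(p, c("p1", "p2", "p3", "p4")))
}
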