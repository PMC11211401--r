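#' Run an ensemble of independent stochastic realisations
#'
#' Executes one of the standard protocols many times with per-realisation
#' seeds split from a single root seed (so the ensemble is reproducible and
#' order-independent):
#' \describe{
#'   \item{`"sieve"`}{one focal taxon per realisation with a fresh fitness
#'     effect drawn from the truncated normal pool ([sample_w()]), introduced
#'     into `carriers` hosts; records which fitness effects reach fixation
#'     under each transmission mode.}
#'   \item{`"fixed"`}{as `"sieve"` but with a fixed, supplied `w`.}
#'   \item{`"multitaxon"`}{`n_taxa` taxa with freshly drawn effects, each
#'     independently inoculated into `inoculated` hosts; runs until the
#'     population is monomorphic in carriage sets or `t_max`.}
#'   \item{`"modifier"`}{one focal taxon with fixed `w`; males carry the
#'     Y-linked modifier M- (suppressing male transmission) with initial
#'     frequency `mminus_frac`, M+ otherwise.}
#' }
#'
#' @param protocol One of `"sieve"`, `"fixed"`, `"multitaxon"`,
#'   `"modifier"`.
#' @param mode `"biparental"` or `"maternal"` (ignored for `"modifier"`,
#'   where the mating-level mode is set by the father's allele).
#' @param n_reps Number of independent realisations.
#' @param seed Root seed; per-realisation seeds are drawn from it.
#' @param n_hosts Founder population size.
#' @param dp A [demography_params()] object.
#' @param carriers Initial carriers of the focal taxon (single-taxon
#'   protocols).
#' @param t_max Time horizon per realisation.
#' @param w Fitness effect for `"fixed"` and `"modifier"`; optional fixed
#'   pool (vector) for `"multitaxon"`.
#' @param w_dist Parameters of the truncated normal fitness pool, a list
#'   with `mean`, `sd`, `lo`, `hi`.
#' @param n_taxa,inoculated Multi-taxon protocol: number of taxa and hosts
#'   inoculated per taxon.
#' @param mminus_frac Initial fraction of M- males (modifier protocol).
#' @param record_dt Trajectory sampling interval.
#' @param engine `"C"` or `"R"`.
#' @param keep_trajectories Attach the per-realisation trajectories as
#'   attribute `"trajectories"`.
#' @param exact_split Use an exact 1:1 founder sex split.
#' @return A data frame with one row per realisation: `rep`, `seed`,
#'   `mode`, `outcome`, `t_end`, `n_final`, `n_plus_final`, plus
#'   protocol-specific columns (`w`; for `"modifier"`: `mminus_final`,
#'   `mminus_fixed`, `d_max`; for `"multitaxon"`: `w_best`,
#'   `modal_mask`, `modal_n_taxa`, `modal_is_best_single`, `new_combos`).
#' @export
run_ensemble <- function(protocol = c("sieve", "fixed", "multitaxon", "modifier"),
                         mode = c("biparental", "maternal"),
                         n_reps = 100, seed = 1,
                         n_hosts = 1000, dp = demography_params(),
                         carriers = 10, t_max = 200,
                         w = NULL,
                         w_dist = list(mean = 1, sd = 0.3, lo = 0, hi = 2.5),
                         n_taxa = 20, inoculated = 50, mminus_frac = 0.1,
                         record_dt = 0.5, engine = "C",
                         keep_trajectories = FALSE, exact_split = FALSE) {
  protocol <- match.arg(protocol)
  mode <- match.arg(mode)
  if (protocol %in% c("fixed", "modifier") && is.null(w))
    stop(sprintf("protocol '%s' needs a fixed `w`", protocol))
  set.seed(seed)
  seeds <- sample.int(2147483646L, n_reps)

  rows <- vector("list", n_reps)
  trajs <- if (keep_trajectories) vector("list", n_reps) else NULL
  for (i in seq_len(n_reps)) {
    set.seed(seeds[i])
    wi <- NA_real_
    extra <- NULL
    if (protocol == "sieve") {
      wi <- sample_w(1, w_dist$mean, w_dist$sd, w_dist$lo, w_dist$hi)
      st <- init_single(n_hosts, carriers, wi, mode, exact_split)
    } else if (protocol == "fixed") {
      wi <- w
      st <- init_single(n_hosts, carriers, wi, mode, exact_split)
    } else if (protocol == "modifier") {
      wi <- w
      st <- init_modifier(n_hosts, carriers, wi, mminus_frac, exact_split)
    } else {
      wl <- if (is.null(w)) {
        sample_w(n_taxa, w_dist$mean, w_dist$sd, w_dist$lo, w_dist$hi)
      } else w
      st <- init_multitaxon(n_hosts, wl, inoculated, mode, exact_split)
      wi <- max(wl)
    }
    res <- run_realisation(st, dp, t_max = t_max, record_dt = record_dt,
                           engine = engine,
                           record_taxa = protocol == "multitaxon")
    fin <- res$final[res$final$count > 0L, ]
    n_final <- sum(fin$count)
    n_plus_final <- sum(fin$count[bitwAnd(fin$mask, 1L) == 1L])
    row <- data.frame(rep = i, seed = seeds[i],
                      mode = if (protocol == "modifier") "modifier" else mode,
                      w = wi, outcome = res$outcome, t_end = res$t_end,
                      n_final = n_final, n_plus_final = n_plus_final,
                      stringsAsFactors = FALSE)
    if (protocol == "modifier") {
      males <- fin$sex == 1L
      n_male <- sum(fin$count[males])
      row$mminus_final <- if (n_male > 0)
        sum(fin$count[males & fin$allele == .ALLELE_MMINUS]) / n_male else NA_real_
      row$mminus_fixed <- isTRUE(row$mminus_final == 1)
      row$symbiont_lost <- res$outcome == "loss"
      row$d_max <- suppressWarnings(max(res$trajectory$D, na.rm = TRUE))
    }
    if (protocol == "multitaxon") {
      # modal carriage set over hosts, resolving ties by first occurrence
      by_mask <- tapply(fin$count, fin$mask, sum)
      modal <- as.integer(names(by_mask)[which.max(by_mask)])
      best_taxon <- which.max(st$w_list)
      row$w_best <- max(st$w_list)
      row$modal_mask <- modal
      row$modal_n_taxa <- sum(bitwAnd(modal, bitwShiftL(1L, seq_len(st$n_taxa) - 1L)) != 0L)
      row$modal_is_best_single <- modal == bitwShiftL(1L, best_taxon - 1L)
      init_masks <- unique(st$classes$mask)
      observed <- unique(res$final$mask) # every class ever instantiated
      row$new_combos <- any(!(observed %in% init_masks))
    }
    rows[[i]] <- row
    if (keep_trajectories) trajs[[i]] <- res$trajectory
  }
  out <- do.call(rbind, rows)
  attr(out, "root_seed") <- seed
  if (keep_trajectories) attr(out, "trajectories") <- trajs
  out
}

#' Ensemble mean of recorded trajectories on a common time grid
#'
#' Averages a list of realisation trajectories over replicates at each time
#' of a regular grid, carrying the last recorded state forward for
#' realisations that terminated early.
#'
#' @param trajs List of trajectory data frames (attribute `"trajectories"`
#'   of [run_ensemble()] output).
#' @param t_grid Times at which to average.
#' @param cols Columns to average.
#' @return Data frame with `t`, the across-replicate mean of each column,
#'   and its standard error (`se_<col>`).
#' @export
ensemble_mean_trajectory <- function(trajs, t_grid,
                                     cols = c("p_carrier", "mminus_freq")) {
  n_reps <- length(trajs)
  out <- data.frame(t = t_grid)
  for (cc in cols) {
    vals <- vapply(trajs, function(tr) {
      idx <- findInterval(t_grid + 1e-9, tr$t)
      idx[idx < 1L] <- 1L
      tr[[cc]][idx]
    }, numeric(length(t_grid)))
    vals <- matrix(vals, nrow = length(t_grid))
    out[[cc]] <- rowMeans(vals, na.rm = TRUE)
    out[[paste0("se_", cc)]] <- apply(vals, 1L, function(v)
      stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  }
  out
}
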