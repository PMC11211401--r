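# Host population state for the stochastic simulator.
#
# Individuals are exchangeable within a class defined by (sex, Y-linked
# modifier allele, symbiont carriage set), so the state is stored as a class
# table rather than one record per host. Carriage sets are integer bitmasks
# over the taxa (taxon i <-> bit i-1); the focal taxon for horizontal uptake
# and for fixation/loss bookkeeping is taxon 1 (bit 0). Allele codes:
# 0 = none (females), 1 = M- (suppresses male transmission, maternal
# matings), 2 = M+ (allows male transmission, biparental matings).
# Transmission through the mother is always present. Class-table rows are
# never removed once created (counts may drop to zero), so the table also
# records every carriage combination ever observed in a realisation.

.ALLELE_NONE <- 0L
.ALLELE_MMINUS <- 1L
.ALLELE_MPLUS <- 2L

# mean fitness effect of a carriage bitmask; 1 for the empty set
.mask_weff <- function(mask, w_list) {
  if (mask == 0L) return(1)
  bits <- which(bitwAnd(mask, bitwShiftL(1L, seq_along(w_list) - 1L)) != 0L)
  mean(w_list[bits])
}

#' Host fitness effect of a carriage set
#'
#' The combined effect of the carried symbiont taxa on a host is the
#' arithmetic mean of the per-taxon fitness effects `w_i` over the taxa
#' present; a host with no added symbionts has effect exactly 1 (its death
#' rate is unmodified).
#'
#' @param carriage Integer vector of carried taxon indices (1-based), or an
#'   integer bitmask if `bitmask = TRUE`.
#' @param w_list Numeric vector of positive per-taxon fitness effects.
#' @param bitmask Interpret `carriage` as a bitmask rather than indices.
#' @return A single positive number.
#' @examples
#' host_fitness_effect(integer(0), 0.6)        # 1
#' host_fitness_effect(c(1, 2), c(0.5, 1.5))   # 1
#' @export
host_fitness_effect <- function(carriage, w_list, bitmask = FALSE) {
  if (any(w_list <= 0)) stop("all fitness effects must be positive")
  if (bitmask) return(.mask_weff(as.integer(carriage), w_list))
  if (length(carriage) == 0L) return(1)
  carriage <- as.integer(carriage)
  if (any(carriage < 1L) || any(carriage > length(w_list)))
    stop("carriage indices outside the taxon pool")
  mean(w_list[unique(carriage)])
}

#' Per-capita death rate of a host
#'
#' Death has a logistic component common to all hosts,
#' `d0 + dprime * n` with `n` the current population size, and the whole
#' rate is divided by the host's fitness effect `w`: carriers of beneficial
#' symbionts (`w > 1`) die more slowly, carriers of deleterious ones
#' (`w < 1`) more quickly.
#'
#' @inheritParams host_fitness_effect
#' @param n Current total host count (at least 1).
#' @param dp A [demography_params()] object.
#' @return Non-negative death rate.
#' @examples
#' death_rate(integer(0), 1000, demography_params(), 0.6) # 2
#' death_rate(1, 1000, demography_params(), 0.6)          # 2 / 0.6
#' @export
death_rate <- function(carriage, n, dp, w_list, bitmask = FALSE) {
  stopifnot(inherits(dp, "demography_params"))
  if (n < 1) stop("`n` must be at least 1")
  (dp$d0 + dp$dprime * n) / host_fitness_effect(carriage, w_list, bitmask)
}

#' Carriage set of a newborn host
#'
#' Applies the per-taxon vertical transmission rule: under biparental
#' transmission the newborn carries a taxon if either parent carries it
#' (set union); under maternal transmission the newborn's carriage is a copy
#' of the mother's.
#'
#' @param mother,father Integer vectors of carried taxon indices.
#' @param mode `"biparental"` or `"maternal"`.
#' @return Sorted integer vector of the newborn's carried taxa.
#' @examples
#' offspring_carriage(c(1, 2), c(2, 3), "biparental") # 1 2 3
#' offspring_carriage(integer(0), 1, "maternal")      # integer(0)
#' @export
offspring_carriage <- function(mother, father, mode = c("biparental", "maternal")) {
  mode <- match.arg(mode)
  out <- if (mode == "biparental") union(mother, father) else mother
  sort(as.integer(out))
}

#' Construct a host population state from per-individual vectors
#'
#' Low-level constructor. Individuals with identical (sex, allele, carriage)
#' are aggregated into classes; class order is the order of first appearance,
#' which the simulation engines preserve.
#'
#' @param sex Character (`"F"`/`"M"`) or integer (0 = female, 1 = male)
#'   vector, one entry per host.
#' @param mask Integer carriage bitmasks, one per host (taxon i is bit
#'   i - 1).
#' @param allele Modifier alleles for males: `"Mminus"`/`"Mplus"` (or codes
#'   1/2). Females must have `NA`, `"none"` or 0. Default: all males
#'   `"Mplus"`.
#' @param w_list Positive per-taxon fitness effects; its length sets the
#'   number of taxa.
#' @param t Initial time.
#' @return An object of class `sym_population`: a list with the class table
#'   (`classes`), current time `t`, `n_taxa` and `w_list`.
#' @export
population_state <- function(sex, mask, allele = NULL, w_list = 1, t = 0) {
  if (is.character(sex)) sex <- ifelse(toupper(sex) == "M", 1L, 0L)
  sex <- as.integer(sex)
  mask <- as.integer(mask)
  if (length(mask) != length(sex)) stop("`sex` and `mask` lengths differ")
  if (any(w_list <= 0)) stop("all fitness effects must be positive")
  n_taxa <- length(w_list)
  if (any(mask < 0L) || any(mask >= bitwShiftL(1L, n_taxa)))
    stop("carriage mask refers to taxa outside the pool")
  if (is.null(allele)) {
    allele <- ifelse(sex == 1L, .ALLELE_MPLUS, .ALLELE_NONE)
  } else if (is.character(allele)) {
    allele <- match(allele, c("none", "Mminus", "Mplus")) - 1L
    allele[is.na(allele)] <- .ALLELE_NONE
  }
  allele <- as.integer(allele)
  allele[is.na(allele)] <- .ALLELE_NONE
  if (any(sex == 0L & allele != .ALLELE_NONE))
    stop("females carry no Y-linked modifier allele")
  if (any(sex == 1L & !(allele %in% c(.ALLELE_MMINUS, .ALLELE_MPLUS))))
    stop("males must carry allele Mminus or Mplus")

  key <- paste(sex, allele, mask)
  first <- !duplicated(key)
  idx <- match(key, key[first])
  classes <- data.frame(
    sex = sex[first],
    allele = allele[first],
    mask = mask[first],
    count = as.integer(tabulate(idx, nbins = sum(first)))
  )
  structure(list(t = as.numeric(t), classes = classes,
                 n_taxa = n_taxa, w_list = as.numeric(w_list)),
            class = "sym_population")
}

#' @export
print.sym_population <- function(x, ...) {
  cnt <- pop_counts(x)
  cat(sprintf("sym_population at t = %g: %d hosts (%d female), %d carrying taxon 1, %d taxa\n",
              x$t, cnt["n"], cnt["n_female"], cnt["n_plus"], x$n_taxa))
  cls <- x$classes[x$classes$count > 0L, ]
  cat(sprintf("  %d occupied classes\n", nrow(cls)))
  invisible(x)
}

#' Summary counts of a population state
#'
#' @param state A `sym_population`.
#' @return Named integer vector with `n`, `n_female`, `n_male`, `n_plus`
#'   (carriers of the focal taxon 1) and `n_minus`.
#' @export
pop_counts <- function(state) {
  cl <- state$classes
  n <- sum(cl$count)
  nf <- sum(cl$count[cl$sex == 0L])
  np <- sum(cl$count[bitwAnd(cl$mask, 1L) == 1L])
  c(n = n, n_female = nf, n_male = n - nf, n_plus = np, n_minus = n - np)
}

# sexes for n founders: random 1:1, or an exact split (variance reduction)
.draw_sexes <- function(n, exact_split) {
  if (exact_split) {
    sex <- rep(c(0L, 1L), length.out = n)
    sample(sex)
  } else {
    as.integer(runif(n) < 0.5) # 1 = male
  }
}

#' Initial population for the single-taxon invasion protocol
#'
#' `n` founder hosts, each female or male with probability 1/2 (or an exact
#' 1:1 split), with the focal symbiont introduced into `carriers` hosts
#' chosen uniformly without replacement irrespective of sex. The
#' transmission mode is encoded through the male modifier allele: all males
#' carry M+ under `"biparental"` and M- under `"maternal"`.
#'
#' @param n Number of founder hosts.
#' @param carriers Number of initial carriers of the focal taxon.
#' @param w Fitness effect of the focal taxon.
#' @param mode `"biparental"` or `"maternal"`.
#' @param exact_split Use an exact 1:1 sex split instead of binomial
#'   sampling.
#' @return A `sym_population`.
#' @export
init_single <- function(n, carriers, w, mode = c("biparental", "maternal"),
                        exact_split = FALSE) {
  mode <- match.arg(mode)
  if (carriers > n) stop("more carriers than hosts")
  sex <- .draw_sexes(n, exact_split)
  mask <- integer(n)
  if (carriers > 0) mask[sample.int(n, carriers)] <- 1L
  allele <- ifelse(sex == 1L,
                   if (mode == "biparental") .ALLELE_MPLUS else .ALLELE_MMINUS,
                   .ALLELE_NONE)
  population_state(sex, mask, allele, w_list = w)
}

#' Initial population for the modifier-gene protocol
#'
#' As [init_single()], but males carry the transmission-suppressing allele
#' M- with probability `mminus_frac` and M+ otherwise, so vertical
#' transmission starts predominantly biparental.
#'
#' @inheritParams init_single
#' @param mminus_frac Initial fraction of males carrying M-.
#' @return A `sym_population`.
#' @export
init_modifier <- function(n, carriers, w, mminus_frac = 0.1,
                          exact_split = FALSE) {
  .check_prob(mminus_frac, "mminus_frac")
  if (carriers > n) stop("more carriers than hosts")
  sex <- .draw_sexes(n, exact_split)
  mask <- integer(n)
  if (carriers > 0) mask[sample.int(n, carriers)] <- 1L
  allele <- integer(n)
  males <- which(sex == 1L)
  allele[males] <- ifelse(runif(length(males)) < mminus_frac,
                          .ALLELE_MMINUS, .ALLELE_MPLUS)
  population_state(sex, mask, allele, w_list = w)
}

#' Initial population for the multi-taxon inoculation protocol
#'
#' Each of the `length(w_list)` symbiont taxa is independently inoculated
#' into `inoculated` hosts chosen uniformly without replacement, so most
#' inoculated hosts start with a single taxon and a few with more.
#'
#' @inheritParams init_single
#' @param w_list Per-taxon fitness effects (one per taxon).
#' @param inoculated Number of hosts inoculated with each taxon.
#' @param mode Transmission mode applied population-wide.
#' @return A `sym_population`.
#' @export
init_multitaxon <- function(n, w_list, inoculated,
                            mode = c("biparental", "maternal"),
                            exact_split = FALSE) {
  mode <- match.arg(mode)
  if (inoculated > n) stop("more inoculated hosts than hosts")
  if (length(w_list) > 30L) stop("at most 30 taxa supported (bitmask storage)")
  sex <- .draw_sexes(n, exact_split)
  mask <- integer(n)
  for (i in seq_along(w_list)) {
    chosen <- sample.int(n, inoculated)
    mask[chosen] <- bitwOr(mask[chosen], bitwShiftL(1L, i - 1L))
  }
  allele <- ifelse(sex == 1L,
                   if (mode == "biparental") .ALLELE_MPLUS else .ALLELE_MMINUS,
                   .ALLELE_NONE)
  population_state(sex, mask, allele, w_list = w_list)
}
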