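# Independent oracles used across the suite.

# Offspring carriage probability per mating class by brute-force enumeration
# of the two independent parental transmission events.
enum_offspring_pS <- function(alpha, beta) {
  pS <- function(p_mother_transmits, p_father_transmits) {
    total <- 0
    for (mt in c(TRUE, FALSE)) for (ft in c(TRUE, FALSE)) {
      pr <- (if (mt) p_mother_transmits else 1 - p_mother_transmits) *
            (if (ft) p_father_transmits else 1 - p_father_transmits)
      if (mt || ft) total <- total + pr
    }
    total
  }
  # mother listed first: s x s, S x s, s x S, S x S
  c(pS(0, 0), pS(alpha, 0), pS(0, beta), pS(alpha, beta))
}

# Mean fitness as the fitness-weighted offspring mass over Table-style
# mating classes (mating frequencies under random mating).
enum_mean_fitness <- function(p, w, alpha, beta) {
  q <- 1 - p
  freq <- c(q^2, p * q, p * q, p^2)
  pS <- enum_offspring_pS(alpha, beta)
  sum(freq * (w * pS + (1 - pS)))
}

# Invasion threshold by bisection on the sign of the frequency change at
# rarity (p = 1e-6).
bisect_threshold <- function(tp, lo = 1e-3, hi = 1e3, tol = 1e-9) {
  f <- function(w) delta_p(1e-6, w, tp)
  stopifnot(f(lo) < 0, f(hi) > 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Small deterministic population state for engine tests.
make_small_state <- function(n = 40, carriers = 8, w = 0.7,
                             mode = "biparental", seed = 7) {
  set.seed(seed)
  init_single(n, carriers, w, mode)
}
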