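# Pure-R reference implementation of the Gillespie engine.
#
# This mirrors src/gillespie.cpp line for line, consuming the R RNG stream
# through the identical sequence of uniform draws, so that for a given seed
# the two engines produce identical trajectories. It exists as a readable
# specification of the event rules and as the target of engine-equality
# tests; production ensembles use the compiled engine.

.sim_gillespie_r <- function(sex, allele, mask, count, w_list,
                             b0, d0, dprime, e0,
                             t_max, record_dt,
                             term_mode, record_taxa, max_events = 1e8) {
  n_taxa <- length(w_list)
  count <- as.numeric(count)
  weff <- vapply(mask, .mask_weff, numeric(1), w_list = w_list)

  ncol_rec <- 8L + if (record_taxa) n_taxa else 0L
  nrcap <- floor(t_max / record_dt) + 3L
  traj <- matrix(NA_real_, nrcap, ncol_rec)
  irec <- 0L

  rec <- function(tt) {
    if (irec >= nrcap) return(invisible())
    occ <- count > 0
    n <- sum(count[occ])
    car <- bitwAnd(mask, 1L) == 1L
    nF <- sum(count[occ & sex == 0L])
    nplus <- sum(count[occ & car])
    m <- numeric(4)
    for (j in 1:4) {
      al <- if (j <= 2) .ALLELE_MMINUS else .ALLELE_MPLUS
      cr <- j %% 2 == 0
      m[j] <- sum(count[occ & sex == 1L & allele == al & car == cr])
    }
    row <- c(tt, n, nF, nplus, m)
    if (record_taxa) {
      tax <- vapply(seq_len(n_taxa), function(k) {
        sum(count[occ & bitwAnd(mask, bitwShiftL(1L, k - 1L)) != 0L])
      }, numeric(1))
      row <- c(row, tax)
    }
    irec <<- irec + 1L
    traj[irec, ] <<- row
    invisible()
  }

  term_check <- function() {
    occ <- count > 0
    n <- sum(count[occ])
    if (n == 0) return(3L)
    if (term_mode == 2L) return(0L)
    if (term_mode == 1L) {
      um <- unique(mask[occ])
      if (length(um) == 1L) return(if (um == 0L) 1L else 2L)
      return(0L)
    }
    nplus <- sum(count[occ & bitwAnd(mask, 1L) == 1L])
    if (nplus == n) return(2L)
    if (nplus == 0 && e0 == 0) return(1L)
    0L
  }

  find_or_add <- function(s, a, m) {
    hit <- which(sex == s & allele == a & mask == m)
    if (length(hit)) return(hit[1L])
    sex <<- c(sex, s)
    allele <<- c(allele, a)
    mask <<- c(mask, m)
    count <<- c(count, 0)
    weff <<- c(weff, .mask_weff(m, w_list))
    length(sex)
  }

  t <- 0; t_end <- 0; k <- 1; events <- 0
  outcome <- term_check()
  rec(0)

  while (outcome == 0L) {
    occ <- count > 0
    n <- sum(count[occ])
    nF <- sum(count[occ & sex == 0L])
    nM <- n - nF
    nnoncar <- sum(count[occ & bitwAnd(mask, 1L) == 0L])
    B <- if (nM > 0) b0 * nF else 0
    dpc <- d0 + dprime * n
    Dc <- count * dpc / weff
    sumD <- sum(Dc)
    U <- e0 * nnoncar
    Rtot <- B + sumD + U
    if (!(Rtot > 0)) { outcome <- 4L; t_end <- t; break }

    u1 <- runif(1)
    tnew <- t - log(u1) / Rtot
    tstop <- min(tnew, t_max)
    while (k * record_dt <= tstop) {
      rec(k * record_dt)
      k <- k + 1
    }
    if (tnew >= t_max) {
      outcome <- 4L
      t_end <- t_max
      if (irec == 0L || traj[irec, 1L] < t_max) rec(t_max)
      break
    }
    t <- tnew

    u2 <- runif(1)
    r <- u2 * Rtot
    if (r < B) {
      rm <- runif(1) * nF
      mi <- -1L
      for (i in seq_along(count)) {
        if (sex[i] != 0L || count[i] <= 0) next
        if (rm < count[i]) { mi <- i; break }
        rm <- rm - count[i]
      }
      if (mi < 0L) mi <- max(which(sex == 0L & count > 0))
      rf <- runif(1) * nM
      fi <- -1L
      for (i in seq_along(count)) {
        if (sex[i] != 1L || count[i] <= 0) next
        if (rf < count[i]) { fi <- i; break }
        rf <- rf - count[i]
      }
      if (fi < 0L) fi <- max(which(sex == 1L & count > 0))
      csex <- if (runif(1) < 0.5) 0L else 1L
      cmask <- bitwOr(mask[mi],
                      if (allele[fi] == .ALLELE_MPLUS) mask[fi] else 0L)
      callele <- if (csex == 1L) allele[fi] else 0L
      idx <- find_or_add(csex, callele, cmask)
      count[idx] <- count[idx] + 1
    } else {
      r <- r - B
      di <- -1L
      for (i in seq_along(count)) {
        if (r < Dc[i]) { di <- i; break }
        r <- r - Dc[i]
      }
      if (di > 0L) {
        count[di] <- count[di] - 1
      } else if (U > 0 && nnoncar > 0) {
        ru <- runif(1) * nnoncar
        ui <- -1L
        for (i in seq_along(count)) {
          if (bitwAnd(mask[i], 1L) == 1L || count[i] <= 0) next
          if (ru < count[i]) { ui <- i; break }
          ru <- ru - count[i]
        }
        if (ui < 0L) ui <- max(which(bitwAnd(mask, 1L) == 0L & count > 0))
        count[ui] <- count[ui] - 1
        idx <- find_or_add(sex[ui], allele[ui], bitwOr(mask[ui], 1L))
        count[idx] <- count[idx] + 1
      } else {
        i <- max(which(count > 0))
        count[i] <- count[i] - 1
      }
    }

    events <- events + 1
    if (events >= max_events) { outcome <- 4L; t_end <- t; break }
    outcome <- term_check()
    if (outcome != 0L) {
      t_end <- t
      if (irec == 0L || traj[irec, 1L] < t) rec(t)
      break
    }
  }

  list(outcome = outcome, t_end = t_end,
       trajectory = traj[seq_len(irec), , drop = FALSE],
       sex = as.integer(sex), allele = as.integer(allele),
       mask = as.integer(mask), count = as.integer(round(count)),
       events = events)
}
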