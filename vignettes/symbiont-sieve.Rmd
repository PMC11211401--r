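---
title: "Methods: vertical transmission models and the symbiont sieve"
author: "symsieve developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertical transmission models and the symbiont sieve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symsieve)
```

# The question

A host population acquires a new microbial symbiont that changes the fitness
of hosts carrying it by a factor $w$ (relative to hosts without it; the
package implements this as a $1/w$ multiplier on the host death rate, so
$w > 1$ is beneficial and $w < 1$ deleterious). Whether the symbiont can
invade depends decisively on the host's mode of *vertical* transmission.
When either parent transmits ("biparental"), a rare symbiont — whose
carriers almost always mate with non-carriers — is passed to offspring from
twice as many matings as under maternal-only transmission. That twofold
boost lets deleterious symbionts with $1/2 < w < 1$ invade. Maternal
transmission removes the boost and acts as a *sieve*: only $w > 1$ invades.
The package provides three mutually consistent model layers for this
question, plus the selection the sieve generates on host
transmission-modifier genes.

# Layer 1: the discrete-generation recursion

Hosts carry either the augmented symbiont community (frequency $p$) or the
resident one ($q = 1-p$). With random mating, transmission probabilities
$\alpha$ (mother) and $\beta$ (father), and carrier relative fitness $w$,
the next-generation frequency is
$$p' = \frac{p\,w}{\bar w}\,(\alpha + \beta - \alpha\beta p), \qquad
\bar w = 1 - p(1-w)(\alpha+\beta-\alpha\beta p),$$
giving
$$\Delta p = \frac{p}{\bar w}\left(\phi\,(p + wq) - 1\right),
\qquad \phi = \alpha+\beta-\alpha\beta p .$$
At rarity ($p \to 0^+$) the sign of $\Delta p$ flips at the invasion
threshold $w_0 = 1/(\alpha+\beta)$: $1/2$ biparental, $1$ maternal.

Assumptions: discrete non-overlapping generations, infinite population (no
drift), no sex-specific bookkeeping beyond $\alpha,\beta$, no horizontal
uptake. `next_frequency()` clips to $[0,1]$ only within $10^{-12}$ of the
boundary; any larger excursion is treated as a bug and raises an error
rather than being silently clipped. `invasion_threshold()` returns the
closed form; the test suite confirms it against an independent bisection on
the sign of `delta_p()` at $p = 10^{-6}$. When $\alpha = \beta = 0$ there is
no vertical route at all and the threshold is undefined; the package raises
a distinct error instead of returning infinity. Long-run classification
(`recursion_fate()`) declares absorption within $10^{-6}$ of 0 or 1, with a
default cap of $10^4$ generations.

# Layer 2: the stochastic birth–death process

`run_realisation()` simulates a continuous-time, sex-structured host
population by the exact Gillespie algorithm. Events and rates:

* **Birth**, total rate $b_0 \times (\#\text{females})$ while at least one
  male is present (a random father is required; there is no asexual
  fallback, so an all-female population only declines). Mother and father
  are uniform among their sexes, the newborn is female or male with
  probability $1/2$, and carriage is set per taxon: under biparental rules
  the newborn carries a taxon iff either parent does (set union); under
  maternal rules it copies the mother. Sons inherit the father's Y-linked
  modifier allele.
* **Death** of host $i$ at rate $(d_0 + d'n)/w_i$, where $n$ is the current
  population size and $w_i$ the mean fitness effect over the taxa host $i$
  carries (exactly 1 for empty carriage). The $1/w$ factor divides the
  *whole* rate, including the density-dependent part, matching the
  mean-field death term $(d_0 + 2d'\nu(x^+{+}\,x^-))/w$.
* **Horizontal uptake** of the focal taxon by a uniform non-carrier, total
  rate $e_0 \times (\#\text{non-carriers})$ (only the focal taxon is taken
  up; multi-taxon uptake is out of scope).

Parameters and defaults (`demography_params()`): $b_0 = 4$ births per
female per unit time, $d_0 = 1$, $d' = 0.001$ per host, $e_0 = 0$. The
symbiont-free equilibrium is $(b_0/2 - d_0)/d' = 1000$ hosts (daughters are
produced at $b_0/2$ per female). Time is measured in units of the intrinsic
death rate.

Transmission modes are encoded uniformly through the male allele: in plain
biparental (maternal) populations every male carries M+ (M−); in modifier
experiments males carry M− with some initial frequency. The association
between allele and carriage is summarised by the disequilibrium coefficient
$D = p_1p_4 - p_2p_3$ over the four male classes (M−/M+ crossed with
non-carrier/carrier), computable via `disequilibrium_D()`.

Implementation notes. The population is stored as a class table over (sex,
allele, carriage bitmask) — individuals within a class are exchangeable, so
this is exact, and the table's rows double as a record of every carriage
combination ever observed (rows are never deleted). Event selection is a
single uniform draw against the cumulative rate vector in class-table order
with no priority ordering. The production engine is compiled (Rcpp) but
draws all randomness from R's RNG; a line-for-line pure-R engine consumes
the identical draw sequence, and the test suite asserts byte-level
trajectory agreement between the two on biparental, maternal, modifier and
multi-taxon cases. Realisations terminate at focal-taxon loss (only when
$e_0 = 0$, where absence is absorbing), fixation, host extinction, or
`t_max`; multi-taxon runs terminate when the population is monomorphic in
carriage sets. Ensembles draw per-realisation seeds from a root seed, so
they are reproducible and order-independent.

## What the generator emulates, and what it does not

The fitness-effect pool (`sample_w()`) is a normal distribution with mean 1
and standard deviation 0.3 truncated to $[0, 2.5]$ (rejection sampling; the
bounds sit 3.3 and 5 standard deviations out, so the truncation shifts the
mean by well under $10^{-3}$). It emulates a stream of candidate symbionts
centred on neutrality with realistic deleterious and beneficial tails. It
does **not** model within-host dynamics, interactions between taxa (the
combined effect on a host is the plain mean of per-taxon effects),
microbiome evolution, direct host-to-host infection, or spatial/age
structure. A green sieve test therefore establishes the population-genetic
filtering effect of the transmission mode — nothing about microbial
ecology inside hosts.

## Finite-population caveats

Three drift effects matter at desk scales and are deliberately left visible
rather than patched over:

* Within roughly $|w - 1| \lesssim$ a few times $1/N_e$ of neutrality,
  fixation is governed by drift, not the sieve; in a 200-host population
  occasional *slightly* deleterious symbionts fix under maternal
  transmission. Every clearly deleterious symbiont is still sieved.
* Below the biparental threshold ($w < 1/2$) drift can still push a
  symbiont transiently into *all* hosts of a small, collapsing population;
  such "fixations" are demographically non-viable (the all-carrier
  equilibrium is negative) and end in host extinction when continued. The
  tests assert exactly that.
* Selection on the modifier allele is second order — it acts through the
  association $D$ — and drift attenuates $D$, so the stochastic M− sweep
  lags its deterministic counterpart at carrying capacity 1000. The
  ensemble mean converges to the six-type solution as the population grows.

# Layer 3: mean-field differential equations

Assuming a 1:1 sex ratio, the two-type system tracks female densities
$x^+$ (carriers) and $x^-$:
$$\dot x^+ = \frac{b_0}{2}\,
\frac{(x^+)^2(\alpha{+}\beta{-}\alpha\beta) + (\alpha{+}\beta)x^-x^+}{x^++x^-}
 - x^+\,\frac{d_0 + 2d'\nu(x^++x^-)}{w} + e_0x^-,$$
$$\dot x^- = \frac{b_0}{2}\,
\frac{(x^-)^2 + (2{-}\alpha{-}\beta)x^-x^+ + (1{-}\alpha)(1{-}\beta)(x^+)^2}{x^++x^-}
 - x^-\left(d_0 + 2d'\nu(x^++x^-)\right) - e_0x^-.$$
With the default scaling $\nu = 1$, densities are female counts and
$2d'\nu(x^++x^-)$ equals $d'\times$(total hosts), so equilibrium I
($\hat x^- = (b_0/2-d_0)/(2d'\nu)$, 500 females = 1000 hosts at the default
parameters) matches the stochastic model. Equilibrium II
($\hat x^+ = (wb_0/2-d_0)/(2d'\nu)$) exists whenever at least one parent
transmits with certainty ($\alpha = 1$ or $\beta = 1$ — true for every mode
used here; otherwise the all-carrier state leaks non-carrier offspring at
rate $(1-\alpha)(1-\beta)$). Its density reaches zero at the extinction
threshold $w_1 = 2d_0/b_0$. The per-capita carrier growth rate at
equilibrium I is $(b_0/2)\,[(\alpha+\beta) - 1/w]$, specialising to
$b_0(1 - 1/2w)$ (biparental) and $(b_0/2)(1-1/w)$ (maternal).

The six-type modifier system adds male densities $y^\pm$ (M−) and $z^\pm$
(M+): M− fathers sire maternal-rule offspring, M+ fathers biparental-rule
offspring, every non-carrier class takes up the focal symbiont at rate
$e_0$, and death is $(d_0 + d'\nu N)/w^{\text{carrier}}$ with $N$ the total
over all six types. The female birth terms are normalised by the male
density total and the male birth terms by the female total; these coincide
under the 1:1 ratio the reduction assumes, and the package implements the
equations in exactly that printed form rather than symmetrising them.

## Numerical choices

No ODE solver package is available in the supported environment, so the
package carries a Dormand–Prince 5(4) adaptive integrator
(`ode_integrate()`, default `rtol` $10^{-8}$, `atol` $10^{-10}$), plus a
compiled copy hard-wired to the two-type system for grid scans. Densities
that undershoot zero within solver tolerance are clamped to zero; larger
excursions warn.

Long-run classification (`classify_outcome()`) integrates from the invasion
initial condition — equilibrium I plus carriers at 1% of $\hat x^-$ — and
stops when the state is stationary to tolerance. Stationarity is judged by
the *density-scaled* criterion $|\dot y_i| < 10^{-8}(1 + |y_i|)$: an
absolute criterion at $10^{-8}$ is unattainable because an adaptive
integrator at `rtol` $10^{-8}$ leaves a derivative floor of order $10^{-6}$
at an attractor when densities are of order $10^2$–$10^3$. Labels use
$\varepsilon = 10^{-6}$ for "a type is absent" (`loss` is only reachable at
$e_0 = 0$, where the symbiont-free axis is invariant), and a converged
state with total density below one host (at $\nu = 1$) is labelled
`host_extinction`: exactly marginal parameter rows (e.g. $e_0 = 1$ with the
defaults) decay algebraically and stall at sub-individual densities whose
biological meaning is extinction. The integration horizon is $10^4$ time
units; non-convergence is reported as `unresolved`, never silently
relabelled. The degenerate limit $w = 0$ (carriers die instantly) is
classified analytically: carriers never persist and the non-carrier
population survives iff $b_0/2 > d_0 + e_0$. Phase scans default to the
0.01-step grid with optional bisection refinement of region boundaries
along $w$.

On weakly damped spiral cells the stationarity test is razor-edged: the
compiled and R classification paths can disagree by `unresolved` versus the
true label while agreeing on the terminal state to three decimals. The test
suite accepts exactly that disagreement and no other.

# Design choices on genuinely open points

* **Initial modifier frequency.** The modifier experiment starts M− "at a
  low frequency"; no published value exists. The package default is 0.2:
  in the deterministic six-type race at $w = 0.6$ the symbiont fixes and
  the sweep stalls for starting frequencies below about 0.15, while from
  0.2 the mean field reproduces the published dynamics (M− to fixation,
  symbiont eliminated). Both the initial frequency and the initial
  carrier count (default 10, matching the single-taxon protocols) are
  plain arguments.
* **Founder composition.** Founders are assigned sex independently with
  probability 1/2 (an exact 1:1 split is available for variance
  reduction); initial carriers are placed uniformly without regard to sex.
  The six-type default initial condition instead places all carriers among
  females (1% of them); the `trajectory` experiment builds the matched
  stochastic initial state explicitly so the overlay compares like with
  like.
* **Desk presets.** The sieve experiment scales the population to 200
  hosts ($d' = 0.005$) and 300 realisations, which preserves the sieve
  contrast. The modifier and multi-taxon desk presets keep the published
  1000-host population — the sweep probability and the survival of the
  best founder matriline degrade qualitatively in a 200-host population —
  and reduce only the replicate count. Every deviation of a preset from
  the published protocol sizes is written into the run manifest.
* **Multi-taxon termination.** Runs end when all hosts share one carriage
  set (or at `t_max`); per-taxon carrier counts can be recorded along the
  way. Under maternal rules no carriage combination absent at inoculation
  can ever be created, and the class table proves it per run.

# Known limitations

The stochastic-versus-deterministic overlay agrees within Monte-Carlo error
only as the population grows; at carrying capacity 1000 the ensemble mean
deviates measurably from the six-type solution (metastable escape toward
fixation, drift-attenuated $D$). The modifier sweep is not the majority
outcome of unconditioned realisations at the default initial conditions —
roughly half of runs lose the symbiont before it establishes, and the
stepwise path to maternal transmission (repeated partial sweeps) is the
typical route; the tests and ledger document this rather than forcing it.
No analytic bifurcation tracking is provided; stability is assessed by
forward integration from the invasion initial condition, which by
construction selects the bimorphic attractor wherever it coexists with
fixation. The supplementary milk-volume trade-off model is out of scope.
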